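#' Normalize a nucleotide sequence
#'
#' Builds a `nuc_seq` object: an uppercase DNA-alphabet string over
#' \{A,C,G,T,N\} with an alphabet tag recording whether the source was RNA.
#' Lowercase letters are uppercased (the original case is kept as a mask,
#' used downstream to annotate promoter regions), `U` is mapped to `T`, and
#' whitespace is stripped. Degenerate IUPAC codes other than `N` are
#' rejected: the screen is exact-match and silently accepting ambiguity
#' codes would change its semantics.
#'
#' @param raw single character string; nucleotide letters plus optional
#'   whitespace.
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to auto-detect (`U` present
#'   implies RNA).
#' @return A `nuc_seq`: list with `residues` (normalized string),
#'   `alphabet`, and `case_mask` (logical, `TRUE` where the source letter
#'   was uppercase).
#' @examples
#' nuc_seq("ggccaccacccc")$residues
#' nuc_seq("GGGGUGGUGGCC")$alphabet
#' @export
nuc_seq <- function(raw, alphabet = NULL) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("`raw` must be a single non-NA string")
  if (!nzchar(raw)) stop("`raw` must be non-empty")
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  ws <- grepl("[[:space:]]", chars)
  body <- chars[!ws]
  pos <- which(!ws)
  if (!length(body)) stop("`raw` contains only whitespace")
  up <- toupper(body)
  bad <- which(!(up %in% c("A", "C", "G", "T", "U", "N")))
  if (length(bad)) {
    stop(sprintf("invalid nucleotide '%s' at position %d (only A/C/G/T/U/N supported)",
                 body[bad[1L]], pos[bad[1L]]))
  }
  if (is.null(alphabet)) alphabet <- if (any(up == "U")) "RNA" else "DNA"
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  structure(
    list(residues  = chartr("U", "T", paste(up, collapse = "")),
         alphabet  = alphabet,
         case_mask = body == toupper(body)),
    class = "nuc_seq"
  )
}

#' Coerce to nuc_seq
#'
#' @param x a `nuc_seq` or a single string.
#' @param ... passed to [nuc_seq()] for character input.
#' @return a `nuc_seq`.
#' @export
as_nuc_seq <- function(x, ...) {
  if (inherits(x, "nuc_seq")) return(x)
  nuc_seq(x, ...)
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq %s, %d nt> %s\n", x$alphabet, nchar(x$residues),
              if (nchar(x$residues) > 60) paste0(substr(x$residues, 1, 57), "...")
              else x$residues))
  invisible(x)
}

#' @export
length.nuc_seq <- function(x) nchar(x$residues)

#' Watson-Crick reverse complement
#'
#' Reverse complement in the DNA alphabet; `N` maps to `N`. RNA input is
#' normalized to DNA first, so the reverse complement of an RNA segment is
#' the DNA strand it would pair with.
#'
#' @param s a `nuc_seq` or string.
#' @return a `nuc_seq` tagged DNA.
#' @examples
#' reverse_complement("GGCCACCACCCC")$residues  # "GGGGTGGTGGCC"
#' @export
reverse_complement <- function(s) {
  s <- as_nuc_seq(s)
  comp <- chartr("ACGT", "TGCA", s$residues)
  structure(
    list(residues  = paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = ""),
         alphabet  = "DNA",
         case_mask = rev(s$case_mask)),
    class = "nuc_seq"
  )
}

#' Construct a binding motif
#'
#' A motif is a DNA word plus the minimum number of contiguous matching
#' nucleotides (`min_match`) that counts as a hit. The default
#' `min_match = 10` reflects the published screening rule of at least 10
#' continuous nucleotides of the motif or its reverse complement.
#'
#' @param word DNA word (`nuc_seq` or string); must contain no `N`.
#' @param min_match integer in `[1, nchar(word)]`.
#' @param label free-text label.
#' @return a `motif` object.
#' @examples
#' motif("GGCCACCACCCC", min_match = 10)
#' @export
motif <- function(word, min_match = 10L, label = "") {
  word <- as_nuc_seq(word)
  if (grepl("N", word$residues, fixed = TRUE))
    stop("motif word must not contain N")
  min_match <- as.integer(min_match)
  if (is.na(min_match) || min_match < 1L || min_match > nchar(word$residues))
    stop(sprintf("min_match must be in [1, %d], got %s",
                 nchar(word$residues), min_match))
  structure(list(word = word, min_match = min_match, label = label),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif '%s'%s, min_match=%d>\n", x$word$residues,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              x$min_match))
  invisible(x)
}

#' Derive a DNA binding motif from an RNA segment
#'
#' Takes a 1-based inclusive sub-segment of an RNA and returns the motif
#' whose word is the DNA reverse complement of that segment — the genomic
#' sequence the RNA segment is exactly complementary to. For the 451-nt
#' lncRNA TERC, sites 25-36 (5'-GGGGUGGUGGCC-3') yield the binding motif
#' GGCCACCACCCC.
#'
#' @param rna `nuc_seq` tagged RNA (or string containing `U`).
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param min_match passed to [motif()]; default 10.
#' @param label motif label.
#' @return a `motif`.
#' @examples
#' motif_from_rna(nuc_seq("GGGGUGGUGGCC"), 1, 12)$word$residues
#' @export
motif_from_rna <- function(rna, start, end, min_match = 10L, label = "") {
  rna <- as_nuc_seq(rna)
  if (rna$alphabet != "RNA") stop("`rna` must be tagged RNA")
  n <- nchar(rna$residues)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end > n || start > end)
    stop(sprintf("coordinates out of range: need 1 <= start <= end <= %d", n))
  seg <- substr(rna$residues, start, end)
  motif(reverse_complement(nuc_seq(seg, alphabet = "DNA")),
        min_match = min_match, label = label)
}

#' Enumerate partial-match search words
#'
#' All distinct contiguous sub-words of the motif word with length between
#' `min_match` and the full word length (orientation `"forward"`), together
#' with the same enumeration over the reverse complement of the word
#' (orientation `"reverse"`). Duplicates are collapsed within an
#' orientation but a word shared by both orientations is retained once per
#' orientation tag.
#'
#' @param m a `motif`.
#' @return data.frame with columns `word`, `orientation`.
#' @export
enumerate_search_words <- function(m) {
  stopifnot(inherits(m, "motif"))
  subwords <- function(w, k_min) {
    n <- nchar(w)
    unique(unlist(lapply(k_min:n, function(k) {
      substring(w, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    })))
  }
  fw <- subwords(m$word$residues, m$min_match)
  rv <- subwords(reverse_complement(m$word)$residues, m$min_match)
  data.frame(
    word = c(fw, rv),
    orientation = rep(c("forward", "reverse"), c(length(fw), length(rv))),
    stringsAsFactors = FALSE
  )
}
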