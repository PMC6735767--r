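## The screen itself: multi-pattern exact search over the enumerated
## partial-match word set, with post-hoc maximality filtering. The word set
## is tiny (at most 2 * sum over lengths of windows), so a direct
## overlapping-occurrence search is exact, fast, and easy to compare with a
## brute-force oracle.

# Overlapping occurrences of `word` in `seq_str`; 0-based starts.
.find_occurrences <- function(seq_str, word) {
  if (nchar(word) > nchar(seq_str)) return(integer())
  m <- gregexpr(paste0("(?=", word, ")"), seq_str, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer())
  as.integer(m) - 1L
}

# Drop hits properly contained in a longer hit of the same orientation.
.maximal_filter <- function(df) {
  if (nrow(df) < 2L) return(df)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    contained <- df$orientation == df$orientation[i] &
      df$start <= df$start[i] & df$end >= df$end[i] &
      (df$end - df$start) > (df$end[i] - df$start[i])
    if (any(contained)) keep[i] <- FALSE
  }
  df[keep, , drop = FALSE]
}

#' Scan one promoter for partial motif matches
#'
#' Reports every maximal occurrence of any search word from
#' [enumerate_search_words()] in the promoter sequence. A hit is maximal if
#' it is not properly contained in another hit of the same orientation;
#' overlapping hits of opposite orientation are both reported. Coordinates
#' are 0-based half-open, both promoter-relative and TSS-relative.
#'
#' @param rec a `promoter_record`.
#' @param m a `motif`.
#' @param maximal_only if `FALSE`, nested sub-word occurrences are kept
#'   (occurrence-level output).
#' @return data.frame with columns `gene`, `start`, `end`, `orientation`,
#'   `matched_word`, `match_len`, `tss_rel_start`, `tss_rel_end`; rows
#'   ordered by (start, orientation forward-first, end).
#' @export
scan_promoter <- function(rec, m, maximal_only = TRUE) {
  stopifnot(inherits(rec, "promoter_record"), inherits(m, "motif"))
  words <- enumerate_search_words(m)
  seq_str <- rec$seq$residues
  parts <- lapply(seq_len(nrow(words)), function(i) {
    st <- .find_occurrences(seq_str, words$word[i])
    if (!length(st)) return(NULL)
    data.frame(gene = rec$gene, start = st,
               end = st + nchar(words$word[i]),
               orientation = words$orientation[i],
               matched_word = words$word[i],
               match_len = nchar(words$word[i]),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, parts)
  if (is.null(hits)) hits <- .empty_hits()
  if (maximal_only) hits <- .maximal_filter(hits)
  hits <- hits[order(hits$start,
                     match(hits$orientation, c("forward", "reverse")),
                     hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits$tss_rel_start <- hits$start - rec$tss_index
  hits$tss_rel_end <- hits$end - rec$tss_index
  hits
}

.empty_hits <- function() {
  data.frame(gene = character(), start = integer(), end = integer(),
             orientation = character(), matched_word = character(),
             match_len = integer(), stringsAsFactors = FALSE)
}

#' Scan a promoter collection
#'
#' Runs [scan_promoter()] over every record and summarizes promoter-level
#' positives: the screen's headline statistic is the number of promoters
#' with at least one hit, not the occurrence count.
#'
#' @param recs non-empty list of `promoter_record`.
#' @param m a `motif`.
#' @param maximal_only see [scan_promoter()].
#' @return a `scan_result`: list with `hits` (row-bound, input order then
#'   start), `promoters_scanned`, `promoters_with_hit`, `params`.
#' @examples
#' \dontrun{
#' res <- scan_database(load_table1_fixture(), motif("GGCCACCACCCC", 10))
#' res$promoters_with_hit  # 30
#' }
#' @export
scan_database <- function(recs, m, maximal_only = TRUE) {
  if (!is.list(recs) || length(recs) == 0L)
    stop("`recs` must be a non-empty list of promoter records")
  per <- lapply(recs, scan_promoter, m = m, maximal_only = maximal_only)
  hits <- do.call(rbind, per)
  rownames(hits) <- NULL
  structure(
    list(hits = hits,
         promoters_scanned = length(recs),
         promoters_with_hit = length(unique(hits$gene)),
         params = list(word = m$word$residues, min_match = m$min_match,
                       label = m$label, maximal_only = maximal_only)),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result: %d/%d promoters with >=1 hit (%d hits; motif %s, min_match %d)>\n",
              x$promoters_with_hit, x$promoters_scanned, nrow(x$hits),
              x$params$word, x$params$min_match))
  invisible(x)
}

#' Per-gene hit summary
#'
#' One row per gene with a hit: hit count, the best (longest, ties by
#' earliest start then forward orientation) match, the orientations seen,
#' and the TSS-relative start of the best match. Genes appear in first-hit
#' order.
#'
#' @param res a `scan_result`.
#' @return data.frame with columns `gene`, `n_hits`, `best_word`,
#'   `best_len`, `best_orientation`, `orientations`, `best_tss_rel_start`.
#' @export
summarize_hits <- function(res) {
  stopifnot(inherits(res, "scan_result"))
  h <- res$hits
  if (nrow(h) == 0L) {
    return(data.frame(gene = character(), n_hits = integer(),
                      best_word = character(), best_len = integer(),
                      best_orientation = character(),
                      orientations = character(),
                      best_tss_rel_start = integer(),
                      stringsAsFactors = FALSE))
  }
  genes <- unique(h$gene)
  rows <- lapply(genes, function(g) {
    hg <- h[h$gene == g, , drop = FALSE]
    hg <- hg[order(-hg$match_len, hg$start,
                   match(hg$orientation, c("forward", "reverse"))), ,
             drop = FALSE]
    data.frame(gene = g, n_hits = nrow(hg),
               best_word = hg$matched_word[1L],
               best_len = hg$match_len[1L],
               best_orientation = hg$orientation[1L],
               orientations = paste(sort(unique(hg$orientation)), collapse = ","),
               best_tss_rel_start = hg$tss_rel_start[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
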