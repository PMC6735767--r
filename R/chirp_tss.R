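## Distance-to-TSS annotation of chromatin-pulldown (ChIRP) fragments.
## Sign convention (documented, since published "distance to TSS" axes
## rarely state one): distances are signed relative to the gene strand,
## negative = upstream of the TSS, so a fragment 300 bp 5' of a +strand TSS
## is at -300 and the same geometry on a -strand gene is +300.

#' Read genomic intervals from BED
#'
#' Minimal validated BED reader (first 4 columns used; `#`/`track`/
#' `browser` lines skipped). Coordinates stay 0-based half-open as in BED.
#'
#' @param path BED file.
#' @return data.frame `chrom`, `start`, `end`, `id`, sorted by
#'   (chrom, start); zero rows with a warning for an empty file.
#' @export
read_intervals_bed <- function(path) {
  lines <- .read_bed_lines(path)
  if (!length(lines)) {
    warning("empty BED: ", path)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), id = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d in %s: fewer than 3 fields", i, path))
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      stop(sprintf("malformed BED line %d in %s: non-numeric coordinates", i, path))
    if (start >= end)
      stop(sprintf("zero-length or inverted interval at BED line %d in %s", i, path))
    data.frame(chrom = f[1L], start = start, end = end,
               id = if (length(f) >= 4L && nzchar(f[4L])) f[4L]
                    else sprintf("frag_%d", i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

.read_bed_lines <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
}

#' Read TSS annotations from BED or GFF
#'
#' BED input: `pos` is the interval start (column 2, already 0-based),
#' strand from column 6 (default `+`), gene from column 4. GFF input (via
#' `rtracklayer`): the TSS is the feature start on the `+` strand and the
#' feature end on the `-` strand, converted to 0-based.
#'
#' @param path input file.
#' @param format `"bed"` or `"gff"`.
#' @return data.frame `chrom`, `pos` (0-based), `strand`, `gene`, sorted
#'   by (chrom, pos).
#' @export
read_tss <- function(path, format = c("bed", "gff")) {
  format <- match.arg(format)
  if (format == "bed") {
    lines <- .read_bed_lines(path)
    if (!length(lines)) {
      warning("empty TSS file: ", path)
      return(.empty_tss())
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    out <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) < 3L)
        stop(sprintf("malformed TSS BED line %d in %s", i, path))
      pos <- suppressWarnings(as.integer(f[2L]))
      if (is.na(pos)) stop(sprintf("malformed TSS BED line %d in %s", i, path))
      strand <- if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "+"
      data.frame(chrom = f[1L], pos = pos, strand = strand,
                 gene = if (length(f) >= 4L && nzchar(f[4L])) f[4L]
                        else sprintf("tss_%d", i),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
  } else {
    md <- as.data.frame(rtracklayer::import(path))
    if (nrow(md) == 0L) {
      warning("empty TSS file: ", path)
      return(.empty_tss())
    }
    strand <- as.character(md$strand)
    strand[!strand %in% c("+", "-")] <- "+"
    gene <- if ("Name" %in% names(md) && !all(is.na(md$Name))) as.character(md$Name)
            else if ("ID" %in% names(md)) as.character(md$ID)
            else sprintf("tss_%d", seq_len(nrow(md)))
    gene[is.na(gene)] <- sprintf("tss_%d", which(is.na(gene)))
    # rtracklayer is 1-based inclusive; convert to 0-based TSS position
    pos <- ifelse(strand == "+", md$start - 1L, md$end - 1L)
    out <- data.frame(chrom = as.character(md$seqnames),
                      pos = as.integer(pos), strand = strand, gene = gene,
                      stringsAsFactors = FALSE)
  }
  if (any(out$pos < 0L)) stop("negative TSS position in ", path)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

.empty_tss <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             gene = character(), stringsAsFactors = FALSE)
}

#' Signed distance to the nearest TSS
#'
#' For each fragment, finds the TSS on the same chromosome minimizing the
#' absolute distance and reports the distance signed by gene strand
#' (negative = upstream). `measure = "midpoint"` (default) measures from
#' `floor((start + end) / 2)`; `measure = "edge"` measures from the nearest
#' fragment base (0 if the TSS falls inside the fragment). Ties on absolute
#' distance break toward the smaller TSS coordinate. Fragments on
#' chromosomes with no TSS get `NA` distance and `assigned = FALSE`.
#'
#' @param frags data.frame from [read_intervals_bed()].
#' @param tsss data.frame from [read_tss()].
#' @param measure `"midpoint"` or `"edge"`.
#' @return data.frame `id`, `chrom`, `gene`, `distance`, `assigned`.
#' @export
distance_to_nearest_tss <- function(frags, tsss, measure = c("midpoint", "edge")) {
  measure <- match.arg(measure)
  if (nrow(frags) == 0L || nrow(tsss) == 0L)
    stop("fragments and TSS annotations must both be non-empty")
  tsss <- tsss[order(tsss$chrom, tsss$pos), , drop = FALSE]
  by_chrom <- split(tsss, tsss$chrom)
  res <- lapply(seq_len(nrow(frags)), function(i) {
    chrom <- frags$chrom[i]
    tc <- by_chrom[[chrom]]
    if (is.null(tc)) {
      return(data.frame(id = frags$id[i], chrom = chrom, gene = NA_character_,
                        distance = NA_real_, assigned = FALSE,
                        stringsAsFactors = FALSE))
    }
    ref <- if (measure == "midpoint") {
      rep(floor((frags$start[i] + frags$end[i]) / 2), nrow(tc))
    } else {
      pmin(pmax(tc$pos, frags$start[i]), frags$end[i] - 1L)  # nearest base
    }
    d_gen <- ref - tc$pos
    absd <- abs(d_gen)
    j <- which(absd == min(absd))[1L]   # tc sorted by pos -> smallest pos wins
    d <- if (tc$strand[j] == "+") d_gen[j] else -d_gen[j]
    data.frame(id = frags$id[i], chrom = chrom, gene = tc$gene[j],
               distance = as.numeric(d), assigned = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bin signed TSS distances
#'
#' Histograms distances into half-open bins `[lo, hi)` built from strictly
#' increasing interior edges, extended with -Inf/+Inf flanks. The default
#' edges reproduce a conventional promoter-proximity layout: beyond -10 kb,
#' -10 to -5 kb, -5 to -1 kb, within +/-1 kb, 1-5 kb, 5-10 kb, beyond
#' +10 kb. Fractions are over assigned fragments and sum to 1.
#'
#' @param records output of [distance_to_nearest_tss()].
#' @param edges strictly increasing numeric interior edges.
#' @return data.frame `bin`, `lo`, `hi`, `count`, `fraction`.
#' @export
bin_distances <- function(records,
                          edges = c(-10000, -5000, -1000, 1000, 5000, 10000)) {
  if (any(diff(edges) <= 0)) stop("`edges` must be strictly increasing")
  full <- c(-Inf, edges, Inf)
  d <- records$distance[records$assigned]
  idx <- findInterval(d, full, left.open = FALSE)  # bins are [lo, hi)
  counts <- tabulate(idx, nbins = length(full) - 1L)
  lab <- sprintf("[%s, %s)", full[-length(full)], full[-1L])
  data.frame(bin = lab, lo = full[-length(full)], hi = full[-1L],
             count = counts,
             fraction = if (length(d)) counts / length(d) else rep(NA_real_, length(counts)),
             stringsAsFactors = FALSE)
}
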