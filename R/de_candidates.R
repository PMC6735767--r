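#' Classify differential-expression status
#'
#' Applies the literal thresholding rule used by the screen: a gene is
#' `up` iff `log2fc >= fc_threshold` and `fdr < fdr_threshold`, `down` iff
#' `log2fc <= -fc_threshold` and `fdr < fdr_threshold`, else `unchanged`.
#' The fold-change boundary is inclusive and the FDR boundary exclusive —
#' both deliberately literal and both configurable.
#'
#' @param table data.frame with columns `gene`, `log2fc`, `fdr`.
#' @param fc_threshold log2 fold-change threshold (default 2).
#' @param fdr_threshold FDR threshold (default 0.01).
#' @return the table with an added `status` column
#'   (`up`/`down`/`unchanged`).
#' @examples
#' classify_de(data.frame(gene = "G1", log2fc = 2, fdr = 0.005))$status
#' @export
classify_de <- function(table, fc_threshold = 2, fdr_threshold = 0.01) {
  need <- c("gene", "log2fc", "fdr")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(table$gene))
    stop("duplicate gene identifiers in expression table")
  if (any(is.na(table$fdr)) || any(table$fdr < 0) || any(table$fdr > 1))
    stop("fdr values must lie in [0, 1]")
  sig <- table$fdr < fdr_threshold
  table$status <- ifelse(sig & table$log2fc >= fc_threshold, "up",
                  ifelse(sig & table$log2fc <= -fc_threshold, "down",
                         "unchanged"))
  table
}

#' Read an expression-results table
#'
#' TSV or CSV with a header containing at least `gene`, `log2fc`, `fdr`.
#'
#' @param path input file.
#' @param sep field separator; default tab.
#' @return data.frame.
#' @export
read_de_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "fdr")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  tab
}

#' Nominate candidate target genes
#'
#' Intersects motif-positive promoters with the expression table and ranks
#' candidates by absolute log2 fold change (descending, ties by gene
#' name). With `require_de = TRUE` only genes classified `up`/`down`
#' survive; `top_k` optionally truncates the ranked list (the published
#' screen highlighted the top six). Gene identifiers are joined exactly
#' after uppercasing; no alias resolution is attempted.
#'
#' @param scan a `scan_result`.
#' @param de a classified expression table (see [classify_de()]); an
#'   unclassified table is classified with default thresholds.
#' @param require_de keep only `up`/`down` genes (default `TRUE`).
#' @param top_k optional integer truncation.
#' @return data.frame `gene`, `n_hits`, `best_word`, `best_len`,
#'   `best_orientation`, `log2fc`, `fdr`, `status`, `rank`.
#' @export
nominate <- function(scan, de, require_de = TRUE, top_k = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  if (!"status" %in% names(de)) de <- classify_de(de)
  hits <- summarize_hits(scan)
  hits$key <- toupper(hits$gene)
  de$key <- toupper(de$gene)
  merged <- merge(hits, de[, c("key", "log2fc", "fdr", "status")], by = "key")
  if (require_de)
    merged <- merged[merged$status != "unchanged", , drop = FALSE]
  if (nrow(merged) == 0L) {
    warning("no candidate genes after intersection")
    return(data.frame(gene = character(), n_hits = integer(),
                      best_word = character(), best_len = integer(),
                      best_orientation = character(), log2fc = numeric(),
                      fdr = numeric(), status = character(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  merged <- merged[order(-abs(merged$log2fc), merged$gene), , drop = FALSE]
  merged$rank <- seq_len(nrow(merged))
  if (!is.null(top_k)) merged <- merged[seq_len(min(top_k, nrow(merged))), ,
                                        drop = FALSE]
  rownames(merged) <- NULL
  merged[, c("gene", "n_hits", "best_word", "best_len", "best_orientation",
             "log2fc", "fdr", "status", "rank")]
}
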