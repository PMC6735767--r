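## End-to-end orchestration. Stages hand data off as plain files (BED/TSV)
## so every intermediate is inspectable and diffable, and a JSON manifest
## records parameters plus md5 checksums of all inputs and outputs so a
## rerun can be verified byte-identical. No timestamps go in the manifest:
## reruns with the same config must produce identical bytes.

#' Build a run configuration
#'
#' @param motif_word motif DNA word (default the 12-nt lncRNA binding
#'   motif GGCCACCACCCC).
#' @param min_match minimum contiguous match length (default 10).
#' @param promoters `"table1"` for the packaged 30-promoter fixture, or a
#'   FASTA path.
#' @param de_table optional path to an expression table (TSV: gene,
#'   log2fc, fdr).
#' @param fc_threshold,fdr_threshold DE thresholds (defaults 2, 0.01).
#' @param top_k optional candidate-list truncation.
#' @param require_de require DE status for candidates (default TRUE).
#' @param fragments,tss optional BED paths for fragment TSS annotation.
#' @param tss_format `"bed"` or `"gff"`.
#' @param measure distance measure, `"midpoint"` or `"edge"`.
#' @param edges interior bin edges for the distance histogram.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed recorded in the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(motif_word = "GGCCACCACCCC", min_match = 10L,
                       promoters = "table1", de_table = NULL,
                       fc_threshold = 2, fdr_threshold = 0.01,
                       top_k = NULL, require_de = TRUE,
                       fragments = NULL, tss = NULL, tss_format = "bed",
                       measure = "midpoint",
                       edges = c(-10000, -5000, -1000, 1000, 5000, 10000),
                       out_dir = "triplexscreen_out", seed = 1L) {
  cfg <- list(motif_word = motif_word, min_match = as.integer(min_match),
              promoters = promoters, de_table = de_table,
              fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
              top_k = top_k, require_de = require_de,
              fragments = fragments, tss = tss, tss_format = tss_format,
              measure = measure, edges = edges, out_dir = out_dir,
              seed = as.integer(seed))
  for (p in c(if (!identical(cfg$promoters, "table1")) cfg$promoters,
              cfg$de_table, cfg$fragments, cfg$tss)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold > 1)
    stop("fdr_threshold must be in (0, 1]")
  structure(cfg, class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  path
}

#' Run the end-to-end nomination screen
#'
#' Executes scan -> (optional) TSS annotation -> (optional) DE filter and
#' candidate nomination, writing `hits.bed`, `scan_summary.tsv`, and when
#' inputs are configured `tss_distances.tsv`, `tss_bins.tsv`,
#' `de_classified.tsv`, `candidates.tsv`, plus `manifest.json`.
#'
#' @param config a `run_config`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_screen <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- motif(config$motif_word, min_match = config$min_match)

  say("stage scan: loading promoters (", config$promoters, ")")
  recs <- if (identical(config$promoters, "table1")) load_table1_fixture()
          else read_promoter_fasta(config$promoters)
  res <- scan_database(recs, m)
  say(sprintf("stage scan: %d/%d promoters with a hit",
              res$promoters_with_hit, res$promoters_scanned))
  outputs <- character()
  outputs["hits_bed"] <- write_hits_bed(res$hits, file.path(config$out_dir, "hits.bed"))
  outputs["scan_summary"] <- .write_tsv(summarize_hits(res),
                                        file.path(config$out_dir, "scan_summary.tsv"))

  dist_rec <- NULL
  if (!is.null(config$fragments) && !is.null(config$tss)) {
    say("stage annotate-tss")
    frags <- read_intervals_bed(config$fragments)
    tsss <- read_tss(config$tss, format = config$tss_format)
    dist_rec <- distance_to_nearest_tss(frags, tsss, measure = config$measure)
    outputs["tss_distances"] <- .write_tsv(dist_rec,
                                           file.path(config$out_dir, "tss_distances.tsv"))
    outputs["tss_bins"] <- .write_tsv(bin_distances(dist_rec, config$edges),
                                      file.path(config$out_dir, "tss_bins.tsv"))
  }

  cands <- NULL
  if (!is.null(config$de_table)) {
    say("stage de-filter + nominate")
    de <- classify_de(read_de_table(config$de_table),
                      fc_threshold = config$fc_threshold,
                      fdr_threshold = config$fdr_threshold)
    outputs["de_classified"] <- .write_tsv(de, file.path(config$out_dir, "de_classified.tsv"))
    cands <- nominate(res, de, require_de = config$require_de,
                      top_k = config$top_k)
    outputs["candidates"] <- .write_tsv(cands, file.path(config$out_dir, "candidates.tsv"))
  }

  inputs <- c(if (!identical(config$promoters, "table1")) c(promoters = config$promoters),
              if (!is.null(config$de_table)) c(de_table = config$de_table),
              if (!is.null(config$fragments)) c(fragments = config$fragments),
              if (!is.null(config$tss)) c(tss = config$tss))
  manifest <- list(
    tool = "triplexscreen",
    version = as.character(utils::packageVersion("triplexscreen")),
    params = unclass(config),
    promoters_scanned = res$promoters_scanned,
    promoters_with_hit = res$promoters_with_hit,
    n_hits = nrow(res$hits),
    n_candidates = if (is.null(cands)) NA_integer_ else nrow(cands),
    inputs = if (length(inputs))
      lapply(inputs, function(p) list(path = p, md5 = unname(tools::md5sum(p))))
      else setNames(list(), character()),
    outputs = lapply(as.list(outputs),
                     function(p) list(path = p, md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  say("wrote manifest: ", manifest_path)
  invisible(list(scan = res, distances = dist_rec, candidates = cands,
                 manifest = manifest, manifest_path = manifest_path))
}
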