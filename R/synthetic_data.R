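## Synthetic inputs with exact recorded ground truth. Backgrounds are
## i.i.d. with tunable GC (not Markov genomic mimics): exactness of the
## ground truth matters more than compositional realism here, and chance
## motif hits are removed by rejection resampling rather than masking so
## sensitivity/specificity tests are exact. Every generator takes one
## explicit seed and touches no global random state (withr::with_seed).

.random_dna <- function(len, gc_fraction) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Generate promoter sequences with planted motif sub-words
#'
#' Each promoter is i.i.d. background DNA with, optionally, one motif
#' sub-word of controlled length/orientation planted at a fixed or random
#' position. After planting, the sequence is rescanned with the motif's
#' full search-word set and resampled (bounded attempts) unless every hit
#' lies inside the planted interval — so the emitted ground truth is
#' exact: a promoter has a hit iff its plant is at least `min_match` long.
#'
#' @param n number of promoters.
#' @param length sequence length (default 60, the scale of EPD-style
#'   60-mer extracts).
#' @param gc_fraction background GC content in `[0, 1]`.
#' @param m the `motif` whose sub-words are planted and screened against.
#' @param plant_spec `NULL` (no plants) or a data.frame with columns
#'   `len` (sub-word length, `<=` motif length; 0 = no plant),
#'   `orientation` (`"forward"`/`"reverse"`), `pos` (0-based start or `NA`
#'   for random); rows are recycled over promoters.
#' @param seed integer seed.
#' @param max_attempts resampling bound per promoter before failing.
#' @return list with `records` (list of `promoter_record`, genes
#'   `SYNP0001`...) and `truth` (data.frame `gene`, `planted_word`, `len`,
#'   `orientation`, `pos`, plus the seed as an attribute).
#' @export
gen_promoters <- function(n, length = 60L, gc_fraction = 0.5, m,
                          plant_spec = NULL, seed = 1L,
                          max_attempts = 1000L) {
  stopifnot(inherits(m, "motif"), n >= 1L, length >= 1L,
            gc_fraction >= 0, gc_fraction <= 1)
  if (!is.null(plant_spec)) {
    stopifnot(all(c("len", "orientation", "pos") %in% names(plant_spec)))
    if (any(plant_spec$len > nchar(m$word$residues)))
      stop("plant length exceeds motif length")
    if (any(!is.na(plant_spec$pos) &
            plant_spec$pos + plant_spec$len > length))
      stop("fixed plant position does not fit in sequence")
  }
  words <- enumerate_search_words(m)
  withr::with_seed(seed, {
    genes <- sprintf("SYNP%04d", seq_len(n))
    truth <- vector("list", n)
    records <- vector("list", n)
    for (i in seq_len(n)) {
      spec <- if (is.null(plant_spec)) NULL
              else plant_spec[((i - 1L) %% nrow(plant_spec)) + 1L, ]
      plant_len <- if (is.null(spec) || spec$len == 0L) 0L else as.integer(spec$len)
      plant_word <- NA_character_
      if (plant_len > 0L) {
        src <- if (spec$orientation == "forward") m$word$residues
               else reverse_complement(m$word)$residues
        off <- sample.int(nchar(src) - plant_len + 1L, 1L)
        plant_word <- substr(src, off, off + plant_len - 1L)
      }
      done <- FALSE
      for (att in seq_len(max_attempts)) {
        s <- .random_dna(length, gc_fraction)
        pos <- NA_integer_
        if (plant_len > 0L) {
          pos <- if (!is.na(spec$pos)) as.integer(spec$pos)
                 else sample.int(length - plant_len + 1L, 1L) - 1L
          substr(s, pos + 1L, pos + plant_len) <- plant_word
        }
        # accept iff every chance occurrence of a search word lies inside
        # the planted interval
        clean <- TRUE
        for (k in seq_len(nrow(words))) {
          occ <- .find_occurrences(s, words$word[k])
          if (!base::length(occ)) next
          wl <- nchar(words$word[k])
          inside <- plant_len > 0L & occ >= pos & (occ + wl) <= (pos + plant_len)
          if (!all(inside)) { clean <- FALSE; break }
        }
        if (clean) {
          records[[i]] <- promoter_record(genes[i], nuc_seq(s, alphabet = "DNA"),
                                          tss_rule_epd()(length),
                                          source = "synthetic")
          truth[[i]] <- data.frame(gene = genes[i], planted_word = plant_word,
                                   len = plant_len,
                                   orientation = if (plant_len > 0L) spec$orientation else NA_character_,
                                   pos = pos, stringsAsFactors = FALSE)
          done <- TRUE
          break
        }
      }
      if (!done)
        stop(sprintf("could not generate clean background for promoter %d in %d attempts",
                     i, max_attempts))
    }
    truth <- do.call(rbind, truth)
    attr(truth, "seed") <- seed
    list(records = records, truth = truth)
  })
}

#' Generate a differential-expression results table with planted truth
#'
#' Planted `up` genes draw `log2fc` uniformly in `fc_range` and `fdr` in
#' `fdr_alt_range`; `down` genes are mirrored; nulls get either
#' `|log2fc| < fc_threshold` (any fdr) or a large fold change with
#' `fdr` in `fdr_null_range`. Ranges that straddle the thresholds are
#' rejected because they would make the ground truth ambiguous.
#'
#' @param genes character vector of gene identifiers.
#' @param n_up,n_down planted counts; `n_up + n_down <= length(genes)`.
#' @param fc_range log2 fold-change magnitude range for planted genes;
#'   must sit at/above `fc_threshold`.
#' @param fdr_alt_range fdr range for planted genes; below `fdr_threshold`.
#' @param fdr_null_range fdr range for large-fc nulls; at/above
#'   `fdr_threshold`.
#' @param fc_threshold,fdr_threshold the thresholds the table is built
#'   around (defaults 2 and 0.01).
#' @param seed integer seed.
#' @return list with `table` (data.frame `gene`, `log2fc`, `fdr`) and
#'   `truth` (data.frame `gene`, `status`).
#' @export
gen_de_table <- function(genes, n_up, n_down,
                         fc_range = c(2, 6),
                         fdr_alt_range = c(1e-06, 0.009),
                         fdr_null_range = c(0.02, 0.9),
                         fc_threshold = 2, fdr_threshold = 0.01,
                         seed = 1L) {
  n <- length(genes)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (n_up + n_down > n) stop("n_up + n_down exceeds number of genes")
  if (fc_range[1] < fc_threshold)
    stop("fc_range straddles fc_threshold: ground truth would be ambiguous")
  if (fdr_alt_range[2] >= fdr_threshold)
    stop("fdr_alt_range straddles fdr_threshold")
  if (fdr_null_range[1] < fdr_threshold)
    stop("fdr_null_range straddles fdr_threshold")
  withr::with_seed(seed, {
    status <- rep("unchanged", n)
    de_idx <- sample.int(n, n_up + n_down)
    status[de_idx[seq_len(n_up)]] <- "up"
    if (n_down > 0L) status[de_idx[n_up + seq_len(n_down)]] <- "down"
    log2fc <- numeric(n); fdr <- numeric(n)
    for (i in seq_len(n)) {
      if (status[i] == "up") {
        log2fc[i] <- stats::runif(1, fc_range[1], fc_range[2])
        fdr[i] <- stats::runif(1, fdr_alt_range[1], fdr_alt_range[2])
      } else if (status[i] == "down") {
        log2fc[i] <- -stats::runif(1, fc_range[1], fc_range[2])
        fdr[i] <- stats::runif(1, fdr_alt_range[1], fdr_alt_range[2])
      } else if (stats::runif(1) < 0.5) {
        log2fc[i] <- stats::runif(1, -0.95 * fc_threshold, 0.95 * fc_threshold)
        fdr[i] <- stats::runif(1, 0, 1)
      } else {
        log2fc[i] <- stats::runif(1, -2 * fc_threshold, 2 * fc_threshold)
        fdr[i] <- stats::runif(1, fdr_null_range[1], fdr_null_range[2])
      }
    }
    truth <- data.frame(gene = genes, status = status,
                        stringsAsFactors = FALSE)
    attr(truth, "seed") <- seed
    list(table = data.frame(gene = genes, log2fc = log2fc, fdr = fdr,
                            stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate ChIRP-like fragments around known TSSs
#'
#' Fragments are centered at the TSS plus a Normal(0, `offset_sd_bp`)
#' offset measured along the gene direction (strand-signed), so the
#' planted signed offset equals the midpoint distance the annotator should
#' recover exactly. Offsets are rounded to integer base pairs.
#'
#' @param tss_list data.frame `chrom`, `pos`, `strand`, `gene` (see
#'   [read_tss()]).
#' @param n number of fragments; TSSs are sampled with replacement.
#' @param offset_sd_bp offset standard deviation in bp.
#' @param fragment_len fragment length in bp.
#' @param seed integer seed.
#' @return list with `fragments` (data.frame `chrom`, `start`, `end`,
#'   `id`) and `truth` (data.frame `id`, `gene`, `offset`).
#' @export
gen_fragments <- function(tss_list, n, offset_sd_bp = 400,
                          fragment_len = 500L, seed = 1L) {
  stopifnot(nrow(tss_list) >= 1L, n >= 1L, fragment_len >= 1L)
  withr::with_seed(seed, {
    pick <- sample.int(nrow(tss_list), n, replace = TRUE)
    offset <- as.integer(round(stats::rnorm(n, 0, offset_sd_bp)))
    tss <- tss_list[pick, , drop = FALSE]
    center <- ifelse(tss$strand == "+", tss$pos + offset, tss$pos - offset)
    start <- as.integer(center - floor(fragment_len / 2))
    if (any(start < 0L))
      stop("offsets produce negative coordinates; move TSSs further from 0")
    id <- sprintf("frag_%04d", seq_len(n))
    truth <- data.frame(id = id, gene = tss$gene, offset = offset,
                        stringsAsFactors = FALSE)
    attr(truth, "seed") <- seed
    list(fragments = data.frame(chrom = tss$chrom, start = start,
                                end = start + as.integer(fragment_len),
                                id = id, stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate a two-state melting curve
#'
#' `F(T) = baseline + amplitude / (1 + exp((T - tm) / width))` plus i.i.d.
#' Gaussian noise — a decreasing sigmoid whose inflection is the planted
#' Tm. Defaults mirror a LightCycler-style readout: 60-95 degrees C at
#' 0.2 degree C intervals.
#'
#' @param tm planted melting temperature, strictly inside `(t_lo, t_hi)`.
#' @param width transition width parameter, degrees C (> 0).
#' @param baseline,amplitude fluorescence baseline and transition
#'   amplitude, arbitrary units.
#' @param noise_sd additive Gaussian noise sd (same units as fluorescence).
#' @param t_lo,t_hi,dt temperature grid.
#' @param condition label for the curve.
#' @param seed integer seed.
#' @return list with `curve` (a `melt_curve`) and `truth` (list `tm`,
#'   `width`, `seed`).
#' @export
gen_melt_curve <- function(tm, width = 0.8, baseline = 0, amplitude = 1,
                           noise_sd = 0.01, t_lo = 60, t_hi = 95, dt = 0.2,
                           condition = "", seed = 1L) {
  if (!(t_lo < tm && tm < t_hi)) stop("tm must lie strictly inside (t_lo, t_hi)")
  if (width <= 0) stop("width must be > 0")
  temps <- seq(t_lo, t_hi, by = dt)
  withr::with_seed(seed, {
    fluor <- baseline + amplitude / (1 + exp((temps - tm) / width)) +
      stats::rnorm(length(temps), 0, noise_sd)
    list(curve = melt_curve(temps, fluor, condition = condition),
         truth = list(tm = tm, width = width, seed = seed))
  })
}
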