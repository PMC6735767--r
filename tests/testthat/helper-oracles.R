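# Independent brute-force oracles and tiny generators used across tests.
# These deliberately avoid the package's own code paths wherever the test
# compares implementation against oracle.

rand_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc_str <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# all distinct contiguous sub-words with length in [k_min, nchar(w)]
oracle_subwords <- function(w, k_min) {
  out <- character()
  for (k in k_min:nchar(w)) {
    for (i in 1:(nchar(w) - k + 1L)) out <- c(out, substr(w, i, i + k - 1L))
  }
  unique(out)
}

# brute-force window scan: every window of every length >= min_match is
# tested for being a contiguous sub-word of the motif (forward) or of its
# reverse complement (reverse); then windows properly contained in another
# kept window of the same orientation are dropped.
oracle_scan <- function(seq_str, word, min_match) {
  L <- nchar(seq_str)
  rows <- list()
  rcw <- rc_str(word)
  for (k in min_match:nchar(word)) {
    if (k > L) next
    for (i in 1:(L - k + 1L)) {
      win <- substr(seq_str, i, i + k - 1L)
      if (grepl(win, word, fixed = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(start = i - 1L, end = i - 1L + k,
                                                orientation = "forward")
      if (grepl(win, rcw, fixed = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(start = i - 1L, end = i - 1L + k,
                                                orientation = "reverse")
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      orientation = character(), stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, rows))
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i != j && df$orientation[i] == df$orientation[j] &&
          df$start[j] <= df$start[i] && df$end[j] >= df$end[i] &&
          (df$end[j] - df$start[j]) > (df$end[i] - df$start[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start, df$orientation, df$end), , drop = FALSE]
}

# all-pairs nearest-TSS oracle (signed by strand, upstream negative)
oracle_nearest <- function(frags, tsss, measure = "midpoint") {
  t(vapply(seq_len(nrow(frags)), function(i) {
    tc <- tsss[tsss$chrom == frags$chrom[i], , drop = FALSE]
    if (nrow(tc) == 0L) return(c(NA_real_, NA_real_))
    best <- NULL
    for (j in order(tc$pos)) {
      ref <- if (measure == "midpoint") floor((frags$start[i] + frags$end[i]) / 2)
             else min(max(tc$pos[j], frags$start[i]), frags$end[i] - 1L)
      dg <- ref - tc$pos[j]
      d <- if (tc$strand[j] == "+") dg else -dg
      if (is.null(best) || abs(d) < abs(best)) best <- d
    }
    c(best, 0)
  }, numeric(2)))[, 1L]
}

hit_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(sprintf("%d:%d:%s", df$start, df$end, df$orientation))
}

paper_motif <- function(min_match = 10L) motif("GGCCACCACCCC", min_match)
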