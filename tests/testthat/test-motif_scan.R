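test_that("fixture promoters produce the expected hits", {
  recs <- load_table1_fixture()
  genes <- vapply(recs, `[[`, character(1), "gene")
  m <- paper_motif()

  tyrobp <- scan_promoter(recs[[which(genes == "TYROBP")]], m)
  expect_gte(nrow(tyrobp), 1L)
  expect_true(any(tyrobp$orientation == "forward" &
                  grepl("GCCACCACC", tyrobp$matched_word, fixed = TRUE)))

  # ALPL carries the full-length reverse-complement word (verified by
  # independent substring search before the scanner was built)
  alpl_seq <- recs[[which(genes == "ALPL")]]$seq$residues
  expect_true(grepl("GGGGTGGTGGCC", alpl_seq, fixed = TRUE))
  alpl <- scan_promoter(recs[[which(genes == "ALPL")]], m)
  expect_true(any(alpl$orientation == "reverse" & alpl$match_len == 12L))

  polyA <- promoter_record("PA", strrep("A", 60), 49)
  expect_equal(nrow(scan_promoter(polyA, m)), 0L)
})

test_that("scanner equals the brute-force window oracle on random instances", {
  set.seed(11)
  checked <- 0L
  while (checked < 500L) {
    wlen <- sample(6:14, 1)
    word <- rand_dna(wlen, gc = runif(1, 0.3, 0.7))
    mm <- sample(3:wlen, 1)
    L <- sample(30:200, 1)
    s <- rand_dna(L, gc = runif(1, 0.3, 0.7))
    # splice in motif fragments half the time so hits are frequent
    if (runif(1) < 0.5) {
      k <- sample(mm:wlen, 1)
      at <- sample(1:(L - k + 1), 1)
      frag <- if (runif(1) < 0.5) substr(word, 1, k)
              else substr(rc_str(word), 1, k)
      substr(s, at, at + k - 1) <- frag
    }
    rec <- promoter_record("r", s, 0)
    got <- scan_promoter(rec, motif(word, mm))
    expect_identical(hit_key(got), hit_key(oracle_scan(s, word, mm)))
    # maximality invariant on every scan
    if (nrow(got) >= 2L) {
      for (i in seq_len(nrow(got))) {
        contained <- got$orientation == got$orientation[i] &
          got$start <= got$start[i] & got$end >= got$end[i] &
          (got$end - got$start) > (got$end[i] - got$start[i])
        expect_false(any(contained))
      }
    }
    checked <- checked + 1L
  }
})

test_that("all-occurrences mode keeps nested sub-words", {
  rec <- promoter_record("GX", paste0(strrep("A", 10), "GGCCACCACCCC", strrep("A", 10)), 0)
  m <- paper_motif()
  maximal <- scan_promoter(rec, m)
  everything <- scan_promoter(rec, m, maximal_only = FALSE)
  expect_equal(nrow(maximal), 1L)
  expect_equal(nrow(everything), 6L)  # 3 ten-mers + 2 eleven-mers + 12-mer
  expect_true(all(hit_key(maximal) %in% hit_key(everything)))
})

test_that("database scan counts promoters, not occurrences, and is ordered", {
  recs <- load_table1_fixture()
  res <- scan_database(recs, paper_motif())
  expect_s3_class(res, "scan_result")
  expect_equal(res$promoters_scanned, 30L)
  expect_equal(res$promoters_with_hit, length(unique(res$hits$gene)))
  expect_lte(res$promoters_with_hit, res$promoters_scanned)
  # deterministic ordering: input order, then start
  genes_in <- vapply(recs, `[[`, character(1), "gene")
  expect_identical(unique(res$hits$gene),
                   genes_in[genes_in %in% res$hits$gene])
  expect_error(scan_database(list(), paper_motif()), "non-empty")
  expect_error(scan_database(recs, motif("GGCCACCACCCC", 13)), "min_match")
})

test_that("raising min_match never increases promoters_with_hit", {
  recs <- load_table1_fixture()
  counts <- vapply(10:12, function(k) {
    scan_database(recs, motif("GGCCACCACCCC", k))$promoters_with_hit
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted search words are recovered exactly on certified-clean promoters", {
  m <- paper_motif()
  # plant 12-mers in 2 of every 5 promoters -> 40 of 100 planted
  spec <- data.frame(len = c(12L, 10L, 0L, 0L, 0L),
                     orientation = c("forward", "reverse", NA, NA, NA),
                     pos = NA_integer_)
  g <- gen_promoters(100, length = 60, m = m, plant_spec = spec, seed = 202)
  res <- scan_database(g$records, m)
  planted <- g$truth$gene[g$truth$len >= m$min_match]
  expect_length(planted, 40L)
  expect_equal(res$promoters_with_hit, 40L)
  expect_setequal(unique(res$hits$gene), planted)
  # every planted word is recovered at its planted position
  for (i in which(g$truth$len >= m$min_match)) {
    h <- res$hits[res$hits$gene == g$truth$gene[i], , drop = FALSE]
    expect_true(any(h$start <= g$truth$pos[i] &
                    h$end >= g$truth$pos[i] + g$truth$len[i]))
  }
  # sub-threshold plants yield zero hits
  below <- data.frame(len = 9L, orientation = "forward", pos = NA_integer_)
  gb <- gen_promoters(30, length = 60, m = m, plant_spec = below, seed = 203)
  expect_equal(scan_database(gb$records, m)$promoters_with_hit, 0L)
})

test_that("summarize_hits aggregates per gene", {
  empty <- scan_database(list(promoter_record("PA", strrep("A", 60), 0)),
                         paper_motif())
  expect_equal(nrow(summarize_hits(empty)), 0L)

  two <- promoter_record("G2", paste0("GGCCACCACCCC", strrep("A", 20),
                                      "GGGGTGGTGGCC"), 0)
  res <- scan_database(list(two), paper_motif())
  tab <- summarize_hits(res)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_hits, 2L)
  expect_equal(tab$orientations, "forward,reverse")

  expect_equal(nrow(summarize_hits(scan_database(load_table1_fixture(),
                                                 paper_motif()))), 30L)
})
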