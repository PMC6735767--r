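make_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("BED and GFF readers validate and use the right conventions", {
  frags <- read_intervals_bed(make_bed("chr1\t100\t200\tf1"))
  expect_equal(frags$start, 100L)
  expect_equal(frags$end, 200L)
  expect_equal(frags$id, "f1")

  expect_error(read_intervals_bed(make_bed("chr1\t100\t100\tf1")), "line 1")
  expect_error(read_intervals_bed(make_bed(c("chr1\t1\t2\tf1", "chr1\toops"))),
               "line 2")
  expect_warning(empty <- read_intervals_bed(make_bed(character())), "empty")
  expect_equal(nrow(empty), 0L)

  tss <- read_tss(make_bed("chr1\t500\t501\tg1\t0\t-"), format = "bed")
  expect_equal(tss$pos, 500L)
  expect_equal(tss$strand, "-")

  # GFF: minus-strand gene spanning 0-based [500, 900) has its TSS at 899
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t501\t900\t.\t-\t.\tID=g1;Name=g1"), gff)
  gtss <- read_tss(gff, format = "gff")
  expect_equal(gtss$pos, 899L)
  expect_equal(gtss$gene, "g1")
})

test_that("signed distance follows the documented sign convention", {
  tss_plus <- data.frame(chrom = "chr1", pos = 1000L, strand = "+", gene = "g")
  tss_minus <- transform(tss_plus, strand = "-")
  frag_at <- data.frame(chrom = "chr1", start = 900L, end = 1100L, id = "f")   # midpoint 1000
  frag_up <- data.frame(chrom = "chr1", start = 600L, end = 800L, id = "f")    # midpoint 700

  expect_equal(distance_to_nearest_tss(frag_at, tss_plus)$distance, 0)
  expect_equal(distance_to_nearest_tss(frag_up, tss_plus)$distance, -300)
  expect_equal(distance_to_nearest_tss(frag_up, tss_minus)$distance, 300)

  # edge measure: TSS inside the fragment is distance 0
  inside <- data.frame(chrom = "chr1", start = 950L, end = 1100L, id = "f")
  expect_equal(distance_to_nearest_tss(inside, tss_plus, measure = "edge")$distance, 0)
  expect_equal(distance_to_nearest_tss(frag_up, tss_plus, measure = "edge")$distance, -201)

  # fragments on chromosomes without any TSS are flagged unassigned
  lost <- data.frame(chrom = "chrX", start = 0L, end = 10L, id = "f")
  out <- distance_to_nearest_tss(lost, tss_plus)
  expect_false(out$assigned)
  expect_true(is.na(out$distance))
})

test_that("nearest-TSS equals the all-pairs oracle; invariances hold", {
  set.seed(19)
  for (rep in 1:10) {
    frags <- data.frame(chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
                        start = s <- sample.int(1e6, 60),
                        end = s + sample(100:1000, 60, replace = TRUE),
                        id = sprintf("f%d", 1:60))
    tsss <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                       pos = sample.int(1e6, 40),
                       strand = sample(c("+", "-"), 40, replace = TRUE),
                       gene = sprintf("g%d", 1:40))
    for (measure in c("midpoint", "edge")) {
      got <- distance_to_nearest_tss(frags, tsss, measure = measure)
      expect_equal(abs(got$distance), abs(oracle_nearest(frags, tsss, measure)))
      # translation invariance
      sh <- distance_to_nearest_tss(transform(frags, start = start + 7919L,
                                              end = end + 7919L),
                                    transform(tsss, pos = pos + 7919L),
                                    measure = measure)
      expect_equal(sh$distance, got$distance)
      # strand flip negates every signed distance
      fl <- distance_to_nearest_tss(frags,
                                    transform(tsss, strand = ifelse(strand == "+", "-", "+")),
                                    measure = measure)
      expect_equal(fl$distance, -got$distance)
    }
  }
  expect_error(distance_to_nearest_tss(frags[0, ], tsss), "non-empty")
})

test_that("tie on absolute distance breaks toward the smaller TSS coordinate", {
  tsss <- data.frame(chrom = "chr1", pos = c(900L, 1100L), strand = "+",
                     gene = c("lo", "hi"))
  frag <- data.frame(chrom = "chr1", start = 990L, end = 1010L, id = "f")  # midpoint 1000
  expect_equal(distance_to_nearest_tss(frag, tsss)$gene, "lo")
})

test_that("distance binning is half-open, normalized, and validated", {
  rec <- data.frame(id = "f", chrom = "chr1", gene = "g",
                    distance = 0, assigned = TRUE)
  bins <- bin_distances(rec)
  expect_equal(sum(bins$count), 1L)
  expect_equal(bins$count[bins$lo == -1000], 1L)  # central bin [-1000, 1000)
  expect_equal(sum(bins$fraction), 1)

  many <- data.frame(id = as.character(1:7), chrom = "chr1", gene = "g",
                     distance = c(-20000, -7000, -3000, 999, 1500, 5000, 10000),
                     assigned = TRUE)
  b <- bin_distances(many)
  expect_equal(sum(b$fraction), 1)
  expect_equal(b$count, rep(1L, 7L))  # one per bin incl. boundary cases
  expect_error(bin_distances(many, edges = c(1, 1, 2)), "increasing")
})

test_that("synthetic fragment offsets land in the central bin at the closed-form rate", {
  tss <- data.frame(chrom = "chr1", pos = seq(1e6, by = 1e5, length.out = 20),
                    strand = rep(c("+", "-"), 10), gene = sprintf("g%d", 1:20))
  g <- gen_fragments(tss, n = 2198, offset_sd_bp = 400, seed = 77)
  rec <- distance_to_nearest_tss(g$fragments, tss)
  # recovered distances equal the generator's planted offsets exactly
  expect_equal(rec$distance[match(g$truth$id, rec$id)], as.numeric(g$truth$offset))
  frac_1kb <- mean(abs(rec$distance) < 1000)
  # oracle: P(|N(0, 400)| < 1000) = Phi(2.5) - Phi(-2.5) ~ 0.9876
  expect_lt(abs(frac_1kb - (pnorm(2.5) - pnorm(-2.5))), 0.01)
})
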