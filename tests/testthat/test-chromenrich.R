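# Per-chromosome counts, expected counts, goodness of fit, differential
# overlap, annotation.

test_that("per-chromosome counts tally correctly and reject unknowns", {
  gt <- genome_table(c("chr1", "chr2", "chr3"), c(3e6, 2e6, 1e6))
  p <- peak_table(data.frame(
    chrom = rep(c("chr1", "chr2"), c(5, 3)),
    start = seq(100, by = 1000, length.out = 8),
    end = seq(600, by = 1000, length.out = 8)))
  cnt <- count_peaks_per_chrom(p, gt)
  expect_identical(cnt, c(chr1 = 5L, chr2 = 3L, chr3 = 0L))
  expect_identical(sum(cnt), nrow(p))
  empty <- peak_table(data.frame(chrom = character(), start = integer(),
                                 end = integer()))
  expect_identical(count_peaks_per_chrom(empty, gt),
                   c(chr1 = 0L, chr2 = 0L, chr3 = 0L))
  bad <- peak_table(data.frame(chrom = "chrZ", start = 1L, end = 2L))
  expect_error(count_peaks_per_chrom(bad, gt), "chrZ")
})

test_that("expected counts split the total by weights, exactly", {
  expect_equal(expected_counts(30, c(chr1 = 2e6, chr2 = 1e6)),
               c(chr1 = 20, chr2 = 10))
  expect_equal(expected_counts(40, c(a = 100, b = 300)), c(a = 10, b = 30))
  expect_equal(unname(expected_counts(12, c(a = 7, b = 7, c = 7))),
               rep(4, 3))
  expect_equal(sum(expected_counts(117, c(a = 1.3, b = 2.9, c = 0.4))), 117)
  expect_error(expected_counts(10, c(a = 0, b = 1)), "weights")
  expect_error(expected_counts(-1, c(a = 1)), "total")
})

test_that("the X^2 statistic and p-values match hand values and chisq.test", {
  o <- c(a = 10L, b = 10L)
  g0 <- goodness_of_fit(o, c(a = 10, b = 10), method = "chi-square")
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)

  g1 <- goodness_of_fit(c(a = 25L, b = 5L), c(a = 15, b = 15),
                        method = "chi-square")
  expect_equal(g1$statistic, 200 / 15, tolerance = 1e-12)
  expect_identical(g1$df, 1L)

  # cross-check statistic and p against stats::chisq.test
  obs <- c(a = 40L, b = 55L, c = 61L, d = 44L)
  w <- c(a = 1, b = 1.2, c = 1.4, d = 1)
  ex <- expected_counts(sum(obs), w)
  mine <- goodness_of_fit(obs, ex, method = "chi-square")
  ref <- suppressWarnings(chisq.test(obs, p = w / sum(w)))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)

  # monte-carlo agrees with the asymptotic p when expected counts are large
  mc <- goodness_of_fit(obs, ex, method = "monte-carlo", n_sim = 10000,
                        seed = 5)
  se <- sqrt(mine$p_value * (1 - mine$p_value) / 10000)
  expect_lt(abs(mc$p_value - mine$p_value), 2 * se + 2e-4)

  # auto switches to monte-carlo when any expected count < 5
  au <- goodness_of_fit(c(a = 6L, b = 2L), c(a = 4, b = 4), method = "auto",
                        n_sim = 500, seed = 1)
  expect_identical(au$method, "monte-carlo")
  expect_error(goodness_of_fit(c(a = 1L, b = 1L), c(a = 2, b = 0)),
               "weights must cover")
  expect_error(goodness_of_fit(c(a = 5L, b = 5L), c(a = 4, b = 4)),
               "sum")
})

test_that("differential overlap matches the hand fixture and the all-pairs scan", {
  # toy: A has 4 peaks, B has 3; 2 overlaps, 1 direction-concordant
  a <- peak_table(data.frame(
    chrom = "chr1",
    start = c(0, 1000, 2000, 3000), end = c(50, 1100, 2050, 3050),
    direction = c("gain", "loss", "gain", "gain")))
  b <- peak_table(data.frame(
    chrom = "chr1",
    start = c(10, 1010, 50000), end = c(60, 1060, 50050),
    direction = c("gain", "gain", "loss")))
  ov <- differential_overlap(a, b)
  expect_identical(ov$n_overlap, 2L)
  expect_identical(ov$n_same_direction, 1L)

  # identical tables / disjoint tables
  same <- differential_overlap(a, a)
  expect_identical(same$n_overlap, nrow(a))
  expect_identical(same$n_same_direction, nrow(a))
  far <- peak_table(data.frame(chrom = "chr1", start = 9e6, end = 9e6 + 10,
                               direction = "gain"))
  none <- differential_overlap(a, far)
  expect_identical(none$n_overlap, 0L)
  expect_identical(none$n_same_direction, 0L)

  nodir <- peak_table(data.frame(chrom = "chr1", start = 1L, end = 2L))
  expect_error(differential_overlap(nodir, b), "direction")

  # invariant: same_direction <= overlap <= min(n_a, n_b was not required);
  # overlap count symmetric for internally non-overlapping tables
  a2 <- rand_peaks(71); a2 <- a2[!duplicated(a2$chrom), ]
  b2 <- rand_peaks(72); b2 <- b2[!duplicated(b2$chrom), ]
  expect_identical(differential_overlap(a2, b2)$n_overlap,
                   differential_overlap(b2, a2)$n_overlap)
})

test_that("annotation assigns by midpoint with TSS > promoter > body precedence", {
  genes <- data.frame(chrom = "chr1",
                      txStart = c(1000, 5000, 9000),
                      txEnd = c(3000, 7000, 9500),
                      strand = c("+", "-", "+"))
  pk <- peak_table(data.frame(
    chrom = "chr1",
    start = c(975, 400, 2000, 8000, 9200, 20000),
    end = c(1025, 600, 2100, 8200, 9300, 20100)))
  # hand assignment: mid 1000 -> TSS(g1); 500 -> promoter(g1); 2050 -> body;
  # 8100 -> promoter(g3); 9250 -> body(g3); 20050 -> intergenic
  cnt <- annotate_peaks(pk, genes)
  expect_identical(cnt, c(TSS = 1L, promoter = 2L, gene_body = 2L,
                          intergenic = 1L))
  expect_identical(sum(cnt), nrow(pk))
  # minus-strand TSS: midpoint at txEnd of a minus gene
  pk2 <- peak_table(data.frame(chrom = "chr1", start = 6950, end = 7050))
  expect_identical(annotate_peaks(pk2, genes)[["TSS"]], 1L)
})

test_that("enrichment recovery: a known fold is recovered within its band", {
  gt <- mouse_chrom_sizes()
  pk <- sample_peak_table(500, gt, fold_map = c(chr11 = 5), seed = 31)
  en <- chrom_enrichment(pk, gt, seed = 8)
  s11 <- en$table$enrichment_score[en$table$chrom == "chr11"]
  exp11 <- en$table$expected[en$table$chrom == "chr11"]
  expect_lt(abs(s11 - 5), 3 * sqrt(5 / exp11))
  expect_identical(en$table$chrom[which.max(en$table$enrichment_score)],
                   "chr11")
})

test_that("BED round trip preserves intervals and directions", {
  p <- rand_peaks(5)
  f <- tempfile(fileext = ".bed")
  write_bed(p, f)
  p2 <- read_bed(f)
  expect_equal(p2$chrom, p$chrom)
  expect_equal(p2$start, p$start)
  expect_equal(p2$end, p$end)
  # direction lands in the 4th column and round-trips via name slot;
  # score-sign derivation
  sc <- peak_table(data.frame(chrom = "chr1", start = c(0, 100),
                              end = c(50, 150), name = c("p1", "p2"),
                              score = c(1.5, -2)))
  f2 <- tempfile(fileext = ".bed")
  write_bed(sc, f2)
  p3 <- read_bed(f2, direction_from_score = TRUE)
  expect_identical(p3$direction, c("gain", "loss"))
  # chrom.sizes reader
  f3 <- tempfile()
  writeLines(c("chr1\t3000000", "chr2\t1000000"), f3)
  g <- read_chrom_sizes(f3)
  expect_s3_class(g, "genome_table")
  expect_equal(g$size, c(3e6, 1e6))
})
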