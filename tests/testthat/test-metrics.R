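test_that("RPKM follows 1e9 * C / (N * L) and its invariances", {
  expect_equal(rpkm(1000, 2000, 1e7), 50)
  expect_equal(rpkm(0, 2000, 1e7), 0)
  expect_error(rpkm(10, 0, 1e6), "exon_length_bp")
  expect_error(rpkm(10, 100, 0), "library_size")

  # scaling counts and library size together leaves RPKM unchanged
  set.seed(12)
  C <- sample(1:1e4, 50); L <- sample(100:5000, 50); N <- sample(1e5:1e7, 50)
  f <- sample(2:20, 50, replace = TRUE)
  expect_equal(rpkm(C * f, L, N * f), rpkm(C, L, N))
})

test_that("I/E ratio handles zeros, pseudocounts and undefined cases", {
  expect_equal(ie_ratio(50, 100), 0.5)
  expect_equal(ie_ratio(0, 500), 0)  # mature transcripts sit near zero
  expect_true(is.na(ie_ratio(5, 0)))
  expect_equal(ie_ratio(5, 0, pseudocount = 1), 6)
  expect_error(ie_ratio(-1, 10), "nonnegative")

  # strictly monotone: up in intron reads, down in exon reads
  set.seed(7)
  for (i in 1:50) {
    I <- sample(0:100, 1); E <- sample(1:100, 1)
    expect_gt(ie_ratio(I + 1, E), ie_ratio(I, E))
    expect_lt(ie_ratio(I, E + 1), ie_ratio(I, E))
  }
})

test_that("diagonal distance is the signed perpendicular distance to y = x", {
  expect_equal(diagonal_distance(1, 1), 0)
  expect_equal(diagonal_distance(0, 2), sqrt(2))
  expect_equal(diagonal_distance(3, 1), -sqrt(2))
  # antisymmetric under swapping the conditions
  set.seed(3)
  x <- runif(100, 0, 10); y <- runif(100, 0, 10)
  expect_equal(diagonal_distance(x, y), -diagonal_distance(y, x))
  # |d| equals the grid-search point-to-line minimum (small sample here;
  # the full equivalence check runs in the acceptance suite)
  for (i in 1:25) {
    expect_equal(abs(diagonal_distance(x[i], y[i])),
                 oracle_diag_distance(x[i], y[i]), tolerance = 1e-6)
  }
})

test_that("one-sample comparison matches the closed-form t and guards degeneracy", {
  # hand-evaluated t for distances {1,2,3,4,5}: t = mean / (sd/sqrt(n))
  d <- c(1, 2, 3, 4, 5)
  res <- compare_conditions(x = rep(0, 5), y = d * sqrt(2))
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(res$t_statistic, t_hand)
  expect_equal(res$p_value, p_hand)
  expect_equal(res$df, 4)

  # all distances exactly zero: t = 0, p = 1
  z <- compare_conditions(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  expect_equal(z$t_statistic, 0)
  expect_equal(z$p_value, 1)
  expect_false(z$degenerate)
  expect_equal(z$n_unchanged, 4L)

  # distances {1,1,1,1}: zero variance, nonzero mean -> machine-floor p, flagged
  g <- compare_conditions(x = rep(0, 4), y = rep(sqrt(2), 4))
  expect_true(g$degenerate)
  expect_true(is.infinite(g$t_statistic) && g$t_statistic > 0)
  expect_lte(g$p_value, .Machine$double.xmin)
})

test_that("undefined genes are excluded, never imputed", {
  x <- c(0.1, NA, 0.3, 0.2, 0.5)
  y <- c(0.2, 0.1, NA, 0.25, 0.6)
  res <- compare_conditions(x, y, gene_id = sprintf("g%d", 1:5))
  expect_equal(res$n_used, 3L)
  expect_setequal(res$distances$gene_id, c("g1", "g4", "g5"))
  expect_equal(res$n_increased + res$n_decreased + res$n_unchanged, 3L)
  expect_error(compare_conditions(c(1, NA, NA), c(1, 2, 3)), ">= 3 genes")
})

test_that("two-sample mode equals an independent Student's t on the distance sets", {
  set.seed(19)
  x1 <- runif(40); y1 <- x1 + rnorm(40, 0.2, 0.1)
  x2 <- runif(30); y2 <- x2 + rnorm(30, 0, 0.1)
  res <- compare_conditions(x1, y1, test = "two_sample", x2 = x2, y2 = y2)
  d1 <- (y1 - x1) / sqrt(2); d2 <- (y2 - x2) / sqrt(2)
  tt <- t.test(d1, d2, var.equal = TRUE)
  expect_equal(res$t_statistic, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
})

test_that("change classification applies the fold rule symmetrically", {
  expect_equal(classify_change(0.01, 0.5, 2, 0.01), "increased")
  expect_equal(classify_change(0.3, 0.3, 2, 0.01), "unchanged")
  expect_equal(classify_change(0.5, 0.01, 2, 0.01), "decreased")
  expect_error(classify_change(0.1, 0.2, fold_threshold = 1), "> 1")

  set.seed(5)
  x <- runif(200, 0, 2); y <- runif(200, 0, 2)
  fwd <- classify_change(x, y, 2, 0.01)
  rev <- classify_change(y, x, 2, 0.01)
  swap <- c(increased = "decreased", decreased = "increased",
            unchanged = "unchanged")
  expect_equal(unname(swap[fwd]), rev)
})

test_that("restoration classification follows the full/partial/none rule", {
  expect_equal(classify_restoration(0.02, 1.0, 0.03, 2, 0.01), "full")
  expect_equal(classify_restoration(0.02, 1.0, 0.2, 2, 0.01), "partial")
  expect_equal(classify_restoration(0.02, 1.0, 0.9, 2, 0.01), "none")
  # not increased in the defect -> ineligible
  expect_equal(classify_restoration(0.5, 0.5, 0.5, 2, 0.01), "ineligible")
})

test_that("the splice table keeps RPKM finite where I/E is undefined", {
  m <- gene_models(tibble::tibble(
    gene_id = c("multi", "multi", "solo"), chrom = "chr1",
    start = c(0L, 200L, 1000L), end = c(100L, 300L, 1400L), strand = "+"))
  counts <- tibble::tibble(
    gene_id = c("multi", "solo"), condition_id = "c1",
    exon_reads = c(80L, 40L), intron_reads = c(8L, 0L),
    library_size = 1000L)
  tab <- splice_table(counts, m)
  solo <- tab[tab$gene_id == "solo", ]
  expect_true(is.na(solo$ie_c1))           # permanently undefined
  expect_true(is.finite(solo$rpkm_c1))     # expression still measured
  expect_equal(tab$ie_c1[tab$gene_id == "multi"], 0.1)
  expect_equal(tab$rpkm_c1[tab$gene_id == "multi"],
               1e9 * 80 / (1000 * 200))
})
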