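boundary_gene <- function() {
  gene_models(tibble::tibble(
    gene_id = "g1", chrom = "chr1",
    start = c(0L, 200L), end = c(120L, 300L), strand = "+"))
}

test_that("the overlap predicate is half-open and matches per-base sets", {
  expect_false(intervals_overlap(0, 10, 10, 20))  # abutment
  expect_true(intervals_overlap(0, 10, 9, 20))
  expect_true(intervals_overlap(5, 6, 0, 100))

  set.seed(31)
  for (i in 1:200) {
    a <- sort(sample(0:50, 2)); b <- sort(sample(0:50, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1L
    if (b[1] == b[2]) b[2] <- b[2] + 1L
    expect_identical(intervals_overlap(a[1], a[2], b[1], b[2]),
                     oracle_overlap(a[1], a[2], b[1], b[2]))
  }
})

test_that("a boundary-spanning read increments both feature classes", {
  m <- boundary_gene()  # exons [0,120) [200,300), intron [120,200)
  reads <- tibble::tibble(chrom = "chr1", start = 100L, end = 150L,
                          read_id = "r1", score = 0L, strand = "+")
  cts <- count_reads(m, reads, "c")
  expect_equal(cts$exon_reads, 1L)
  expect_equal(cts$intron_reads, 1L)

  intronic <- tibble::tibble(chrom = "chr1", start = 130L, end = 180L,
                             read_id = "r2", score = 0L, strand = "+")
  cts2 <- count_reads(m, intronic, "c")
  expect_equal(cts2$exon_reads, 0L)
  expect_equal(cts2$intron_reads, 1L)
})

test_that("boundary policies assign a straddling read to one class only", {
  m <- boundary_gene()
  reads <- tibble::tibble(chrom = "chr1", start = 100L, end = 150L,
                          read_id = "r1", score = 0L, strand = "+")
  ep <- count_reads(m, reads, "c", boundary_policy = "exon_priority")
  expect_equal(c(ep$exon_reads, ep$intron_reads), c(1L, 0L))
  ip <- count_reads(m, reads, "c", boundary_policy = "intron_priority")
  expect_equal(c(ip$exon_reads, ip$intron_reads), c(0L, 1L))
})

test_that("counts agree exactly with the nested-loop oracle", {
  m <- random_models(30, seed = 17)
  reads <- random_reads(1500, seed = 18)
  cts <- count_reads(m, reads, "c")
  orc <- oracle_count(m, reads)
  expect_equal(cts$exon_reads, orc$exon_reads)
  expect_equal(cts$intron_reads, orc$intron_reads)
})

test_that("counting is order-independent", {
  m <- random_models(20, seed = 23)
  reads <- random_reads(800, seed = 24)
  set.seed(1)
  shuffled <- reads[sample.int(nrow(reads)), ]
  a <- count_reads(m, reads, "c")
  b <- count_reads(m, shuffled, "c")
  expect_equal(a, b)
})

test_that("unknown chromosomes stay in the library size but reach no gene", {
  m <- boundary_gene()
  reads <- tibble::tibble(
    chrom = c("chr1", "chrMystery"), start = c(10L, 10L), end = c(60L, 60L),
    read_id = c("r1", "r2"), score = 0L, strand = "+")
  expect_message(cts <- count_reads(m, reads, "c"), "unknown chromosome")
  expect_equal(cts$library_size, 2L)
  expect_equal(cts$exon_reads, 1L)
  expect_equal(attr(cts, "unknown_chrom_reads"), 1L)
})

test_that("stranded mode counts same-strand reads only", {
  m <- boundary_gene()  # gene on +
  reads <- tibble::tibble(
    chrom = "chr1", start = c(10L, 10L), end = c(60L, 60L),
    read_id = c("r1", "r2"), score = 0L, strand = c("+", "-"))
  default <- count_reads(m, reads, "c")
  expect_equal(default$exon_reads, 2L)  # strand-agnostic by default
  stranded <- count_reads(m, reads, "c", stranded = TRUE)
  expect_equal(stranded$exon_reads, 1L)
})

test_that("exon+intron tallies bracket the span hits (boundary double-counts only)", {
  m <- random_models(15, seed = 41)
  reads <- random_reads(600, seed = 42)
  cts <- count_reads(m, reads, "c")
  for (gi in seq_len(nrow(m$genes))) {
    g <- m$genes[gi, ]
    span_hits <- sum(reads$chrom == g$chrom &
                       reads$start < g$span_end & g$span_start < reads$end)
    total <- cts$exon_reads[gi] + cts$intron_reads[gi]
    expect_gte(total, span_hits)  # exons+introns tile the span
    expect_lte(total, 2L * span_hits)
    expect_gte(span_hits, cts$exon_reads[gi])
    expect_gte(span_hits, cts$intron_reads[gi])
  }
})

test_that("the SAM adapter degrades alignments to the same intervals", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    # POS is 1-based: 101 -> 0-based start 100; 50M -> end 150
    "r1\t0\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t131\t60\t50M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"  # unmapped: dropped
  ), sam)
  reads <- read_reads_sam(sam)
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$start, c(100L, 130L))
  expect_equal(reads$end, c(150L, 180L))
  expect_equal(reads$strand, c("+", "-"))

  m <- boundary_gene()
  cts <- count_reads(m, reads, "c")
  expect_equal(cts$exon_reads, 1L)   # r1 spans the exon/intron boundary
  expect_equal(cts$intron_reads, 2L) # both overlap the intron
})
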