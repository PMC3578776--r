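test_that("simulated gene sets are deterministic and hit the single-exon count", {
  cfg <- sim_config(n_genes = 100L, single_exon_fraction = 0.2, seed = 7L)
  m1 <- simulate_gene_models(cfg)
  m2 <- simulate_gene_models(cfg)
  expect_equal(sum(m1$genes$single_exon), 20L)
  expect_identical(m1$genes, m2$genes)
  expect_identical(m1$exons, m2$exons)
})

test_that("degenerate structure settings produce the promised shapes", {
  all_single <- simulate_gene_models(
    sim_config(n_genes = 30L, single_exon_fraction = 1, seed = 1L))
  expect_true(all(all_single$genes$single_exon))
  expect_equal(nrow(all_single$introns), 0L)

  two_exon <- simulate_gene_models(
    sim_config(n_genes = 30L, single_exon_fraction = 0,
               exons_per_gene = c(2L, 2L), seed = 1L))
  n_introns <- table(two_exon$introns$gene_id)
  expect_true(all(n_introns == 1L))
  expect_equal(length(n_introns), 30L)
})

test_that("infeasible ranges are rejected up front", {
  expect_error(sim_config(exon_length_bp = c(500L, 100L)))
  expect_error(sim_config(conditions = c(a = 1.5)))
  expect_error(sim_config(conditions = c(0.1)))  # unnamed
})

test_that("u = 0 emits no intron-overlapping read and conserves the total", {
  cfg <- sim_config(n_genes = 40L, single_exon_fraction = 0, seed = 3L)
  m <- simulate_gene_models(cfg)
  sim <- simulate_reads(m, "base", u = 0, n_reads = 2e4, read_length = 50,
                        seed = 11)
  expect_equal(nrow(sim$reads), 2e4)
  cts <- count_reads(m, sim$reads, "base")
  expect_equal(sum(cts$intron_reads), 0L)
  expect_true(all(sim$truth$expected_IE == 0))
  # every read lies within its source gene's chromosome layout
  expect_true(all(sim$reads$end > sim$reads$start))
})

test_that("u = 1 coverage splits between intron and exon by length", {
  # one gene, 1000 bp of exon + 1000 bp of intron; pure pre-mRNA reads are
  # uniform over the span so intronic/exonic hits approach 1 (uniform-
  # coverage oracle: expected hits proportional to feature length)
  m <- gene_models(tibble::tibble(
    gene_id = "g1", chrom = "chr1",
    start = c(0L, 1500L), end = c(500L, 2000L), strand = "+"))
  sim <- simulate_reads(m, "mut", u = 1, n_reads = 2e5, read_length = 20,
                        seed = 5, abundance = 1)
  cts <- count_reads(m, sim$reads, "mut")
  ratio <- cts$intron_reads / cts$exon_reads
  expect_lt(abs(ratio - 1), 0.05)
  expect_equal(sim$truth$expected_IE, 1.0)  # u * L_I / L_E = 1 * 1000/1000
})

test_that("read output is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 25L, seed = 13L)
  m <- simulate_gene_models(cfg)
  b1 <- withr::local_tempfile(fileext = ".bed")
  b2 <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(simulate_reads(m, "c1", 0.2, 5e3, 50, seed = 99)$reads, b1)
  write_reads_bed(simulate_reads(m, "c1", 0.2, 5e3, 50, seed = 99)$reads, b2)
  expect_identical(readLines(b1), readLines(b2))
})

test_that("BED6 write/read preserves read intervals and ids", {
  cfg <- sim_config(n_genes = 10L, seed = 2L)
  m <- simulate_gene_models(cfg)
  sim <- simulate_reads(m, "c1", 0.3, 500, 50, seed = 4)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(sim$reads, bed)
  back <- read_reads_bed(bed)
  expect_equal(back$chrom, sim$reads$chrom)
  expect_equal(back$start, sim$reads$start)
  expect_equal(back$end, sim$reads$end)
  expect_equal(back$read_id, sim$reads$read_id)
  expect_equal(back$strand, sim$reads$strand)
})

test_that("reads longer than the spliced transcript are shrunk, not dropped", {
  m <- gene_models(tibble::tibble(
    gene_id = "tiny", chrom = "chr1",
    start = c(0L, 40L), end = c(20L, 60L), strand = "+"))
  expect_message(
    sim <- simulate_reads(m, "c", u = 0, n_reads = 200, read_length = 100,
                          seed = 1, abundance = 1),
    "shrunk")
  expect_equal(nrow(sim$reads), 200L)
  expect_true(all(sim$reads$end <= 60L))
  cts <- count_reads(m, sim$reads, "c")
  expect_equal(sum(cts$intron_reads), 0L)  # still no intronic contamination
})

test_that("per-gene u vectors drive heterogeneous defects", {
  cfg <- sim_config(n_genes = 2L, single_exon_fraction = 0,
                    exons_per_gene = c(2L, 2L),
                    exon_length_bp = c(1000L, 1000L),
                    intron_length_bp = c(1000L, 1000L), seed = 8L)
  m <- simulate_gene_models(cfg)
  u <- c(0, 0.5)
  sim <- simulate_reads(m, "c", u = u, n_reads = 1e5, read_length = 30,
                        seed = 21, abundance = c(1, 1))
  cts <- count_reads(m, sim$reads, "c")
  ie <- ie_ratio(cts$intron_reads, cts$exon_reads)
  expect_equal(ie[1], 0)
  # expected I/E = u * L_I / L_E = 0.5 * 1000 / 2000
  expect_lt(abs(ie[2] - 0.25), 0.05)
})
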