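# Fixtures are built in code; oracles here are deliberately brute-force and
# independent of the implementation paths they check.

# per-base membership oracle for interval overlap (0-based half-open)
oracle_overlap <- function(a_start, a_end, b_start, b_end) {
  length(intersect(seq(a_start, a_end - 1L), seq(b_start, b_end - 1L))) > 0L
}

# brute-force intron derivation: every base in the gene span not covered
# by an exon, collapsed into maximal runs
oracle_introns <- function(exons) {
  span <- seq(min(exons$start), max(exons$end) - 1L)
  covered <- unlist(mapply(function(s, e) seq(s, e - 1L),
                           exons$start, exons$end, SIMPLIFY = FALSE))
  gaps <- sort(setdiff(span, covered))
  if (length(gaps) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  run_id <- cumsum(c(1L, diff(gaps) != 1L))
  tibble::tibble(
    start = as.integer(tapply(gaps, run_id, min)),
    end = as.integer(tapply(gaps, run_id, max)) + 1L
  )
}

# nested-loop counting oracle: tests every (read, feature) pair with the
# elementary overlap predicate; one count per (read, gene) per class
oracle_count <- function(models, reads) {
  g <- models$genes
  exon_counts <- integer(nrow(g))
  intron_counts <- integer(nrow(g))
  for (gi in seq_len(nrow(g))) {
    ex <- models$exons[models$exons$gene_id == g$gene_id[gi], ]
    inr <- models$introns[models$introns$gene_id == g$gene_id[gi], ]
    hit_e <- rep(FALSE, nrow(reads))
    for (k in seq_len(nrow(ex))) {
      hit_e <- hit_e | (reads$chrom == ex$chrom[k] &
                          reads$start < ex$end[k] & ex$start[k] < reads$end)
    }
    hit_i <- rep(FALSE, nrow(reads))
    for (k in seq_len(nrow(inr))) {
      hit_i <- hit_i | (reads$chrom == inr$chrom[k] &
                          reads$start < inr$end[k] & inr$start[k] < reads$end)
    }
    exon_counts[gi] <- sum(hit_e)
    intron_counts[gi] <- sum(hit_i)
  }
  tibble::tibble(gene_id = g$gene_id, exon_reads = exon_counts,
                 intron_reads = intron_counts)
}

# grid-search point-to-line oracle: minimise the Euclidean distance from
# (x, y) to points (t, t) on a grid, zooming around the argmin until the
# grid is fine enough for 1e-6 agreement
oracle_diag_distance <- function(x, y, rounds = 3L, n_grid = 2001L) {
  lo <- min(x, y) - 1
  hi <- max(x, y) + 1
  best <- Inf
  for (r in seq_len(rounds)) {
    t_grid <- seq(lo, hi, length.out = n_grid)
    d <- sqrt((x - t_grid)^2 + (y - t_grid)^2)
    i <- which.min(d)
    best <- d[i]
    step <- t_grid[2] - t_grid[1]
    lo <- t_grid[i] - 2 * step
    hi <- t_grid[i] + 2 * step
  }
  best
}

# small random gene set built directly from exon tables (independent of the
# package's simulator)
random_models <- function(n_genes, seed, n_chroms = 3L) {
  set.seed(seed)
  ex <- lapply(seq_len(n_genes), function(i) {
    k <- sample(1:5, 1)
    lens <- sample(20:200, 2 * k - 1, replace = TRUE)
    offset <- sample(0:5000, 1)
    starts <- offset + cumsum(c(0L, lens[-length(lens)]))
    keep <- seq(1, 2 * k - 1, by = 2)  # alternate exon/intron
    tibble::tibble(
      gene_id = sprintf("g%03d", i),
      chrom = sprintf("chr%d", sample.int(n_chroms, 1)),
      start = as.integer(starts[keep]),
      end = as.integer(starts[keep] + lens[keep]),
      strand = sample(c("+", "-"), 1)
    )
  })
  gene_models(dplyr::bind_rows(ex))
}

random_reads <- function(n_reads, seed, n_chroms = 3L, max_pos = 7000L,
                         len_range = c(10L, 80L)) {
  set.seed(seed)
  start <- sample(0:max_pos, n_reads, replace = TRUE)
  len <- sample(len_range[1]:len_range[2], n_reads, replace = TRUE)
  tibble::tibble(
    chrom = sprintf("chr%d", sample.int(n_chroms, n_reads, replace = TRUE)),
    start = start, end = start + len,
    read_id = sprintf("r%05d", seq_len(n_reads)),
    score = 0L,
    strand = sample(c("+", "-"), n_reads, replace = TRUE)
  )
}
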