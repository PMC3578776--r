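#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the three-condition design the analysis is built for:
#' a permissive-temperature baseline with near-complete splicing, a
#' restrictive-temperature condition where a large fraction of transcripts
#' remain unspliced, and a complemented strain returning to baseline.
#'
#' @param n_genes Number of genes.
#' @param single_exon_fraction Proportion of genes with a single exon (no
#'   introns; they carry RPKM but never an I/E ratio).
#' @param exons_per_gene Integer range `c(min, max)` of exon counts for
#'   multi-exon genes.
#' @param exon_length_bp,intron_length_bp Uniform sampling ranges
#'   `c(min, max)` for feature lengths, in bp.
#' @param expression_log_mean,expression_log_sd Parameters (natural-log
#'   scale) of the log-normal over relative transcript abundance; the
#'   default spread covers several decades, matching the dynamic range of
#'   bulk RNA-seq expression.
#' @param conditions Named numeric vector: names are condition ids, values
#'   the unspliced fraction `u` in `[0, 1]` (the molar fraction of a
#'   gene's transcript molecules that are unspliced pre-mRNA).
#' @param total_reads_per_condition Library size per condition.
#' @param read_length_bp Read length in bp.
#' @param class_proportions Named proportions for cycle classes
#'   `c(G1 = , SM = , NP = )`.
#' @param n_chroms Number of chromosomes genes are laid out on.
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       single_exon_fraction = 0.25,
                       exons_per_gene = c(2L, 8L),
                       exon_length_bp = c(100L, 2000L),
                       intron_length_bp = c(200L, 2000L),
                       expression_log_mean = 0,
                       expression_log_sd = 1.5,
                       conditions = c(perm34 = 0.02, mut40 = 0.40,
                                      comp40 = 0.02),
                       total_reads_per_condition = 1e6,
                       read_length_bp = 50L,
                       class_proportions = c(G1 = 0.28, SM = 0.21, NP = 0.51),
                       n_chroms = 14L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              single_exon_fraction = single_exon_fraction,
              exons_per_gene = as.integer(exons_per_gene),
              exon_length_bp = as.integer(exon_length_bp),
              intron_length_bp = as.integer(intron_length_bp),
              expression_log_mean = expression_log_mean,
              expression_log_sd = expression_log_sd,
              conditions = conditions,
              total_reads_per_condition = as.numeric(total_reads_per_condition),
              read_length_bp = as.integer(read_length_bp),
              class_proportions = class_proportions,
              n_chroms = as.integer(n_chroms),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0L,
              single_exon_fraction >= 0, single_exon_fraction <= 1,
              length(exons_per_gene) == 2L,
              exons_per_gene[1] >= 2L, exons_per_gene[2] >= exons_per_gene[1],
              length(exon_length_bp) == 2L, exon_length_bp[1] > 0L,
              exon_length_bp[2] >= exon_length_bp[1],
              length(intron_length_bp) == 2L, intron_length_bp[1] > 0L,
              intron_length_bp[2] >= intron_length_bp[1],
              expression_log_sd >= 0,
              length(conditions) >= 1L, !is.null(names(conditions)),
              all(nzchar(names(conditions))),
              all(conditions >= 0), all(conditions <= 1),
              all(total_reads_per_condition > 0),
              read_length_bp > 0L,
              abs(sum(class_proportions) - 1) < 1e-8,
              all(sort(names(class_proportions)) == c("G1", "NP", "SM")),
              n_chroms >= 1L)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a gene-model set
#'
#' Draws gene structures (exon counts and feature lengths uniform over the
#' configured ranges), lays genes out across chromosomes with fixed
#' intergenic gaps, assigns cycle-class labels by the configured
#' proportions and a per-gene relative abundance from the configured
#' log-normal. Deterministic under the config seed. The requested
#' single-exon fraction is met exactly up to rounding.
#'
#' @param config A [sim_config()].
#' @return A `gene_models` object whose `genes` tibble carries an extra
#'   `true_abundance` column.
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  n_single <- round(n * config$single_exon_fraction)
  is_single <- rep(FALSE, n)
  if (n_single > 0L) is_single[sample.int(n, n_single)] <- TRUE

  # sample() treats a length-1 vector as 1:x; index explicitly instead
  resample <- function(x, k) x[sample.int(length(x), k, replace = TRUE)]

  n_ex <- ifelse(is_single, 1L,
                 resample(seq(config$exons_per_gene[1],
                              config$exons_per_gene[2]), n))
  gene_id <- sprintf("gene%05d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cls <- sample(names(config$class_proportions), n, replace = TRUE,
                prob = config$class_proportions)
  abundance <- stats::rlnorm(n, config$expression_log_mean,
                             config$expression_log_sd)
  chrom <- sprintf("chr%02d", (seq_len(n) - 1L) %% config$n_chroms + 1L)

  exon_len <- lapply(n_ex, function(k)
    resample(seq(config$exon_length_bp[1], config$exon_length_bp[2]), k))
  intron_len <- lapply(n_ex, function(k)
    if (k > 1L) resample(seq(config$intron_length_bp[1],
                             config$intron_length_bp[2]), k - 1L)
    else integer())

  # lay out genes sequentially per chromosome, 500 bp intergenic gap
  gap <- 500L
  offset <- integer(n)
  cursor <- stats::setNames(rep(0L, config$n_chroms),
                            sprintf("chr%02d", seq_len(config$n_chroms)))
  span <- vapply(seq_len(n), function(i)
    sum(exon_len[[i]]) + sum(intron_len[[i]]), numeric(1))
  for (i in seq_len(n)) {
    offset[i] <- cursor[[chrom[i]]]
    cursor[[chrom[i]]] <- cursor[[chrom[i]]] + as.integer(span[i]) + gap
  }

  ex_list <- lapply(seq_len(n), function(i) {
    el <- exon_len[[i]]; il <- intron_len[[i]]
    starts <- offset[i] + cumsum(c(0L, el[-length(el)] + il))
    tibble::tibble(gene_id = gene_id[i], chrom = chrom[i],
                   start = as.integer(starts),
                   end = as.integer(starts + el), strand = strand[i])
  })
  ex <- dplyr::bind_rows(ex_list)

  models <- gene_models(ex, class_table = tibble::tibble(gene_id = gene_id,
                                                         class = cls))
  models$genes$true_abundance <-
    abundance[match(models$genes$gene_id, gene_id)]
  models
}

#' Simulate aligned reads for one condition
#'
#' Reads are drawn from a two-component transcript pool per gene: a
#' fraction `u` of the gene's transcript molecules are unspliced pre-mRNA
#' (full gene span), the rest are spliced mRNA (exonic bases only). Read
#' sampling is proportional to molecule abundance times molecule length,
#' so the expected intronic/exonic read ratio of a gene is
#' `u * intron_length / exon_length`. Conditional on its component a read
#' start is uniform over the molecule; a spliced-component read that would
#' cross an exon junction is truncated at the junction boundary, so
#' spliced reads never cover an intronic base. Reads are emitted as single
#' contiguous genomic intervals on the gene's strand.
#'
#' @param models A `gene_models` object with a `true_abundance` column
#'   (from [simulate_gene_models()]), or any `gene_models` plus an
#'   `abundance` argument.
#' @param condition_id Condition label stamped on reads and truth records.
#' @param u Unspliced molar fraction in `[0, 1]` — a scalar applied to all
#'   genes, or a per-gene vector aligned with `models$genes` for
#'   heterogeneous-defect scenarios.
#' @param n_reads Number of reads to emit (exactly).
#' @param read_length Read length in bp; shrunk per-gene when longer than
#'   the spliced transcript (logged once).
#' @param seed Integer seed.
#' @param abundance Optional per-gene relative abundance overriding
#'   `models$genes$true_abundance`.
#' @return A list with `reads` (tibble `chrom`, `start`, `end`, `read_id`,
#'   `score`, `strand`; BED6 column order) and `truth` (tibble `gene_id`,
#'   `condition_id`, `true_u`, `true_abundance`, `expected_IE`).
#' @export
simulate_reads <- function(models, condition_id, u, n_reads,
                           read_length = 50L, seed = 1L, abundance = NULL) {
  stopifnot(inherits(models, "gene_models"), n_reads > 0, read_length > 0)
  g <- models$genes
  n_genes <- nrow(g)
  if (is.null(abundance)) abundance <- g$true_abundance
  if (is.null(abundance)) {
    stop("models carry no true_abundance; supply `abundance`", call. = FALSE)
  }
  stopifnot(length(abundance) == n_genes, all(abundance > 0))
  u <- if (length(u) == 1L) rep(u, n_genes) else u
  stopifnot(length(u) == n_genes, all(u >= 0), all(u <= 1))
  n_reads <- as.integer(n_reads)

  L_e <- g$exon_length_bp
  L_span <- L_e + g$intron_length_bp
  # read sampling weight: molecules x length, summed over the two components
  w <- abundance * ((1 - u) * L_e + u * L_span)
  p_unspliced <- u * L_span / ((1 - u) * L_e + u * L_span)

  set.seed(seed)
  gene_of <- sample.int(n_genes, n_reads, replace = TRUE, prob = w)
  unspliced <- stats::runif(n_reads) < p_unspliced[gene_of]

  if (any(read_length > L_e)) {
    message("read length ", read_length, " exceeds the spliced transcript of ",
            sum(read_length > L_e), " gene(s); reads there are shrunk")
  }

  # per-gene exon maps in transcript coordinates
  ex <- models$exons
  ex_by_gene <- split(seq_len(nrow(ex)), match(ex$gene_id, g$gene_id))

  start_out <- integer(n_reads)
  end_out <- integer(n_reads)
  n_truncated <- 0L

  idx_by_gene <- split(seq_len(n_reads), gene_of)
  for (gs in names(idx_by_gene)) {
    gi <- as.integer(gs)
    idx <- idx_by_gene[[gs]]
    rl_sp <- min(read_length, L_e[gi])
    rl_un <- min(read_length, L_span[gi])
    un <- idx[unspliced[idx]]
    sp <- idx[!unspliced[idx]]
    if (length(un) > 0L) {
      s <- g$span_start[gi] +
        floor(stats::runif(length(un)) * (L_span[gi] - rl_un + 1L))
      start_out[un] <- as.integer(s)
      end_out[un] <- as.integer(s + rl_un)
    }
    if (length(sp) > 0L) {
      rows <- ex_by_gene[[as.character(gi)]]
      el <- ex$end[rows] - ex$start[rows]
      cum0 <- cumsum(c(0L, el))            # transcript offsets of exon starts
      tpos <- floor(stats::runif(length(sp)) * (L_e[gi] - rl_sp + 1L))
      exon_idx <- findInterval(tpos, cum0[-length(cum0)],
                               rightmost.closed = FALSE)
      gstart <- ex$start[rows][exon_idx] + (tpos - cum0[exon_idx])
      gend_full <- gstart + rl_sp
      gend <- pmin(gend_full, ex$end[rows][exon_idx])  # truncate at junction
      n_truncated <- n_truncated + sum(gend < gend_full)
      start_out[sp] <- as.integer(gstart)
      end_out[sp] <- as.integer(gend)
    }
  }
  if (n_truncated > 0L) {
    message(condition_id, ": ", n_truncated,
            " spliced-component read(s) truncated at exon junctions")
  }

  reads <- tibble::tibble(
    chrom = g$chrom[gene_of],
    start = start_out,
    end = end_out,
    read_id = sprintf("%s_r%07d", condition_id, seq_len(n_reads)),
    score = 0L,
    strand = g$strand[gene_of]
  )
  truth <- tibble::tibble(
    gene_id = g$gene_id,
    condition_id = condition_id,
    true_u = u,
    true_abundance = abundance,
    expected_IE = ifelse(g$single_exon, 0,
                         u * g$intron_length_bp / g$exon_length_bp)
  )
  list(reads = reads, truth = truth)
}

#' Simulate reads for every configured condition
#'
#' Convenience wrapper: one [simulate_reads()] call per condition, seeds
#' derived deterministically from the config seed.
#'
#' @param models A `gene_models` from [simulate_gene_models()].
#' @param config The same [sim_config()] used to build `models`.
#' @return Named list per condition, each with `reads` and `truth`.
#' @export
simulate_all_conditions <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  out <- vector("list", length(config$conditions))
  names(out) <- names(config$conditions)
  for (k in seq_along(config$conditions)) {
    out[[k]] <- simulate_reads(
      models, names(config$conditions)[k], config$conditions[[k]],
      n_reads = config$total_reads_per_condition,
      read_length = config$read_length_bp,
      seed = derive_seed(config$seed, k)
    )
  }
  out
}

#' Write reads as BED6
#' @param reads Tibble as returned in `simulate_reads()$reads`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end),
    strand = ifelse(reads$strand %in% c("+", "-"), reads$strand, "*"),
    name = reads$read_id, score = reads$score
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read aligned reads from BED6
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end`, `read_id`, `score`, `strand`
#'   (0-based half-open).
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    read_id = if (!is.null(S4Vectors::mcols(gr)$name))
      S4Vectors::mcols(gr)$name else sprintf("read%d", seq_along(gr)),
    score = if (!is.null(S4Vectors::mcols(gr)$score))
      as.integer(S4Vectors::mcols(gr)$score) else 0L,
    strand = as.character(GenomicRanges::strand(gr))
  )
}
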