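#' Do two half-open intervals overlap?
#'
#' The package-wide overlap predicate: at least one shared base under
#' 0-based half-open coordinates. Abutting intervals do not overlap.
#' Vectorised over all four arguments.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds (end exclusive).
#' @return Logical vector.
#' @examples
#' intervals_overlap(0, 10, 10, 20)  # FALSE: abutment
#' intervals_overlap(0, 10, 9, 20)   # TRUE
#' @export
intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

#' Count exonic and intronic reads per gene
#'
#' For every gene, tallies the reads overlapping (by at least one base)
#' any of its exons and, separately, any of its derived introns — the
#' native equivalent of two independent coverageBed runs against the exon
#' and intron feature sets. A read spanning an exon/intron boundary
#' therefore increments both counters by default; a read touching two
#' exons of the same gene still counts once. Counting is strand-agnostic
#' unless `stranded = TRUE`. Genes are counted independently: a read over
#' two overlapping genes counts toward both.
#'
#' @param models A `gene_models` object.
#' @param reads Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and `strand` (only consulted when `stranded = TRUE`).
#' @param condition_id Condition label stamped on the output.
#' @param stranded If `TRUE`, only same-strand reads count.
#' @param boundary_policy How a read overlapping both an exon and an
#'   intron of the same gene is tallied: `"both"` (default; what two
#'   coverageBed runs produce), `"exon_priority"` or `"intron_priority"`
#'   assign it to one class only.
#' @return A tibble with one row per gene: `gene_id`, `condition_id`,
#'   `exon_reads`, `intron_reads`, `library_size` (total input reads,
#'   including reads on unknown chromosomes). The number of reads skipped
#'   for lying on chromosomes absent from the models is attached as
#'   attribute `unknown_chrom_reads`.
#' @export
count_reads <- function(models, reads, condition_id,
                        stranded = FALSE,
                        boundary_policy = c("both", "exon_priority",
                                            "intron_priority")) {
  stopifnot(inherits(models, "gene_models"), is.data.frame(reads))
  boundary_policy <- match.arg(boundary_policy)
  n_total <- nrow(reads)
  known <- reads$chrom %in% unique(models$genes$chrom)
  n_unknown <- sum(!known)
  if (n_unknown > 0L) {
    message(n_unknown, " read(s) on unknown chromosome(s) counted in the ",
            "library size but assigned to no gene")
  }
  rd <- reads[known, , drop = FALSE]
  n_genes <- nrow(models$genes)

  q <- if (nrow(rd) > 0L) GenomicRanges::GRanges(
    rd$chrom, IRanges::IRanges(rd$start + 1L, rd$end),
    strand = if (stranded) rd$strand else "*") else NULL

  # unique (read, gene) pair keys however many features a read touches
  hit_pairs <- function(features) {
    if (nrow(features) == 0L || is.null(q)) return(numeric())
    s <- GenomicRanges::GRanges(
      features$chrom, IRanges::IRanges(features$start + 1L, features$end),
      strand = if (stranded) features$strand else "*")
    h <- GenomicRanges::findOverlaps(q, s, ignore.strand = !stranded)
    gidx <- match(features$gene_id, models$genes$gene_id)
    unique((as.numeric(S4Vectors::queryHits(h)) - 1) * n_genes +
             gidx[S4Vectors::subjectHits(h)])
  }

  pairs_e <- hit_pairs(models$exons)
  pairs_i <- hit_pairs(models$introns)
  if (boundary_policy == "exon_priority") {
    pairs_i <- setdiff(pairs_i, pairs_e)
  } else if (boundary_policy == "intron_priority") {
    pairs_e <- setdiff(pairs_e, pairs_i)
  }

  tally <- function(pairs) {
    tabulate(as.integer((pairs - 1) %% n_genes) + 1L, nbins = n_genes)
  }

  out <- tibble::tibble(
    gene_id = models$genes$gene_id,
    condition_id = condition_id,
    exon_reads = tally(pairs_e),
    intron_reads = tally(pairs_i),
    library_size = n_total
  )
  attr(out, "unknown_chrom_reads") <- n_unknown
  out
}

#' Write per-gene counts as TSV
#' @param counts Output of [count_reads()] (rows from several conditions
#'   may be bound together).
#' @param path Output path.
#' @param header_lines Optional `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path, header_lines = character()) {
  write_tsv_with_header(counts, path, header_lines)
}

#' Read per-gene counts from TSV
#' @param path Path written by [write_counts_tsv()].
#' @return Tibble of counts.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read aligned reads from SAM/BAM, degraded to intervals
#'
#' Adapter for alignment files: each mapped record becomes one
#' `(chrom, start, end, strand)` interval (0-based half-open), with the
#' reference span approximated by the query width. Needs the Rsamtools
#' package; SAM input is converted to BAM in a temporary file first.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return Tibble with the same columns as [read_reads_bed()].
#' @export
read_reads_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("the SAM/BAM adapter needs the Rsamtools package", call. = FALSE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "strand"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos)
  tibble::tibble(
    chrom = as.character(rec$rname)[keep],
    start = rec$pos[keep] - 1L,
    end = rec$pos[keep] - 1L + rec$qwidth[keep],
    read_id = rec$qname[keep],
    score = 0L,
    strand = as.character(rec$strand)[keep]
  )
}
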