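#' Derive intron intervals from exon coordinates
#'
#' Introns are never taken from the annotation: they are exactly the gaps
#' between consecutive exons of a gene. Coordinates are 0-based half-open
#' throughout the package.
#'
#' @param exons A data frame with integer columns `start` and `end`
#'   (0-based half-open), sorted by `start`, pairwise non-overlapping.
#' @return A tibble with columns `start`, `end`; zero rows for genes with
#'   at most one exon.
#' @examples
#' derive_introns(data.frame(start = c(0, 200, 400), end = c(100, 300, 500)))
#' @export
derive_introns <- function(exons) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  n <- nrow(exons)
  if (n <= 1L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  if (is.unsorted(exons$start, strictly = FALSE)) {
    stop("exons must be sorted by start before deriving introns", call. = FALSE)
  }
  if (any(exons$start[-1] < exons$end[-n])) {
    stop("exons overlap; introns are undefined", call. = FALSE)
  }
  tibble::tibble(
    start = as.integer(exons$end[-n]),
    end   = as.integer(exons$start[-1])
  )
}

#' Assemble a gene-model set from an exon table
#'
#' Validates per-gene exon chains, derives introns, attaches cell-cycle
#' class labels, and computes summary lengths. Genes whose exons overlap
#' are rejected with a diagnostic rather than silently kept; a gene whose
#' exons sit on more than one chromosome is a hard error (that indicates a
#' corrupted annotation, not a questionable gene model).
#'
#' @param exons Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `strand` ("+", "-" or "*").
#'   Multiple rows per gene are one exon each; duplicated/overlapping rows
#'   from multiple transcript lines should be unioned before this call
#'   (see [parse_gene_models()]).
#' @param class_table Optional data frame `gene_id`, `class` with class in
#'   `{G1, SM, NP}`. Genes absent from the table are labelled `NP`.
#' @return An object of class `gene_models`: a list with tibbles `genes`
#'   (one row per gene: `gene_id`, `chrom`, `strand`, `cycle_class`,
#'   `n_exons`, `single_exon`, `exon_length_bp`, `intron_length_bp`,
#'   `span_start`, `span_end`), `exons` and `introns` (interval tables with
#'   `gene_id`), plus a `rejected` attribute naming genes dropped for
#'   overlapping exons.
#' @export
gene_models <- function(exons, class_table = NULL) {
  stopifnot(is.data.frame(exons),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  if (!"strand" %in% names(exons)) exons$strand <- "*"
  exons <- tibble::as_tibble(exons)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start < 0L) || any(exons$end <= exons$start)) {
    stop("invalid exon interval: need start >= 0 and end > start", call. = FALSE)
  }

  chrom_per_gene <- tapply(exons$chrom, exons$gene_id, function(x) length(unique(x)))
  if (any(chrom_per_gene > 1L)) {
    bad <- names(chrom_per_gene)[chrom_per_gene > 1L]
    stop("gene(s) with exons on multiple chromosomes: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  exons <- dplyr::arrange(exons, .data$gene_id, .data$start)

  # reject genes with overlapping exons (diagnostic, not fatal)
  ov <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(bad = dplyr::n() > 1L &&
                       any(.data$start[-1] < .data$end[-dplyr::n()]))
  rejected <- ov$gene_id[ov$bad]
  if (length(rejected) > 0L) {
    message("rejecting ", length(rejected),
            " gene(s) with overlapping exons: ",
            paste(utils::head(rejected, 5), collapse = ", "))
    exons <- exons[!exons$gene_id %in% rejected, , drop = FALSE]
  }
  if (nrow(exons) == 0L) stop("no valid gene models", call. = FALSE)

  exons <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(exon_rank = dplyr::row_number()) |>
    dplyr::ungroup()

  introns <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::reframe(chrom = .data$chrom[1], strand = .data$strand[1],
                   derive_introns(dplyr::pick(dplyr::everything()))) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(intron_rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand", "intron_rank")

  genes <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(chrom = .data$chrom[1], strand = .data$strand[1],
                     n_exons = dplyr::n(),
                     exon_length_bp = sum(.data$end - .data$start),
                     span_start = min(.data$start), span_end = max(.data$end)) |>
    dplyr::mutate(single_exon = .data$n_exons == 1L)
  il <- introns |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(intron_length_bp = sum(.data$end - .data$start))
  genes <- dplyr::left_join(genes, il, by = "gene_id")
  genes$intron_length_bp[is.na(genes$intron_length_bp)] <- 0L

  genes$cycle_class <- "NP"
  if (!is.null(class_table)) {
    stopifnot(all(c("gene_id", "class") %in% names(class_table)))
    bad_class <- setdiff(unique(class_table$class), c("G1", "SM", "NP"))
    if (length(bad_class) > 0L) {
      stop("unknown cycle class: ", paste(bad_class, collapse = ", "), call. = FALSE)
    }
    idx <- match(genes$gene_id, class_table$gene_id)
    genes$cycle_class <- ifelse(is.na(idx), "NP", class_table$class[idx])
  }

  genes <- dplyr::arrange(genes, .data$chrom, .data$span_start, .data$gene_id)
  genes <- dplyr::select(genes, "gene_id", "chrom", "strand", "cycle_class",
                         "n_exons", "single_exon", "exon_length_bp",
                         "intron_length_bp", "span_start", "span_end")
  ord <- genes$gene_id
  exons <- exons[order(match(exons$gene_id, ord), exons$start), ]
  introns <- introns[order(match(introns$gene_id, ord), introns$start), ]

  structure(
    list(genes = genes,
         exons = dplyr::select(exons, "gene_id", "chrom", "start", "end",
                               "strand", "exon_rank"),
         introns = introns),
    rejected = rejected,
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  g <- x$genes
  cat(sprintf("gene_models: %d genes (%d single-exon) on %d chromosome(s)\n",
              nrow(g), sum(g$single_exon), length(unique(g$chrom))))
  cat(sprintf("  exons: %d   introns: %d   classes: %s\n",
              nrow(x$exons), nrow(x$introns),
              paste(sprintf("%s=%d", names(table(g$cycle_class)),
                            table(g$cycle_class)), collapse = " ")))
  invisible(x)
}

#' Parse gene models from a GFF3/GTF annotation
#'
#' Reads exon features with [rtracklayer::import()], converts the 1-based
#' closed coordinates of GFF/GTF to the package's 0-based half-open
#' convention at this boundary (the only place dialect logic lives), unions
#' exons across multiple transcript lines of the same gene, and assembles
#' validated models via [gene_models()].
#'
#' @param path Path to a GFF3 or GTF file.
#' @param class_table Optional gene to cycle-class mapping (see
#'   [gene_models()]), or a path to a two-column TSV `gene_id  class`.
#' @param feature_type Feature type to keep (default `"exon"`).
#' @param gene_id_attribute Attribute naming the gene. Default `"gene_id"`;
#'   falls back to `Parent` then `ID` when absent.
#' @param format Passed to [rtracklayer::import()]; inferred from the file
#'   extension by default.
#' @return A `gene_models` object, deterministically ordered by
#'   (chrom, span start, gene id).
#' @export
parse_gene_models <- function(path, class_table = NULL, feature_type = "exon",
                              gene_id_attribute = "gene_id", format = NULL) {
  gr <- if (is.null(format)) rtracklayer::import(path) else
    rtracklayer::import(path, format = format)
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
             as.character(S4Vectors::mcols(gr)$type) == feature_type]
  if (length(gr) == 0L) {
    stop("no '", feature_type, "' features found in ", path, call. = FALSE)
  }
  mc <- S4Vectors::mcols(gr)
  gid <- NULL
  for (key in unique(c(gene_id_attribute, "Parent", "ID"))) {
    if (key %in% names(mc)) {
      v <- mc[[key]]
      if (methods::is(v, "List")) v <- vapply(v, function(e)
        if (length(e)) as.character(e[1]) else NA_character_, character(1))
      v <- as.character(v)
      if (!all(is.na(v))) { gid <- v; break }
    }
  }
  if (is.null(gid) || anyNA(gid)) {
    stop("could not resolve a gene identifier for every exon feature",
         call. = FALSE)
  }

  ex <- tibble::tibble(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GFF 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )

  # several transcript lines for one gene -> union of exon intervals
  ex_union <- ex |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::reframe(reduce_intervals(.data$start, .data$end)) |>
    dplyr::ungroup()
  if (nrow(ex_union) < nrow(ex)) {
    message("merged overlapping/duplicate exon lines for ",
            length(unique(ex$gene_id[duplicated(ex[c("gene_id", "start", "end")]) |
              duplicated(ex[c("gene_id", "start", "end")], fromLast = TRUE)])),
            " gene(s) (union of exons taken)")
  }

  if (is.character(class_table) && length(class_table) == 1L) {
    class_table <- read_class_table(class_table)
  }
  gene_models(ex_union, class_table = class_table)
}

#' Union of a set of intervals on one chromosome
#' @noRd
reduce_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
  tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature and its `exon` features per gene, 1-based
#' closed per the GFF3 dialect. Version/date comment lines that would vary
#' between runs are stripped so output bytes depend only on the models.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$exons
  g <- models$genes
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$span_start + 1L, g$span_end),
    strand = ifelse(g$strand %in% c("+", "-"), g$strand, "*"),
    source = "spliceratio", type = "gene", ID = g$gene_id, gene_id = g$gene_id
  )
  exon_gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
    strand = ifelse(ex$strand %in% c("+", "-"), ex$strand, "*"),
    source = "spliceratio", type = "exon",
    ID = sprintf("%s.exon%d", ex$gene_id, ex$exon_rank),
    Parent = ex$gene_id, gene_id = ex$gene_id
  )
  all_gr <- c(gene_gr, exon_gr)
  all_gr <- all_gr[order(as.character(GenomicRanges::seqnames(all_gr)),
                         GenomicRanges::start(all_gr),
                         S4Vectors::mcols(all_gr)$gene_id,
                         as.character(S4Vectors::mcols(all_gr)$type) != "gene")]
  rtracklayer::export(all_gr, path, format = "gff3")
  lines <- readLines(path)
  keep <- !grepl("^##(source-version|date)", lines)
  writeLines(lines[keep], path)
  invisible(path)
}

#' Read a cycle-class table
#'
#' @param path Two-column TSV `gene_id  class` with class in `{G1, SM, NP}`.
#'   A header line is optional.
#' @return A tibble `gene_id`, `class`.
#' @export
read_class_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^gene_id\\b", first)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           col.names = c("gene_id", "class"),
                           colClasses = "character")
  tibble::as_tibble(tab)
}

#' Write a cycle-class table
#' @param models A `gene_models` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_class_table <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  utils::write.table(models$genes[, c("gene_id", "cycle_class")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("gene_id", "class"))
  invisible(path)
}
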