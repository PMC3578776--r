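#' Gene strata for stratified comparisons
#'
#' Builds the standard strata: `all` (every gene), the cycle classes
#' `G1` / `SM` / `NP` restricted to multi-exon genes (so that the three
#' classes partition the intron-containing genes a splicing comparison
#' can use), and `single_exon` (the splicing-independent expression
#' control stratum, meaningful only for RPKM comparisons).
#'
#' Stratum membership comes only from the class labels attached to the
#' models (annotation table or simulator truth); the package never
#' re-derives cell-cycle peaks from expression.
#'
#' @param models A `gene_models` object.
#' @return Named list of character vectors of gene ids.
#' @export
make_strata <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  multi <- g$gene_id[!g$single_exon]
  list(
    all = g$gene_id,
    G1 = intersect(g$gene_id[g$cycle_class == "G1"], multi),
    SM = intersect(g$gene_id[g$cycle_class == "SM"], multi),
    NP = intersect(g$gene_id[g$cycle_class == "NP"], multi),
    single_exon = g$gene_id[g$single_exon]
  )
}

#' Run a condition comparison inside one gene stratum
#'
#' Identical contract to [compare_from_table()], restricted to the genes
#' of the stratum; the result carries the stratum name. The `all` stratum
#' reproduces the unstratified comparison exactly.
#'
#' @param tab A [splice_table()].
#' @param cond_x,cond_y Condition ids.
#' @param stratum_name Name of the stratum (looked up in `strata`).
#' @param strata Named list from [make_strata()].
#' @inheritParams compare_from_table
#' @return A `comparison_result` with `$stratum` set.
#' @export
stratified_compare <- function(tab, cond_x, cond_y, stratum_name, strata,
                               metric = c("ie", "rpkm"),
                               test = "one_sample",
                               fold_threshold = 2, pseudocount = 0.01,
                               count_pseudocount = 1) {
  metric <- match.arg(metric)
  if (!stratum_name %in% names(strata)) {
    stop("unknown stratum '", stratum_name, "'", call. = FALSE)
  }
  ids <- strata[[stratum_name]]
  if (length(intersect(ids, tab$gene_id)) == 0L) {
    stop("stratum '", stratum_name, "' is empty for this table",
         call. = FALSE)
  }
  compare_from_table(tab, cond_x, cond_y, metric = metric,
                     genes = ids, test = test,
                     fold_threshold = fold_threshold,
                     pseudocount = pseudocount,
                     count_pseudocount = count_pseudocount,
                     stratum = stratum_name)
}
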