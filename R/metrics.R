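#' RPKM expression level
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `1e9 * C / (N * L)` for `C` exonic reads, exon length `L` bp and
#' library size `N`. Intronic hits are excluded by construction: `C` is
#' the exon-overlap count.
#'
#' @param exon_reads Exonic read count(s) `C`.
#' @param exon_length_bp Exon model length(s) `L` in bp, `> 0`.
#' @param library_size Total mapped reads `N`, `> 0`.
#' @return Numeric RPKM, zero iff `exon_reads == 0`.
#' @examples
#' rpkm(1000, 2000, 1e7)  # 50
#' @export
rpkm <- function(exon_reads, exon_length_bp, library_size) {
  if (any(exon_length_bp <= 0)) stop("exon_length_bp must be > 0", call. = FALSE)
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  1e9 * as.numeric(exon_reads) /
    (as.numeric(library_size) * as.numeric(exon_length_bp))
}

#' Intronic/exonic read ratio (I/E)
#'
#' `(I + pseudocount) / (E + pseudocount)`. Near zero for fully spliced
#' transcript populations; elevated when unspliced pre-mRNA accumulates.
#' Undefined (`NA`) when the denominator is zero — never coerced to zero,
#' since absence of exonic evidence says nothing about splicing.
#'
#' @param intron_reads,exon_reads Nonnegative counts, vectorised.
#' @param pseudocount Nonnegative count added to both numerator and
#'   denominator. Default 0 (raw reported ratios); classification
#'   downstream uses 1.
#' @return Numeric ratio, `NA` where undefined.
#' @export
ie_ratio <- function(intron_reads, exon_reads, pseudocount = 0) {
  if (any(intron_reads < 0) || any(exon_reads < 0)) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  if (any(pseudocount < 0)) stop("pseudocount must be nonnegative", call. = FALSE)
  num <- intron_reads + pseudocount
  den <- exon_reads + pseudocount
  ifelse(den == 0, NA_real_, num / den)
}

#' Signed diagonal distance to the identity line
#'
#' For a gene measured in two conditions, the point `(x, y)` lies on
#' `y = x` when nothing changed. The statistic is the perpendicular
#' (shortest) distance from `(x, y)` to that diagonal, signed by
#' direction: `d = (y - x) / sqrt(2)`, positive when the Y condition
#' exceeds the X condition. `abs(d)` is the geometric point-to-line
#' distance; the sign makes a two-tailed t-test of the distances against
#' zero directional and well-posed.
#'
#' @param x,y Finite values of the same quantity (I/E or RPKM) in the two
#'   conditions. Vectorised.
#' @return Signed numeric distance(s).
#' @examples
#' diagonal_distance(1, 1)  # 0
#' diagonal_distance(0, 2)  # sqrt(2)
#' @export
diagonal_distance <- function(x, y) {
  (y - x) / sqrt(2)
}

#' Classify the direction of an I/E change
#'
#' `increased` when `(ie_y + pseudocount) / (ie_x + pseudocount)` meets
#' the fold threshold, `decreased` for the reciprocal, otherwise
#' `unchanged`. Antisymmetric under swapping x and y.
#'
#' @param ie_x,ie_y Defined (non-`NA`) ratios, vectorised.
#' @param fold_threshold Fold change required to call a direction; `> 1`.
#' @param pseudocount Nonnegative offset added to both ratios before the
#'   fold comparison so calls are stable near zero.
#' @return Character vector in `{increased, decreased, unchanged}` (`NA`
#'   where either input is `NA`).
#' @export
classify_change <- function(ie_x, ie_y, fold_threshold = 2, pseudocount = 0.01) {
  if (any(fold_threshold <= 1)) stop("fold_threshold must be > 1", call. = FALSE)
  if (any(pseudocount < 0)) stop("pseudocount must be nonnegative", call. = FALSE)
  r <- (ie_y + pseudocount) / (ie_x + pseudocount)
  out <- ifelse(r >= fold_threshold, "increased",
                ifelse(r <= 1 / fold_threshold, "decreased", "unchanged"))
  out[is.na(ie_x) | is.na(ie_y)] <- NA_character_
  out
}

#' Classify restoration under genetic rescue
#'
#' A gene is eligible when its ratio is classified `increased` in the
#' defect condition relative to the reference. Restoration is `full` when
#' the rescued ratio is `unchanged` versus the reference, `partial` when
#' the rescued ratio dropped from the defect by at least the fold
#' threshold yet remains `increased` versus the reference, else `none`.
#' Ineligible genes are labelled `ineligible` and tallied separately.
#'
#' @param ie_ref,ie_defect,ie_rescued Defined ratios in the reference,
#'   defect and rescued conditions. Vectorised.
#' @inheritParams classify_change
#' @return Character vector in `{full, partial, none, ineligible}`.
#' @export
classify_restoration <- function(ie_ref, ie_defect, ie_rescued,
                                 fold_threshold = 2, pseudocount = 0.01) {
  defect_call <- classify_change(ie_ref, ie_defect, fold_threshold, pseudocount)
  rescued_vs_ref <- classify_change(ie_ref, ie_rescued, fold_threshold, pseudocount)
  dropped <- (ie_defect + pseudocount) / (ie_rescued + pseudocount) >=
    fold_threshold
  out <- rep(NA_character_, length(ie_ref))
  elig <- !is.na(defect_call) & defect_call == "increased" &
    !is.na(rescued_vs_ref)
  out[!elig] <- "ineligible"
  out[elig & rescued_vs_ref == "unchanged"] <- "full"
  out[elig & rescued_vs_ref == "increased" & dropped] <- "partial"
  out[elig & is.na(out)] <- "none"
  out
}

#' Per-gene splice table across conditions
#'
#' The per-gene summary of the whole experiment: raw I/E ratio (no
#' pseudocount; `NA` where undefined, permanently `NA` for single-exon
#' genes), RPKM, and the underlying counts, one column set per condition,
#' plus the cycle class.
#'
#' @param counts Tibble of per-gene counts, rows from all conditions bound
#'   together (see [count_reads()]).
#' @param models The `gene_models` the counts were made against.
#' @return A wide tibble: `gene_id`, `cycle_class`, `single_exon`,
#'   `exon_length_bp`, `intron_length_bp`, then per condition
#'   `exon_reads_<cond>`, `intron_reads_<cond>`, `ie_<cond>`,
#'   `rpkm_<cond>`.
#' @export
splice_table <- function(counts, models) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  long <- counts |>
    dplyr::left_join(g[, c("gene_id", "single_exon", "exon_length_bp")],
                     by = "gene_id") |>
    dplyr::mutate(
      ie = ifelse(.data$single_exon, NA_real_,
                  ie_ratio(.data$intron_reads, .data$exon_reads)),
      rpkm = rpkm(.data$exon_reads, .data$exon_length_bp, .data$library_size)
    ) |>
    dplyr::select("gene_id", "condition_id", "exon_reads", "intron_reads",
                  "ie", "rpkm")
  wide <- tidyr::pivot_wider(
    long, id_cols = "gene_id", names_from = "condition_id",
    values_from = c("exon_reads", "intron_reads", "ie", "rpkm"),
    names_glue = "{.value}_{condition_id}"
  )
  out <- dplyr::left_join(
    g[, c("gene_id", "cycle_class", "single_exon",
          "exon_length_bp", "intron_length_bp")],
    wide, by = "gene_id")
  tibble::as_tibble(out)
}

#' Compare splicing (or expression) between two conditions
#'
#' Forms per-gene signed diagonal distances between paired values in
#' condition X and condition Y, tests them, and classifies each gene's
#' direction of change. Genes undefined in either condition are excluded
#' from the distance set (never imputed). `one_sample` mode runs a
#' two-tailed Student's t-test of the mean signed distance against zero.
#' `two_sample` mode contrasts this comparison's distance set against a
#' second one (e.g. reference-vs-defect against reference-vs-rescued)
#' with a two-tailed two-sample Student's t-test; supply `x2`/`y2`.
#'
#' @param x,y Per-gene values (same gene order) in conditions X and Y;
#'   `NA` marks undefined.
#' @param gene_id Optional gene identifiers aligned with `x`.
#' @param test `"one_sample"` or `"two_sample"`.
#' @param x2,y2 Second value pair for `two_sample` mode.
#' @param fold_threshold,pseudocount Passed to [classify_change()]. The
#'   classification may be run on separate (e.g. count-pseudocounted)
#'   values via `class_x`/`class_y`.
#' @param class_x,class_y Values used for the change classification;
#'   default to `x` and `y`.
#' @param label_x,label_y Condition labels carried in the result.
#' @param stratum Optional stratum name carried in the result.
#' @return A `comparison_result`: list with `distances` (tibble
#'   `gene_id`, `x`, `y`, `distance`, `abs_distance`, `change`),
#'   `t_statistic`, `df`, `p_value`, `mean_distance`, tallies
#'   `n_increased`/`n_decreased`/`n_unchanged`, `n_used`, `test`,
#'   and `degenerate` (`TRUE` when the distance set had zero variance
#'   with nonzero mean, in which case the p-value is reported at the
#'   machine floor).
#' @export
compare_conditions <- function(x, y, gene_id = NULL,
                               test = c("one_sample", "two_sample"),
                               x2 = NULL, y2 = NULL,
                               fold_threshold = 2, pseudocount = 0.01,
                               class_x = x, class_y = y,
                               label_x = "x", label_y = "y",
                               stratum = "all") {
  test <- match.arg(test)
  stopifnot(length(x) == length(y))
  if (is.null(gene_id)) gene_id <- sprintf("gene%d", seq_along(x))
  ok <- !is.na(x) & !is.na(y) & is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) {
    stop("need >= 3 genes with defined values in both conditions; have ",
         sum(ok), call. = FALSE)
  }
  d <- diagonal_distance(x[ok], y[ok])
  change <- classify_change(class_x[ok], class_y[ok],
                            fold_threshold, pseudocount)
  distances <- tibble::tibble(
    gene_id = gene_id[ok], x = x[ok], y = y[ok],
    distance = d, abs_distance = abs(d), change = change
  )

  degenerate <- FALSE
  if (test == "one_sample") {
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        t_stat <- 0; p <- 1; df <- length(d) - 1L
      } else {
        t_stat <- sign(mean(d)) * Inf; p <- .Machine$double.xmin
        df <- length(d) - 1L; degenerate <- TRUE
      }
    } else {
      tt <- stats::t.test(d, mu = 0)
      t_stat <- unname(tt$statistic); p <- tt$p.value
      df <- unname(tt$parameter)
    }
  } else {
    stopifnot(!is.null(x2), !is.null(y2), length(x2) == length(y2))
    ok2 <- !is.na(x2) & !is.na(y2) & is.finite(x2) & is.finite(y2)
    if (sum(ok2) < 3L) {
      stop("second distance set needs >= 3 defined genes; have ",
           sum(ok2), call. = FALSE)
    }
    d2 <- diagonal_distance(x2[ok2], y2[ok2])
    if (stats::sd(c(d, d2)) == 0) {
      t_stat <- 0; p <- 1; df <- length(d) + length(d2) - 2L
    } else {
      tt <- stats::t.test(d, d2, var.equal = TRUE)
      t_stat <- unname(tt$statistic); p <- tt$p.value
      df <- unname(tt$parameter)
    }
  }

  structure(
    list(pair = c(x = label_x, y = label_y), test = test, stratum = stratum,
         distances = distances,
         mean_distance = mean(d),
         t_statistic = t_stat, df = df, p_value = p,
         degenerate = degenerate,
         n_used = nrow(distances),
         n_increased = sum(change == "increased", na.rm = TRUE),
         n_decreased = sum(change == "decreased", na.rm = TRUE),
         n_unchanged = sum(change == "unchanged", na.rm = TRUE),
         fold_threshold = fold_threshold, pseudocount = pseudocount),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison [%s]: %s vs %s (%s, stratum %s)\n",
              "diagonal-distance", x$pair[["x"]], x$pair[["y"]],
              x$test, x$stratum))
  cat(sprintf("  n = %d genes; mean signed distance = %.4g\n",
              x$n_used, x$mean_distance))
  cat(sprintf("  t = %.4g on %.1f df, p = %.3g%s\n", x$t_statistic, x$df,
              x$p_value,
              if (x$degenerate) " (zero-variance guard: p at machine floor)"
              else ""))
  cat(sprintf("  increased %d / decreased %d / unchanged %d (fold >= %g)\n",
              x$n_increased, x$n_decreased, x$n_unchanged, x$fold_threshold))
  invisible(x)
}

#' Compare two conditions straight from a splice table
#'
#' Pulls the chosen metric columns for the two conditions out of a
#' [splice_table()] and runs [compare_conditions()]. For `metric = "ie"`
#' the distance set uses the raw ratios while the change classification
#' uses count-level pseudocounted ratios (`(I + k) / (E + k)`), keeping
#' reporting and inference separate.
#'
#' @param tab A [splice_table()].
#' @param cond_x,cond_y Condition ids (column suffixes in `tab`).
#' @param metric `"ie"` or `"rpkm"`.
#' @param genes Optional gene-id subset (stratification).
#' @param count_pseudocount Pseudocount (reads) for classification ratios
#'   when `metric = "ie"`.
#' @inheritParams compare_conditions
#' @return A `comparison_result`.
#' @export
compare_from_table <- function(tab, cond_x, cond_y, metric = c("ie", "rpkm"),
                               genes = NULL,
                               test = "one_sample", x2 = NULL, y2 = NULL,
                               fold_threshold = 2, pseudocount = 0.01,
                               count_pseudocount = 1, stratum = "all") {
  metric <- match.arg(metric)
  col <- function(cond) {
    nm <- paste0(metric, "_", cond)
    if (!nm %in% names(tab)) {
      stop("no column '", nm, "' in the splice table; condition '", cond,
           "' unknown?", call. = FALSE)
    }
    tab[[nm]]
  }
  if (!is.null(genes)) {
    keep <- tab$gene_id %in% genes
    if (!any(keep)) stop("gene subset is empty for this table", call. = FALSE)
    tab <- tab[keep, , drop = FALSE]
  }
  x <- col(cond_x); y <- col(cond_y)
  if (metric == "ie") {
    cx <- (tab[[paste0("intron_reads_", cond_x)]] + count_pseudocount) /
      (tab[[paste0("exon_reads_", cond_x)]] + count_pseudocount)
    cy <- (tab[[paste0("intron_reads_", cond_y)]] + count_pseudocount) /
      (tab[[paste0("exon_reads_", cond_y)]] + count_pseudocount)
    cx[tab$single_exon] <- NA_real_
    cy[tab$single_exon] <- NA_real_
  } else {
    cx <- x; cy <- y
  }
  compare_conditions(x, y, gene_id = tab$gene_id, test = test,
                     x2 = x2, y2 = y2,
                     fold_threshold = fold_threshold,
                     pseudocount = pseudocount,
                     class_x = cx, class_y = cy,
                     label_x = cond_x, label_y = cond_y, stratum = stratum)
}

#' Restoration tallies for a rescue experiment
#'
#' Classifies every gene across (reference, defect, rescued) and tallies
#' `{full, partial, none}` among eligible genes. Classification uses
#' count-pseudocounted ratios as in [compare_from_table()].
#'
#' @param tab A [splice_table()].
#' @param cond_ref,cond_defect,cond_rescued Condition ids.
#' @inheritParams compare_from_table
#' @return List with `calls` (tibble `gene_id`, `restoration`) and
#'   `tally` (named counts incl. `eligible` and `restored_fraction` =
#'   (full + partial) / eligible).
#' @export
restoration_summary <- function(tab, cond_ref, cond_defect, cond_rescued,
                                fold_threshold = 2, pseudocount = 0.01,
                                count_pseudocount = 1) {
  cls <- function(cond) {
    v <- (tab[[paste0("intron_reads_", cond)]] + count_pseudocount) /
      (tab[[paste0("exon_reads_", cond)]] + count_pseudocount)
    v[tab$single_exon] <- NA_real_
    v
  }
  r <- classify_restoration(cls(cond_ref), cls(cond_defect), cls(cond_rescued),
                            fold_threshold, pseudocount)
  calls <- tibble::tibble(gene_id = tab$gene_id, restoration = r)
  elig <- sum(r %in% c("full", "partial", "none"))
  tally <- c(full = sum(r == "full", na.rm = TRUE),
             partial = sum(r == "partial", na.rm = TRUE),
             none = sum(r == "none", na.rm = TRUE),
             ineligible = sum(r == "ineligible", na.rm = TRUE))
  list(calls = calls,
       tally = tally,
       eligible = elig,
       restored_fraction = if (elig > 0)
         unname((tally["full"] + tally["partial"]) / elig) else NA_real_)
}
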