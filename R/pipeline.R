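#' Build a run configuration
#'
#' Declarative description of an end-to-end run: either a simulation
#' block or input paths, the ordered comparison design, thresholds, and
#' an output directory. Every random draw in the run flows from the one
#' seed carried here.
#'
#' @param out_dir Output directory (created; must not already exist
#'   unless `overwrite = TRUE` at run time).
#' @param simulate A [sim_config()], or `NULL` when real inputs are given.
#' @param inputs List with `gene_models` (GFF3/GTF path), `reads` (named
#'   list/vector of BED6 paths, one per condition) and optional
#'   `class_table` (TSV path). Ignored when `simulate` is set.
#' @param design List of comparisons, each a list/vector with elements
#'   `x`, `y` and optional `test` (default `"one_sample"`).
#' @param metric `"ie"` or `"rpkm"` for the comparisons.
#' @param strata Character vector of stratum names to additionally run
#'   each comparison in (see [make_strata()]); `"all"` is always run.
#' @param fold_threshold,pseudocount,count_pseudocount Thresholds for
#'   classification (see [classify_change()], [compare_from_table()]).
#' @param restoration Optional list/vector with `ref`, `defect`,
#'   `rescued` condition ids to tally restoration calls.
#' @param seed Root seed; recorded in every output header.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       simulate = NULL, inputs = NULL,
                       design = list(),
                       metric = "ie",
                       strata = character(),
                       fold_threshold = 2, pseudocount = 0.01,
                       count_pseudocount = 1,
                       restoration = NULL,
                       seed = 1L) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  if (is.null(simulate) && is.null(inputs)) {
    stop("config needs either a simulation block or input paths", call. = FALSE)
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  stopifnot(metric %in% c("ie", "rpkm"), fold_threshold > 1,
            pseudocount >= 0, count_pseudocount >= 0)
  cfg <- list(out_dir = out_dir, simulate = simulate, inputs = inputs,
              design = design, metric = metric, strata = strata,
              fold_threshold = fold_threshold, pseudocount = pseudocount,
              count_pseudocount = count_pseudocount,
              restoration = restoration, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' The file mirrors [run_config()]: top-level keys `out_dir`, `design`,
#' `metric`, `strata`, `thresholds` (`fold_threshold`, `pseudocount`,
#' `count_pseudocount`), `restoration`, `seed`, and either `simulate`
#' (keys of [sim_config()]; `conditions` as a `name: u` map) or `inputs`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    s$conditions <- unlist(s$conditions)
    if (!is.null(y$seed) && is.null(s$seed)) s$seed <- y$seed
    sim <- do.call(sim_config, s)
  }
  # YAML 1.1 reads a bare `y`/`n` key as a boolean; map it back
  design <- lapply(y$design %||% list(), function(cmp) {
    names(cmp)[names(cmp) %in% c("TRUE", "yes")] <- "y"
    cmp
  })
  th <- y$thresholds %||% list()
  run_config(
    out_dir = y$out_dir,
    simulate = sim,
    inputs = y$inputs,
    design = design,
    metric = y$metric %||% "ie",
    strata = unlist(y$strata) %||% character(),
    fold_threshold = th$fold_threshold %||% 2,
    pseudocount = th$pseudocount %||% 0.01,
    count_pseudocount = th$count_pseudocount %||% 1,
    restoration = y$restoration,
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end pipeline
#'
#' simulate (or load) -> count -> splice table -> comparisons (plus
#' strata) -> restoration tallies -> report. All outputs are staged in a
#' temporary directory and renamed into place only on success, so no
#' partial output survives an error. Every TSV carries `#` header lines
#' with the config hash, seed and thresholds; outputs are byte-identical
#' across runs with the same config and seed.
#'
#' @param config A [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @param overwrite Replace an existing output directory.
#' @param quiet Suppress stage narration.
#' @return The run manifest (list: paths of all outputs relative to
#'   `out_dir`, plus per-comparison summary statistics), invisibly also
#'   written as `manifest.json`.
#' @export
run_pipeline <- function(config, overwrite = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)

  out_dir <- config$out_dir
  if (dir.exists(out_dir)) {
    if (!overwrite) stop("output directory exists: ", out_dir, call. = FALSE)
    unlink(out_dir, recursive = TRUE)
  }

  # fail before any computation if declared inputs are missing
  if (is.null(config$simulate)) {
    missing_in <- character()
    if (!file.exists(config$inputs$gene_models %||% "")) {
      missing_in <- c(missing_in, "gene_models")
    }
    for (cond in names(config$inputs$reads)) {
      if (!file.exists(config$inputs$reads[[cond]])) {
        missing_in <- c(missing_in, paste0("reads[", cond, "]"))
      }
    }
    if (length(missing_in) > 0L) {
      stop("missing inputs: ", paste(missing_in, collapse = ", "),
           call. = FALSE)
    }
  }

  stage <- tempfile("spliceratio-stage-")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  # hash the analysis content, not the output location
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  hdr <- c(paste0("config_hash=", hash),
           paste0("seed=", config$seed),
           paste0("fold_threshold=", num_chr(config$fold_threshold)),
           paste0("pseudocount=", num_chr(config$pseudocount)),
           paste0("count_pseudocount=", num_chr(config$count_pseudocount)))

  manifest <- list(config_hash = hash, seed = config$seed, outputs = list(),
                   summaries = list())

  # ---- stage 1: models and reads -----------------------------------------
  if (!is.null(config$simulate)) {
    say("simulating gene models (", config$simulate$n_genes, " genes)")
    models <- simulate_gene_models(config$simulate)
    sims <- simulate_all_conditions(models, config$simulate)
    write_gene_models_gff3(models, file.path(stage, "gene_models.gff3"))
    write_class_table(models, file.path(stage, "class_table.tsv"))
    manifest$outputs$gene_models <- "gene_models.gff3"
    manifest$outputs$class_table <- "class_table.tsv"
    truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
    write_tsv_with_header(truth, file.path(stage, "truth.tsv"), hdr)
    manifest$outputs$truth <- "truth.tsv"
    reads_by_cond <- lapply(sims, `[[`, "reads")
    for (cond in names(reads_by_cond)) {
      bed <- paste0("reads_", cond, ".bed")
      write_reads_bed(reads_by_cond[[cond]], file.path(stage, bed))
      manifest$outputs[[paste0("reads_", cond)]] <- bed
      say("  ", cond, ": ", nrow(reads_by_cond[[cond]]), " reads")
    }
  } else {
    say("loading gene models from ", config$inputs$gene_models)
    models <- parse_gene_models(config$inputs$gene_models,
                                class_table = config$inputs$class_table)
    reads_by_cond <- lapply(config$inputs$reads, read_reads_bed)
  }

  # ---- stage 2: counting --------------------------------------------------
  counts <- dplyr::bind_rows(lapply(names(reads_by_cond), function(cond) {
    cc <- count_reads(models, reads_by_cond[[cond]], cond)
    say("counted ", cond, ": ", sum(cc$exon_reads), " exon hits, ",
        sum(cc$intron_reads), " intron hits")
    cc
  }))
  write_counts_tsv(counts, file.path(stage, "counts.tsv"), hdr)
  manifest$outputs$counts <- "counts.tsv"

  # ---- stage 3: splice table ---------------------------------------------
  tab <- splice_table(counts, models)
  write_tsv_with_header(tab, file.path(stage, "splice_table.tsv"), hdr)
  manifest$outputs$splice_table <- "splice_table.tsv"

  # ---- stage 4: comparisons (plus strata) --------------------------------
  strata <- make_strata(models)
  strat_names <- unique(c("all", config$strata))
  for (cmp in config$design) {
    cmp <- as.list(cmp)
    test <- cmp$test %||% "one_sample"
    for (sn in strat_names) {
      res <- stratified_compare(tab, cmp$x, cmp$y, sn, strata,
                                metric = config$metric, test = test,
                                fold_threshold = config$fold_threshold,
                                pseudocount = config$pseudocount,
                                count_pseudocount = config$count_pseudocount)
      tag <- paste0(cmp$x, "_vs_", cmp$y,
                    if (sn != "all") paste0("_", sn) else "")
      fn <- paste0("comparison_", tag, ".tsv")
      write_tsv_with_header(res$distances, file.path(stage, fn), hdr)
      manifest$outputs[[paste0("comparison_", tag)]] <- fn
      manifest$summaries[[tag]] <- list(
        x = cmp$x, y = cmp$y, test = res$test, stratum = sn,
        n_used = res$n_used, mean_distance = res$mean_distance,
        t_statistic = res$t_statistic, df = res$df, p_value = res$p_value,
        n_increased = res$n_increased, n_decreased = res$n_decreased,
        n_unchanged = res$n_unchanged
      )
      say("compared ", tag, ": n=", res$n_used,
          " mean d=", signif(res$mean_distance, 4),
          " p=", signif(res$p_value, 3))
    }
  }

  # ---- stage 5: restoration ----------------------------------------------
  if (!is.null(config$restoration)) {
    r <- as.list(config$restoration)
    rs <- restoration_summary(tab, r$ref, r$defect, r$rescued,
                              fold_threshold = config$fold_threshold,
                              pseudocount = config$pseudocount,
                              count_pseudocount = config$count_pseudocount)
    write_tsv_with_header(rs$calls, file.path(stage, "restoration.tsv"), hdr)
    manifest$outputs$restoration <- "restoration.tsv"
    manifest$summaries$restoration <- list(
      ref = r$ref, defect = r$defect, rescued = r$rescued,
      tally = as.list(rs$tally), eligible = rs$eligible,
      restored_fraction = rs$restored_fraction
    )
    say("restoration: ", rs$tally[["full"]], " full / ",
        rs$tally[["partial"]], " partial / ", rs$tally[["none"]],
        " none of ", rs$eligible, " eligible")
  }

  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$outputs$manifest <- "manifest.json"

  # atomic publish
  parent <- dirname(out_dir)
  if (!dir.exists(parent)) dir.create(parent, recursive = TRUE)
  if (!file.rename(stage, out_dir)) {
    # staging tempdir may sit on another filesystem; fall back to copy
    dir.create(out_dir, recursive = TRUE)
    ok <- file.copy(list.files(stage, full.names = TRUE), out_dir,
                    recursive = TRUE)
    if (!all(ok)) stop("failed to publish outputs to ", out_dir, call. = FALSE)
  }
  on.exit(NULL, add = FALSE)
  unlink(stage, recursive = TRUE)
  say("run complete: ", out_dir)
  invisible(manifest)
}
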