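#' Derive a child seed from a root seed
#'
#' Deterministic, collision-poor within a run, and kept below 2^31 so the
#' result is always a valid R integer seed.
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

#' Write a tibble as TSV with `#` provenance header lines
#' @noRd
write_tsv_with_header <- function(df, path, header_lines = character()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(header_lines) > 0L) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stable hash of a configuration object
#'
#' md5 of the deparsed object; used to stamp outputs so a table can be
#' traced back to the exact configuration that produced it.
#' @noRd
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}

#' Format a number for JSON/report output without locale surprises
#' @noRd
num_chr <- function(x) format(x, scientific = FALSE, trim = TRUE)
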