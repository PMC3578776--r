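#!/usr/bin/env Rscript
# Step 2 — count exonic and intronic reads per gene.
#
# Loads the gene models and per-condition BED reads written by
# 01_simulate.R, tallies reads overlapping exons and derived introns
# (>= 1 base, both classes for boundary-spanning reads), and writes one
# counts table for all conditions to results/counts.tsv.

library(spliceratio)

data_dir <- "results/data"
models <- parse_gene_models(file.path(data_dir, "gene_models.gff3"),
                            class_table = file.path(data_dir,
                                                    "class_table.tsv"))

bed_files <- list.files(data_dir, pattern = "^reads_.*\\.bed$",
                        full.names = TRUE)
conditions <- sub("^reads_(.*)\\.bed$", "\\1", basename(bed_files))

counts <- do.call(rbind, lapply(seq_along(bed_files), function(i) {
  reads <- read_reads_bed(bed_files[i])
  cc <- count_reads(models, reads, conditions[i])
  message(sprintf("%s: %d exon hits, %d intron hits over %d genes",
                  conditions[i], sum(cc$exon_reads), sum(cc$intron_reads),
                  nrow(cc)))
  cc
}))

write_counts_tsv(counts, "results/counts.tsv",
                 header_lines = paste0("source=", data_dir))
message("wrote results/counts.tsv")
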