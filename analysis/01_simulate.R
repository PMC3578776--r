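#!/usr/bin/env Rscript
# Step 1 — build the synthetic study.
#
# Three conditions mimicking a temperature-sensitive splicing-factor
# experiment: a permissive-temperature baseline in which ~2% of transcript
# molecules are unspliced, a restrictive-temperature condition in which
# splicing fails for 40% of molecules, and a complemented strain back at
# baseline. 300 genes (25% single-exon), 1e5 aligned reads per condition.
# Writes gene models (GFF3), reads (BED6), class labels and the truth
# table under results/data/.

library(spliceratio)

cfg <- read_run_config(system.file("extdata", "demo_run.yaml",
                                   package = "spliceratio"))$simulate
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

models <- simulate_gene_models(cfg)
print(models)

write_gene_models_gff3(models, file.path(out, "gene_models.gff3"))
write_class_table(models, file.path(out, "class_table.tsv"))

sims <- simulate_all_conditions(models, cfg)
truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
utils::write.table(truth, file.path(out, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (cond in names(sims)) {
  write_reads_bed(sims[[cond]]$reads,
                  file.path(out, paste0("reads_", cond, ".bed")))
  message(sprintf("%s: %d reads (u = %.2f)", cond,
                  nrow(sims[[cond]]$reads), cfg$conditions[[cond]]))
}
message("wrote ", out)
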