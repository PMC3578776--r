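# spliceratio

Genome-wide quantification of mRNA splicing defects from aligned RNA-seq
reads.

When a general splicing factor is lost — the motivating case is a
temperature-sensitive mutant of an RRM-domain splicing regulator shifted to
its restrictive temperature — unspliced pre-mRNA accumulates across the
transcriptome. This package measures that failure, per gene and genome-wide,
and tests whether a genetic rescue restores it.

## The statistic

For every intron-containing gene, reads overlapping exons (`C_E`) and reads
overlapping the introns derived from the exon coordinates (`C_I`) are
counted — the equivalent of two independent coverageBed runs — giving the
intronic/exonic ratio **I/E = C_I / C_E** (near zero for mature mRNA,
elevated when pre-mRNA accumulates) and the expression level
**RPKM = 10⁹ · C_E / (N · L_E)**.

Comparing two conditions, each gene is a point (I/E_x, I/E_y). Under no
change the point lies on the diagonal y = x, so the per-gene statistic is
the perpendicular distance to that line, kept signed:

    d = (y − x) / √2

|d| is the geometric point-to-line distance; the sign makes the two-tailed
one-sample Student's t-test of mean d against 0 directional. Genes are
additionally classified `increased` / `decreased` / `unchanged` by a
pseudocounted two-fold rule, and rescue experiments tally per-gene
restoration (`full` / `partial` / `none`) among genes whose ratio rose in
the defect.

A synthetic-data generator produces gene models and aligned reads from
mixtures of spliced and unspliced transcript molecules (per-condition
unspliced fraction `u`, log-normal expression spread), with a truth table
satisfying `E[I/E] = u · L_I / L_E` so the whole estimator chain can be
validated by parameter recovery. See the methods vignette
(`vignettes/splicing-defect-quantification.Rmd`) for the model,
conventions and limitations.

## Worked example

The `analysis/` scripts run the full study on a simulated three-condition
design — permissive baseline (`perm34`, u = 0.02), splicing defect
(`mut40`, u = 0.40), complemented rescue (`comp40`, u = 0.02); 300 genes,
10⁵ reads per condition:

```sh
Rscript analysis/01_simulate.R   # gene models (GFF3), reads (BED6), truth
Rscript analysis/02_count.R      # exon/intron read tallies per gene
Rscript analysis/03_metrics.R    # I/E, RPKM, distances, tests, restoration
Rscript analysis/04_stratify.R   # G1 / S-M / NP and single-exon strata
```

Step 3 prints:

```
comparison [diagonal-distance]: perm34 vs mut40 (one_sample, stratum all)
  n = 223 genes; mean signed distance = 0.2275
  t = 25.96 on 222.0 df, p = 3.4e-69
  increased 213 / decreased 0 / unchanged 10 (fold >= 2)
comparison [diagonal-distance]: perm34 vs comp40 (one_sample, stratum all)
  n = 224 genes; mean signed distance = -0.0006577
  t = -0.5505 on 223.0 df, p = 0.583
  increased 5 / decreased 16 / unchanged 203 (fold >= 2)
restoration: 193 full + 5 partial of 215 eligible (92.1%); 17 not restored
```

Reading it: the defect shifts I/E up transcriptome-wide (mean signed
distance 0.23, overwhelmingly significant; 213 of 223 genes individually
two-fold increased), while the complemented strain is statistically
indistinguishable from baseline (p = 0.58) with 92% of affected genes
fully or partially restored at this sequencing depth. Step 4 shows the
G1, S/M and non-periodic strata moving alike under the class-uniform
defect, and compares single-exon genes — which have no I/E — on RPKM.

The same pipeline runs from files on disk (GFF3/GTF gene models, BED6
reads, TSV class labels) through a declarative YAML config; see
`inst/extdata/demo_run.yaml` and `?run_pipeline`.

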