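---
title: "Quantifying genome-wide splicing defects with intron/exon read ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genome-wide splicing defects with intron/exon read ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceratio)
```

## The problem and the measurement model

When a general splicing factor fails — for instance a temperature-sensitive
allele shifted to its restrictive temperature — unspliced pre-mRNA
accumulates across the transcriptome. Aligned RNA-seq reads make this
directly measurable: reads from mature transcripts fall on exons, while
reads from retained introns betray pre-mRNA. For every intron-containing
gene the package counts

* $C_E$ — reads overlapping (by at least one base) any exon of the gene, and
* $C_I$ — reads overlapping any intron, where introns are *derived* as the
  gaps between consecutive exon coordinates, never taken from annotation,

and forms the intronic/exonic ratio $I/E = C_I / C_E$. A fully spliced
transcript population has $I/E$ near zero; a splicing defect raises it.
Expression level is summarised as RPKM, $10^9 C_E / (N L_E)$, with $N$ the
library size and $L_E$ the summed exon length in bp; intronic hits are
excluded from $C_E$ by construction.

To compare two conditions, each gene becomes a point $(I/E_x,\; I/E_y)$.
Under no change the point sits on the diagonal $y = x$, so the natural
per-gene statistic is the shortest (perpendicular) distance from the point
to that line. We keep the direction:

$$ d = \frac{y - x}{\sqrt 2}, $$

whose magnitude is exactly the geometric point-to-line distance. The sign
matters: a two-tailed Student's t-test on strictly nonnegative distances
could never distinguish "splicing got worse" from "splicing got better",
whereas the signed version makes the one-sample test of $\bar d = 0$ both
two-tailed and directional. The unsigned distance is reported alongside.
A two-sample mode contrasts two whole distance sets (e.g. baseline→defect
against baseline→rescue) with a two-sample Student's t-test.

The test is one *global* test per comparison — the question is whether
splicing changed transcriptome-wide, not gene-by-gene — so no per-gene
multiple-testing correction applies.

## Counting conventions

Counting mirrors two independent coverageBed-style runs against the exon
and the intron feature sets:

* Overlap means at least one shared base; interval arithmetic is 0-based
  half-open internally, with GFF's 1-based closed coordinates converted at
  the parser boundary and nowhere else.
* A read spanning an exon/intron boundary increments **both** counters —
  exactly what two independent feature-set runs produce. Because this
  convention is a genuine choice, `boundary_policy` can instead assign
  such reads to one class (`exon_priority`, `intron_priority`).
* A read touching two exons of the same gene counts once per gene per
  class: the unit is "reads aligning", not bases.
* Counting is strand-agnostic by default (`stranded = TRUE` restricts to
  same-strand hits), duplicate read records are deliberately not
  collapsed, and genes are counted independently, so a read inside two
  overlapping gene loci counts toward both.
* Reads on chromosomes absent from the models stay in the library size
  $N$ but reach no gene; they are tallied in a diagnostic.

Single-exon genes have no introns, hence a permanently undefined $I/E$;
they keep a well-defined RPKM and serve as a splicing-independent
expression control stratum.

## Classification rules

Reported ratios are raw ($C_I / C_E$, undefined when $C_E = 0$); inference
about individual genes adds a pseudocount. This separation exists because
a reported table should show the data, while a fold-change call must be
stable near zero. Defaults, stamped into every output header:

* `count_pseudocount = 1` read, applied as $(C_I + 1)/(C_E + 1)$ when
  ratios feed classification;
* `fold_threshold = 2`: a gene is `increased` when the (offset) ratio of
  ratios reaches 2, `decreased` below 1/2, else `unchanged`;
* for a rescue experiment, a gene `increased` in defect-vs-reference is
  *eligible*, and is restored `full`y when its rescued ratio is
  `unchanged` versus the reference, `partial`ly when it dropped at least
  two-fold from the defect yet remains `increased` versus reference,
  otherwise `none`.

The fold threshold of 2 is the conventional minimal fold change used for
such calls; it is exposed in the configuration rather than hard-coded.
Genes undefined in either compared condition are excluded from the
distance set, never imputed — imputation would manufacture distances.

## What the simulator emulates

`simulate_gene_models()` + `simulate_reads()` generate the study the
analysis assumes, with a truth table for parameter recovery:

* gene structures: exon counts uniform on 2–8 (a configurable fraction of
  genes single-exon, default 25%), exon lengths 100–2000 bp, intron
  lengths 200–2000 bp, genes laid out over 14 chromosomes;
* expression: per-gene relative abundance from a log-normal
  ($\sigma_{\log} = 1.5$), reproducing the multi-decade spread seen on
  log-log expression axes in real data;
* the defect: each condition has an unspliced fraction $u$, interpreted
  as the **molar fraction of transcript molecules that are unspliced**.
  A read picks its source molecule proportional to abundance × molecule
  length, so with probability
  $u L_{\text{span}} / (u L_{\text{span}} + (1-u) L_E)$ it comes from
  pre-mRNA (uniform over the gene span) and otherwise from the spliced
  transcript (uniform over exonic bases, mapped back to the genome). This
  length-weighted mixture gives the clean identity
  $\mathbb E[I/E] = u\, L_I / L_E$, which the recovery checks lean on. A
  per-read mixture that ignored molecule length would instead give
  $u L_I / (L_E + L_I - u L_I)$ and no such identity;
* default conditions `perm34` ($u = 0.02$), `mut40` ($u = 0.40$),
  `comp40` ($u = 0.02$): a near-clean baseline, a severe but partial
  splicing failure, and a complemented strain returning to baseline.

Reads are emitted as single contiguous intervals; a spliced-component
read that would cross an exon junction is truncated at the junction
(logged), so spliced reads never touch an intron and plain BED interval
counting stays exact. What the simulator does *not* model: sequencing
error, mapping ambiguity, multi-mapping, paired ends, coverage biases,
isoform structure, or genes with overlapping loci. Passing recovery tests
therefore validates the estimator chain, not robustness to those
real-data complications.

Because reads are counted by ≥1-base overlap, a read of length $R$
"smears" each feature by $R - 1$ positions; with the default geometry
(several-hundred-bp introns, $R = 50$) this inflates observed $I/E$ by a
few percent over $u L_I / L_E$, visible as recovery slopes slightly above
1 and covered by the ±10% recovery band.

## Numerical and degenerate-input choices

* Zero-variance distance sets: all distances exactly zero yields
  $t = 0,\ p = 1$; zero variance with nonzero mean (a degenerate but
  directional set) reports $p$ at the machine floor with a `degenerate`
  flag rather than failing inside `t.test()`.
* Comparisons require at least 3 genes defined in both conditions and
  fail with the deficit named.
* Log-scale plots floor zero values at a printed constant (default
  `1e-4`) instead of silently dropping them.
* Overlapping exons within a gene reject that gene with a diagnostic;
  exons of one gene on two chromosomes are a hard error. Multiple
  transcript lines for one gene are unioned into one exon chain (logged):
  one exon chain per gene is the operating assumption.
* All randomness flows from one root seed (child seeds are derived
  deterministically and kept below $2^{31}$); fixed-seed runs are
  byte-identical, which the test suite asserts file-by-file.
* Outputs are staged in a temporary directory and renamed into place on
  success, so no partial output survives an error.

## Problem sizes used by the checks

The validation suite exercises: oracle equivalence for the distance
statistic (10³ random points against an iteratively refined grid search,
agreement to 10⁻⁶) and for counting (20 random fixtures up to 10⁴ reads ×
50 genes against a nested-loop overlap oracle, exact agreement);
parameter recovery on 1,000 multi-exon genes at 10⁶ reads per condition
(recovery slope within 1 ± 0.1, defect $p < 10^{-6}$, rescue
$p \ge 0.05$, ≥95% of eligible genes restored, RPKM–abundance rank
correlation > 0.95); and the type-I error of the one-sample test over
1,000 identical-$u$ replicates of 500 genes (rejection rate 5% ± 2% at
nominal $\alpha = 0.05$). The shipped demo configuration uses 300 genes
and 10⁵ reads per condition, which is ample for the global test while
keeping a laptop run in seconds; per-gene restoration calls sharpen with
depth, so the demo's restored fraction sits a little below the
full-depth value.

## Known limitations

* $I/E$ compares conditions, not genes: longer-intron genes have larger
  expected ratios at the same $u$, so cross-gene comparisons need the
  $u L_I / L_E$ scaling the truth table records.
* The ratio estimator is noisy for weakly expressed genes; the global
  t-test tolerates this, but per-gene calls at low counts lean on the
  pseudocount.
* Cycle-class strata come from the supplied annotation only; the package
  does not re-derive periodicity from expression.
* One exon chain per gene: alternative isoforms are out of scope, and a
  union of transcripts stands in where annotations disagree.
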