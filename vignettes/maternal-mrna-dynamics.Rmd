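---
title: "Methods: spike-in-calibrated maternal mRNA dynamics in single oocytes and embryos"
author: "oodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maternal mRNA dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oodyn)
```

## The problem

During oocyte maturation transcription is silent: the germinal-vesicle (GV)
oocyte carries a fixed store of maternal mRNA that is degraded in programmed
waves — first during the GV-to-MII transition (M-decay), then after
fertilisation — while zygotic genome activation (ZGA) begins new
transcription by day 3 (D3). A mutation that perturbs this machinery shows
up in three ways: a changed absolute mRNA dosage in GV oocytes, shallower
decay of maternal transcripts at MII and D3, and weaker ZGA output at D3.
None of these is visible to ordinary relative RNA-seq normalisation, which
forces every sample to the same scale; quantifying them needs ERCC
spike-ins, added in equal absolute amounts to every sample.

`oodyn` implements this analysis for a control-versus-mutant, GV/MII/D3
single-sample design: spike-in-calibrated dosage, small-\(n\)
negative-binomial differential expression, a nine-cluster taxonomy of decay
trajectories, transition (Sankey) and quadrant analyses, gene-set overlaps,
and — for the companion protein experiment — differential AP-MS interactome
thresholding. A synthetic-data generator with full ground truth stands in
for restricted-access patient data, so every stage is testable.

## Quantification and calibration

TPM is computed over **all** rows, endogenous genes and spike-ins together:

\[ \mathrm{TPM}_{gs} = 10^6 \cdot
   \frac{c_{gs}/\ell_g}{\sum_{g'} c_{g's}/\ell_{g'}} \]

with \(c\) counts and \(\ell\) effective length in bases. Spikes must share
the per-million denominator — that is what lets them carry absolute
information. Because spike input is constant per cell, a sample's spike TPM
total is inversely proportional to its endogenous content, and the
calibration factor

\[ k_s = \frac{\operatorname{median}_{s'}\bigl(\sum_{g \in \mathrm{spike}}
  \mathrm{TPM}_{gs'}\bigr)}{\sum_{g \in \mathrm{spike}} \mathrm{TPM}_{gs}} \]

rescales each column so endogenous calibrated totals compare across samples
as absolute per-cell dosage. The median sample anchors the scale: robust to
a single degraded oocyte, and it makes recalibration a no-op. Calibration
never changes within-sample gene ratios. Dosage summaries exclude spike
rows and compare genotypes per stage with a two-sided Welch *t*-test on
per-sample totals (Welch rather than pooled-variance because group
variances at \(n \le 5\) cannot be assumed equal).

Differential expression runs on **raw counts** with internal size factors,
not on calibrated values: a global dosage shift (the mutant-GV phenotype)
is deliberately absorbed by normalisation there, while dosage and decay
analyses use the calibrated scale. Keeping the two scales separate is what
lets the pipeline distinguish "less of everything" from "more of this
transcript relative to that".

## Differential expression at tiny n

The tester is a negative-binomial Wald test built from first principles so
that each step is inspectable:

* **Size factors** — median-of-ratios across genes detected in every
  sample, falling back to library-size ratios.
* **Dispersion** — method of moments on size-factor-scaled counts, pooled
  across groups after centring each group mean:
  \(\hat\alpha = \max\{0, (s^2-\bar\mu)/\bar\mu^2\}\), then shrunk half-way
  toward a mean–dispersion trend \(\alpha(\mu) = a + b/\mu\) (least squares
  on genes with positive raw estimates, coefficients clamped non-negative,
  fallback to the mean raw dispersion), floored at \(10^{-8}\). The
  half-weight shrink trades a little bias for a large variance reduction at
  \(n = 3\) per group; the trend form mirrors the standard parametric
  choice in the field.
* **Wald statistic** — \(\log_2\mathrm{FC} = \log_2\frac{\bar\mu_{mut} +
  0.5}{\bar\mu_{ctrl} + 0.5}\); the 0.5 pseudocount stabilises zeros at
  \(n \le 3\). The NB variance \(\mu + \alpha\mu^2\) is propagated to the
  log-ratio by the delta method; p-values are two-sided normal.
* **Multiple testing** — Benjamini–Hochberg step-up, written out explicitly
  (`bhAdjust()`), with `stats::p.adjust` and a brute-force step-up kept as
  independent oracles in the test suite.

A gene is called **up** iff \(\log_2\mathrm{FC} > 1\) *and* adjusted
\(p < 0.05\) — strict inequalities on both sides — and **down**
symmetrically. On simulated data these choices give empirical type-I error
near the nominal 5% and high power at a true 4-fold change with three
samples per group; the test suite and `scripts/acceptance.R` recompute both.

## The decay-cluster taxonomy

Per gene, stage and genotype the expression summary is the **median over
replicates of \(\log_2(\mathrm{calibrated\ TPM} + 1)\)** — the median
because at \(n \le 5\) one aberrant oocyte should not move a trajectory.
Two transitions follow: \(\Delta_1 = \mathrm{MII} - \mathrm{GV}\) and
\(\Delta_2 = \mathrm{D3} - \mathrm{MII}\).

Genes expressed in controls (median calibrated TPM \(> 2\) at one or more
stages) are classified on their **control** transitions: *degraded* when
\(\Delta \le -1\), *elevated* when \(\Delta \ge +1\), else *stable*. The
boundary is inclusive — "2-fold" means at least 2-fold — which is the
natural reading of a fold-change rule and is configurable. The \(3 \times
3\) table defines the clusters:

| | \(\Delta_2\) degraded | \(\Delta_2\) stable | \(\Delta_2\) elevated |
|---|---|---|---|
| **\(\Delta_1\) degraded** | III | I | VIII |
| **\(\Delta_1\) stable** | II | IV | VI |
| **\(\Delta_1\) elevated** | IX | V | VII |

Clusters I–III are the maternal-decay classes; VI is the ZGA class.
Mutant genes inherit the control-defined cluster, so mutant trajectories
overlay the same classes. Per cluster the **impairment statistic** is the
median over member genes of (mutant \(\Delta\)) − (control \(\Delta\)) on
the cluster's defining degrading transitions — positive when mutant decay
is shallower — with a one-sided Wilcoxon signed-rank test across member
genes; elevation-defined clusters get the analogous elevation deficit.

Two companion views use the per-stage DEG calls: the **Sankey flows**
count, on the common gene universe, movements between up/down/ns status
across GV→MII and MII→D3 (marginals are conserved by construction); the
**quadrant analysis** crosses control \(\Delta_1\) with the mutant-vs-
control fold change at MII. Its headline quadrant — up in mutant MII with
control \(\Delta_1 < -1\) — contains exactly the transcripts that should
have been cleared during maturation but escaped. Quadrant membership uses
strict inequalities on both axes so that the four labels partition the
changed MII DEGs.

## Gene-set overlaps and the interactome rules

Overlaps are reported as \(100\cdot|L \cap S|/|L|\) with an integer
display rounding (half away from zero) alongside the exact value, plus an
upper-tail hypergeometric enrichment p computed in log space. The universe
defaults to the DEG-tested genes of that stage. One reported fraction is
worth a note: 457 of 1145 is 39.9%, which this package displays as 40%;
the source literature rounds it to 41%. The arithmetic here is exact and
left unreconciled.

The AP-MS module applies the published thresholds: a protein is a bait
interactor when its pulldown is **more than ten-fold** over the vector
control (strict, one-sided — enrichment is the only biologically meaningful
direction in a pulldown, despite absolute-value phrasing in methods texts);
a wild-type interactor shows **reduced binding** when mutant/wild-type
\(\le 2/3\) (inclusive: "at least 30% reduction" includes exactly 30%). A
3-fold variant of the reduction rule is available as an option. Zero
intensities are guarded by a small pseudocount (default 0.01) rather than
imputed; missing-at-zero is monotone and simple.

## What the generator emulates — and what it does not

`simulateExperiment()` draws, per gene, a baseline \(\log_2\) GV rate, adds
signed steps of `cluster_step_log2` across the two transitions according to
the gene's cluster, then applies three mutant effects:

* `mutant_gv_dosage_factor` (default **0.6**) multiplies every endogenous
  mutant rate — the global GV dosage reduction;
* `mutant_decay_attenuation` (default **0.3**) scales each *degradation*
  step — mutant decay keeps only 30% of its depth;
* `mutant_zga_attenuation` (default **0.3**) scales *elevation* steps of
  the MII→D3 transition only — ZGA impairment is a day-3 phenomenon, so
  GV→MII elevation (clusters V, VII, IX) is left intact in mutants.

Spike-ins have identical absolute rates in every sample. Counts arise by
drawing a log-normal library size (mean \(10^6\), CV 0.2 — typical
low-input single-oocyte depth), allocating it across relative rates, and
sampling each gene from a negative binomial with dispersion 0.1. All
randomness flows through one seed.

Default design values: three samples per stage-by-genotype cell (a
realistic patient-material budget; the dosage-recovery analyses use five),
nine clusters of 200 genes, 92 spike-in species (the size of the standard
ERCC mix) at 5% of the control-GV library.

The baseline distribution (\(\log_2\) mean 6, SD 1.5) was set so that
simulated transcripts sit at \(10^2\)–\(10^3\) TPM, where planted
trajectories are identifiable under the \(\log_2(x+1)\) measurement: below
roughly TPM 2 the pseudocount compresses a true 4-fold step to under the
2-fold threshold, so truth labels there would be unrecoverable *by
construction* — low-expression behaviour is instead exercised directly by
the filter tests. This is the main sense in which the generator is easier
than real data. Other simplifications: no batch or technical covariates, no
gene–gene correlation, equal cluster sizes by default (real decay classes
are very unequal — decay-dominated size configurations are exercised in the
tests), mutant effects uniform across genes, and a pure global scaling for
the mutant GV effect, which makes genotype DE at GV structurally null after
normalisation (in real data GV DEGs exist because the dosage change is not
perfectly uniform). Passing recovery tests therefore demonstrates
correctness of the machinery under the assumed NB/compositional model, not
performance on real single-oocyte libraries.

## Numerical and degenerate-input choices

* TPM columns sum to \(10^6\) within \(10^{-6}\) relative; an all-zero
  sample stays all-zero and is flagged in provenance instead of erroring.
* A sample with zero spike signal is an error naming the sample — there is
  no defensible imputation for it.
* Dispersion floor \(10^{-8}\); all-zero genes get dispersion 0 with a
  flag; genes zero in both groups get fold change 0 and \(p = 1\).
* BH excludes `NA` p-values from \(m\) and propagates them.
* The hypergeometric tail is summed in log space (log-sum-exp), accurate
  for extreme enrichment.
* Tables are UTF-8 tab-separated, `#` comments ignored, id in the first
  column; floats are written at 17 significant digits so write→read is the
  identity to \(10^{-12}\) relative or better; every result directory
  carries a JSON manifest with file checksums, parameters and seed.
* PCA runs on the 500 most variable endogenous genes (all, with a warning,
  if fewer) of \(\log_2(\mathrm{calibrated}+1)\), centred per gene;
  coordinates are deterministic up to sign.

## Worked example

```{r example, eval = FALSE}
sim <- simulateExperiment(simulationConfig(seed = 1))
res <- runPipeline(sim$experiment, sim$spike_ref,
                   gene_sets = sim$gene_sets, out_dir = "oodyn-results")
res$dosage$tests                 # per-stage control-vs-mutant dosage
table(res$clusters$cluster)      # decay-cluster census
res$trajectories$impairment      # mutant decay impairment per cluster
```

## Known limitations

* The NB Wald test is a documented stand-in, not a reimplementation of any
  published package; its contracts are its own (calibration and power are
  verified by simulation, and a reference NB fit serves as a cross-check in
  the test suite).
* With \(n = 3\) the Welch test on dosage totals has few degrees of
  freedom; its p-values are indicative rather than sharp.
* The cluster taxonomy is threshold-based, not model-based: genes near a
  boundary flip clusters under resampling. No half-life or kinetic model
  is fitted.
* Replicate averaging for AP-MS intensities (geometric mean of positive
  values) happens upstream of `callInteractors()`; the module does not
  model protein-level variance.
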