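---
title: "Models and methods behind cropqtl"
author: "cropqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cropqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cropqtl analyzes pooled single-cell CRISPRi screens of the CROP-seq type,
in which a library of guide RNAs — most targeting promoters (TSS) or
candidate regulatory elements, plus non-targeting (NT) controls — is
transduced into cells at low multiplicity of infection (MOI), and both
the transcriptome and the guide repertoire of each cell are read out by
single-cell RNA-seq. The analytical question is which element perturbs
which gene: element-to-gene (E2G) mapping. This vignette explains the
statistical models the package implements, the defaults and why they were
chosen, what the bundled synthetic screen generator does and does not
emulate, and the package's known limitations.

## Guide-to-cell assignment

For cell $c$ and guide $g$, let $x_{gc}$ be the guide's UMI count in the
cell's guide library, $N_c = \sum_g x_{gc}$ the cell's total guide-library
size, and $p_g$ the guide's expected proportion estimated from plasmid
library sequencing. Under pure background (ambient RNA, PCR artifacts),
$x_{gc} \sim \mathrm{Binomial}(N_c, p_g)$. A guide is called present when
the inclusive upper tail $P[X \ge x_{gc}]$, Bonferroni-adjusted, falls
below $\alpha = 0.001$, and the call is supported by **more than 3 UMIs**
(significant calls with 3 or fewer UMIs are discarded). Because the test
conditions on $N_c$ and on $p_g$, it adapts both to per-cell differences
in guide-transcript recovery and to per-guide differences in library
abundance — the two main noise sources a fixed UMI threshold ignores.

Design choices worth noting:

* **Bonferroni family.** The correction is per cell across *all* guides
  in the library (not only observed guides, not pooled across cells).
  This is the most conservative reading that keeps cells independent; the
  family is configurable.
* **Floor after significance.** The UMI floor is applied to
  already-significant calls (`assigned <=> significant AND x >= 4`), so
  lowering `alpha` can only shrink the assigned set.
* A cell may be assigned any number of guides; cells are classed
  `unassigned` / `single` / `multi`, and only `single` cells enter
  differential expression.
* `alpha = 1` disables the significance gate (useful as a limit check:
  every guide with any support above the floor is then assigned).

## Quality control

Per cell we compute total UMIs, detected genes and the mitochondrial
count fraction, and remove cells deviating by **more than** 3 median
absolute deviations (MADs) from their batch's median: totals and gene
counts on the log1p scale (they are right-skewed), mitochondrial fraction
on the natural scale, in both directions — unusually *low* mitochondrial
fractions mark stripped nuclei. The MAD uses the 1.4826 normal-consistency
constant; cells exactly at the threshold are kept; a zero MAD makes the
corresponding metric inert in that batch (documented degenerate
behavior). Thresholds are computed independently per batch, so
sequencing-depth differences between experiments do not bleed across.
Doublets are flagged by a deliberately simple heuristic — multi-guide
cells above their batch's 95th total-UMI percentile — rather than a
neighbor-simulation caller; the flag is advisory and removal is an option.

## Normalization

Size factors are per-cell totals scaled to median one, and expression
values are $\log_2(1 + x_{gc}/s_c)$. Pooling-based deconvolution factors
would be the standard refinement; library-size factors were chosen to
keep the package dependency-light, and the factor definition is isolated
in one function so an alternative can be substituted. Downstream tests
are agnostic to the factor definition.

## Per-guide differential expression: the hurdle model

Each non-NT target is tested against a fixed background of up to 5,000
cells whose only assigned guide is non-targeting, sampled once per run.
For each target, all cells carrying any of its guides (single-assigned
only) are pooled with the background, and every tested gene within 1 Mb
of the target (closed interval, TSS inside `[start - 1 Mb, end + 1 Mb]`)
is fit with a two-part ("hurdle") model:

* a **detection component**: logistic regression of the detection
  indicator on guide-group indicators, experiment (batch) and the
  cellular detection rate (CDR; the standardized fraction of tested genes
  detected per cell);
* a **continuous component**: Gaussian regression of the log-normalized
  value among detected cells on the same design.

Each guide is tested by refitting both components with that guide's
indicator removed (its cells merged into the background baseline) and
summing the two likelihood-ratio statistics; the reference distribution
is $\chi^2$ with degrees of freedom equal to the number of estimable
dropped parameters — 2 normally, 1 when a component is degenerate for
that gene. Genes are tested only when detected in at least 5% of cells
(inclusive boundary).

Numerical choices:

* The logistic component carries a ridge penalty of $10^{-6}$ on guide
  coefficients so separated fits are finite and deterministic; a fit is
  flagged degenerate when a guide coefficient exceeds 15 in absolute
  value (odds ratios beyond $e^{15}$ carry no usable information).
  Both full and reduced fits maximize the same penalized objective, so
  likelihood ratios are well-defined and reproducible by any optimizer.
* The detection component is skipped (df reduced) when fewer than 3
  detected or 3 undetected cells exist overall; the continuous component
  requires at least 3 detected cells in the dropped guide group and 3 in
  the remainder.
* The log2 fold-change is the difference in mean log-normalized
  expression, zeros included, perturbed minus background — negative
  values mean downregulation.
* LR via refit (not Wald) because it is invariant to coefficient scaling
  and directly checkable against an independent maximum-likelihood fit.
* Cells with multiple assigned guides are excluded: exposure is then
  unambiguous, and in a low-MOI screen the loss is small.

A stratified Wilcoxon rank-sum backend (van Elteren combination across
batches, tie-corrected normal approximation) is available as an
alternative with the same output schema.

Benjamini-Hochberg adjustment of guide-level p-values spans all
(guide, gene) tests of a run; the family is configurable.

## Target-level aggregation and confidence tiers

Per (target, gene) pair, the raw p-values of the target's guides are
combined with Fisher's method, $X^2 = -2\sum_i \ln p_i \sim \chi^2(2k)$.
Guides with no recovered cells are dropped, reducing $k$, rather than
imputed at $p = 1$ (imputation would bias asymmetrically toward the
null). Combined p-values are BH-adjusted across every pair tested in the
run. Significant pairs (FDR < 5%) receive a confidence tier from their
*support*: the number of guides with raw $p < 0.05$ whose fold-change
sign matches the majority sign among those guides (ties broken by the
cell-count-weighted mean). Support 3-4 is high confidence, 2 medium, 1
low; headline summaries use medium + high only, since single-guide calls
are more likely off-target effects. The summary fold-change is the
cell-count-weighted mean of per-guide fold-changes; distances are
measured from the target interval midpoint to the gene TSS, and the
nearest-gene flag is computed among detection-filtered genes on the same
chromosome.

## Null calibration with NT pseudo-targets

Non-targeting guides are randomly partitioned into disjoint groups of 4
("pseudo-targets") that mimic the guides-per-target structure, and run
through the *same* DE entry point as real targets. Because pseudo-targets
have no genomic position, each is tested against the union of window
genes of all real targets. A pseudo-target's own cells are removed from
the NT background in its fits so no cell sits on both sides. Note 35 NT
guides yield $\lfloor 35/4 \rfloor = 8$ disjoint groups with 3 guides
unused — a library of 36 would be needed for nine groups. The report
contains the Kolmogorov-Smirnov statistic against U(0,1), an inflation
factor (median observed $-\log_{10} p$ over the expected 0.301), and
empirical type-I rates at 0.05 and 0.01.

## The synthetic screen generator

Every stage above is exercised on screens generated by
`simulate_screen()`, which emulates:

* the published library structure — 80 targets (35 TSS, 28 enhancers, 11
  intronic + 3 intergenic cCREs, 3 LCR elements) x 4 guides + 35 NT
  controls = 355 guides — on a toy genome (one 250 Mb chromosome, gene
  TSSs every 50 kb, a 13-gene mitochondrial contig), which guarantees
  every target has genes inside and outside its 1 Mb window;
* lognormal plasmid abundances (sigma 0.5, the shape seen in sequencing
  of cloned pooled libraries);
* Poisson(MOI = 0.3) integrations with identities drawn by plasmid
  proportion, followed by puromycin-style selection (profiled cells are
  drawn from the transduced fraction, so the single-guide fraction among
  them follows the zero-truncated Poisson, about 85.7% at MOI 0.3);
* guide UMIs: Poisson(mean 25) scaled by a lognormal(0, 0.3) per-cell
  capture factor, plus ambient UMIs allocated multinomially by plasmid
  proportion at a 5% expected share — the noise the binomial assignment
  is designed to absorb;
* negative-binomial expression (dispersion theta = 2) with lognormal
  per-gene means, lognormal(0, 0.3) cell size factors and per-gene
  multiplicative batch effects (two experiments of 20% / 80% of cells);
* planted effects: each target's expected gene is multiplied by
  $(1 - e \cdot f)$ in carrier cells, where $e$ is the class-mean
  knockdown (0.31 TSS, 0.29 LCR, 0.20 enhancer/cCRE classes — the average
  reductions reported for such screens) and $f$ a per-guide efficiency
  drawn once per guide from Beta(5, 1) (mean 5/6). An optional Beta
  spread of per-target effects around the class mean is available but off
  by default, so the planted conditions are exactly the class means;
* expected-gene baselines sampled log-uniformly between 0.1 and 20 UMIs
  per cell, so planted effects span the dynamic range of expression and
  the dependence of power on expression is visible;
* per-cell QC covariates (batch-specific mitochondrial Beta fractions, a
  1% tail of stripped nuclei with halved gene counts), and 5% doublets
  formed by summing two cells' columns.

Problem sizes were chosen once as the package's desk-scale study
conditions: the default screen simulates 135,000 profiled cells, giving a
median of about 280 single-assigned cells per guide (matching the
reported median of 282 cells per guide in the motivating screen), over
2,500 genes evenly subsampled from the toy genome (expected genes always
retained; about 20 genes per testing window). The calibration screen
plants no effects, carries 240 NT guides grouped into 60 pseudo-targets,
and simulates 100,000 cells, yielding more than 10,000 guide-level null
tests. Both complete in minutes on one CPU.

What the generator does **not** emulate: read-level artifacts (PCR
duplication, barcode collisions), cell-cycle or T-cell activation-state
heterogeneity, empty droplets (matrices are assumed cell-called),
correlated gene-gene expression structure, and trans effects of
perturbations. Consequently, a calibrated and powerful pipeline on these
screens demonstrates correctness of the statistics under the stated
noise model — not robustness to every failure mode of real data; the
non-targeting calibration diagnostic exists precisely to check the null
behavior on any real dataset.

## Known limitations

* Library-size factors can be biased when a perturbation changes a large
  fraction of a cell's transcriptome; deconvolution factors would
  mitigate this.
* The Gaussian continuous component relies on asymptotic likelihood-ratio
  calibration; for guides with very few cells on lowly detected genes
  the chi-square reference is approximate (the df-reduction rules bound,
  but do not remove, this).
* The doublet heuristic is intentionally minimal and will miss doublets
  whose two cells share a guide or have modest total counts.
* Pseudo-target calibration consumes NT cells; in NT-poor libraries the
  background and the pseudo-targets compete for the same cells.
* Windows are strand-agnostic and anchored at interval midpoints; no
  attempt is made to resolve element-gene contacts beyond linear
  distance.
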