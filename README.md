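# cropqtl

Analysis of pooled single-cell CRISPRi screens of regulatory elements
("crisprQTL" / CROP-seq screens) in R: from raw gene x cell and
guide x cell UMI matrices to tiered element-to-gene (E2G) links, with a
ground-truthed synthetic screen generator that makes every stage testable
without external data.

In such a screen, a library of guide RNAs — promoter (TSS) positive
controls, candidate enhancers/cCREs/LCR elements, and non-targeting (NT)
controls, typically 4 guides per target — is delivered at low MOI so most
cells carry one guide, and single-cell RNA-seq reads out both the
perturbation and the transcriptome. The pipeline answers: *which element
regulates which gene?*

## What the package implements

| Stage | Method |
|---|---|
| QC | per-batch median ± 3 MAD gates on total UMIs, detected genes, mitochondrial fraction (both tails; low-mito outliers are stripped nuclei); heuristic doublet flag |
| Guide assignment | per (cell, guide) inclusive upper-tail binomial test of UMI count `x` against the cell's guide-library size `N` and the guide's plasmid proportion `p_g`; Bonferroni across the library per cell, call if adjusted p < 0.001 **and** x ≥ 4 |
| Differential expression | two-part (hurdle) model per gene within ±1 Mb of each target: logistic detection + Gaussian expression components with guide-group, batch and detection-rate covariates; per-guide likelihood-ratio test against up to 5,000 single-NT background cells; stratified Wilcoxon backend as an alternative |
| Aggregation | Fisher's method over the target's guide p-values (χ² with 2k df), BH across all target-gene pairs; tiers by concordant support: 3–4 guides = high, 2 = medium, 1 = low |
| Calibration | NT guides grouped into pseudo-targets of 4 and run through the identical DE entry point; KS statistic, inflation factor, type-I rates |
| Simulation | full generative model of the screen (lognormal plasmid library, truncated-Poisson low-MOI transduction, ambient guide noise, NB expression with planted class-mean knockdowns, batches, mito fractions, doublets) with complete ground truth |

The core statistic for assignment is, for guide *g* in cell *c*,

    p_gc = P[ X >= x_gc ],   X ~ Binomial(N_c, p_g)

and for aggregation, Fisher's combination X² = −2 Σ ln p_i ~ χ²(2k).

## Worked example

```r
library(cropqtl)

# a small synthetic screen: 6 targets x 4 guides + 8 NT controls
design <- build_design(c(TSS = 3, ENH = 3), guides_per_target = 4,
                       n_nt = 8, genome = toy_genome(c(chr1 = 40e6)),
                       seed = 42)
screen <- simulate_screen(design, sim_params(n_cells = 4000,
                                             n_genes = 400, seed = 99))
screen
#> crop_screen: 4000 cells, 413 genes, 32 guides, 6 targets (+ 8 NT)

an <- analyze_screen(screen, nt_background_n = 600, seed = 1)
an$assignments
#> guide assignment: 3912 cells; 81.7% single, 18.3% multi, 0.0% unassigned

an$e2g$summaries$tier_counts
#>   high medium    low     ns
#>      2      0      0     91

an$e2g$summaries$expected_gene_recovery
#>   class n recovered
#> 1   ENH 3         0
#> 2   TSS 3         2
```

The assignment line says 81.7% of QC-passing cells carry exactly one
confidently assigned guide (low-MOI transduction after selection gives
~86% singles among transduced cells; doublets and true multiple
integrations make up the rest). With only ~100 cells per guide, two of
the three planted promoter (TSS) knockdowns — the strong, 31% effects —
are recovered as high-confidence links at FDR < 5%, while the subtler
20% enhancer effects stay below detection: exactly the
power-versus-effect-size behavior such screens show at full scale. The
default 135,000-cell screen (`simulate_screen()` with no arguments,
~280 cells per guide) recovers essentially all planted links whose genes
are expressed at 2 UMIs/cell or more; `scripts/acceptance.R` measures
this.

The same stages run from the shell over on-disk matrices
(`exec/cropqtl simulate|run|calibrate ...`), reading 10X-style
MatrixMarket triplets, a BED target table, a gene annotation TSV and a
guide library TSV, and writing TSV/JSON artifacts plus a checksummed
manifest (see `?pipeline_config`, `?run_pipeline`).

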