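# immunomethyl

Immunomethylomics for matched case-control studies of blood DNA: estimate
circulating immune-cell ratios and methylation-derived
neutrophil-to-lymphocyte ratios (mdNLR) from CpG beta values, validate them
by reference-based cell-type deconvolution, and run the full 1:1 matched
association analysis. The package is aimed at molecular-epidemiology
analysts working with processed methylation array data (e.g. Illumina 450K
beta values) from case-control cohorts with age-matched pairs, where fresh
blood for flow cytometry is unavailable.

## What it computes

* **Marker selection.** From a reference methylome of sorted leukocyte
  subtypes (NK, CD4+ T, CD8+ T, Treg, monocytes, neutrophils, B cells),
  `select_isus()` finds immune-cell-specific unmethylated sites (ISUS:
  beta ≤ 0.3 in the target subtype, ≥ 0.7 in all others, ranked by the
  specificity margin) and `select_opposing_markers()` finds CpGs methylated
  only in neutrophils or only in pan-lymphocytes. A curated published panel
  (21 ISUS + 3 neutrophil + 3 pan-lymphocyte CpGs, GRCh37 coordinates) ships
  with the package: `tnbc_marker_panel()`.
* **Proxy scores.** Unmethylation `1 - beta` at an ISUS tracks its
  subtype's cell ratio; the mdNLR is
  `beta(neutrophil CpG) / beta(pan-lymphocyte CpG)`, one score per probe
  pair (nine for a 3 × 3 panel): `compute_mdnlr()`,
  `unmethylation_ratio_panel()`, `nk_neutrophil_ratio()`.
* **Deconvolution.** `deconvolve()` solves, per sample,
  `min ‖y − Xw‖²` s.t. `w ≥ 0, Σw = 1` over six cell types and derives
  `mdnlr_ref()` = Neu / (NK + CD4 T + CD8 T + B).
* **Matched inference.** `fit_clogit()` maximises the paired conditional
  likelihood `Σ log σ(dᵢᵀβ)` (Newton, Wald intervals; OR per 0.1 beta),
  `auc()` with DeLong intervals, `holm_adjust()`, `backward_select()` at a
  20% stay level, `bootstrap_adjusted_auc()` (Harrell optimism bootstrap
  resampling pairs), plus exact-small-sample `wilcoxon_signed_rank()`,
  `mann_whitney()`, `jonckheere_terpstra()` and `spearman_rho()`.
* **Synthetic cohorts.** `simulate_reference()`, `simulate_cohort()` and
  `simulate_prospective_ddpcr()` generate the calibrated ground-truth
  substrate (Dirichlet cell mixtures; neutrophil means 0.49 cases vs 0.45
  controls, pan-lymphocyte 0.36 vs 0.403, NK carrying the largest relative
  drop) used throughout the tests.

## Worked example

```r
library(immunomethyl)
ref    <- simulate_reference(n_probes = 400, seed = 11)
panel  <- build_panel(ref)
panel
#> Marker panel: 27 probes
#>   B               3
#>   Mono            3
#>   Neu             3
#>   neutrophil      3
#>   NK              3
#>   pan-lymphocyte  3
#>   TCD4            3
#>   TCD8            3
#>   Treg            3

cohort <- simulate_cohort(ref, n_pairs = 231, seed = 12)
mdnlr  <- compute_mdnlr(cohort$betas,
                        panel_probes(panel, "neutrophil"),
                        panel_probes(panel, "pan-lymphocyte"))
association_scan(cohort$sheet, mdnlr, colnames(mdnlr)[1:3])
#> Matched case-control association scan (3 exposures, 231 pairs; OR per 0.1 on the beta scale)
#>               exposure beta    se   OR ci_low ci_high        p    p_adj   auc auc_low auc_high n_pairs
#>  cg00000023.cg00000025 2.18 0.362 1.24   1.16    1.33 1.73e-09 4.05e-09 0.710   0.663    0.757     231
#>  cg00000023.cg00000026 2.41 0.398 1.27   1.18    1.38 1.35e-09 4.05e-09 0.713   0.666    0.760     231
#>  cg00000023.cg00000027 2.15 0.356 1.24   1.16    1.33 1.71e-09 4.05e-09 0.704   0.657    0.751     231
```

Each row is one mdNLR (neutrophil CpG × pan-lymphocyte CpG): the odds ratio
per 0.1 increase in the score with its 95% Wald interval, the Wald p and its
Holm adjustment within the block, and the AUC with a DeLong interval. All
mdNLRs run above 1 here because the simulated cases carry the higher
neutrophil / lower lymphocyte mix.

```r
deconvolve(cohort$betas, build_signature(ref, panel))
#> Reference-based deconvolution: 462 samples, 6 cell types, 24 signature probes
#> Mean proportions:
#>     NK   TCD4   TCD8   Mono    Neu      B
#> 0.0612 0.1498 0.1000 0.1501 0.4686 0.0702
#> Median fit RMSE: 0.0176

bootstrap_adjusted_auc(cohort$sheet, cohort$betas,
                       unlist(isus_sets(panel)), B = 200, seed = 13)
#> Optimism-corrected bootstrap validation (200 replicates)
#> Selected exposures: cg00000002, cg00000003, cg00000004, cg00000005, cg00000006,
#>   cg00000012, cg00000013, cg00000014, cg00000015, cg00000017
#> Apparent AUC: 0.7634   optimism: 0.04088   adjusted AUC: 0.7225
```

The deconvolved mean proportions recover the generator's group means, and
the backward-selected ISUS model discriminates cases from controls with an
optimism-corrected AUC of about 0.72.

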