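---
title: "Methylation-derived immune cell ratios in matched case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-derived immune cell ratios in matched case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunomethyl)
```

## The problem

The composition of circulating leukocytes shifts in many diseases, and the
neutrophil-to-lymphocyte ratio (NLR) in particular is a widely used marker of
systemic inflammation. Because DNA methylation is cell-type specific,
chemically stable and measurable in archival blood DNA, the methylation level
(beta value, the fraction of methylated alleles at a CpG, in [0, 1]) at a
carefully chosen CpG can serve as a *proxy* for the abundance of one
leukocyte subtype — no intact cells or flow cytometry needed. This package
implements that immunomethylomic workflow for 1:1 age-matched case-control
designs:

1. **Marker selection** from a reference methylome of sorted leukocyte
   subtypes (NK, CD4+ T, CD8+ T, regulatory T, monocytes, neutrophils,
   B cells): per-subtype *immune-cell-specific unmethylated sites* (ISUS) and
   two opposing sets — CpGs methylated only in neutrophils and CpGs
   methylated only in the pan-lymphocyte group.
2. **Proxy scoring**: unmethylation (1 − beta) at an ISUS tracks the ratio of
   its subtype; the methylation-derived NLR (mdNLR) is the beta at a
   neutrophil-specific CpG divided by the beta at a pan-lymphocyte-specific
   CpG, giving nine scores for a 3 × 3 panel.
3. **Reference-based deconvolution** (constrained projection in the Houseman
   tradition) of six cell-type proportions per sample, used to validate the
   single-CpG proxies; mdNLR_ref is the neutrophil proportion over the
   summed NK + CD4 T + CD8 T + B proportions.
4. **Matched inference**: univariable and multivariable conditional logistic
   regression for 1:1 pairs, AUC with DeLong intervals, Holm correction
   within analysis blocks, backward selection, optimism-corrected bootstrap
   validation, and the nonparametric tests used for clinical correlates
   (Wilcoxon signed-rank, Mann-Whitney, Jonckheere-Terpstra, Spearman).
5. **A calibrated synthetic cohort generator** providing ground truth for
   all of the above.

## Marker selection model

For a probe with per-cell-type mean betas, specificity is summarised by a
*margin*: for a target-unmethylated probe, the smallest non-target beta minus
the largest target beta (symmetrically for target-methylated probes). A probe
qualifies as an ISUS for subtype $t$ when its beta in $t$ is at most
`low_thr` and at least `high_thr` in every other subtype; candidates are
ranked by margin and the top `k_per_type` kept. Defaults `low_thr = 0.3`,
`high_thr = 0.7`, `k_per_type = 3` reproduce the classical 21-ISUS / 3 + 3
panel structure; the thresholds are deliberately generous because the margin
ranking, not the gate, determines the final panel. The margin is simple,
invariant to probe and column order, and needs no variance model — a
moderated statistic would require per-dataset replicate variances that a
mean-profile reference does not carry. The opposing sets constrain only the
cell types involved (neutrophils vs pan-lymphocytes, with monocytes required
unmethylated on both sides); the Treg column is left unconstrained there
because regulatory T cells are a CD4 subpopulation whose profile rides with
the lymphoid pool.

## Proxy scales

Three scales are exposed because each downstream analysis has a natural one:
raw beta (odds ratios per 0.1, i.e. a 10-percentage-point methylation
increase), unmethylation 1 − beta (cell-ratio direction), and
logit(beta) with clipping at `eps = 1e-6` (for ddPCR readouts and
ratio-of-proxy comparisons). The clip constant also floors every ratio
denominator; at 1e-6 it is far below biological beta resolution, so interior
values are untouched while boundary values stay finite.

## Deconvolution

Per sample we solve
$\hat w = \arg\min_w \lVert y - Xw \rVert^2$ subject to $w \ge 0$,
$\sum_c w_c = 1$, where $X$ is the signature matrix (marker probes × six
cell types). The solver is active-set nonnegative least squares on a system
augmented with a heavily weighted sum-to-one row, followed by exact
renormalisation — mathematically equivalent at the reported precision to
enforcing the equality constraint directly, and verified in the tests
against exhaustive simplex grid search down to the grid step. Rank
deficiency is detected by pivoted QR and reported with the collinear column
names; samples with missing betas lose those probes pairwise rather than
being dropped. The default signature takes the panel probes (top 50 by
margin) for the six deconvolvable types.

## Matched inference

For 1:1 pairs the conditional likelihood reduces to
$\sum_i \log \sigma(d_i^\top \beta)$ with $d_i$ the case-minus-control
covariate difference; we maximise it by Newton iteration (tolerance 1e-8,
at most 100 iterations) and report Wald intervals from the observed
information — the conventional output of the standard survival-analysis
stack, which the package's tests cross-check coefficient-for-coefficient.
Monotone likelihoods (separation) are detected when all fitted pair
differences share one sign while a standardised coefficient exceeds 15, and
are flagged rather than reported as odds ratios. Pairs missing any exposure
value are dropped (complete-pair analysis). Holm adjustment is applied
within an analysis block (e.g. the nine mdNLRs), mirroring per-figure
families.

Backward selection refits the multivariable model, dropping the largest
Wald p above the 20% stay level (ties by name, for determinism). Internal
validation follows the Harrell optimism bootstrap: pairs — the exchangeable
unit in a matched design — are resampled with replacement, model building is
repeated per replicate, and the mean of (replicate AUC − original-data AUC
of the replicate model) is subtracted from the apparent AUC. An empty
selected model scores AUC 0.5 by the tie convention, which keeps the
procedure well-defined under pure noise.

The rank tests use exact null distributions where feasible (signed-rank up
to n = 25 without ties; rank-sum with both groups at most 25;
Jonckheere-Terpstra by exhaustive permutation up to total n = 10) and
tie-corrected normal or seeded Monte-Carlo permutation approximations
beyond, with the choice recorded in each result.

## What the synthetic cohort emulates — and what it does not

The generator is the package's test substrate and defines its study
conditions:

- **Reference** (`simulate_reference`): planted ISUS with target beta
  ~ U(0.02, 0.1) against U(0.85, 0.98), opposing sets analogously,
  background probes sharing one U(0.2, 0.8) value across types. Planted
  margins are therefore at least 0.75 and selection recovers the planted
  truth exactly — an end-to-end identifiability check.
- **Cohort** (`simulate_cohort`): per-sample cell-type weights
  ~ Dirichlet(mass × group means) on the six mixing types; observed betas
  are the convex mixture of reference profiles plus N(0, 0.02) measurement
  noise, clipped to [0, 1]. Group means are anchored to the printed
  neutrophil (0.49 cases vs 0.45 controls) and pan-lymphocyte
  (0.36 vs 0.403) totals; the subtype split of the lymphoid total is a
  declared calibration choice with NK taking the largest relative drop
  (0.043 vs 0.063). The Dirichlet total mass of 60 sets the between-subject
  spread; real within-group variances are not published, so this is a free
  knob chosen once to give mdNLR standard deviations of realistic size.
  A fixed 10% of the CD4 weight is routed through the Treg reference
  profile when composing betas, so Treg ISUS respond to the CD4 pool while
  the recorded truth stays on the six deconvolvable types. This is also the
  main known source of deconvolution bias (about 0.01-0.015 mean absolute
  error on CD4 T), deliberately retained as a realistic model mismatch.
- **Prospective arm** (`simulate_prospective_ddpcr`): the single-locus
  "unmethylation" readout is the latent NK proportion times a
  multiplicative assay efficiency ~ N(1, 0.05), pairs age-matched at
  ±5 years (±1 year in the retrospective arm).
- Ages are truncated-normal N(55, 8) on 30-80; BMI, menopausal status,
  parity and smoking are filled with plausible marginals for interface
  completeness but carry no effect on methylation in the generator.

Not emulated: array batch and probe-type effects, beta-distributed
(heteroscedastic) measurement error, age- or smoking-dependent cell
composition, survival outcomes. Passing tests therefore demonstrate
correctness of the estimators and the direction-level reproduction of the
case-control shifts under clean mixing — not robustness to array artefacts.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at the design scale of the
emulated study: 231 retrospective and 146 prospective pairs, a 400-probe
reference for the pipeline, a 50-probe signature on 200 samples for the
recovery experiment, 500 replicates for type-I error and coverage
calibration at 100 pairs, 100 seeds for the direction-level reproduction
check, and 200 bootstrap replicates for model validation. Determinism:
every stochastic entry point takes a seed and restores the caller's RNG
stream; grid oracles in the tests use steps of 1e-3 to 1e-4 with matching
tolerances.

## Known limitations

- The marker thresholds stand in for unpublished selection criteria; they
  reproduce the published panel *structure*, not its exact probe list
  (which ships separately as the packaged panel).
- Odds ratios "per 10% methylation" are implemented as +0.1 on the absolute
  beta scale, consistent with beta's [0, 1] range.
- The conditional-logistic machinery is specific to 1:1 matching; general
  m:n strata are out of scope.
- mdNLR values depend on the chosen CpG pair; the package reports all nine
  pairwise scores rather than a pooled statistic, as is conventional.
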