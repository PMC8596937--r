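#' Run the full immunomethylomic pipeline on a synthetic matched cohort
#'
#' End-to-end orchestration used by the worked examples and the acceptance
#' script: simulate a leukocyte reference and a matched case-control cohort,
#' select the marker panel, score mdNLRs and subtype ratio proxies, run the
#' univariable association scans, deconvolve cell proportions
#' (mdNLR_ref included), build the backward-selected diagnostic model with
#' optimism-bootstrap validation, and analyse a prospective single-locus
#' ddPCR arm.
#'
#' @param seed integer seed driving every stochastic step (sub-seeds are
#'   derived from it).
#' @param n_pairs retrospective matched pairs.
#' @param n_probes reference probe count.
#' @param markers_per_type planted (and selected) markers per subtype.
#' @param n_pairs_prospective prospective matched pairs.
#' @param B bootstrap replicates for the model validation (0 skips it).
#' @return a list with the intermediate objects and result tables; see the
#'   package vignette for a walk-through.
#' @export
run_pipeline <- function(seed = 1, n_pairs = 231, n_probes = 400,
                         markers_per_type = 3, n_pairs_prospective = 146,
                         B = 200) {
  seeds <- .with_seed(seed, sample.int(2^31 - 1, 4L))
  ref <- simulate_reference(n_probes, markers_per_type = markers_per_type,
                            seed = seeds[1L])
  panel <- build_panel(ref, k_per_type = markers_per_type)
  cohort <- simulate_cohort(ref, n_pairs, seed = seeds[2L])

  neu <- panel_probes(panel, "neutrophil")
  lym <- panel_probes(panel, "pan-lymphocyte")
  mdnlr <- compute_mdnlr(cohort$betas, neu, lym)
  assoc_mdnlr <- association_scan(cohort$sheet, mdnlr, colnames(mdnlr),
                                  scale = "beta", increment = 0.1)

  subtype <- subtype_ratio_scores(cohort$betas, panel)
  assoc_subtype <- association_scan(cohort$sheet, subtype,
                                    colnames(subtype), scale = "beta",
                                    increment = 0.1)

  sig <- build_signature(ref, panel)
  dec <- deconvolve(cohort$betas, sig)
  nlr_ref <- mdnlr_ref(dec)

  isus <- unlist(isus_sets(panel), use.names = FALSE)
  model <- if (B > 0)
    bootstrap_adjusted_auc(cohort$sheet, cohort$betas, isus, B = B,
                           seed = seeds[3L])
  else backward_select(cohort$sheet, cohort$betas, isus)

  prosp <- simulate_prospective_ddpcr(n_pairs_prospective,
                                      seed = seeds[4L])
  lg <- logit_transform(prosp$unmeth)
  d <- lg[prosp$status == "case"][order(prosp$pair_id[prosp$status == "case"])] -
    lg[prosp$status == "control"][order(prosp$pair_id[prosp$status == "control"])]
  prosp_wilcoxon <- wilcoxon_signed_rank(d)
  prosp_clogit <- fit_clogit(prosp, NULL, "unmeth", scale = "logit")

  list(seed = seed, ref = ref, panel = panel, cohort = cohort,
       mdnlr = mdnlr, assoc_mdnlr = assoc_mdnlr,
       subtype_scores = subtype, assoc_subtype = assoc_subtype,
       signature = sig, deconv = dec, mdnlr_ref = nlr_ref,
       model = model, prospective = prosp,
       prosp_wilcoxon = prosp_wilcoxon, prosp_clogit = prosp_clogit)
}
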