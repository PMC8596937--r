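# Synthetic study substrate: a leukocyte reference methylome with planted
# cell-type-specific markers, matched case-control cohorts built as noisy
# convex mixtures of the reference profiles, and single-locus ddPCR-style
# prospective readouts. Group mean proportions default to the printed
# calibration anchors of the emulated study design (neutrophils 49% vs 45%,
# pan-lymphocytes 36% vs 40.3%, NK carrying the largest relative drop).

.LEUKOCYTE_TYPES <- c("NK", "TCD4", "TCD8", "Treg", "Mono", "Neu", "B")

#' Default group mean cell proportions for the cohort generator
#'
#' Control and case means over the six deconvolvable leukocyte types. The
#' neutrophil and pan-lymphocyte totals (0.45/0.403 in controls, 0.49/0.36
#' in cases) are the calibration anchors; the subtype-level split of the
#' pan-lymphocyte totals is a declared calibration choice with NK taking the
#' largest relative case-control drop.
#'
#' @param group \code{"control"} or \code{"case"}.
#' @return named numeric vector summing to one.
#' @export
default_group_props <- function(group = c("control", "case")) {
  group <- match.arg(group)
  if (group == "control")
    c(Neu = 0.45, NK = 0.063, TCD4 = 0.17, TCD8 = 0.10, B = 0.07,
      Mono = 0.147)
  else
    c(Neu = 0.49, NK = 0.043, TCD4 = 0.155, TCD8 = 0.095, B = 0.067,
      Mono = 0.15)
}

#' Simulate a leukocyte reference methylome with planted markers
#'
#' Generates per-cell-type mean beta profiles for the seven leukocyte
#' subtypes. For each subtype, \code{markers_per_type} immune-cell-specific
#' unmethylated sites are planted (target beta ~ U(0.02, 0.1), all other
#' types ~ U(0.85, 0.98)); \code{opposing_per_set} neutrophil-specific
#' methylated probes (high in neutrophils, low in lymphocytes and
#' monocytes) and pan-lymphocyte-specific methylated probes (high in NK,
#' CD4 T, CD8 T, Treg and B, low in neutrophils and monocytes) are planted
#' analogously. Background probes share one U(0.2, 0.8) value across all
#' types, so they carry no cell-type specificity. Probe rows are shuffled;
#' the planted truth is attached as \code{attr(, "planted")}.
#'
#' @param n_probes total probe count.
#' @param cell_types cell-type labels (default the seven leukocyte types).
#' @param markers_per_type planted unmethylated markers per subtype.
#' @param opposing_per_set planted probes per opposing set.
#' @param seed optional RNG seed (caller's RNG stream is preserved).
#' @return probes x cell types beta matrix with \code{cg}-style rownames.
#' @export
simulate_reference <- function(n_probes = 400,
                               cell_types = .LEUKOCYTE_TYPES,
                               markers_per_type = 3, opposing_per_set = 3,
                               seed = NULL) {
  k <- length(cell_types)
  n_planted <- markers_per_type * k + 2L * opposing_per_set
  if (n_probes < n_planted)
    stop("n_probes too small for the requested planted markers")
  .with_seed(seed, {
    ref <- matrix(rep(stats::runif(n_probes, 0.2, 0.8), k),
                  nrow = n_probes, ncol = k,
                  dimnames = list(sprintf("cg%08d", seq_len(n_probes)),
                                  cell_types))
    planted <- data.frame(probe_id = character(), target = character(),
                          orientation = character(),
                          stringsAsFactors = FALSE)
    row <- 0L
    for (tp in cell_types) {
      idx <- row + seq_len(markers_per_type); row <- row + markers_per_type
      ref[idx, ] <- stats::runif(length(idx) * k, 0.85, 0.98)
      ref[idx, tp] <- stats::runif(length(idx), 0.02, 0.10)
      planted <- rbind(planted, data.frame(
        probe_id = rownames(ref)[idx], target = tp,
        orientation = "target-unmethylated", stringsAsFactors = FALSE))
    }
    lymph <- intersect(c("NK", "TCD4", "TCD8", "Treg", "B"), cell_types)
    myelo <- intersect(c("Neu", "Mono"), cell_types)
    idx <- row + seq_len(opposing_per_set); row <- row + opposing_per_set
    ref[idx, ] <- stats::runif(length(idx) * k, 0.02, 0.10)
    ref[idx, "Neu"] <- stats::runif(length(idx), 0.85, 0.98)
    planted <- rbind(planted, data.frame(
      probe_id = rownames(ref)[idx], target = "neutrophil",
      orientation = "target-methylated", stringsAsFactors = FALSE))
    idx <- row + seq_len(opposing_per_set)
    ref[idx, myelo] <- stats::runif(length(idx) * length(myelo), 0.02, 0.10)
    ref[idx, lymph] <- stats::runif(length(idx) * length(lymph), 0.85, 0.98)
    planted <- rbind(planted, data.frame(
      probe_id = rownames(ref)[idx], target = "pan-lymphocyte",
      orientation = "target-methylated", stringsAsFactors = FALSE))
    ref <- ref[sample.int(n_probes), , drop = FALSE]
    attr(ref, "planted") <- planted
    ref
  })
}

# Internal: truncated-normal ages by rejection.
.rage <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    a <- stats::rnorm(2L * (n - length(out)), mean, sd)
    out <- c(out, a[a >= range[1L] & a <= range[2L]])
  }
  round(out[seq_len(n)], 1)
}

#' Simulate a matched case-control cohort of blood methylomes
#'
#' Each sample's beta profile is a convex mixture of the reference cell-type
#' profiles plus Gaussian measurement noise (clipped to [0, 1]). Cell-type
#' weights are drawn per sample from a Dirichlet distribution with
#' concentration \code{mass * group mean proportions}; cases and controls
#' use shifted mean vectors. Controls get ages ~ N(55, 8) truncated to
#' 30-80 and each case an age within the matching tolerance of its control.
#' When the reference contains a Treg column, a fixed fraction
#' \code{treg_frac} of each sample's CD4 T weight is re-routed through the
#' Treg profile when composing betas (regulatory T cells ride along with the
#' CD4 pool); recorded true proportions stay on the six mixing types.
#'
#' @param ref reference methylome from \code{\link{simulate_reference}} (or
#'   compatible matrix containing the six mixing types).
#' @param n_pairs number of matched case-control pairs.
#' @param props_control,props_case named group mean proportions over the six
#'   mixing types; each must sum to one.
#' @param mass Dirichlet total concentration (between-subject spread knob).
#' @param noise_sd Gaussian beta measurement noise sd.
#' @param age_mean,age_sd,age_range control age distribution.
#' @param age_tol case-control age matching tolerance in years.
#' @param treg_frac fraction of the CD4 T weight carried by the Treg
#'   profile when a Treg reference column is present.
#' @param seed optional RNG seed.
#' @return list of class \code{synthetic_cohort}: \code{betas} (samples x
#'   probes), \code{sheet} (matched sample sheet with ages and
#'   epidemiological covariates), \code{truth} (latent per-sample cell
#'   proportions).
#' @export
simulate_cohort <- function(ref, n_pairs = 231,
                            props_control = default_group_props("control"),
                            props_case = default_group_props("case"),
                            mass = 60, noise_sd = 0.02,
                            age_mean = 55, age_sd = 8,
                            age_range = c(30, 80), age_tol = 1,
                            treg_frac = 0.1, seed = NULL) {
  ref <- .validate_reference(ref)
  types <- names(props_control)
  if (is.null(types) || !setequal(types, names(props_case)))
    stop("props_control and props_case must be named over the same types")
  if (abs(sum(props_control) - 1) > 1e-8 || abs(sum(props_case) - 1) > 1e-8)
    stop("group mean proportions must sum to 1")
  if (!all(types %in% colnames(ref)))
    stop("reference lacks cell type(s): ",
         paste(setdiff(types, colnames(ref)), collapse = ", "))
  stopifnot(noise_sd >= 0, mass > 0, n_pairs >= 1)
  props_case <- props_case[types]
  has_treg <- "Treg" %in% colnames(ref) && "TCD4" %in% types &&
    treg_frac > 0
  .with_seed(seed, {
    pair_id <- sprintf("P%04d", seq_len(n_pairs))
    age_ctrl <- .rage(n_pairs, age_mean, age_sd, age_range)
    age_case <- pmin(pmax(age_ctrl + stats::runif(n_pairs, -age_tol, age_tol),
                          age_range[1L]), age_range[2L])
    W <- rbind(.rdirichlet(n_pairs, mass * props_case),
               .rdirichlet(n_pairs, mass * props_control))
    ids <- c(sprintf("case_%04d", seq_len(n_pairs)),
             sprintf("ctrl_%04d", seq_len(n_pairs)))
    rownames(W) <- ids
    sheet <- data.frame(
      sample_id = ids,
      pair_id = rep(pair_id, 2L),
      status = rep(c("case", "control"), each = n_pairs),
      age = round(c(age_case, age_ctrl), 1),
      bmi = round(pmin(pmax(stats::rnorm(2L * n_pairs, 26, 4), 16), 45), 1),
      stringsAsFactors = FALSE)
    sheet$menopause <- ifelse(
      stats::runif(2L * n_pairs) < stats::plogis((sheet$age - 51) / 2),
      "post", "pre_peri")
    sheet$ever_parous <- stats::rbinom(2L * n_pairs, 1L, 0.8)
    sheet$current_smoker <- stats::rbinom(2L * n_pairs, 1L, 0.2)
    # compose betas; optionally split TCD4 mass through the Treg profile
    Wmix <- W
    mix_types <- types
    if (has_treg) {
      Wmix <- cbind(W, Treg = treg_frac * W[, "TCD4"])
      Wmix[, "TCD4"] <- (1 - treg_frac) * W[, "TCD4"]
      mix_types <- c(types, "Treg")
    }
    B <- Wmix %*% t(ref[, mix_types, drop = FALSE])
    if (noise_sd > 0)
      B <- B + stats::rnorm(length(B), 0, noise_sd)
    B <- pmin(pmax(B, 0), 1)
    truth <- data.frame(sample_id = ids, pair_id = rep(pair_id, 2L),
                        status = rep(c("case", "control"), each = n_pairs),
                        W, stringsAsFactors = FALSE, row.names = NULL)
    structure(list(betas = B,
                   sheet = as_matched_cohort(sheet, age_tol = age_tol),
                   truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- nrow(x$betas)
  cat("Synthetic matched cohort:", n / 2L, "pairs,", ncol(x$betas),
      "probes\n")
  cat("Mean true proportions (cases vs controls):\n")
  w <- x$truth[, setdiff(names(x$truth),
                         c("sample_id", "pair_id", "status"))]
  print(round(rbind(case = colMeans(w[x$truth$status == "case", ]),
                    control = colMeans(w[x$truth$status == "control", ])), 4))
  invisible(x)
}

#' Simulate prospective single-locus ddPCR unmethylation readouts
#'
#' Emulates a droplet-digital-PCR "unmethylation" assay at one NK-specific
#' unmethylated site in a prospective matched sample set: each sample's
#' readout is its latent NK proportion (Beta-distributed marginal of the
#' cohort Dirichlet) scaled by a multiplicative assay efficiency
#' ~ N(1, \code{efficiency_sd}), clipped to (0, 1). Pairs are age-matched at
#' \code{age_tol} years (default 5).
#'
#' @param n_pairs number of matched pairs.
#' @param nk_case,nk_control group mean NK proportions.
#' @param mass Dirichlet total concentration.
#' @param efficiency_sd sd of the multiplicative assay efficiency.
#' @param age_mean,age_sd,age_range,age_tol age model as in
#'   \code{\link{simulate_cohort}}.
#' @param seed optional RNG seed.
#' @return matched sample sheet with an \code{unmeth} readout column and a
#'   \code{true_nk} latent-proportion column.
#' @export
simulate_prospective_ddpcr <- function(n_pairs = 146,
                                       nk_case = 0.043, nk_control = 0.063,
                                       mass = 60, efficiency_sd = 0.05,
                                       age_mean = 55, age_sd = 8,
                                       age_range = c(30, 80), age_tol = 5,
                                       seed = NULL) {
  stopifnot(n_pairs >= 1, nk_case > 0, nk_case < 1,
            nk_control > 0, nk_control < 1, efficiency_sd >= 0)
  .with_seed(seed, {
    pair_id <- sprintf("P%04d", seq_len(n_pairs))
    age_ctrl <- .rage(n_pairs, age_mean, age_sd, age_range)
    age_case <- pmin(pmax(age_ctrl + stats::runif(n_pairs, -age_tol, age_tol),
                          age_range[1L]), age_range[2L])
    w_nk <- c(stats::rbeta(n_pairs, mass * nk_case, mass * (1 - nk_case)),
              stats::rbeta(n_pairs, mass * nk_control,
                           mass * (1 - nk_control)))
    eff <- stats::rnorm(2L * n_pairs, 1, efficiency_sd)
    unmeth <- pmin(pmax(w_nk * eff, 1e-6), 1 - 1e-6)
    sheet <- data.frame(
      sample_id = c(sprintf("case_%04d", seq_len(n_pairs)),
                    sprintf("ctrl_%04d", seq_len(n_pairs))),
      pair_id = rep(pair_id, 2L),
      status = rep(c("case", "control"), each = n_pairs),
      age = round(c(age_case, age_ctrl), 1),
      unmeth = unmeth, true_nk = w_nk,
      stringsAsFactors = FALSE)
    as_matched_cohort(sheet, age_tol = age_tol)
  })
}
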