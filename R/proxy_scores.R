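#' Logit-transform beta values
#'
#' \code{ln(b / (1 - b))} with \code{b} clipped into
#' \code{[eps, 1 - eps]} so boundary betas stay finite. Strictly increasing
#' on the clipped range; missing values propagate.
#'
#' @param beta numeric vector of beta values in \code{[0, 1]}.
#' @param eps clipping constant in \code{(0, 0.5)}.
#' @return numeric vector of logits.
#' @export
logit_transform <- function(beta, eps = 1e-6) {
  if (!(eps > 0 && eps < 0.5)) stop("eps must lie in (0, 0.5)")
  ok <- is.na(beta) | (beta >= 0 & beta <= 1)
  if (!all(ok)) stop("beta values outside [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log(b / (1 - b))
}

# Internal: samples x probes beta matrix with required probes present.
.check_probes <- function(betas, probes) {
  if (is.data.frame(betas)) betas <- as.matrix(betas)
  miss <- setdiff(probes, colnames(betas))
  if (length(miss))
    stop("probe(s) absent from beta matrix: ", paste(miss, collapse = ", "))
  betas
}

#' Methylation-derived neutrophil-to-lymphocyte ratios (mdNLR)
#'
#' For every combination of a neutrophil-specific and a pan-lymphocyte-
#' specific CpG, the per-sample score is the beta value at the neutrophil
#' probe divided by the beta value at the pan-lymphocyte probe (denominator
#' floored at \code{eps}). Three probes per set give the nine classical
#' mdNLR scores. Samples with a missing input beta get a missing score but
#' are retained.
#'
#' @param betas samples x probes matrix (or data frame) of beta values with
#'   sample ids as rownames.
#' @param neu_probes,lym_probes probe ids of the neutrophil- and
#'   pan-lymphocyte-specific sets.
#' @param eps denominator floor.
#' @return samples x (neu x lym) numeric matrix; columns named
#'   \code{"<neuProbe>.<lymProbe>"}.
#' @export
compute_mdnlr <- function(betas, neu_probes, lym_probes, eps = 1e-6) {
  betas <- .check_probes(betas, c(neu_probes, lym_probes))
  stopifnot(eps > 0)
  out <- matrix(NA_real_, nrow(betas), length(neu_probes) * length(lym_probes),
                dimnames = list(rownames(betas), NULL))
  nm <- character(ncol(out)); k <- 0L
  for (np in neu_probes) for (lp in lym_probes) {
    k <- k + 1L
    out[, k] <- betas[, np] / pmax(betas[, lp], eps)
    nm[k] <- paste0(np, ".", lp)
  }
  colnames(out) <- nm
  out
}

#' Per-sample unmethylation proxies at panel ISUS
#'
#' A high beta at an immune-cell-specific unmethylated site (ISUS) means a
#' low ratio of the corresponding leukocyte subtype, so the cell-ratio proxy
#' is the unmethylation value \code{1 - beta}. Returns one row per sample and
#' ISUS with the raw beta, the unmethylation proxy and the logit of beta.
#'
#' @param betas samples x probes beta matrix.
#' @param panel a \code{marker_panel}; only its
#'   \code{"target-unmethylated"} rows are used.
#' @param eps logit clipping constant.
#' @return data frame with columns \code{sample_id}, \code{probe_id},
#'   \code{target}, \code{beta}, \code{unmeth}, \code{logit_beta}.
#' @export
unmethylation_ratio_panel <- function(betas, panel, eps = 1e-6) {
  p <- panel[panel$orientation == "target-unmethylated", , drop = FALSE]
  betas <- .check_probes(betas, p$probe_id)
  b <- betas[, p$probe_id, drop = FALSE]
  out <- data.frame(
    sample_id = rep(rownames(b), times = ncol(b)),
    probe_id = rep(colnames(b), each = nrow(b)),
    target = rep(p$target, each = nrow(b)),
    beta = as.vector(b),
    stringsAsFactors = FALSE)
  out$unmeth <- 1 - out$beta
  out$logit_beta <- logit_transform(out$beta, eps)
  out
}

#' Subtype-level ratio proxies (mean unmethylation over each ISUS set)
#'
#' Collapses the per-probe unmethylation proxies to one score per sample and
#' cell type by averaging \code{1 - beta} over the subtype's ISUS (missing
#' probes ignored per sample).
#'
#' @inheritParams unmethylation_ratio_panel
#' @return samples x cell types numeric matrix of mean unmethylation.
#' @export
subtype_ratio_scores <- function(betas, panel) {
  sets <- isus_sets(panel)
  betas <- .check_probes(betas, unlist(sets))
  out <- sapply(sets, function(pr)
    rowMeans(1 - betas[, pr, drop = FALSE], na.rm = TRUE))
  out[is.nan(out)] <- NA_real_
  out
}

#' NK-cell-to-neutrophil ratio proxies
#'
#' Ratio of unmethylation proxies: \code{(1 - beta)} at an NK-specific ISUS
#' divided by \code{(1 - beta)} at a neutrophil-specific ISUS (denominator
#' floored at \code{eps}), one score per (NK, neutrophil) probe pair. Both
#' numerator and denominator then increase with the abundance of their cell
#' type, so the score tracks the NK:neutrophil cell ratio.
#'
#' @param betas samples x probes beta matrix.
#' @param nk_isus,neu_isus NK- and neutrophil-specific ISUS probe ids.
#' @param eps denominator floor.
#' @return samples x (nk x neu) matrix with columns
#'   \code{"<nkProbe>.<neuProbe>"}.
#' @export
nk_neutrophil_ratio <- function(betas, nk_isus, neu_isus, eps = 1e-6) {
  betas <- .check_probes(betas, c(nk_isus, neu_isus))
  stopifnot(eps > 0)
  out <- matrix(NA_real_, nrow(betas), length(nk_isus) * length(neu_isus),
                dimnames = list(rownames(betas), NULL))
  nm <- character(ncol(out)); k <- 0L
  for (np in nk_isus) for (up in neu_isus) {
    k <- k + 1L
    out[, k] <- (1 - betas[, np]) / pmax(1 - betas[, up], eps)
    nm[k] <- paste0(np, ".", up)
  }
  colnames(out) <- nm
  out
}
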