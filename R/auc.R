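#' Area under the ROC curve with DeLong confidence interval
#'
#' Rank-based AUC, counting tied case/control score pairs as one half:
#' \code{AUC = (concordant + 0.5 * ties) / (n_case * n_control)}. The
#' confidence interval uses the DeLong placement-variance estimator
#' \code{var(V10)/n_case + var(V01)/n_control}, truncated to \code{[0, 1]}.
#' Missing scores are dropped.
#'
#' @param scores numeric score vector.
#' @param labels case/control indicator aligned with \code{scores}: logical,
#'   0/1, or \code{"case"}/\code{"control"}.
#' @param conf_level confidence level.
#' @return list with \code{auc}, \code{se}, \code{ci} (length 2),
#'   \code{n_case}, \code{n_control}.
#' @export
auc <- function(scores, labels, conf_level = 0.95) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("case", "control")))
      stop("labels must be 'case'/'control' (or logical / 0-1)")
    labels <- labels == "case"
  }
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  x <- scores[labels]; y <- scores[!labels]
  n1 <- length(x); n0 <- length(y)
  if (n1 == 0L || n0 == 0L)
    stop("both cases and controls are required for AUC")
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0          # case placements
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1 # control placements
  est <- mean(v10)
  se <- if (n1 > 1L && n0 > 1L)
    sqrt(stats::var(v10) / n1 + stats::var(v01) / n0) else NA_real_
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else
    pmin(pmax(est + c(-q, q) * se, 0), 1)
  list(auc = est, se = se, ci = ci, n_case = n1, n_control = n0)
}

#' Holm step-down adjustment of p-values
#'
#' Family-wise error rate control by the Holm step-down procedure: p-values
#' are sorted ascending, the i-th smallest is multiplied by (m - i + 1), a
#' running maximum enforces monotonicity and values are capped at one.
#'
#' @param p numeric vector of p-values in \code{[0, 1]} (NA allowed).
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  pp <- p[!is.na(p)]
  if (length(pp) && (any(pp < 0) || any(pp > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}
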