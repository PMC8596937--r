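# Matched 1:1 case-control inference. The conditional likelihood for 1:1
# pairs reduces to logistic regression without intercept on the within-pair
# covariate differences d_i = x_case - x_control:
#   l(beta) = sum_i log sigma(d_i' beta)
# which is maximised here by Newton iteration on that difference form.

# Internal: build the pair-level design from a sample sheet and a score
# matrix. Pairs with any missing exposure value (either member) are dropped
# (complete-pair analysis). Returns case/control covariate rows aligned by
# pair.
.pair_design <- function(cohort, scores, exposures,
                         scale = c("beta", "logit"), eps = 1e-6) {
  scale <- match.arg(scale)
  # structural validation only here; the matching tolerance was checked when
  # the sheet was built/read and travels as an attribute
  tol <- attr(cohort, "age_tol")
  cohort <- as_matched_cohort(cohort, age_tol = if (is.null(tol)) Inf else tol)
  if (is.null(scores)) {
    S <- as.matrix(cohort[, exposures, drop = FALSE])
    rownames(S) <- cohort$sample_id
  } else {
    if (is.data.frame(scores)) scores <- as.matrix(scores)
    miss <- setdiff(exposures, colnames(scores))
    if (length(miss)) stop("exposure column(s) absent from scores: ",
                           paste(miss, collapse = ", "))
    absent <- setdiff(cohort$sample_id, rownames(scores))
    if (length(absent)) stop("samples absent from score matrix: ",
                             paste(utils::head(absent, 5), collapse = ", "))
    S <- scores[cohort$sample_id, exposures, drop = FALSE]
  }
  storage.mode(S) <- "double"
  if (scale == "logit") S <- apply(S, 2L, logit_transform, eps = eps)
  ca <- cohort[cohort$status == "case", c("sample_id", "pair_id")]
  co <- cohort[cohort$status == "control", c("sample_id", "pair_id")]
  co <- co[match(ca$pair_id, co$pair_id), ]
  Xc <- S[ca$sample_id, , drop = FALSE]
  Xk <- S[co$sample_id, , drop = FALSE]
  ok <- stats::complete.cases(Xc) & stats::complete.cases(Xk)
  list(Xc = Xc[ok, , drop = FALSE], Xk = Xk[ok, , drop = FALSE],
       pair_id = ca$pair_id[ok], n_dropped = sum(!ok), scale = scale)
}

# Internal: Newton maximisation of the paired conditional likelihood.
.clogit_newton <- function(D, tol = 1e-8, maxit = 100L) {
  D <- as.matrix(D)
  if (nrow(D) < 2L) stop("need at least 2 complete pairs")
  if (all(abs(D) < .Machine$double.eps))
    stop("no within-pair variation in the exposures")
  const <- apply(D, 2L, function(v) all(abs(v) < .Machine$double.eps))
  if (any(const))
    stop("no within-pair variation in exposure(s): ",
         paste(colnames(D)[const], collapse = ", "))
  p <- ncol(D)
  beta <- rep(0, p)
  # column scale for the runaway-coefficient check (root mean square, which
  # is nonzero for any column with within-pair variation)
  sds <- sqrt(colMeans(D^2))
  converged <- FALSE; separation <- FALSE; iter <- 0L
  H <- NULL
  for (iter in seq_len(maxit)) {
    z <- drop(D %*% beta)
    pr <- stats::plogis(z)
    g <- drop(crossprod(D, 1 - pr))
    W <- pr * (1 - pr)
    H <- crossprod(D, D * W)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    # monotone likelihood: fitted pair differences all one-signed and the
    # standardised coefficient running away
    z2 <- drop(D %*% beta)
    if (max(abs(beta * sds)) > 15 &&
        (all(z2 >= -1e-12) || all(z2 <= 1e-12))) {
      separation <- TRUE
      break
    }
    if (max(abs(step)) < tol && max(abs(g)) < sqrt(tol)) {
      converged <- TRUE
      break
    }
  }
  z <- drop(D %*% beta)
  loglik <- sum(stats::plogis(z, log.p = TRUE))
  vcov <- if (!separation && !is.null(H))
    tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  else matrix(NA_real_, p, p)
  dimnames(vcov) <- list(colnames(D), colnames(D))
  list(coefficients = stats::setNames(beta, colnames(D)),
       vcov = vcov, loglik = loglik, iter = iter,
       converged = converged, separation = separation)
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Fits the paired conditional likelihood by Newton iteration on within-pair
#' covariate differences (tolerance 1e-8, at most 100 iterations). Pairs
#' with a missing exposure value in either member are dropped. Under
#' \code{scale = "beta"} odds ratios are reported per \code{increment}
#' (default 0.1, i.e. a 10-percentage-point increase in methylation); under
#' \code{scale = "logit"} exposures are logit-transformed first and odds
#' ratios are per logit unit. Complete separation (monotone likelihood) is
#' detected and flagged: coefficients are then not interpretable and no odds
#' ratio is reported.
#'
#' @param cohort matched sample sheet (see \code{\link{as_matched_cohort}}):
#'   columns \code{sample_id}, \code{pair_id}, \code{status}
#'   ("case"/"control"), plus covariates.
#' @param scores samples x scores matrix with sample ids as rownames, or
#'   \code{NULL} to take exposures from \code{cohort} columns.
#' @param exposures names of the exposure columns to include.
#' @param scale analysis scale for the exposures.
#' @param increment odds-ratio increment on the beta scale.
#' @param eps logit clipping constant.
#' @return an object of class \code{clogit_fit}.
#' @export
fit_clogit <- function(cohort, scores = NULL, exposures,
                       scale = c("beta", "logit"), increment = 0.1,
                       eps = 1e-6) {
  scale <- match.arg(scale)
  md <- .pair_design(cohort, scores, exposures, scale, eps)
  fit <- .clogit_newton(md$Xc - md$Xk)
  structure(c(fit, list(n_pairs = nrow(md$Xc), n_dropped = md$n_dropped,
                        exposures = exposures, scale = scale,
                        increment = if (scale == "beta") increment else 1)),
            class = "clogit_fit")
}

#' @export
coef.clogit_fit <- function(object, ...) object$coefficients

#' @export
vcov.clogit_fit <- function(object, ...) object$vcov

#' @export
logLik.clogit_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_pairs, class = "logLik")
}

#' @export
confint.clogit_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  se <- sqrt(diag(object$vcov))[parm]
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - q * se, cf[parm] + q * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
summary.clogit_fit <- function(object, conf_level = 0.95, ...) {
  cf <- object$coefficients
  se <- sqrt(diag(object$vcov))
  z <- cf / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  inc <- object$increment
  tab <- data.frame(
    beta = cf, se = se, z = z, p = p,
    OR = exp(inc * cf),
    ci_low = exp(inc * (cf - q * se)),
    ci_high = exp(inc * (cf + q * se)),
    row.names = names(cf))
  if (object$separation) tab[, c("OR", "ci_low", "ci_high")] <- NA_real_
  structure(list(coefficients = tab, n_pairs = object$n_pairs,
                 n_dropped = object$n_dropped, loglik = object$loglik,
                 converged = object$converged,
                 separation = object$separation,
                 increment = inc, scale = object$scale),
            class = "summary.clogit_fit")
}

#' @export
print.summary.clogit_fit <- function(x, digits = 4, ...) {
  cat("1:1 conditional logistic regression (", x$n_pairs, " pairs",
      if (x$n_dropped) paste0(", ", x$n_dropped, " dropped"), ")\n", sep = "")
  if (x$separation)
    cat("WARNING: monotone likelihood (separation); estimates unreliable\n")
  else if (!x$converged) cat("WARNING: Newton iteration did not converge\n")
  if (x$scale == "beta")
    cat("Odds ratios per ", x$increment, " exposure increase\n", sep = "")
  print(signif(as.matrix(x$coefficients), digits))
  cat("log-likelihood:", signif(x$loglik, digits), "\n")
  invisible(x)
}

#' @export
print.clogit_fit <- function(x, ...) {
  print(summary(x), ...)
  invisible(x)
}
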