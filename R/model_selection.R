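# Multivariable model building on the matched design: backward selection on
# Wald p-values and Harrell optimism-bootstrap internal validation of the
# AUC.

# Internal: sample-level AUC of the linear predictor X beta for a matched
# design md (list Xc, Xk). Empty models score 0.5 (all ties).
.lp_auc <- function(md, selected, beta) {
  n <- nrow(md$Xc)
  if (length(selected) == 0L)
    return(auc(rep(0, 2L * n), rep(c(TRUE, FALSE), each = n))$auc)
  lp <- c(drop(md$Xc[, selected, drop = FALSE] %*% beta),
          drop(md$Xk[, selected, drop = FALSE] %*% beta))
  auc(lp, rep(c(TRUE, FALSE), each = n))$auc
}

# Internal: backward selection loop on a prebuilt design.
.backward_core <- function(md, exposures, alpha_stay) {
  current <- sort(exposures)
  trace <- data.frame(step = integer(), dropped = character(),
                      p_drop = numeric(), stringsAsFactors = FALSE)
  fit <- NULL
  step <- 0L
  while (length(current)) {
    fit <- .clogit_newton(md$Xc[, current, drop = FALSE] -
                            md$Xk[, current, drop = FALSE])
    se <- sqrt(diag(fit$vcov))
    p <- 2 * stats::pnorm(-abs(fit$coefficients / se))
    if (all(is.finite(p)) && max(p) <= alpha_stay) break
    # drop the largest p (non-finite p counts as largest); ties by name
    p_drop <- ifelse(is.finite(p), p, Inf)
    worst <- names(p_drop)[order(-p_drop, names(p_drop))][1L]
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = worst,
                                     p_drop = unname(p[worst]),
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, worst)
    fit <- NULL
  }
  list(selected = current, fit = fit, trace = trace)
}

#' Univariable association scan over a block of exposures
#'
#' Runs a univariable 1:1 conditional logistic regression and an AUC
#' analysis for every exposure in a block, with Holm adjustment of the Wald
#' p-values across the block. Mirrors the per-marker association tables of
#' matched case-control methylation studies (odds ratio per 0.1 beta
#' increase, 95 percent Wald interval, raw and Holm-adjusted p, AUC with
#' DeLong interval).
#'
#' @inheritParams fit_clogit
#' @param conf_level confidence level for both interval types.
#' @return a data frame of class \code{assoc_table}, one row per exposure:
#'   \code{exposure}, \code{beta}, \code{se}, \code{OR}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{p_adj}, \code{auc}, \code{auc_low},
#'   \code{auc_high}, \code{n_pairs}.
#' @export
association_scan <- function(cohort, scores = NULL, exposures,
                             scale = c("beta", "logit"), increment = 0.1,
                             conf_level = 0.95, eps = 1e-6) {
  scale <- match.arg(scale)
  rows <- lapply(exposures, function(ex) {
    fit <- fit_clogit(cohort, scores, ex, scale, increment, eps)
    s <- summary(fit, conf_level)$coefficients
    md <- .pair_design(cohort, scores, ex, scale, eps)
    n <- nrow(md$Xc)
    a <- auc(c(md$Xc[, 1L], md$Xk[, 1L]),
             rep(c(TRUE, FALSE), each = n), conf_level)
    data.frame(exposure = ex, beta = s$beta, se = s$se, OR = s$OR,
               ci_low = s$ci_low, ci_high = s$ci_high, p = s$p,
               auc = a$auc, auc_low = a$ci[1L], auc_high = a$ci[2L],
               n_pairs = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_adjust(out$p)
  out <- out[, c("exposure", "beta", "se", "OR", "ci_low", "ci_high",
                 "p", "p_adj", "auc", "auc_low", "auc_high", "n_pairs")]
  structure(out, class = c("assoc_table", "data.frame"),
            scale = scale, increment = increment)
}

#' @export
print.assoc_table <- function(x, digits = 3, ...) {
  cat("Matched case-control association scan (", nrow(x), " exposures, ",
      x$n_pairs[1L], " pairs; OR per ", attr(x, "increment"),
      " on the ", attr(x, "scale"), " scale)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Backward selection for the multivariable matched model
#'
#' Iteratively refits the multivariable conditional logistic model and
#' removes the exposure with the largest Wald p-value while it exceeds
#' \code{alpha_stay} (default 20 percent, the conventional stay level for
#' diagnostic model building). Ties are broken by dropping the
#' lexicographically smallest name among the worst; an empty final model is
#' allowed. Deterministic given the data.
#'
#' @inheritParams fit_clogit
#' @param alpha_stay significance level for staying in the model.
#' @return an object of class \code{model_fit}: \code{selected},
#'   \code{fit} (a \code{clogit_fit} or NULL if empty),
#'   \code{trace} (drop history), \code{apparent_auc} (sample-level AUC of
#'   the linear predictor), \code{n_pairs}.
#' @export
backward_select <- function(cohort, scores = NULL, exposures,
                            alpha_stay = 0.20, scale = c("beta", "logit"),
                            increment = 0.1, eps = 1e-6) {
  scale <- match.arg(scale)
  md <- .pair_design(cohort, scores, exposures, scale, eps)
  res <- .backward_core(md, exposures, alpha_stay)
  fit <- NULL
  if (length(res$selected)) {
    fit <- structure(
      c(res$fit, list(n_pairs = nrow(md$Xc), n_dropped = md$n_dropped,
                      exposures = res$selected, scale = scale,
                      increment = if (scale == "beta") increment else 1)),
      class = "clogit_fit")
  }
  structure(list(selected = res$selected, fit = fit, trace = res$trace,
                 apparent_auc = .lp_auc(md, res$selected,
                                        res$fit$coefficients),
                 alpha_stay = alpha_stay, n_pairs = nrow(md$Xc)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  cat("Backward-selected matched model (stay level ", x$alpha_stay,
      ", ", x$n_pairs, " pairs)\n", sep = "")
  if (length(x$selected)) {
    cat("Selected exposures:", paste(x$selected, collapse = ", "), "\n")
    print(signif(as.matrix(summary(x$fit)$coefficients), digits))
  } else cat("Selected exposures: none (empty model)\n")
  cat("Apparent AUC:", signif(x$apparent_auc, digits), "\n")
  if (nrow(x$trace))
    cat("Dropped:", paste(x$trace$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Optimism-corrected bootstrap AUC for the selected model
#'
#' Harrell internal validation of the backward-selected model, resampling
#' matched pairs with replacement: each replicate reruns the full selection
#' and fit, and its optimism is the replicate-sample AUC minus the AUC of
#' the replicate model applied to the original sample. The adjusted AUC is
#' the apparent AUC minus the mean optimism over \code{B} replicates.
#' Replicates whose fit fails are skipped and counted; more than 20 percent
#' failures is an error.
#'
#' @inheritParams backward_select
#' @param B number of bootstrap replicates.
#' @param seed optional seed for the pair resampling.
#' @param indices optional list of integer vectors (pair indices) overriding
#'   the random resampling, mainly for testing; its length overrides
#'   \code{B}.
#' @return an object of class \code{optimism_fit}: \code{apparent_auc},
#'   \code{optimism}, \code{adjusted_auc}, \code{B}, \code{B_failed},
#'   \code{selected}, \code{fit}, \code{trace}, \code{seed}.
#' @export
bootstrap_adjusted_auc <- function(cohort, scores = NULL, exposures,
                                   B = 200L, alpha_stay = 0.20,
                                   scale = c("beta", "logit"),
                                   increment = 0.1, eps = 1e-6,
                                   seed = NULL, indices = NULL) {
  scale <- match.arg(scale)
  stopifnot(B >= 1L)
  md <- .pair_design(cohort, scores, exposures, scale, eps)
  n <- nrow(md$Xc)
  full <- .backward_core(md, exposures, alpha_stay)
  apparent <- .lp_auc(md, full$selected, full$fit$coefficients)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  if (is.null(indices))
    indices <- lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  B <- length(indices)
  opt <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- indices[[b]]
    md_b <- list(Xc = md$Xc[idx, , drop = FALSE],
                 Xk = md$Xk[idx, , drop = FALSE])
    res <- tryCatch({
      sel_b <- .backward_core(md_b, exposures, alpha_stay)
      auc_boot <- .lp_auc(md_b, sel_b$selected, sel_b$fit$coefficients)
      auc_orig <- .lp_auc(md, sel_b$selected, sel_b$fit$coefficients)
      auc_boot - auc_orig
    }, error = function(e) NA_real_)
    opt[b] <- res
  }
  failed <- sum(is.na(opt))
  if (failed > 0.2 * B)
    stop("bootstrap failed in ", failed, " of ", B, " replicates")
  optimism <- mean(opt, na.rm = TRUE)
  fit <- NULL
  if (length(full$selected))
    fit <- structure(
      c(full$fit, list(n_pairs = n, n_dropped = md$n_dropped,
                       exposures = full$selected, scale = scale,
                       increment = if (scale == "beta") increment else 1)),
      class = "clogit_fit")
  structure(list(apparent_auc = apparent, optimism = optimism,
                 adjusted_auc = apparent - optimism, B = B,
                 B_failed = failed, selected = full$selected, fit = fit,
                 trace = full$trace, seed = seed, alpha_stay = alpha_stay,
                 n_pairs = n),
            class = "optimism_fit")
}

#' @export
print.optimism_fit <- function(x, digits = 4, ...) {
  cat("Optimism-corrected bootstrap validation (", x$B, " replicates",
      if (x$B_failed) paste0(", ", x$B_failed, " failed"), ")\n", sep = "")
  cat("Selected exposures:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "none",
      "\n")
  cat("Apparent AUC: ", signif(x$apparent_auc, digits),
      "   optimism: ", signif(x$optimism, digits),
      "   adjusted AUC: ", signif(x$adjusted_auc, digits), "\n", sep = "")
  invisible(x)
}
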