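#' Build a deconvolution signature matrix from a marker panel
#'
#' Takes the reference beta columns of the six deconvolvable leukocyte types
#' at the panel's marker probes (ISUS of those types plus the opposing
#' neutrophil/pan-lymphocyte sets), ordered by descending specificity margin
#' and capped at \code{max_probes}.
#'
#' @param ref reference methylome matrix (probes x cell types).
#' @param panel a \code{marker_panel}.
#' @param cell_types columns to deconvolve (default the six classical types).
#' @param max_probes cap on signature size.
#' @return probes x cell types beta matrix.
#' @export
build_signature <- function(ref, panel,
                            cell_types = c("NK", "TCD4", "TCD8",
                                           "Mono", "Neu", "B"),
                            max_probes = 50) {
  ref <- .validate_reference(ref)
  if (!all(cell_types %in% colnames(ref)))
    stop("cell type(s) absent from reference: ",
         paste(setdiff(cell_types, colnames(ref)), collapse = ", "))
  keep <- panel$target %in% c(cell_types, "neutrophil", "pan-lymphocyte")
  p <- panel[keep, , drop = FALSE]
  p <- p[order(-p$margin, p$probe_id), , drop = FALSE]
  probes <- utils::head(unique(p$probe_id), max_probes)
  probes <- probes[probes %in% rownames(ref)]
  if (!length(probes)) stop("no panel probes present in the reference")
  ref[probes, cell_types, drop = FALSE]
}

# Internal: names of (near-)collinear signature columns, via pivoted QR.
.collinear_cols <- function(X, tol = 1e-7) {
  qrX <- qr(X, tol = tol)
  if (qrX$rank == ncol(X)) return(character())
  colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
}

#' Estimate leukocyte proportions for one sample
#'
#' Constrained projection of a sample's beta vector onto reference cell-type
#' profiles: \code{w = argmin ||y - Xw||^2} subject to \code{w >= 0} and
#' \code{sum(w) = 1}. Solved by active-set nonnegative least squares on a
#' system augmented with a heavily weighted sum-to-one row, followed by exact
#' renormalisation; deterministic, KKT-accurate well below 1e-8 on
#' well-conditioned signatures. Probes with a missing beta in \code{y} are
#' dropped (jointly from \code{y} and \code{X}) before solving.
#'
#' @param y named numeric vector of sample betas over the signature probes.
#' @param X signature matrix (probes x cell types).
#' @return list with \code{w} (named proportion vector summing to one) and
#'   \code{residual} (root-mean-square of observed minus fitted betas).
#' @export
estimate_proportions <- function(y, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.null(names(y))) {
    miss <- setdiff(rownames(X), names(y))
    if (length(miss)) stop("sample lacks beta for signature probe(s) ",
                           paste(utils::head(miss, 5), collapse = ", "))
    y <- y[rownames(X)]
  }
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  keep <- !is.na(y) & stats::complete.cases(X)
  y <- y[keep]; Xk <- X[keep, , drop = FALSE]
  if (length(y) < ncol(X))
    stop("fewer usable probes (", length(y), ") than cell types (",
         ncol(X), ")")
  bad <- .collinear_cols(Xk)
  if (length(bad))
    stop("signature is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  lambda <- 1e3 * max(1, sqrt(sum(Xk^2)))
  Xa <- rbind(Xk, lambda)
  ya <- c(y, lambda)
  w <- pracma::lsqnonneg(Xa, ya)$x
  s <- sum(w)
  if (s <= 0) stop("degenerate solution: all proportions zero")
  w <- w / s
  names(w) <- colnames(X)
  list(w = w, residual = sqrt(mean((y - drop(Xk %*% w))^2)))
}

#' Reference-based deconvolution of a cohort beta matrix
#'
#' Runs \code{\link{estimate_proportions}} on every sample, returning a
#' classed result with per-sample proportion vectors (each nonnegative and
#' summing to one) and root-mean-square residuals.
#'
#' @param betas samples x probes beta matrix.
#' @param signature probes x cell types signature matrix (see
#'   \code{\link{build_signature}}).
#' @return an object of class \code{deconv}: list with \code{proportions}
#'   (samples x cell types), \code{residual} (per-sample RMSE) and
#'   \code{signature}.
#' @export
deconvolve <- function(betas, signature) {
  if (!is.matrix(signature)) signature <- as.matrix(signature)
  betas <- .check_probes(betas, rownames(signature))
  B <- betas[, rownames(signature), drop = FALSE]
  fits <- lapply(seq_len(nrow(B)), function(i) {
    y <- B[i, ]; names(y) <- colnames(B)
    estimate_proportions(y, signature)
  })
  W <- do.call(rbind, lapply(fits, `[[`, "w"))
  rownames(W) <- rownames(B)
  structure(list(proportions = W,
                 residual = stats::setNames(vapply(fits, `[[`, 0, "residual"),
                                            rownames(B)),
                 signature = signature),
            class = "deconv")
}

#' @export
print.deconv <- function(x, ...) {
  cat("Reference-based deconvolution:", nrow(x$proportions), "samples,",
      ncol(x$proportions), "cell types,", nrow(x$signature),
      "signature probes\n")
  cat("Mean proportions:\n")
  print(round(colMeans(x$proportions), 4))
  cat("Median fit RMSE:", signif(stats::median(x$residual), 4), "\n")
  invisible(x)
}

#' @export
summary.deconv <- function(object, ...) {
  s <- apply(object$proportions, 2L, stats::quantile,
             probs = c(0.25, 0.5, 0.75))
  structure(list(quartiles = s, residual = summary(object$residual)),
            class = "summary.deconv")
}

#' @export
print.summary.deconv <- function(x, ...) {
  cat("Proportion quartiles by cell type:\n")
  print(round(x$quartiles, 4))
  cat("Fit RMSE:\n"); print(x$residual)
  invisible(x)
}

#' Neutrophil-to-lymphocyte ratio from deconvolved proportions (mdNLR_ref)
#'
#' Estimated neutrophil proportion divided by the summed lymphoid
#' proportions (NK + CD4 T + CD8 T + B); monocytes are excluded from the
#' denominator, which is floored at \code{eps}.
#'
#' @param w a proportion vector, a samples x cell types matrix, or a
#'   \code{deconv} object.
#' @param neu neutrophil column name.
#' @param lymphoid lymphoid column names.
#' @param eps denominator floor.
#' @return numeric vector (one value per sample).
#' @export
mdnlr_ref <- function(w, neu = "Neu", lymphoid = c("NK", "TCD4", "TCD8", "B"),
                      eps = 1e-6) {
  if (inherits(w, "deconv")) w <- w$proportions
  if (is.null(dim(w))) w <- matrix(w, 1L, dimnames = list(NULL, names(w)))
  if (!all(c(neu, lymphoid) %in% colnames(w)))
    stop("proportion columns missing: ",
         paste(setdiff(c(neu, lymphoid), colnames(w)), collapse = ", "))
  out <- drop(w[, neu] / pmax(rowSums(w[, lymphoid, drop = FALSE]), eps))
  names(out) <- rownames(w)
  out
}
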