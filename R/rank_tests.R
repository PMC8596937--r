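# Nonparametric tests used for the paired case-control comparisons and the
# clinical/epidemiological correlation analyses.

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped. For n <= 25 without ties the exact signed-
#' rank null distribution is used; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @param d numeric vector of paired differences (case minus control).
#' @param alternative \code{"two.sided"}, \code{"greater"} or
#'   \code{"less"}.
#' @return list with \code{statistic} (V, sum of positive ranks),
#'   \code{p.value}, \code{method} ("exact" or "normal") and \code{n}
#'   (non-zero differences used).
#' @export
wilcoxon_signed_rank <- function(d, alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate: all differences are zero or missing")
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- n <= 25 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (exact) "exact" else "normal", n = n)
}

#' Mann-Whitney (Wilcoxon rank-sum) test for two independent groups
#'
#' Exact null distribution for small samples (both groups <= 25, no ties),
#' otherwise normal approximation with continuity and tie correction. The
#' statistic U counts pairs where a value from \code{a} exceeds one from
#' \code{b} (ties half-weighted), so \code{U / (nA * nB)} equals the AUC of
#' \code{a}-vs-\code{b}.
#'
#' @param a,b numeric vectors.
#' @param alternative test direction.
#' @return list with \code{statistic} (U), \code{p.value}, \code{method},
#'   \code{n} (c(nA, nB)).
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= 25 && length(b) <= 25 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (exact) "exact" else "normal",
       n = c(length(a), length(b)))
}

# Internal: JT statistic for a list of groups in hypothesised order.
.jt_stat <- function(groups) {
  s <- 0
  k <- length(groups)
  for (g in seq_len(k - 1L)) for (h in seq.int(g + 1L, k)) {
    cmp <- outer(groups[[g]], groups[[h]], "<")
    eq <- outer(groups[[g]], groups[[h]], "==")
    s <- s + sum(cmp) + 0.5 * sum(eq)
  }
  s
}

# Internal: all JT values over distinct assignments of the pooled sample to
# the group sizes (exhaustive permutation null).
.jt_enumerate <- function(pool, sizes) {
  if (length(sizes) == 1L) return(0)  # no between-group pairs remain
  out <- numeric(0)
  idx <- utils::combn(length(pool), sizes[1L])
  for (j in seq_len(ncol(idx))) {
    g1 <- pool[idx[, j]]
    rest <- pool[-idx[, j]]
    # contribution of group 1 against everything after it
    c1 <- sum(outer(g1, rest, "<")) + 0.5 * sum(outer(g1, rest, "=="))
    out <- c(out, c1 + .jt_enumerate(rest, sizes[-1L]))
  }
  out
}

#' Jonckheere-Terpstra trend test for ordered groups
#'
#' Tests for a monotone location trend across k groups given in hypothesised
#' increasing order. The statistic sums, over every ordered group pair, the
#' number of observation pairs in increasing order (ties half-weighted). The
#' null distribution is exhaustive-permutation exact for total n <= 10,
#' Monte-Carlo permutation otherwise (seeded), or a normal approximation on
#' request; the choice is recorded in the result.
#'
#' @param groups list of numeric vectors in hypothesised increasing order.
#' @param alternative \code{"two.sided"}, \code{"increasing"} or
#'   \code{"decreasing"}.
#' @param method \code{"auto"} (exact for total n <= 10, else permutation),
#'   or one of \code{"exact"}, \code{"permutation"}, \code{"normal"}.
#' @param n_perm Monte-Carlo permutation count.
#' @param seed optional seed for the Monte-Carlo null.
#' @return list with \code{statistic}, \code{p.value}, \code{method},
#'   \code{alternative}.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("two.sided", "increasing",
                                                "decreasing"),
                                method = c("auto", "exact", "permutation",
                                           "normal"),
                                n_perm = 10000L, seed = NULL) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 ordered groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, 0L) == 0L))
    stop("every group must be non-empty")
  sizes <- vapply(groups, length, 0L)
  N <- sum(sizes)
  obs <- .jt_stat(groups)
  if (method == "auto") method <- if (N <= 10L) "exact" else "permutation"

  split_stats <- function(vals) {
    # two-sided p from a permutation null
    p_up <- mean(vals >= obs - 1e-12)
    p_dn <- mean(vals <= obs + 1e-12)
    switch(alternative,
           increasing = p_up,
           decreasing = p_dn,
           two.sided = min(1, 2 * min(p_up, p_dn)))
  }
  if (method == "exact") {
    vals <- .jt_enumerate(unlist(groups), sizes)
    p <- split_stats(vals)
  } else if (method == "permutation") {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    pool <- unlist(groups)
    idx_end <- cumsum(sizes)
    idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
    vals <- vapply(seq_len(n_perm), function(i) {
      sh <- sample(pool)
      .jt_stat(lapply(seq_along(sizes),
                      function(g) sh[idx_start[g]:idx_end[g]]))
    }, 0)
    # add-one Monte-Carlo correction
    p_up <- (1 + sum(vals >= obs - 1e-12)) / (1 + n_perm)
    p_dn <- (1 + sum(vals <= obs + 1e-12)) / (1 + n_perm)
    p <- switch(alternative, increasing = p_up, decreasing = p_dn,
                two.sided = min(1, 2 * min(p_up, p_dn)))
  } else {
    mu <- (N^2 - sum(sizes^2)) / 4
    sg <- sqrt((N^2 * (2 * N + 3) - sum(sizes^2 * (2 * sizes + 3))) / 72)
    z <- (obs - mu) / sg
    p <- switch(alternative,
                increasing = stats::pnorm(z, lower.tail = FALSE),
                decreasing = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = obs, p.value = p, method = method,
       alternative = alternative)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p-value by the asymptotic
#' t approximation.
#'
#' @param x,y numeric vectors (pairwise-complete observations used).
#' @return list with \code{rho}, \code{p.value}, \code{n}.
#' @export
spearman_rho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p.value = ht$p.value, n = length(x))
}
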