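# Independent brute-force oracles. Each one recomputes a quantity by
# enumeration, grid search or direct formula, on purpose without touching
# the implementation path it checks.

# exhaustive pairwise AUC count
oracle_auc <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(cases) * length(controls))
}

# Holm step-down by the textbook formula
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# paired conditional log-likelihood grid maximiser (single covariate)
oracle_clogit_grid <- function(d, lo = -10, hi = 10, step = 1e-4) {
  beta <- seq(lo, hi, by = step)
  ll <- vapply(beta, function(b) sum(stats::plogis(d * b, log.p = TRUE)), 0)
  beta[which.max(ll)]
}

oracle_clogit_loglik <- function(d, beta) {
  sum(stats::plogis(drop(d %*% beta), log.p = TRUE))
}

# simplex grid search for 2- and 3-component constrained least squares
oracle_simplex_grid <- function(X, y, step = 1e-3) {
  k <- ncol(X)
  stopifnot(k %in% c(2L, 3L))
  best <- NULL; best_val <- Inf
  w1s <- seq(0, 1, by = step)
  for (w1 in w1s) {
    if (k == 2L) {
      w <- c(w1, 1 - w1)
      v <- sum((y - X %*% w)^2)
      if (v < best_val) { best_val <- v; best <- w }
    } else {
      w2s <- seq(0, 1 - w1, by = step)
      r1 <- y - X[, 1L] * w1
      for (w2 in w2s) {
        w3 <- 1 - w1 - w2
        v <- sum((r1 - X[, 2L] * w2 - X[, 3L] * w3)^2)
        if (v < best_val) { best_val <- v; best <- c(w1, w2, w3) }
      }
    }
  }
  best
}

# exact signed-rank p by enumeration of all 2^n sign patterns
oracle_wilcoxon_exact <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  p_ge <- mean(vs >= v_obs)
  p_le <- mean(vs <= v_obs)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# all permutations of 1..n (recursive, for small n)
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

# Mann-Whitney U and exact p by full permutation of the pooled sample
oracle_mw_exact <- function(a, b, alternative = "two.sided") {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  P <- oracle_perms(n)
  us <- apply(P, 1L, function(ix) u_of(pool[ix[seq_len(na)]],
                                       pool[ix[-seq_len(na)]]))
  p_ge <- mean(us >= u_obs - 1e-12)
  p_le <- mean(us <= u_obs + 1e-12)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Jonckheere-Terpstra statistic and exact permutation p via full n!
# enumeration (independent of the package's combination-based recursion)
oracle_jt_stat <- function(groups) {
  s <- 0; k <- length(groups)
  for (g in seq_len(k - 1L)) for (h in seq.int(g + 1L, k))
    for (x in groups[[g]]) for (y in groups[[h]])
      s <- s + (x < y) + 0.5 * (x == y)
  s
}

oracle_jt_exact <- function(groups, alternative = "two.sided") {
  sizes <- lengths(groups)
  pool <- unlist(groups)
  n <- length(pool)
  ends <- cumsum(sizes); starts <- c(1L, head(ends, -1L) + 1L)
  obs <- oracle_jt_stat(groups)
  P <- oracle_perms(n)
  js <- apply(P, 1L, function(ix) {
    v <- pool[ix]
    oracle_jt_stat(lapply(seq_along(sizes),
                          function(g) v[starts[g]:ends[g]]))
  })
  p_ge <- mean(js >= obs - 1e-12)
  p_le <- mean(js <= obs + 1e-12)
  switch(alternative,
         increasing = p_ge, decreasing = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Spearman rho by the no-ties rank-difference formula
oracle_spearman <- function(x, y) {
  n <- length(x)
  1 - 6 * sum((rank(x) - rank(y))^2) / (n * (n^2 - 1))
}
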