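test_that("signed-rank test is exact for small samples", {
  r <- wilcoxon_signed_rank(c(1, 2, 3), alternative = "greater")
  expect_equal(r$p.value, 1 / 8)
  expect_equal(r$method, "exact")

  r2 <- wilcoxon_signed_rank(c(1, -1.5))
  expect_equal(r2$p.value, 1.0)

  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")

  # zeros dropped before ranking
  r3 <- wilcoxon_signed_rank(c(0, 1, 2, 3), alternative = "greater")
  expect_equal(r3$p.value, 1 / 8)
  expect_equal(r3$n, 3L)
})

test_that("signed-rank p matches sign-pattern enumeration on small vectors", {
  set.seed(15)
  for (rep in 1:8) {
    d <- round(rnorm(sample(4:8, 1)), 2)
    d <- d[d != 0]
    if (anyDuplicated(abs(d))) next
    for (alt in c("two.sided", "greater")) {
      expect_equal(wilcoxon_signed_rank(d, alt)$p.value,
                   oracle_wilcoxon_exact(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("large-sample signed-rank p tracks a Monte-Carlo null", {
  set.seed(16)
  d <- rnorm(30, 0.3)
  r <- wilcoxon_signed_rank(d)
  expect_equal(r$method, "normal")
  # Monte-Carlo null of the signed-rank statistic at these magnitudes
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  B <- 1e5
  signs <- matrix(runif(B * 30) < 0.5, B, 30)
  vs <- drop(signs %*% rk)
  p_mc <- min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs)))
  expect_lt(abs(r$p.value - p_mc), 0.01)
})

test_that("Mann-Whitney handles identity, disjoint supports and the AUC identity", {
  g <- c(1.2, 3.4, 2.2)
  expect_equal(mann_whitney(g, g)$p.value, 1.0)

  r <- mann_whitney(c(3, 4), c(1, 2))
  expect_equal(r$p.value, 2 / 6)
  expect_equal(r$method, "exact")

  set.seed(17)
  a <- sample(seq(0, 1, 0.05), 9, TRUE)
  b <- sample(seq(0, 1, 0.05), 12, TRUE)
  r2 <- mann_whitney(a, b)
  expect_equal(r2$statistic / (9 * 12),
               auc(c(a, b), rep(c(1, 0), c(9, 12)))$auc)
})

test_that("Mann-Whitney agrees with full-permutation enumeration", {
  set.seed(18)
  for (rep in 1:5) {
    a <- round(rnorm(3), 2); b <- round(rnorm(4), 2)
    if (anyDuplicated(c(a, b))) next
    expect_equal(mann_whitney(a, b)$p.value, oracle_mw_exact(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Jonckheere-Terpstra matches its definition and exact null", {
  r <- jonckheere_terpstra(list(c(1, 2), c(3, 4)),
                           alternative = "increasing")
  expect_equal(r$statistic, 4)
  expect_equal(r$p.value, 1 / 6)
  expect_equal(r$method, "exact")

  # null mean over the exact permutation distribution is sum n_g n_h / 2
  groups <- list(c(0.3, 1.1, 2), c(0.7, 0.2), c(1.4, 0.9))
  vals <- immunomethyl:::.jt_enumerate(unlist(groups), lengths(groups))
  N <- sum(lengths(groups))
  expect_equal(mean(vals), (N^2 - sum(lengths(groups)^2)) / 4)

  expect_error(jonckheere_terpstra(list(1:3)), "2 ordered groups")
})

test_that("Jonckheere-Terpstra exact p agrees with an n! permutation oracle", {
  set.seed(19)
  for (rep in 1:4) {
    g <- list(round(rnorm(3), 1), round(rnorm(2), 1), round(rnorm(3), 1))
    for (alt in c("two.sided", "increasing")) {
      expect_equal(jonckheere_terpstra(g, alternative = alt)$p.value,
                   oracle_jt_exact(g, alt), tolerance = 1e-12)
    }
  }
})

test_that("Jonckheere-Terpstra has power against a monotone shift", {
  set.seed(20)
  hits <- 0L
  for (rep in 1:100) {
    g <- list(rnorm(15, 0), rnorm(15, 0.8), rnorm(15, 1.6))
    p <- jonckheere_terpstra(g, alternative = "increasing",
                             method = "normal")$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 90L)
})

test_that("permutation p-values are reproducible given a seed", {
  g <- list(rnorm(6), rnorm(6), rnorm(6))
  p1 <- jonckheere_terpstra(g, method = "permutation", n_perm = 500,
                            seed = 1)$p.value
  p2 <- jonckheere_terpstra(g, method = "permutation", n_perm = 500,
                            seed = 1)$p.value
  expect_identical(p1, p2)
})

test_that("Spearman correlation handles exact monotone data and ties", {
  x <- c(1.2, 4.1, 2.2, 5.5, 3.3, 0.1)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  set.seed(21)
  y <- rnorm(6)
  expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y),
               tolerance = 1e-12)
})
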