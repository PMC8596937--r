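test_that("symmetric pair differences give a null estimate", {
  cc <- make_diff_cohort(c(1, -1))
  fit <- fit_clogit(cc$sheet, cc$scores, "x")
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
  expect_equal(unname(summary(fit)$coefficients$OR), 1, tolerance = 1e-8)
})

test_that("estimate matches the brute-force likelihood grid", {
  cc <- make_diff_cohort(c(1, 1, -1))
  fit <- fit_clogit(cc$sheet, cc$scores, "x")
  b_grid <- oracle_clogit_grid(c(1, 1, -1))
  expect_lt(abs(unname(coef(fit)) - b_grid), 1e-3)
  expect_equal(unname(coef(fit)), log(2), tolerance = 1e-6)
  # likelihood at the estimate dominates every grid point
  ll_hat <- oracle_clogit_loglik(matrix(c(1, 1, -1)), coef(fit))
  bgrid <- seq(-10, 10, by = 0.01)
  lls <- vapply(bgrid, function(b)
    oracle_clogit_loglik(matrix(c(1, 1, -1)), b), 0)
  expect_gte(ll_hat, max(lls) - 1e-10)
})

test_that("one-signed differences raise the separation flag", {
  cc <- make_diff_cohort(c(1, 1, 1))
  fit <- fit_clogit(cc$sheet, cc$scores, "x")
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_true(all(is.na(summary(fit)$coefficients$OR)))
})

test_that("degenerate designs error out with a clear message", {
  cc <- make_diff_cohort(c(0, 0, 0))
  expect_error(fit_clogit(cc$sheet, cc$scores, "x"), "within-pair variation")
  cc2 <- make_diff_cohort(c(1, -1))
  expect_error(fit_clogit(cc2$sheet, cc2$scores[1:2, , drop = FALSE], "x"),
               "absent")
})

test_that("pairs with missing exposures are dropped, not imputed", {
  d <- c(1, 1, -1, 2)
  cc <- make_diff_cohort(d)
  cc$scores[2, 1] <- NA  # case of pair 2
  fit <- fit_clogit(cc$sheet, cc$scores, "x")
  expect_equal(fit$n_pairs, 3L)
  expect_equal(fit$n_dropped, 1L)
})

test_that("multivariable fit agrees with the survival package", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  set.seed(99)
  n <- 120
  Xc <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  Xk <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  # plant effects so the fit is non-trivial
  lp <- function(X) drop(X %*% c(0.8, -0.5, 0))
  pcase <- plogis(lp(Xc) - lp(Xk))
  swap <- runif(n) > pcase
  tmp <- Xc[swap, ]; Xc[swap, ] <- Xk[swap, ]; Xk[swap, ] <- tmp
  cc <- make_score_cohort(Xc, Xk)
  fit <- fit_clogit(cc$sheet, cc$scores, c("a", "b", "c"))
  df <- data.frame(y = rep(c(1, 0), each = n),
                   rbind(Xc, Xk),
                   strat = rep(seq_len(n), 2))
  sv <- survival::clogit(y ~ a + b + c + strata(strat), df)
  expect_equal(unname(coef(fit)), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(sqrt(diag(vcov(sv)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, unname(sv$loglik[2]), tolerance = 1e-8)
})

test_that("odds ratios are reported per increment on the beta scale", {
  set.seed(7)
  d <- rnorm(60, 0.03, 0.05)
  cc <- make_diff_cohort(d)
  fit <- fit_clogit(cc$sheet, cc$scores, "x", increment = 0.1)
  s <- summary(fit)$coefficients
  expect_equal(s$OR, exp(0.1 * s$beta), tolerance = 1e-12)
  q <- qnorm(0.975)
  expect_equal(s$ci_low, exp(0.1 * (s$beta - q * s$se)), tolerance = 1e-12)
  expect_true(s$ci_low <= s$OR && s$OR <= s$ci_high)
})

test_that("logit scale transforms exposures before fitting", {
  set.seed(8)
  n <- 40
  bc <- runif(n, 0.3, 0.7); bk <- runif(n, 0.3, 0.7)
  cc <- make_score_cohort(matrix(bc, ncol = 1, dimnames = list(NULL, "m")),
                          matrix(bk, ncol = 1, dimnames = list(NULL, "m")))
  f_logit <- fit_clogit(cc$sheet, cc$scores, "m", scale = "logit")
  cc2 <- make_score_cohort(
    matrix(logit_transform(bc), ncol = 1, dimnames = list(NULL, "m")),
    matrix(logit_transform(bk), ncol = 1, dimnames = list(NULL, "m")))
  f_manual <- fit_clogit(cc2$sheet, cc2$scores, "m")
  expect_equal(coef(f_logit), coef(f_manual), tolerance = 1e-10)
  expect_equal(summary(f_logit)$coefficients$OR,
               exp(coef(f_logit)[[1]]), tolerance = 1e-12)
})

test_that("grid oracle agreement holds across random small instances", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    d <- round(rnorm(n), 2)
    if (all(d >= 0) || all(d <= 0) || all(d == 0)) next
    cc <- make_diff_cohort(d)
    fit <- fit_clogit(cc$sheet, cc$scores, "x")
    if (fit$separation) next
    expect_lt(abs(unname(coef(fit)) - oracle_clogit_grid(d)), 1e-3)
  }
})
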