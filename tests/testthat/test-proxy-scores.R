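test_that("logit transform matches closed form and clips at the boundary", {
  expect_equal(logit_transform(0.5), 0)
  expect_equal(logit_transform(0.88), log(0.88 / 0.12), tolerance = 1e-12)
  expect_equal(logit_transform(0.88), 1.9924, tolerance = 1e-4)
  expect_equal(logit_transform(0, eps = 1e-6), log(1e-6 / (1 - 1e-6)),
               tolerance = 1e-12)
  expect_equal(logit_transform(0, eps = 1e-6), -13.8155, tolerance = 1e-4)
  expect_error(logit_transform(0.5, eps = 0.7), "eps")
  expect_error(logit_transform(1.2), "outside")
  # strictly increasing on the clipped range
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(logit_transform(b)) > 0))
  expect_true(is.na(logit_transform(NA_real_)))
})

test_that("mdNLR divides neutrophil by pan-lymphocyte betas pairwise", {
  b <- matrix(c(0.4, 0.4), 1, dimnames = list("s1", c("n1", "l1")))
  expect_equal(unname(compute_mdnlr(b, "n1", "l1")[1, 1]), 1.0)

  b2 <- matrix(c(0.56, 0.36), 1,
               dimnames = list("s1", c("cg09993145", "cg04552418")))
  expect_equal(unname(compute_mdnlr(b2, "cg09993145", "cg04552418")[1, 1]),
               0.56 / 0.36, tolerance = 1e-12)
  expect_equal(unname(compute_mdnlr(b2, "cg09993145", "cg04552418")[1, 1]),
               1.5556, tolerance = 1e-4)
})

test_that("three neutrophil and three lymphocyte probes give nine scores", {
  set.seed(1)
  b <- matrix(runif(5 * 6, 0.2, 0.8), 5,
              dimnames = list(paste0("s", 1:5),
                              c("n1", "n2", "n3", "l1", "l2", "l3")))
  md <- compute_mdnlr(b, c("n1", "n2", "n3"), c("l1", "l2", "l3"))
  expect_equal(ncol(md), 9L)
  expect_equal(colnames(md)[1], "n1.l1")
  expect_true(all(is.finite(md) & md > 0))
  expect_error(compute_mdnlr(b, c("n1", "nope"), "l1"), "nope")
})

test_that("mdNLR propagates missing betas without dropping samples", {
  b <- matrix(c(0.5, NA, 0.25, 0.5), 2,
              dimnames = list(c("s1", "s2"), c("n1", "l1")))
  md <- compute_mdnlr(b, "n1", "l1")
  expect_equal(nrow(md), 2L)
  expect_equal(unname(md["s1", 1]), 2)
  expect_true(is.na(md["s2", 1]))
})

test_that("mdNLR is scale-consistent in its inputs", {
  b <- matrix(c(0.3, 0.2), 1, dimnames = list("s", c("n", "l")))
  for (cc in c(0.5, 1.7, 3)) {
    b2 <- b * cc
    expect_equal(unname(compute_mdnlr(b2, "n", "l")[1, 1]),
                 unname(compute_mdnlr(b, "n", "l")[1, 1]),
                 tolerance = 1e-12)
  }
})

test_that("unmethylation proxies are exact complements, keep NAs, and are monotone", {
  ref <- make_binary_ref()
  panel <- build_panel(ref)
  pr <- panel$probe_id[panel$orientation == "target-unmethylated"]
  b <- matrix(runif(3 * length(pr)), 3, dimnames = list(paste0("s", 1:3), pr))
  b[2, 1] <- NA
  prox <- unmethylation_ratio_panel(b, panel)
  expect_equal(prox$unmeth, 1 - prox$beta)
  expect_true("s2" %in% prox$sample_id)
  expect_true(any(is.na(prox$unmeth[prox$sample_id == "s2"])))
  # monotone: larger beta => smaller unmeth, any pair of samples
  i <- order(b[, 2])
  expect_equal(order(prox$unmeth[prox$probe_id == colnames(b)[2]],
                     decreasing = TRUE)[seq_along(i)], i)
})

test_that("NK-to-neutrophil ratio is the ratio of unmethylation proxies", {
  b <- matrix(c(0.3, 0.3), 1, dimnames = list("s", c("nk", "nu")))
  expect_equal(unname(nk_neutrophil_ratio(b, "nk", "nu")[1, 1]), 1.0)
  b2 <- matrix(c(0.2, 0.6), 1, dimnames = list("s", c("nk", "nu")))
  expect_equal(unname(nk_neutrophil_ratio(b2, "nk", "nu")[1, 1]), 2.0)
})

test_that("NK:neutrophil ratio is higher in controls on the default generator", {
  ref <- simulate_reference(n_probes = 100, seed = 21)
  co <- simulate_cohort(ref, n_pairs = 150, seed = 22)
  panel <- build_panel(ref)
  sets <- isus_sets(panel)
  r <- nk_neutrophil_ratio(co$betas, sets$NK, sets$Neu)
  m_case <- colMeans(r[co$sheet$status == "case", , drop = FALSE])
  m_ctrl <- colMeans(r[co$sheet$status == "control", , drop = FALSE])
  expect_true(all(m_ctrl > m_case))
})

test_that("each mdNLR tracks the true neutrophil-to-lymphoid fraction ratio", {
  ref <- simulate_reference(n_probes = 100, seed = 31)
  co <- simulate_cohort(ref, n_pairs = 100, seed = 32)  # 200 samples
  panel <- build_panel(ref)
  md <- compute_mdnlr(co$betas, panel_probes(panel, "neutrophil"),
                      panel_probes(panel, "pan-lymphocyte"))
  tru <- co$truth$Neu / (co$truth$NK + co$truth$TCD4 + co$truth$TCD8 +
                           co$truth$B)
  rhos <- apply(md, 2L, function(s) spearman_rho(s, tru)$rho)
  expect_true(all(rhos > 0.8))
})
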