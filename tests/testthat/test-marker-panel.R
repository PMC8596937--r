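test_that("specificity margin follows the min-vs-max gap definition", {
  types <- LEUK7
  v <- rep(0.95, 7); names(v) <- types; v["NK"] <- 0.05
  expect_equal(specificity_margin(v, "NK", "target-unmethylated"), 0.90)

  flat <- rep(0.5, 7); names(flat) <- types
  expect_equal(specificity_margin(flat, "NK", "target-unmethylated"), 0)

  v2 <- c(Neu = 0.9, NK = 0.1, TCD4 = 0.2, TCD8 = 0.15, Treg = 0.1,
          Mono = 0.1, B = 0.12)
  expect_equal(specificity_margin(v2, "Neu", "target-methylated"),
               0.9 - 0.2)
})

test_that("specificity margin rejects bad input naming the probe", {
  v <- c(NK = 0.1, Neu = 0.9)
  expect_error(specificity_margin(v, character(0)), "empty target")
  expect_error(specificity_margin(v, "Mono", probe_id = "cg123"), "cg123")
  v2 <- c(NK = NA, Neu = 0.9)
  expect_error(specificity_margin(v2, "NK", probe_id = "cgX"), "cgX")
})

test_that("idealized binary reference yields the full 21 + 3 + 3 panel", {
  ref <- make_binary_ref(k = 3, n_opposing = 3)
  isus <- select_isus(ref, k_per_type = 3)
  expect_equal(nrow(isus), 21L)
  expect_equal(as.integer(table(isus$target)), rep(3L, 7L))
  expect_true(all(isus$orientation == "target-unmethylated"))
  expect_true(all(startsWith(isus$probe_id, "isus_")))

  opp <- select_opposing_markers(ref, k = 3)
  expect_equal(sum(opp$target == "neutrophil"), 3L)
  expect_equal(sum(opp$target == "pan-lymphocyte"), 3L)
  expect_true(all(grepl("^opp_neu", opp$probe_id[opp$target == "neutrophil"])))
  expect_true(all(grepl("^opp_lym",
                        opp$probe_id[opp$target == "pan-lymphocyte"])))
})

test_that("uninformative reference yields an empty panel with warnings", {
  ref <- matrix(0.5, 20, 7, dimnames = list(sprintf("cg%03d", 1:20), LEUK7))
  expect_warning(isus <- select_isus(ref), "only 0 of 3")
  expect_equal(nrow(isus), 0L)
  expect_length(attr(isus, "selection_warnings"), 7L)
})

test_that("candidates are ranked by margin and capped at k", {
  ref <- make_binary_ref(k = 0, n_opposing = 0, n_background = 2)
  # two NK candidates with margins 0.8 and 0.6
  extra <- rbind(a_cand1 = c(NK = 0.1, TCD4 = 0.9, TCD8 = 0.9, Treg = 0.9,
                             Mono = 0.9, Neu = 0.9, B = 0.9),
                 b_cand2 = c(NK = 0.1, TCD4 = 0.7, TCD8 = 0.9, Treg = 0.9,
                             Mono = 0.9, Neu = 0.9, B = 0.9))
  ref2 <- rbind(ref[, LEUK7], extra[, LEUK7])
  suppressWarnings(top1 <- select_isus(ref2, k_per_type = 1))
  nk <- top1[top1$target == "NK", ]
  expect_equal(nk$probe_id, "a_cand1")
  expect_equal(nk$margin, 0.8)

  suppressWarnings(top2 <- select_isus(ref2, k_per_type = 2))
  nk2 <- top2[top2$target == "NK", ]
  expect_equal(nk2$margin, c(0.8, 0.6))  # descending
})

test_that("opposing selection honours the neutral (monocyte) constraint", {
  ref <- make_binary_ref(k = 0, n_opposing = 2, n_background = 2)
  bad <- c(NK = 0.05, TCD4 = 0.05, TCD8 = 0.05, Treg = 0.05,
           Mono = 0.9, Neu = 0.9, B = 0.05)  # methylated in Neu AND Mono
  ref2 <- rbind(ref[, LEUK7], neu_mono = bad[LEUK7])
  suppressWarnings(opp <- select_opposing_markers(ref2, k = 5))
  expect_false("neu_mono" %in% opp$probe_id)
})

test_that("opposing sets are returned sorted by descending margin", {
  ref <- make_binary_ref(k = 0, n_opposing = 0, n_background = 2)
  m1 <- c(NK = 0.2, TCD4 = 0.2, TCD8 = 0.2, Treg = 0.2, Mono = 0.2,
          Neu = 0.7, B = 0.2)                       # margin 0.5
  m2 <- c(NK = 0.1, TCD4 = 0.1, TCD8 = 0.1, Treg = 0.1, Mono = 0.1,
          Neu = 0.8, B = 0.1)                       # margin 0.7
  ref2 <- rbind(ref[, LEUK7], p_lo = m1[LEUK7], p_hi = m2[LEUK7])
  suppressWarnings(opp <- select_opposing_markers(ref2, k = 2,
                                                  low_thr = 0.3,
                                                  high_thr = 0.6))
  neu <- opp[opp$target == "neutrophil", ]
  expect_equal(neu$probe_id, c("p_hi", "p_lo"))
  expect_equal(neu$margin, c(0.7, 0.5))
})

test_that("selection is invariant to probe and cell-type order", {
  ref <- simulate_reference(n_probes = 80, seed = 11)
  p1 <- build_panel(ref)
  p2 <- build_panel(ref[sample(nrow(ref)), rev(colnames(ref))])
  o <- function(p) p[order(p$target, p$probe_id),
                     c("probe_id", "target", "margin")]
  expect_equal(o(as.data.frame(p1)), o(as.data.frame(p2)),
               ignore_attr = TRUE)
})

test_that("loosening thresholds never shrinks the candidate set", {
  ref <- simulate_reference(n_probes = 120, seed = 3)
  n_at <- function(lo, hi) {
    nrow(suppressWarnings(select_isus(ref, k_per_type = 1000,
                                      low_thr = lo, high_thr = hi)))
  }
  expect_gte(n_at(0.35, 0.7), n_at(0.3, 0.7))   # raising low_thr
  expect_gte(n_at(0.3, 0.65), n_at(0.3, 0.7))   # lowering high_thr
  expect_gte(n_at(0.35, 0.65), n_at(0.3, 0.7))
})

test_that("planted markers are recovered exactly from a simulated reference", {
  ref <- simulate_reference(n_probes = 100, seed = 7)
  planted <- attr(ref, "planted")
  panel <- build_panel(ref)
  for (tg in unique(planted$target)) {
    expect_setequal(panel_probes(panel, tg),
                    planted$probe_id[planted$target == tg])
  }
})

test_that("no probe is listed under two subtypes", {
  # a probe low in two subtypes is eligible for neither (each blocks the
  # other's all-others-methylated requirement), so panels stay disjoint
  ref <- make_binary_ref(k = 1, n_opposing = 0, n_background = 1)
  amb <- c(NK = 0.05, TCD4 = 0.25, TCD8 = 0.9, Treg = 0.9, Mono = 0.9,
           Neu = 0.9, B = 0.9)
  ref2 <- rbind(ref[, LEUK7], amb = amb[LEUK7])
  suppressWarnings(
    isus <- select_isus(ref2, k_per_type = 3, low_thr = 0.3, high_thr = 0.7))
  expect_false("amb" %in% isus$probe_id)
  expect_false(anyDuplicated(isus$probe_id) > 0)
  ref3 <- simulate_reference(n_probes = 120, seed = 5)
  panel <- build_panel(ref3)
  expect_false(anyDuplicated(
    panel$probe_id[panel$orientation == "target-unmethylated"]) > 0)
})

test_that("probes with missing reference betas are excluded", {
  ref <- make_binary_ref(k = 2, n_opposing = 2, n_background = 2)
  ref["isus_NK_1", "Mono"] <- NA
  suppressWarnings(isus <- select_isus(ref, k_per_type = 2))
  expect_false("isus_NK_1" %in% isus$probe_id)
  expect_true("isus_NK_2" %in% isus$probe_id)
})
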