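# Fixture builders used across test files; everything is generated in code.

LEUK7 <- c("NK", "TCD4", "TCD8", "Treg", "Mono", "Neu", "B")

# idealized binary reference: k perfectly specific unmethylated probes per
# subtype, n_opposing probes per opposing set, plus flat background probes
make_binary_ref <- function(k = 3, n_opposing = 3, n_background = 10,
                            lo = 0.05, hi = 0.95) {
  types <- LEUK7
  rows <- list()
  ids <- character()
  for (tp in types) for (i in seq_len(k)) {
    v <- rep(hi, length(types)); names(v) <- types
    v[tp] <- lo
    rows[[length(rows) + 1L]] <- v
    ids <- c(ids, sprintf("isus_%s_%d", tp, i))
  }
  for (i in seq_len(n_opposing)) {
    v <- rep(lo, length(types)); names(v) <- types
    v["Neu"] <- hi
    rows[[length(rows) + 1L]] <- v
    ids <- c(ids, sprintf("opp_neu_%d", i))
  }
  for (i in seq_len(n_opposing)) {
    v <- rep(lo, length(types)); names(v) <- types
    v[c("NK", "TCD4", "TCD8", "Treg", "B")] <- hi
    rows[[length(rows) + 1L]] <- v
    ids <- c(ids, sprintf("opp_lym_%d", i))
  }
  for (i in seq_len(n_background)) {
    v <- rep(0.5, length(types)); names(v) <- types
    rows[[length(rows) + 1L]] <- v
    ids <- c(ids, sprintf("bg_%d", i))
  }
  ref <- do.call(rbind, rows)
  rownames(ref) <- ids
  ref
}

# matched cohort whose single-exposure within-pair differences equal d:
# case score d_i, control score 0, identical ages
make_diff_cohort <- function(d, name = "x") {
  n <- length(d)
  sheet <- data.frame(
    sample_id = c(sprintf("ca%03d", 1:n), sprintf("co%03d", 1:n)),
    pair_id = rep(sprintf("P%03d", 1:n), 2L),
    status = rep(c("case", "control"), each = n),
    age = 50, stringsAsFactors = FALSE)
  scores <- matrix(c(d, rep(0, n)), ncol = 1L,
                   dimnames = list(sheet$sample_id, name))
  list(sheet = as_matched_cohort(sheet), scores = scores)
}

# matched cohort with arbitrary per-sample score matrices (pairs aligned)
make_score_cohort <- function(Xcase, Xctrl) {
  n <- nrow(Xcase)
  sheet <- data.frame(
    sample_id = c(sprintf("ca%03d", 1:n), sprintf("co%03d", 1:n)),
    pair_id = rep(sprintf("P%03d", 1:n), 2L),
    status = rep(c("case", "control"), each = n),
    age = 50, stringsAsFactors = FALSE)
  scores <- rbind(Xcase, Xctrl)
  rownames(scores) <- sheet$sample_id
  list(sheet = as_matched_cohort(sheet), scores = scores)
}
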