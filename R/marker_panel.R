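#' Specificity margin of a CpG probe for a set of target cell types
#'
#' Quantifies how cleanly a probe separates a target cell-type group from the
#' remaining cell types in a reference methylome. For a
#' \code{"target-unmethylated"} probe the margin is the smallest non-target
#' beta minus the largest target beta; for \code{"target-methylated"} it is
#' the smallest target beta minus the largest non-target beta. An ideal
#' binary profile (target 0, others 1) has margin 1; a probe with no
#' specificity has margin <= 0.
#'
#' @param betas named numeric vector of mean beta values, one per cell type.
#' @param targets character vector of target cell-type labels (non-empty,
#'   all present in \code{names(betas)}).
#' @param orientation \code{"target-unmethylated"} or
#'   \code{"target-methylated"}.
#' @param non_targets optional character vector restricting which cell types
#'   count as the opposing group; defaults to all remaining types.
#' @param probe_id optional probe identifier used in error messages.
#' @return a single numeric margin (may be negative).
#' @export
specificity_margin <- function(betas, targets,
                               orientation = c("target-unmethylated",
                                               "target-methylated"),
                               non_targets = NULL, probe_id = NULL) {
  orientation <- match.arg(orientation)
  id <- if (is.null(probe_id)) "probe" else probe_id
  if (length(targets) == 0L) stop("empty target set for ", id)
  if (is.null(names(betas))) stop("betas must be named by cell type (", id, ")")
  if (!all(targets %in% names(betas)))
    stop("missing beta for target cell type(s) ",
         paste(setdiff(targets, names(betas)), collapse = ", "),
         " at ", id)
  if (is.null(non_targets)) non_targets <- setdiff(names(betas), targets)
  if (length(non_targets) == 0L) stop("no non-target cell types for ", id)
  if (!all(non_targets %in% names(betas)))
    stop("missing beta for cell type(s) ",
         paste(setdiff(non_targets, names(betas)), collapse = ", "),
         " at ", id)
  bt <- betas[targets]
  bo <- betas[non_targets]
  if (anyNA(bt) || anyNA(bo)) stop("missing beta value at ", id)
  if (orientation == "target-unmethylated") {
    unname(min(bo) - max(bt))
  } else {
    unname(min(bt) - max(bo))
  }
}

# Internal: rank candidate rows by margin (desc), probe_id (asc) for
# deterministic output.
.order_markers <- function(df) {
  df[order(-df$margin, df$probe_id), , drop = FALSE]
}

.new_marker_panel <- function(df, params, warnings = character()) {
  rownames(df) <- NULL
  structure(df, class = c("marker_panel", "data.frame"),
            params = params, selection_warnings = warnings)
}

#' Select immune-cell-specific unmethylated sites (ISUS)
#'
#' For each cell type in the reference, keeps probes that are unmethylated in
#' that type (beta <= \code{low_thr}) and methylated in every other type
#' (beta >= \code{high_thr}), ranks them by specificity margin and returns the
#' top \code{k_per_type}. A probe eligible for more than one cell type is
#' assigned to the type where its margin is largest (ties broken by the
#' lexicographically smallest cell-type label). Probes with any missing
#' reference value are excluded before selection. If a cell type yields fewer
#' than \code{k_per_type} candidates the available ones are returned and a
#' warning is recorded on the panel (no error).
#'
#' @param ref numeric matrix of mean beta values, probes x cell types, with
#'   probe ids as rownames and cell-type labels as colnames.
#' @param k_per_type number of markers to keep per cell type.
#' @param low_thr,high_thr unmethylated / methylated beta thresholds,
#'   \code{0 <= low_thr < high_thr <= 1}.
#' @return a \code{marker_panel} data frame with columns \code{probe_id},
#'   \code{target}, \code{orientation}, \code{margin}, sorted within target
#'   by descending margin.
#' @export
select_isus <- function(ref, k_per_type = 3, low_thr = 0.3, high_thr = 0.7) {
  ref <- .validate_reference(ref)
  stopifnot(k_per_type >= 1, low_thr >= 0, high_thr <= 1)
  if (!(low_thr < high_thr)) stop("low_thr must be < high_thr")
  ref <- ref[stats::complete.cases(ref), , drop = FALSE]
  types <- sort(colnames(ref))
  rows <- list()
  for (tp in types) {
    bt <- ref[, tp]
    bo <- ref[, setdiff(colnames(ref), tp), drop = FALSE]
    elig <- bt <= low_thr & apply(bo, 1L, min) >= high_thr
    if (any(elig)) {
      rows[[tp]] <- data.frame(
        probe_id = rownames(ref)[elig],
        target = tp,
        orientation = "target-unmethylated",
        margin = apply(bo[elig, , drop = FALSE], 1L, min) - bt[elig],
        stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(), target = character(),
               orientation = character(), margin = numeric(),
               stringsAsFactors = FALSE)
  # resolve probes eligible under several subtypes: largest margin wins,
  # ties to the lexicographically smallest cell-type label
  if (nrow(cand)) {
    cand <- cand[order(cand$probe_id, -cand$margin, cand$target), ,
                 drop = FALSE]
    cand <- cand[!duplicated(cand$probe_id), , drop = FALSE]
  }
  out <- list(); warn <- character()
  for (tp in types) {
    ci <- .order_markers(cand[cand$target == tp, , drop = FALSE])
    if (nrow(ci) < k_per_type)
      warn <- c(warn, sprintf("cell type %s: only %d of %d requested ISUS found",
                              tp, nrow(ci), k_per_type))
    out[[tp]] <- utils::head(ci, k_per_type)
  }
  panel <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (length(warn)) warning(paste(warn, collapse = "; "), call. = FALSE)
  .new_marker_panel(panel,
                    params = list(op = "select_isus", k_per_type = k_per_type,
                                  low_thr = low_thr, high_thr = high_thr),
                    warnings = warn)
}

#' Select opposing neutrophil- and pan-lymphocyte-specific methylated sites
#'
#' Finds CpGs methylated in neutrophils but unmethylated in pan-lymphocytes
#' (NK, CD4+ T, CD8+ T, B) and monocytes, and conversely CpGs methylated in
#' all pan-lymphocyte types but unmethylated in neutrophils and monocytes.
#' These two opposing sets drive the methylation-derived
#' neutrophil-to-lymphocyte ratio (mdNLR). Margins are computed over the
#' involved cell types only; columns outside \code{group_a}, \code{group_b}
#' and \code{neutral} (e.g. Treg) are unconstrained.
#'
#' @inheritParams select_isus
#' @param group_a cell types that must be methylated in the first set
#'   (default neutrophils).
#' @param group_b the pan-lymphocyte group.
#' @param neutral cell types required to be unmethylated in both sets.
#' @param k markers to keep per set.
#' @return a \code{marker_panel} data frame with targets
#'   \code{"neutrophil"} and \code{"pan-lymphocyte"}.
#' @export
select_opposing_markers <- function(ref, group_a = "Neu",
                                    group_b = c("NK", "TCD4", "TCD8", "B"),
                                    neutral = "Mono", k = 3,
                                    low_thr = 0.3, high_thr = 0.7) {
  ref <- .validate_reference(ref)
  stopifnot(k >= 1, low_thr >= 0, high_thr <= 1, low_thr < high_thr)
  groups <- list(group_a, group_b, neutral)
  if (anyDuplicated(unlist(groups))) stop("group_a, group_b and neutral must be disjoint")
  if (!all(unlist(groups) %in% colnames(ref)))
    stop("cell type(s) absent from reference: ",
         paste(setdiff(unlist(groups), colnames(ref)), collapse = ", "))
  ref <- ref[stats::complete.cases(ref), , drop = FALSE]

  pick <- function(hi, lo, label) {
    H <- ref[, hi, drop = FALSE]; L <- ref[, lo, drop = FALSE]
    elig <- apply(H, 1L, min) >= high_thr & apply(L, 1L, max) <= low_thr
    if (!any(elig))
      return(data.frame(probe_id = character(), target = character(),
                        orientation = character(), margin = numeric(),
                        stringsAsFactors = FALSE))
    df <- data.frame(
      probe_id = rownames(ref)[elig],
      target = label,
      orientation = "target-methylated",
      margin = apply(H[elig, , drop = FALSE], 1L, min) -
        apply(L[elig, , drop = FALSE], 1L, max),
      stringsAsFactors = FALSE)
    .order_markers(df)
  }
  neu <- pick(group_a, c(group_b, neutral), "neutrophil")
  lym <- pick(group_b, c(group_a, neutral), "pan-lymphocyte")
  warn <- character()
  if (nrow(neu) < k) warn <- c(warn, sprintf(
    "neutrophil set: only %d of %d requested markers found", nrow(neu), k))
  if (nrow(lym) < k) warn <- c(warn, sprintf(
    "pan-lymphocyte set: only %d of %d requested markers found", nrow(lym), k))
  panel <- rbind(utils::head(neu, k), utils::head(lym, k))
  if (length(warn)) warning(paste(warn, collapse = "; "), call. = FALSE)
  .new_marker_panel(panel,
                    params = list(op = "select_opposing_markers", k = k,
                                  low_thr = low_thr, high_thr = high_thr,
                                  group_a = group_a, group_b = group_b,
                                  neutral = neutral),
                    warnings = warn)
}

#' Build the complete marker panel (ISUS plus opposing mdNLR sets)
#'
#' Convenience wrapper running \code{\link{select_isus}} and
#' \code{\link{select_opposing_markers}} on the same reference and stacking
#' the results into one panel.
#'
#' @inheritParams select_isus
#' @inheritParams select_opposing_markers
#' @export
build_panel <- function(ref, k_per_type = 3, k_opposing = 3,
                        low_thr = 0.3, high_thr = 0.7,
                        group_a = "Neu", group_b = c("NK", "TCD4", "TCD8", "B"),
                        neutral = "Mono") {
  isus <- select_isus(ref, k_per_type, low_thr, high_thr)
  opp <- select_opposing_markers(ref, group_a, group_b, neutral,
                                 k_opposing, low_thr, high_thr)
  .new_marker_panel(
    rbind(as.data.frame(isus), as.data.frame(opp)),
    params = list(isus = attr(isus, "params"), opposing = attr(opp, "params")),
    warnings = c(attr(isus, "selection_warnings"),
                 attr(opp, "selection_warnings")))
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", nrow(x), "probes\n")
  tab <- table(x$target)
  for (tp in names(tab)) cat(sprintf("  %-15s %d\n", tp, tab[[tp]]))
  w <- attr(x, "selection_warnings")
  if (length(w)) cat("Selection warnings:", length(w), "\n")
  invisible(x)
}

#' Probes of a panel for one target
#'
#' @param panel a \code{marker_panel}.
#' @param target a cell type label, \code{"neutrophil"} or
#'   \code{"pan-lymphocyte"}.
#' @return character vector of probe ids (descending margin order).
#' @export
panel_probes <- function(panel, target) {
  panel$probe_id[panel$target == target]
}

#' ISUS probes grouped by cell type
#'
#' @param panel a \code{marker_panel}.
#' @return named list mapping each cell type with
#'   \code{"target-unmethylated"} markers to its probe ids.
#' @export
isus_sets <- function(panel) {
  p <- panel[panel$orientation == "target-unmethylated", , drop = FALSE]
  split(p$probe_id, p$target)
}
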