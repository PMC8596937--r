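# File interfaces: plain TSV/CSV beta matrices, sample sheets, marker
# panels and result tables with provenance headers. Delimiter follows the
# file extension (.csv -> comma, anything else -> tab).

.delim_for <- function(path) if (grepl("\\.csv$", path, TRUE)) "," else "\t"

#' Validate a matched case-control sample sheet
#'
#' Checks that every pair id carries exactly one case and one control and
#' that within-pair age gaps respect the matching tolerance. Violations are
#' reported with the offending pair ids; age-gap violations are errors under
#' \code{age_policy = "error"} and warnings under \code{"warn"}.
#'
#' @param sheet data frame with columns \code{sample_id}, \code{pair_id},
#'   \code{status} ("case"/"control") and optionally \code{age} plus
#'   covariates.
#' @param age_tol matching tolerance in years (recorded on the object).
#' @param age_policy what to do when a pair exceeds the tolerance.
#' @return the sheet, classed \code{matched_cohort}, with the tolerance in
#'   \code{attr(, "age_tol")}.
#' @export
as_matched_cohort <- function(sheet, age_tol = 1,
                              age_policy = c("error", "warn")) {
  age_policy <- match.arg(age_policy)
  need <- c("sample_id", "pair_id", "status")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  if (!all(sheet$status %in% c("case", "control")))
    stop("status must be 'case' or 'control' (rows ",
         paste(which(!sheet$status %in% c("case", "control")),
               collapse = ", "), ")")
  tab <- table(sheet$pair_id, sheet$status)
  bad <- rownames(tab)[tab[, "case"] != 1L | tab[, "control"] != 1L]
  if (length(bad))
    stop("pair(s) without exactly one case and one control: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if ("age" %in% names(sheet) && !anyNA(sheet$age)) {
    ages <- split(sheet$age, sheet$pair_id)
    gap <- vapply(ages, function(a) abs(diff(range(a))), 0)
    over <- names(gap)[gap > age_tol + 1e-9]
    if (length(over)) {
      msg <- paste0("age gap exceeds +/-", age_tol, " years for pair(s): ",
                    paste(utils::head(over, 10), collapse = ", "))
      if (age_policy == "error") stop(msg) else warning(msg, call. = FALSE)
    }
  }
  structure(as.data.frame(sheet), class = c("matched_cohort", "data.frame"),
            age_tol = age_tol)
}

#' Read a beta matrix from TSV/CSV
#'
#' Expects probes as rows: a \code{probe_id} first column and one numeric
#' column per sample. Values must lie in [0, 1]; \code{NA} and empty cells
#' become missing. Returns the matrix transposed to the package's samples x
#' probes orientation.
#'
#' @param path file path (.csv comma-separated, otherwise tab).
#' @return samples x probes numeric matrix.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path), quote = "",
                          check.names = FALSE, comment.char = "#",
                          na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "probe_id")
    stop("first column must be 'probe_id' in ", path)
  probes <- df$probe_id
  if (anyDuplicated(probes))
    stop("duplicate probe ids in ", path, ": ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1L]))
    stop("duplicate sample ids in ", path)
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(M), nrow(M)))) &
                   !is.na(M), arr.ind = TRUE)[1L, ]
    stop("non-numeric beta at probe ", probes[bad[1L]], ", sample ",
         colnames(M)[bad[2L]], " in ", path)
  }
  out_of_range <- which(M < 0 | M > 1, arr.ind = TRUE)
  if (nrow(out_of_range))
    stop("beta outside [0, 1] at probe ", probes[out_of_range[1L, 1L]],
         ", sample ", colnames(M)[out_of_range[1L, 2L]], " in ", path)
  rownames(M) <- probes
  t(M)
}

#' Write a beta matrix as probes x samples TSV/CSV
#'
#' @param betas samples x probes matrix.
#' @param path output path.
#' @export
write_beta_matrix <- function(betas, path) {
  M <- t(as.matrix(betas))
  df <- data.frame(probe_id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference methylome from TSV/CSV
#'
#' \code{probe_id} first column, one column per cell type; optional
#' \code{chrom}/\code{pos} columns (1-based, GRCh37) are carried as an
#' attribute.
#'
#' @param path file path.
#' @return probes x cell types matrix, optionally with
#'   \code{attr(, "coords")}.
#' @export
read_reference <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path), quote = "",
                          check.names = FALSE, comment.char = "#",
                          na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  ref <- .validate_reference(df)
  if (all(c("chrom", "pos") %in% names(df)))
    attr(ref, "coords") <- df[, c("probe_id", "chrom", "pos")]
  ref
}

#' Write a reference methylome to TSV/CSV
#'
#' @param ref probes x cell types matrix.
#' @param path output path.
#' @export
write_reference <- function(ref, path) {
  df <- data.frame(probe_id = rownames(ref), as.data.frame(ref),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a matched sample sheet from CSV/TSV
#'
#' @inheritParams as_matched_cohort
#' @param path file path.
#' @export
read_sample_sheet <- function(path, age_tol = 1,
                              age_policy = c("error", "warn")) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path), quote = "",
                          comment.char = "#", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  as_matched_cohort(df, age_tol = age_tol, age_policy = age_policy)
}

#' Write a marker panel (TSV with provenance header)
#'
#' @param panel a \code{marker_panel}.
#' @param path output path.
#' @param provenance optional named list written as \code{# key: value}
#'   header lines alongside the selection parameters.
#' @export
write_panel <- function(panel, path, provenance = list()) {
  prov <- c(list(writer = paste0("immunomethyl ",
                                 as.character(utils::packageVersion("immunomethyl")))),
            provenance,
            list(params = .flatten_params(attr(panel, "params"))))
  write_results(as.data.frame(panel), path, provenance = prov)
}

#' Read a marker panel written by \code{\link{write_panel}}
#'
#' Also accepts any TSV/CSV with columns \code{probe_id}, \code{target},
#' \code{orientation} and optionally \code{margin}.
#'
#' @param path file path.
#' @return a \code{marker_panel} data frame.
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path), quote = "",
                          comment.char = "#", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "target", "orientation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$orientation %in% c("target-unmethylated",
                                 "target-methylated")))
    stop("invalid orientation values in ", path)
  if (anyDuplicated(df[c("probe_id", "target")]))
    stop("duplicate probe/target rows in ", path)
  if (!"margin" %in% names(df)) df$margin <- NA_real_
  .new_marker_panel(df, params = list(source = path))
}

.flatten_params <- function(p) {
  if (is.null(p)) return("")
  paste(vapply(names(p), function(k) {
    v <- p[[k]]
    paste0(k, "=", if (is.list(v)) .flatten_params(v)
           else paste(v, collapse = "+"))
  }, ""), collapse = "; ")
}

#' Write a result table with a provenance header
#'
#' Deterministic column order (as given); \code{# key: value} comment lines
#' record the package version, timestamp-free run parameters and any seeds
#' so identical runs produce byte-identical files.
#'
#' @param results data frame.
#' @param path output path (.csv comma-separated, otherwise tab).
#' @param provenance named list of scalar values for the header.
#' @export
write_results <- function(results, path, provenance = list()) {
  prov <- c(list(package = paste0("immunomethyl ",
                                  as.character(utils::packageVersion("immunomethyl")))),
            provenance)
  hdr <- vapply(names(prov), function(k)
    sprintf("# %s: %s", k, paste(format(prov[[k]], trim = TRUE),
                                 collapse = " ")), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(results, con, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{\link{write_results}}
#'
#' @param path file path.
#' @return data frame with the provenance header in
#'   \code{attr(, "provenance")}.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path), quote = "",
                          comment.char = "#", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  attr(df, "provenance") <- sub("^# ", "", hdr)
  df
}

#' The packaged TNBC blood marker panel
#'
#' A curated panel for blood immunomethylomics of triple-negative breast
#' cancer: 21 immune-cell-specific unmethylated sites (three per leukocyte
#' subtype) plus three neutrophil-specific and three pan-lymphocyte-specific
#' methylated CpGs, with GRCh37 coordinates and gene annotations. The six
#' opposing-set rows also carry the published case/control mean beta values
#' used for mdNLR illustration.
#'
#' @return a \code{marker_panel} data frame with extra columns
#'   \code{chrom}, \code{pos}, \code{gene}, \code{genic_region},
#'   \code{beta_cases}, \code{beta_controls}.
#' @export
tnbc_marker_panel <- function() {
  path <- system.file("extdata", "tnbc_blood_panel.tsv",
                      package = "immunomethyl", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  .new_marker_panel(df, params = list(source = "packaged TNBC blood panel"))
}
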