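# Internal helpers shared across modules.

# Run expr with a local RNG state when seed is given; the caller's RNG
# stream is restored afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

# Dirichlet draws via normalised gamma variates: n x length(alpha) matrix.
.rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  out <- g / rowSums(g)
  colnames(out) <- names(alpha)
  out
}

# Validate a reference methylome / signature-style matrix: numeric,
# probes x cell types, unique ids, betas in [0, 1] (NA allowed). Accepts a
# data frame with a probe_id column.
.validate_reference <- function(ref) {
  if (is.data.frame(ref)) {
    if ("probe_id" %in% names(ref)) {
      rn <- ref$probe_id
      ref <- as.matrix(ref[setdiff(names(ref),
                                   c("probe_id", "chrom", "pos"))])
      rownames(ref) <- rn
    } else ref <- as.matrix(ref)
  }
  if (!is.numeric(ref)) stop("reference betas must be numeric")
  if (is.null(rownames(ref)) || is.null(colnames(ref)))
    stop("reference needs probe ids (rownames) and cell types (colnames)")
  if (anyDuplicated(rownames(ref)))
    stop("duplicate probe ids in reference")
  if (anyDuplicated(colnames(ref)))
    stop("duplicate cell-type columns in reference")
  rng <- range(ref, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("reference beta values outside [0, 1]")
  ref
}
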