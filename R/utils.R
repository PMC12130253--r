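#' @keywords internal
"_PACKAGE"

# Stage-specific substream seed derived from a master seed. Keeps every
# generator stage independently reproducible while a single master seed
# drives the whole simulation. Result stays inside 32-bit integer range.
substream_seed <- function(seed, stage) {
  offsets <- c(genotypes = 101L, fluxes = 211L, survival = 307L,
               covariates = 401L, pcs = 503L)
  if (!stage %in% names(offsets)) stop("unknown substream stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

check_corr_matrix <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (max(abs(m - t(m))) > 1e-10)
    stop(what, " must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-10)
    stop(what, " must have unit diagonal")
  # chol() is the PSD check; a failure here is a configuration error
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch))
    stop(what, " is not positive semi-definite")
  ch
}

# Draw n rows from N(0, Sigma) given the upper-triangular Cholesky factor.
rmvn_chol <- function(n, ch) {
  m <- ncol(ch)
  matrix(stats::rnorm(n * m), n, m) %*% ch
}
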