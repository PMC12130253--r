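#' Configuration for a synthetic cohort
#'
#' Bundles everything needed to simulate a genotyped cohort with
#' genetically driven organ-specific reaction fluxes and a survival
#' phenotype generated from a stratified Weibull proportional-hazards
#' model whose linear predictor contains first-order, second-order and
#' SNP-by-flux interaction terms.
#'
#' The generative hazard for individual \eqn{j} in stratum \eqn{s} is
#' \deqn{h_j(t) = h_{0,s}(t) \exp(\eta_j)}
#' with Weibull baseline \eqn{h_{0,s}(t) = (k/\lambda)(t/\lambda)^{k-1}}
#' and, summed over the configured SNP-reaction pairs,
#' \deqn{\eta_j = \sum \beta_{SNP} SNP + \beta_{Flux} Flux +
#'   \beta_{SNP^2} SNP^2 + \beta_{Flux^2} Flux^2 +
#'   \beta_{SNP:Flux} SNP \cdot Flux + \sum \beta_{PC} PC.}
#'
#' @param n_individuals positive integer, cohort size.
#' @param snps data.frame with columns `name` and `maf` (minor/risk allele
#'   frequency, each in (0, 0.5]).
#' @param ld_corr latent haplotype correlation matrix between SNPs
#'   (symmetric PSD, unit diagonal). Controls pairwise dosage LD.
#' @param reactions data.frame with columns `name`, `organ` and optionally
#'   `annotated` (logical; reactions without gene annotation are excluded
#'   from pair testing by the pipeline; default `TRUE`).
#' @param flux_corr named list, one correlation matrix per organ giving the
#'   noise correlation between that organ's reactions; `NULL` for identity.
#' @param eqtl_effects data.frame with columns `snp`, `reaction`, `effect`:
#'   per-dosage shift of the raw flux, in standardized-flux units. `NULL`
#'   for none.
#' @param true_effects data.frame with columns `snp`, `reaction`,
#'   `beta_snp`, `beta_flux`, `beta_snp2`, `beta_flux2`,
#'   `beta_interaction` (log-hazard units). `NULL` for a fully null cohort.
#' @param baseline list with `shape` (Weibull k > 0) and `scale` (Weibull
#'   \eqn{\lambda} > 0, years); each either a scalar or a vector named by
#'   `sex:array` stratum label for stratum-specific baselines.
#' @param censor_age administrative censoring age in years (> 0).
#' @param n_pcs number of simulated genetic principal components.
#' @param pc_effects log-hazard per PC unit, recycled to `n_pcs`.
#' @param cardiometabolic logical; also simulate BMI, systolic blood
#'   pressure, LDL-C, HDL-C and triglycerides for covariate-sensitivity
#'   analyses.
#' @param cardiometabolic_corr scalar in \[0, 1): loading of the first
#'   configured pair's dosage/flux onto the cardiometabolic covariates
#'   (0 = independent).
#' @param seed master integer seed; per-stage substreams are derived from it.
#'
#' @return object of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_individuals,
                       snps,
                       ld_corr = NULL,
                       reactions,
                       flux_corr = NULL,
                       eqtl_effects = NULL,
                       true_effects = NULL,
                       baseline = list(shape = 6, scale = 95),
                       censor_age = 80,
                       n_pcs = 10,
                       pc_effects = 0,
                       cardiometabolic = FALSE,
                       cardiometabolic_corr = 0,
                       seed = 1L) {
  stopifnot(is.numeric(n_individuals), length(n_individuals) == 1,
            n_individuals >= 1)
  snps <- as.data.frame(snps)
  if (!all(c("name", "maf") %in% names(snps)))
    stop("snps needs columns 'name' and 'maf'")
  if (anyDuplicated(snps$name)) stop("duplicated SNP names")
  if (any(snps$maf <= 0 | snps$maf > 0.5))
    stop("MAFs must lie in (0, 0.5]")
  m <- nrow(snps)
  if (is.null(ld_corr)) ld_corr <- diag(m)
  if (nrow(ld_corr) != m) stop("ld_corr dimension does not match snps")
  check_corr_matrix(ld_corr, "ld_corr")

  reactions <- as.data.frame(reactions)
  if (!all(c("name", "organ") %in% names(reactions)))
    stop("reactions needs columns 'name' and 'organ'")
  if (anyDuplicated(reactions$name)) stop("duplicated reaction names")
  if (is.null(reactions$annotated))
    reactions$annotated <- rep(TRUE, nrow(reactions))

  if (!is.null(flux_corr)) {
    if (is.null(names(flux_corr)) || !all(names(flux_corr) %in% reactions$organ))
      stop("flux_corr must be a list named by organ")
    for (org in names(flux_corr)) {
      k <- sum(reactions$organ == org)
      if (nrow(flux_corr[[org]]) != k)
        stop("flux_corr[['", org, "']] dimension does not match its reactions")
      check_corr_matrix(flux_corr[[org]], paste0("flux_corr[['", org, "']]"))
    }
  }

  if (!is.null(eqtl_effects)) {
    eqtl_effects <- as.data.frame(eqtl_effects)
    if (!all(c("snp", "reaction", "effect") %in% names(eqtl_effects)))
      stop("eqtl_effects needs columns 'snp', 'reaction', 'effect'")
    bad <- setdiff(eqtl_effects$snp, snps$name)
    if (length(bad)) stop("eqtl_effects names unknown SNP: ", bad[1])
    bad <- setdiff(eqtl_effects$reaction, reactions$name)
    if (length(bad)) stop("eqtl_effects names unknown reaction: ", bad[1])
  }

  if (!is.null(true_effects)) {
    true_effects <- as.data.frame(true_effects)
    need <- c("snp", "reaction", "beta_snp", "beta_flux", "beta_snp2",
              "beta_flux2", "beta_interaction")
    miss <- setdiff(need, names(true_effects))
    if (length(miss)) stop("true_effects missing column(s): ",
                           paste(miss, collapse = ", "))
    bad <- setdiff(true_effects$snp, snps$name)
    if (length(bad)) stop("true_effects names unknown SNP: ", bad[1])
    bad <- setdiff(true_effects$reaction, reactions$name)
    if (length(bad)) stop("true_effects names unknown reaction: ", bad[1])
  }

  if (any(unlist(baseline[c("shape", "scale")]) <= 0))
    stop("Weibull shape and scale must be positive")
  if (censor_age <= 0) stop("censor_age must be positive")
  n_pcs <- as.integer(n_pcs)
  pc_effects <- rep_len(pc_effects, max(n_pcs, 0L))

  structure(list(
    n_individuals = as.integer(n_individuals),
    snps = snps, ld_corr = ld_corr,
    reactions = reactions, flux_corr = flux_corr,
    eqtl_effects = eqtl_effects, true_effects = true_effects,
    baseline = baseline, censor_age = censor_age,
    n_pcs = n_pcs, pc_effects = pc_effects,
    cardiometabolic = isTRUE(cardiometabolic),
    cardiometabolic_corr = cardiometabolic_corr,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  individuals:", x$n_individuals, "\n")
  cat("  SNPs:", nrow(x$snps), " reactions:", nrow(x$reactions),
      "(", length(unique(x$reactions$organ)), "organ(s) )\n")
  np <- if (is.null(x$true_effects)) 0 else nrow(x$true_effects)
  cat("  pairs with configured effects:", np, "\n")
  cat("  censoring age:", x$censor_age, " PCs:", x$n_pcs,
      " seed:", x$seed, "\n")
  invisible(x)
}
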