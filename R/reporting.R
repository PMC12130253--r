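#' Variant effect sizes per flux quartile
#'
#' Groups individuals into quartiles of a reaction's flux value and
#' estimates the variant (dosage) effect on disease risk within each
#' quartile with a stratified Cox model (genetic PCs as covariates),
#' then fits an inverse-variance weighted trend line of the per-quartile
#' effect sizes on quartile index. A positive trend visualizes
#' amplification; a negative one, buffering.
#'
#' Quartile boundaries sit at the sample quantiles (0.25, 0.5, 0.75);
#' ties are assigned to the lower quartile by rank, so quartile sizes
#' differ by at most one.
#'
#' @param cohort cohort table.
#' @param dosage risk-allele dosage vector.
#' @param flux flux vector with at least 4 distinct values.
#' @param covariates optional extra cohort covariate columns.
#' @param min_events minimum events per quartile (default 10).
#' @return list of class `quartile_profile`: `per_quartile` (data.frame
#'   `quartile`, `beta`, `se`, `n`, `events`), `slope`, `intercept`,
#'   `slope_se`.
#' @export
quartile_variant_effects <- function(cohort, dosage, flux,
                                     covariates = NULL, min_events = 10) {
  n <- nrow(cohort)
  stopifnot(length(dosage) == n, length(flux) == n)
  if (length(unique(flux)) < 4)
    stop("flux needs >= 4 distinct values for quartile binning")
  q <- ceiling(4 * rank(flux, ties.method = "first") / n)
  q[q < 1] <- 1L
  s <- cohort_strata(cohort)
  per <- data.frame(quartile = 1:4, beta = NA_real_, se = NA_real_,
                    n = NA_integer_, events = NA_integer_)
  for (i in 1:4) {
    idx <- which(q == i)
    per$n[i] <- length(idx)
    per$events[i] <- sum(cohort$event[idx])
    if (length(idx) == 0) stop("empty flux quartile ", i)
    if (per$events[i] < min_events)
      stop("quartile ", i, " has fewer than ", min_events, " events")
    X <- cbind(SNP = dosage[idx])
    Z <- cohort_covariates(cohort[idx, , drop = FALSE], covariates)
    if (!is.null(Z)) X <- cbind(X, Z)
    fit <- fit_cox(cohort$age[idx], cohort$event[idx], X, strata = s[idx])
    per$beta[i] <- unname(fit$coef["SNP"])
    per$se[i] <- unname(fit$se["SNP"])
  }
  w <- 1 / per$se^2
  X <- cbind(1, per$quartile)
  cv <- solve(crossprod(X, w * X))
  coefs <- drop(cv %*% crossprod(X, w * per$beta))
  structure(list(per_quartile = per,
                 intercept = unname(coefs[1]), slope = unname(coefs[2]),
                 slope_se = sqrt(cv[2, 2])),
            class = "quartile_profile")
}

#' Compare interaction results between discovery and replication cohorts
#'
#' Restricts both result tables to their shared SNP-flux pairs, then
#' reports the Pearson correlation of interaction effect estimates and of
#' dosage slopes, the fraction of pairs with consistent interaction
#' direction, and how many pairs reach significance or borderline
#' significance in the replication cohort (BH-FDR computed within the
#' replication's tested pair set; a pair counts as replicated when either
#' test passes).
#'
#' @param results_discovery,results_replication data.frames with columns
#'   `snp`, `reaction`, `beta_interaction`, `slope_dosage`,
#'   `p_interaction`, `p_dosage`.
#' @param alpha FDR significance level (default 0.05).
#' @param borderline borderline FDR level (default 0.25).
#' @return list: `n_shared`, `r_interaction`, `r_slope`,
#'   `sign_consistency`, `n_significant`, `n_borderline`.
#' @export
compare_cohorts <- function(results_discovery, results_replication,
                            alpha = 0.05, borderline = 0.25) {
  d <- as.data.frame(results_discovery)
  r <- as.data.frame(results_replication)
  key_d <- paste(d$snp, d$reaction, sep = "\r")
  key_r <- paste(r$snp, r$reaction, sep = "\r")
  shared <- intersect(key_d, key_r)
  if (length(shared) == 0) stop("no shared SNP-flux pairs between cohorts")
  d <- d[match(shared, key_d), , drop = FALSE]
  r <- r[match(shared, key_r), , drop = FALSE]

  # replication-set FDR over its tested pairs
  f1 <- bh_adjust(r$p_interaction)
  f2 <- bh_adjust(r$p_dosage)
  sig <- (f1 < alpha) | (f2 < alpha)
  bord <- !sig & ((f1 < borderline) | (f2 < borderline))

  list(
    n_shared = length(shared),
    r_interaction = stats::cor(d$beta_interaction, r$beta_interaction),
    r_slope = stats::cor(d$slope_dosage, r$slope_dosage),
    sign_consistency = mean(sign(d$beta_interaction) ==
                              sign(r$beta_interaction)),
    n_significant = sum(sig, na.rm = TRUE),
    n_borderline = sum(bord, na.rm = TRUE)
  )
}
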