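# Shared helpers: pull the PC columns (and optional extra covariates such
# as the cardiometabolic set) out of a cohort table, and the sex:array
# stratification factor.

cohort_strata <- function(cohort) {
  interaction(cohort$sex, cohort$array, drop = TRUE, lex.order = TRUE)
}

cohort_covariates <- function(cohort, extra = NULL) {
  pc_cols <- grep("^PC[0-9]+$", names(cohort), value = TRUE)
  cols <- c(pc_cols, extra)
  if (!is.null(extra)) {
    miss <- setdiff(extra, names(cohort))
    if (length(miss)) stop("cohort lacks covariate column(s): ",
                           paste(miss, collapse = ", "))
  }
  if (!length(cols)) return(NULL)
  as.matrix(cohort[cols])
}

#' The five standard cardiometabolic covariate columns
#'
#' Column names used by the covariate-sensitivity variant of both
#' interaction tests: BMI, systolic blood pressure, LDL-cholesterol,
#' HDL-cholesterol and triglycerides.
#' @return character vector of cohort column names.
#' @export
cardiometabolic_covariates <- function() c("bmi", "sbp", "ldl", "hdl", "tg")

#' Regress risk-allele dosage out of a flux
#'
#' Returns the ordinary-least-squares residuals of the flux on
#' (intercept, dosage). Removes any linear dependence of the genetically
#' predicted flux on the risk-allele dosage before interaction testing,
#' guarding against spurious interactions from shared genetic drivers.
#' The residuals are deliberately NOT re-standardized: the adjustment is
#' a projection, not a rescaling, so effect sizes stay commensurate
#' across pairs.
#'
#' @param flux standardized flux vector.
#' @param dosage dosage vector (non-constant).
#' @return residual flux vector (mean zero, exactly uncorrelated with
#'   dosage in-sample).
#' @export
adjust_flux_for_snp <- function(flux, dosage) {
  if (length(flux) != length(dosage)) stop("flux and dosage lengths differ")
  if (stats::var(dosage) == 0)
    stop("degenerate regression: dosage is constant")
  X <- cbind(1, dosage)
  unname(stats::lm.fit(X, flux)$residuals)
}

#' SNP-by-flux interaction effect test
#'
#' Fits the five-term stratified Cox model
#' \deqn{h(t) = h_0(t)\exp(\beta_{SNP} SNP + \beta_{Flux} Flux +
#'   \beta_{SNP^2} SNP^2 + \beta_{Flux^2} Flux^2 +
#'   \beta_{SNP:Flux} SNP\cdot Flux)}
#' with age as timescale, genetic PCs (and optionally the cardiometabolic
#' set) as covariates and sex/array stratification, and evaluates the
#' interaction term with a two-tailed Wald test. By default the flux is
#' first adjusted with [adjust_flux_for_snp()].
#'
#' @param cohort cohort table (`event`, `age`, `sex`, `array`, `PC*`, ...).
#' @param dosage risk-allele dosage vector.
#' @param flux standardized flux vector.
#' @param covariates optional character vector of additional cohort
#'   columns, e.g. [cardiometabolic_covariates()] for the sensitivity
#'   variant.
#' @param adjust_flux adjust the flux for the SNP first (default `TRUE`;
#'   set `FALSE` if the flux is already adjusted).
#' @return list of class `interaction_result`: `beta_interaction`, `se`,
#'   `p`, `fit` (the full [fit_cox()] result), `sensitivity` flag.
#' @export
interaction_effect_test <- function(cohort, dosage, flux, covariates = NULL,
                                    adjust_flux = TRUE) {
  if (adjust_flux) flux <- adjust_flux_for_snp(flux, dosage)
  X <- cbind(SNP = dosage, Flux = flux,
             SNP2 = dosage^2, Flux2 = flux^2,
             SNPxFlux = dosage * flux)
  if (stats::var(X[, "SNPxFlux"]) == 0)
    stop("degenerate design: interaction column is constant")
  Z <- cohort_covariates(cohort, covariates)
  if (!is.null(Z)) X <- cbind(X, Z)
  fit <- fit_cox(cohort$age, cohort$event, X, strata = cohort_strata(cohort))
  structure(list(
    beta_interaction = unname(fit$coef["SNPxFlux"]),
    se = unname(fit$se["SNPxFlux"]),
    p = wald_p(fit, "SNPxFlux"),
    fit = fit,
    sensitivity = !is.null(covariates)
  ), class = "interaction_result")
}

#' Hard-call fractional dosages to genotype groups
#'
#' Nearest-integer rounding of dosages in \[0, 2\] to \{0, 1, 2\}; ties at
#' .5 round half up toward the larger dosage.
#'
#' @param dosage numeric vector in \[0, 2\].
#' @return integer vector of genotype calls.
#' @export
hard_call_dosage <- function(dosage) {
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosage values must lie in [0, 2]")
  as.integer(floor(dosage + 0.5))
}

#' Flux effect sizes within each risk-allele dosage group
#'
#' Splits the cohort by hard-called dosage (0/1/2) and fits, within each
#' group, a stratified Cox model with the (unadjusted) flux as sole
#' exposure plus genetic PCs, each group with its own baseline hazard.
#' Groups with fewer events than `min_events` are flagged absent rather
#' than fitted.
#'
#' @param cohort cohort table.
#' @param dosage_calls integer calls from [hard_call_dosage()].
#' @param flux standardized flux vector (unadjusted; dosage is constant
#'   within each group so adjustment would have no effect).
#' @param covariates optional extra cohort covariate columns.
#' @param min_events minimum events per dosage group (default 10).
#' @return data.frame of class `dosage_strata` with one row per dosage
#'   0/1/2: `dosage`, `beta`, `se`, `n`, `events`, `present`.
#' @export
dosage_specific_fits <- function(cohort, dosage_calls, flux,
                                 covariates = NULL, min_events = 10) {
  stopifnot(length(dosage_calls) == nrow(cohort),
            length(flux) == nrow(cohort))
  out <- data.frame(dosage = 0:2, beta = NA_real_, se = NA_real_,
                    n = 0L, events = 0L, present = FALSE)
  for (d in 0:2) {
    idx <- which(dosage_calls == d)
    out$n[d + 1] <- length(idx)
    out$events[d + 1] <- sum(cohort$event[idx])
    if (length(idx) == 0 || out$events[d + 1] < min_events) next
    X <- cbind(Flux = flux[idx])
    Z <- cohort_covariates(cohort[idx, , drop = FALSE], covariates)
    if (!is.null(Z)) X <- cbind(X, Z)
    fit <- tryCatch(
      fit_cox(cohort$age[idx], cohort$event[idx], X,
              strata = cohort_strata(cohort)[idx]),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    out$beta[d + 1] <- unname(fit$coef["Flux"])
    out$se[d + 1] <- unname(fit$se["Flux"])
    out$present[d + 1] <- TRUE
  }
  class(out) <- c("dosage_strata", "data.frame")
  out
}

#' Welch's heteroscedastic ANOVA on per-dosage effect estimates
#'
#' Tests whether flux effect sizes differ across risk-allele dosage
#' groups without assuming homogeneous variances. Applied at the estimate
#' level: group "mean" is the per-dosage Cox coefficient \eqn{\beta_i},
#' its squared standard error \eqn{SE_i^2} plays the role of \eqn{s_i^2/n_i},
#' and the group size enters only the Welch-Satterthwaite degrees-of-freedom
#' correction.
#'
#' @param estimates a [dosage_specific_fits()] result, or a data.frame
#'   with columns `beta`, `se`, `n` (and optionally `present`).
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(estimates) {
  est <- as.data.frame(estimates)
  if (!is.null(est$present)) est <- est[est$present, ]
  beta <- est$beta; se <- est$se; n <- est$n
  k <- length(beta)
  if (k < 2) stop("Welch ANOVA needs at least 2 dosage groups")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be finite and positive")
  w <- 1 / se^2
  W <- sum(w)
  xbar <- sum(w * beta) / W
  A <- sum(w * (beta - xbar)^2) / (k - 1)
  lambda <- 3 / (k^2 - 1) * sum((1 - w / W)^2 / (n - 1))
  Fstat <- A / (1 + 2 * (k - 2) * lambda / 3)
  df1 <- k - 1
  df2 <- 1 / lambda
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Inverse-variance weighted slope of effect size on dosage
#'
#' Weighted least squares of the per-dosage flux effect sizes on dosage
#' (0, 1, 2) with weights \eqn{1/SE_i^2}; summarizes the dosage-specific
#' test on the same log-hazard-per-dosage scale as the interaction model
#' coefficient. The slope SE comes from the fixed-weight normal
#' equations (no residual-variance rescaling).
#'
#' @inheritParams welch_anova
#' @return list: `slope`, `se`.
#' @export
weighted_dosage_slope <- function(estimates) {
  est <- as.data.frame(estimates)
  if (!is.null(est$present)) est <- est[est$present, ]
  beta <- est$beta; se <- est$se; d <- est$dosage
  if (is.null(d)) d <- seq_along(beta) - 1
  if (length(beta) < 2) stop("weighted slope needs at least 2 dosage groups")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be finite and positive")
  w <- 1 / se^2
  X <- cbind(1, d)
  XtWX <- crossprod(X, w * X)
  cv <- solve(XtWX)
  coefs <- drop(cv %*% crossprod(X, w * beta))
  list(slope = unname(coefs[2]), se = sqrt(cv[2, 2]))
}

#' Run both interaction tests for one SNP-flux pair
#'
#' Convenience wrapper: the interaction effect size test (with flux
#' adjustment) and the dosage-specific test (hard calls, per-dosage fits,
#' Welch ANOVA, weighted slope) for a single pair.
#'
#' @inheritParams interaction_effect_test
#' @param min_events minimum events per dosage group.
#' @return one-row data.frame: `beta_interaction`, `se_interaction`,
#'   `p_interaction`, `F_dosage`, `p_dosage`, `slope_dosage`,
#'   `se_slope`, plus per-dosage `beta`/`se`/`n` columns.
#' @export
test_pair <- function(cohort, dosage, flux, covariates = NULL,
                      min_events = 10) {
  it <- interaction_effect_test(cohort, dosage, flux, covariates)
  calls <- hard_call_dosage(dosage)
  ds <- dosage_specific_fits(cohort, calls, flux, covariates, min_events)
  if (sum(ds$present) < 2)
    stop("dosage-specific test needs >= 2 dosage groups with enough events")
  wa <- welch_anova(ds)
  sl <- weighted_dosage_slope(ds)
  data.frame(
    beta_interaction = it$beta_interaction,
    se_interaction = it$se, p_interaction = it$p,
    F_dosage = wa$F, p_dosage = wa$p,
    slope_dosage = sl$slope, se_slope = sl$se,
    beta_d0 = ds$beta[1], se_d0 = ds$se[1], n_d0 = ds$n[1],
    beta_d1 = ds$beta[2], se_d1 = ds$se[2], n_d1 = ds$n[2],
    beta_d2 = ds$beta[3], se_d2 = ds$se[3], n_d2 = ds$n[3]
  )
}
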