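test_that("flux adjustment is the OLS projection on (1, dosage)", {
  set.seed(1)
  d <- rep(c(0, 1, 2), times = c(5, 8, 3))
  # exact linear dependence vanishes
  expect_equal(adjust_flux_for_snp(2 * d, d), rep(0, length(d)))
  # flux orthogonal to centered dosage: output is mean-centered flux
  f <- rnorm(16)
  dc <- d - mean(d)
  f_orth <- f - sum(f * dc) / sum(dc^2) * dc
  expect_equal(adjust_flux_for_snp(f_orth, d), f_orth - mean(f_orth),
               tolerance = 1e-12)
  # generic case against an independent normal-equations solve
  f2 <- 0.3 * d + rnorm(16)
  X <- cbind(1, d)
  beta_ne <- solve(t(X) %*% X, t(X) %*% f2)
  expect_equal(adjust_flux_for_snp(f2, d), drop(f2 - X %*% beta_ne),
               tolerance = 1e-10)
  # residuals exactly uncorrelated with dosage
  r <- adjust_flux_for_snp(f2, d)
  expect_lt(abs(cov(r, d)), 1e-10)
  expect_error(adjust_flux_for_snp(f2, rep(1, 16)), "constant")
  expect_error(adjust_flux_for_snp(f2[1:5], d), "lengths differ")
})

test_that("hard calls round to the nearest dosage, half up", {
  expect_identical(hard_call_dosage(c(0.49, 0.5, 1.49, 1.5, 0, 1, 2)),
                   c(0L, 1L, 1L, 2L, 0L, 1L, 2L))
  expect_error(hard_call_dosage(c(1, 2.1)), "\\[0, 2\\]")
  expect_error(hard_call_dosage(-0.1), "\\[0, 2\\]")
})

test_that("Welch ANOVA on estimates matches oneway.test on raw groups", {
  # estimate-level inputs (mean, SE of mean, n) must reproduce the
  # classic Welch test computed by stats::oneway.test from raw data
  set.seed(2)
  g <- list(rnorm(40, 0, 1), rnorm(25, 0.5, 2), rnorm(60, 0.2, 0.5))
  est <- data.frame(
    beta = vapply(g, mean, 0),
    se = vapply(g, function(x) sd(x) / sqrt(length(x)), 0),
    n = lengths(g))
  ref <- oneway.test(y ~ grp,
                     data = data.frame(y = unlist(g),
                                       grp = factor(rep(1:3, lengths(g)))),
                     var.equal = FALSE)
  wa <- welch_anova(est)
  expect_equal(wa$F, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(wa$df1, unname(ref$parameter[1]), tolerance = 1e-10)
  expect_equal(wa$df2, unname(ref$parameter[2]), tolerance = 1e-8)
  expect_equal(wa$p, unname(ref$p.value), tolerance = 1e-10)
})

test_that("Welch ANOVA limiting and degenerate cases", {
  eq <- data.frame(beta = c(0.2, 0.2, 0.2), se = c(0.1, 0.2, 0.3),
                   n = c(10, 20, 30))
  wa <- welch_anova(eq)
  expect_equal(wa$F, 0)
  expect_equal(wa$p, 1)
  # two groups: F is the squared Welch t
  two <- data.frame(beta = c(0.1, 0.4), se = c(0.05, 0.08), n = c(50, 30))
  t_welch <- (two$beta[1] - two$beta[2]) / sqrt(sum(two$se^2))
  expect_equal(welch_anova(two)$F, t_welch^2, tolerance = 1e-12)
  # frozen three-group evaluation of the Welch formula
  fr <- data.frame(beta = c(0, 0.2, 0.4), se = rep(0.05, 3), n = rep(1e4, 3))
  wa3 <- welch_anova(fr)
  expect_equal(wa3$F, 15.999467, tolerance = 1e-5)
  expect_equal(wa3$df1, 2)
  expect_equal(wa3$df2, 19998, tolerance = 1)
  expect_error(welch_anova(data.frame(beta = 1, se = 1, n = 5)),
               "at least 2")
  expect_error(welch_anova(data.frame(beta = c(1, 2), se = c(1, 0),
                                      n = c(5, 5))), "positive")
})

test_that("weighted dosage slope matches closed-form WLS", {
  eq <- data.frame(dosage = 0:2, beta = c(0.1, 0.2, 0.3), se = rep(0.05, 3),
                   n = rep(10, 3))
  sl <- weighted_dosage_slope(eq)
  expect_equal(sl$slope, 0.1, tolerance = 1e-12)
  cst <- data.frame(dosage = 0:2, beta = rep(0.2, 3), se = c(.05, .1, .2),
                    n = rep(10, 3))
  expect_equal(weighted_dosage_slope(cst)$slope, 0, tolerance = 1e-12)
  # unequal SEs against the explicit weighted normal equations
  un <- data.frame(dosage = 0:2, beta = c(0.05, 0.22, 0.31),
                   se = c(0.04, 0.07, 0.15), n = rep(10, 3))
  w <- 1 / un$se^2
  dw <- sum(w * un$dosage) / sum(w)
  bw <- sum(w * un$beta) / sum(w)
  slope_cf <- sum(w * (un$dosage - dw) * (un$beta - bw)) /
    sum(w * (un$dosage - dw)^2)
  se_cf <- 1 / sqrt(sum(w * (un$dosage - dw)^2))
  sl2 <- weighted_dosage_slope(un)
  expect_equal(sl2$slope, slope_cf, tolerance = 1e-10)
  expect_equal(sl2$se, se_cf, tolerance = 1e-10)
})

test_that("interaction test rejects a monomorphic dosage", {
  cfg <- one_pair_config(n = 500, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_error(interaction_effect_test(sim$cohort, rep(2, 500),
                                       sim$fluxes[, 1], adjust_flux = FALSE),
               "constant|degenerate")
})

test_that("dosage-specific fits recover ordered per-dosage flux effects", {
  # beta_flux = 0, beta_interaction = 0.15 => flux effect ~ 0.15 * dosage
  cfg <- one_pair_config(n = 20000, beta_flux = 0, beta_interaction = 0.15,
                         seed = 4)
  sim <- simulate_cohort(cfg)
  calls <- hard_call_dosage(sim$genotypes[, 1])
  ds <- dosage_specific_fits(sim$cohort, calls, sim$fluxes[, 1])
  expect_true(all(ds$present))
  expect_equal(sum(ds$n), nrow(sim$cohort))
  expect_true(all(ds$se > 0))
  for (d in 0:2)
    expect_lt(abs(ds$beta[d + 1] - 0.15 * d), 3 * ds$se[d + 1])
  expect_true(ds$beta[1] < ds$beta[2] && ds$beta[2] < ds$beta[3])
})

test_that("homogeneous flux effects agree across dosage groups", {
  cfg <- one_pair_config(n = 20000, beta_flux = 0.2, beta_interaction = 0,
                         seed = 5)
  sim <- simulate_cohort(cfg)
  ds <- dosage_specific_fits(sim$cohort,
                             hard_call_dosage(sim$genotypes[, 1]),
                             sim$fluxes[, 1])
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(ds$beta[i] - ds$beta[j]),
              3 * sqrt(ds$se[i]^2 + ds$se[j]^2))
})

test_that("a stratum below the event minimum is flagged absent", {
  cfg <- one_pair_config(n = 2000, maf = 0.05, seed = 6)
  sim <- simulate_cohort(cfg)
  calls <- hard_call_dosage(sim$genotypes[, 1])
  ds <- dosage_specific_fits(sim$cohort, calls, sim$fluxes[, 1],
                             min_events = 1e6)
  expect_true(all(!ds$present))
  expect_error(welch_anova(ds), "at least 2")
  # all-homozygous cohort: a single stratum cannot support the test
  ds1 <- dosage_specific_fits(sim$cohort, rep(2L, 2000), sim$fluxes[, 1])
  expect_equal(sum(ds1$present), 1)
  expect_error(welch_anova(ds1), "at least 2")
})

test_that("independent cardiometabolic covariates barely move the estimate", {
  deltas <- ses <- numeric(5)
  for (i in 1:5) {
    cfg <- one_pair_config(n = 5000, beta_interaction = 0.2,
                           cardiometabolic = TRUE, seed = 100 + i)
    sim <- simulate_cohort(cfg)
    base <- interaction_effect_test(sim$cohort, sim$genotypes[, 1],
                                    sim$fluxes[, 1])
    sens <- interaction_effect_test(sim$cohort, sim$genotypes[, 1],
                                    sim$fluxes[, 1],
                                    covariates = cardiometabolic_covariates())
    expect_true(sens$sensitivity)
    deltas[i] <- abs(sens$beta_interaction - base$beta_interaction)
    ses[i] <- base$se
  }
  expect_lt(mean(deltas), 0.5 * mean(ses))
})
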