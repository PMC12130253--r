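#' Simulate risk-allele dosages under a latent-Gaussian haplotype model
#'
#' Each of the two haplotypes per individual is drawn by thresholding a
#' multivariate normal vector with the configured latent correlation
#' (`ld_corr`): allele = 1 when the latent variable falls below
#' `qnorm(maf)`. Dosage is the sum of the two independent haplotypes, so
#' each SNP is in Hardy-Weinberg equilibrium at its MAF and pairwise
#' dosage correlation (LD) is tuned by the latent correlation.
#'
#' @param config a [sim_config()].
#' @return numeric matrix (individuals x SNPs, values 0/1/2) with SNP
#'   names as column names and the realized MAF vector in attribute
#'   `"maf"`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  maf <- config$snps$maf
  ch <- chol(config$ld_corr)
  set.seed(substream_seed(config$seed, "genotypes"))
  thr <- stats::qnorm(maf)
  h1 <- sweep(rmvn_chol(n, ch), 2, thr, `<`)
  h2 <- sweep(rmvn_chol(n, ch), 2, thr, `<`)
  g <- h1 + h2
  storage.mode(g) <- "double"
  colnames(g) <- config$snps$name
  attr(g, "maf") <- colMeans(g) / 2
  g
}

#' Simulate organ-specific reaction fluxes
#'
#' Each reaction's raw flux is the sum of its configured per-dosage eQTL
#' contributions plus Gaussian noise correlated within organ according to
#' `flux_corr`. Columns are then standardized to zero mean and unit
#' variance, matching the convention for genetically personalized
#' log2 flux values.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return numeric matrix (individuals x reactions), each column mean 0 /
#'   variance 1, with the organ label of every reaction in attribute
#'   `"organ"` (named character vector).
#' @export
simulate_fluxes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes)
  rx <- config$reactions
  set.seed(substream_seed(config$seed, "fluxes"))
  raw <- matrix(0, n, nrow(rx), dimnames = list(NULL, rx$name))
  # correlated noise, organ by organ
  for (org in unique(rx$organ)) {
    idx <- which(rx$organ == org)
    if (!is.null(config$flux_corr) && org %in% names(config$flux_corr)) {
      ch <- chol(config$flux_corr[[org]])
      raw[, idx] <- rmvn_chol(n, ch)
    } else {
      raw[, idx] <- matrix(stats::rnorm(n * length(idx)), n)
    }
  }
  if (!is.null(config$eqtl_effects)) {
    for (i in seq_len(nrow(config$eqtl_effects))) {
      e <- config$eqtl_effects[i, ]
      if (!e$snp %in% colnames(genotypes))
        stop("eqtl_effects names SNP absent from genotypes: ", e$snp)
      raw[, e$reaction] <- raw[, e$reaction] + e$effect * genotypes[, e$snp]
    }
  }
  fl <- scale(raw)
  attr(fl, "scaled:center") <- NULL
  attr(fl, "scaled:scale") <- NULL
  organ <- stats::setNames(rx$organ, rx$name)
  attr(fl, "organ") <- organ
  fl
}

#' Organ labels of a flux matrix
#' @param fluxes matrix from [simulate_fluxes()] or [read_flux_matrix()].
#' @return named character vector, reaction -> organ.
#' @export
flux_organs <- function(fluxes) attr(fluxes, "organ")

#' Simulate survival outcomes from a stratified Weibull hazard
#'
#' Event ages are drawn by inverse-transform sampling from the Weibull
#' baseline of each individual's `sex:array` stratum under the
#' exponentiated linear predictor assembled from `config$true_effects`
#' (per-pair first-order, second-order and interaction terms) and the PC
#' effects. Individuals whose event time exceeds `censor_age` are
#' administratively censored there.
#'
#' @param genotypes,fluxes matrices from the paired simulate calls.
#' @param config the same [sim_config()].
#' @return list with `cohort` (data.frame: `id`, `event`, `age`, `sex`,
#'   `array`, `PC1..`, optional cardiometabolic columns) and `truth`
#'   (the realized generative parameters, class `sim_truth`).
#' @export
simulate_survival <- function(genotypes, fluxes, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes)
  if (nrow(fluxes) != n) stop("genotypes and fluxes are not conformable")
  k <- config$baseline$shape
  lam <- config$baseline$scale
  if (any(c(k, lam) <= 0)) stop("Weibull shape and scale must be positive")

  set.seed(substream_seed(config$seed, "survival"))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  array <- sample(c("A", "B"), n, replace = TRUE)
  stratum <- paste(sex, array, sep = ":")

  pcs <- NULL
  lp <- numeric(n)
  if (config$n_pcs > 0) {
    pcs <- matrix(stats::rnorm(n * config$n_pcs), n,
                  dimnames = list(NULL, paste0("PC", seq_len(config$n_pcs))))
    lp <- lp + drop(pcs %*% config$pc_effects)
  }
  if (!is.null(config$true_effects)) {
    for (i in seq_len(nrow(config$true_effects))) {
      e <- config$true_effects[i, ]
      g <- genotypes[, e$snp]
      f <- fluxes[, e$reaction]
      lp <- lp + e$beta_snp * g + e$beta_flux * f +
        e$beta_snp2 * g^2 + e$beta_flux2 * f^2 +
        e$beta_interaction * g * f
    }
  }

  shape_of <- function(s) if (length(k) > 1) k[[s]] else k
  scale_of <- function(s) if (length(lam) > 1) lam[[s]] else lam
  u <- stats::runif(n)
  tt <- vapply(seq_len(n), function(j) {
    scale_of(stratum[j]) * (-log(u[j]) / exp(lp[j]))^(1 / shape_of(stratum[j]))
  }, numeric(1))
  event <- as.integer(tt <= config$censor_age)
  age <- pmin(tt, config$censor_age)

  cohort <- data.frame(id = seq_len(n), event = event, age = age,
                       sex = sex, array = array,
                       stringsAsFactors = FALSE)
  if (!is.null(pcs)) cohort <- cbind(cohort, as.data.frame(pcs))

  if (config$cardiometabolic) {
    set.seed(substream_seed(config$seed, "covariates"))
    rho <- config$cardiometabolic_corr
    base <- if (rho > 0 && !is.null(config$true_effects)) {
      e1 <- config$true_effects[1, ]
      drv <- scale(genotypes[, e1$snp] + fluxes[, e1$reaction])
      function() drop(rho * drv + sqrt(1 - rho^2) * stats::rnorm(n))
    } else {
      function() stats::rnorm(n)
    }
    cohort$bmi <- 27 + 4 * base()
    cohort$sbp <- 135 + 18 * base()
    cohort$ldl <- 3.5 + 0.9 * base()
    cohort$hdl <- 1.45 + 0.35 * base()
    cohort$tg  <- 1.7 + 1.0 * base()
  }

  truth <- structure(list(true_effects = config$true_effects,
                          baseline = config$baseline,
                          eqtl_effects = config$eqtl_effects,
                          censor_age = config$censor_age,
                          seed = config$seed),
                     class = "sim_truth")
  list(cohort = cohort, truth = truth)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_fluxes()] and [simulate_survival()] from one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `fluxes`, `cohort`, `truth`.
#' @examples
#' cfg <- sim_config(500,
#'   snps = data.frame(name = "rs1", maf = 0.3),
#'   reactions = data.frame(name = "RX1", organ = "heart"),
#'   true_effects = data.frame(snp = "rs1", reaction = "RX1",
#'     beta_snp = 0.1, beta_flux = 0.1, beta_snp2 = 0, beta_flux2 = 0,
#'     beta_interaction = 0.3),
#'   n_pcs = 2, seed = 7)
#' sim <- simulate_cohort(cfg)
#' head(sim$cohort)
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  f <- simulate_fluxes(g, config)
  s <- simulate_survival(g, f, config)
  list(genotypes = g, fluxes = f, cohort = s$cohort, truth = s$truth)
}
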