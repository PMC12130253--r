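# Shared fixtures: compact single-pair cohort configurations used across
# the unit and acceptance tests.

# One SNP, one reaction, configurable effects. Defaults give ~30% events
# by age 80 under the Weibull(6, 95) baseline.
one_pair_config <- function(n = 5000, beta_interaction = 0,
                            beta_snp = 0.1, beta_flux = 0.1,
                            beta_snp2 = 0, beta_flux2 = 0,
                            maf = 0.3, eqtl = 0, n_pcs = 2,
                            cardiometabolic = FALSE,
                            baseline = list(shape = 6, scale = 95),
                            censor_age = 80, seed = 1) {
  sim_config(
    n_individuals = n,
    snps = data.frame(name = "rs1", maf = maf),
    reactions = data.frame(name = "RX1", organ = "heart"),
    eqtl_effects = if (eqtl != 0)
      data.frame(snp = "rs1", reaction = "RX1", effect = eqtl) else NULL,
    true_effects = data.frame(
      snp = "rs1", reaction = "RX1",
      beta_snp = beta_snp, beta_flux = beta_flux,
      beta_snp2 = beta_snp2, beta_flux2 = beta_flux2,
      beta_interaction = beta_interaction),
    baseline = baseline, censor_age = censor_age,
    n_pcs = n_pcs, cardiometabolic = cardiometabolic,
    seed = seed)
}

# Independent oracle for the latent-Gaussian threshold model: allele
# (= dosage) correlation between two SNPs via univariate reduction of the
# bivariate normal orthant probability.
threshold_model_allele_corr <- function(maf1, maf2, rho) {
  a1 <- qnorm(maf1); a2 <- qnorm(maf2)
  p11 <- stats::integrate(function(z)
    pnorm((a2 - rho * z) / sqrt(1 - rho^2)) * dnorm(z),
    -Inf, a1, rel.tol = 1e-10)$value
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# Definitional BH step-up oracle, coded from the definition (not via
# p.adjust): adj_(i) = min_{j >= i} min(1, n * p_(j) / j).
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, n * ps / seq_len(n))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Naive greedy-pruning oracle re-coded from the procedure description as
# repeated list deletion, a different mechanism than prune_pairs():
# repeatedly take the most significant remaining unprocessed pair, anchor
# its reaction, and delete every remaining pair whose reaction (same
# organ, not already anchored) correlates above the threshold with it.
prune_oracle <- function(pairs, correlations, r_threshold = 0.5) {
  work <- pairs
  work$.maxp <- pmax(work$p_interaction, work$p_dosage)
  work <- work[order(work$.maxp, work$reaction, work$snp), , drop = FALSE]
  anchored <- character(0)
  processed <- rep(FALSE, nrow(work))
  repeat {
    nxt <- which(!processed)[1]
    if (is.na(nxt)) break
    rx <- work$reaction[nxt]
    org <- work$organ[nxt]
    anchored <- union(anchored, rx)
    cm <- correlations[[org]]
    victims <- setdiff(rownames(cm)[abs(cm[rx, ]) > r_threshold],
                       anchored)
    drop_row <- work$organ == org & work$reaction %in% victims
    processed <- processed[!drop_row]
    work <- work[!drop_row, , drop = FALSE]
    processed[which(work$reaction == rx)] <- TRUE
  }
  work$.maxp <- NULL
  work
}

# Union-find connected components of the R^2 > 1 - cut graph: the
# independent oracle for single-linkage LD blocks.
components_oracle <- function(r2, cut = 0.4) {
  m <- nrow(r2)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (1 - r2[i, j] < cut) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

# Random R^2 matrix with planted clumpy structure, for block tests.
random_r2 <- function(m, seed) {
  set.seed(seed)
  x <- matrix(runif(m * m), m)
  r2 <- (x + t(x)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(paste0("s", 1:m), paste0("s", 1:m))
  r2
}
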