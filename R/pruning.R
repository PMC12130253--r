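#' Pairwise Pearson correlation of an organ's reaction fluxes
#'
#' @param fluxes flux matrix with organ labels (attribute `"organ"`).
#' @param organ organ label to subset to.
#' @return symmetric correlation matrix (unit diagonal) over that organ's
#'   non-constant reactions; constant reactions are dropped with a
#'   warning.
#' @export
flux_correlation <- function(fluxes, organ) {
  organs <- flux_organs(fluxes)
  if (is.null(organs)) stop("fluxes has no organ labels")
  rx <- names(organs)[organs == organ]
  if (length(rx) < 2) stop("need >= 2 reactions in organ '", organ, "'")
  sub <- fluxes[, rx, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant flux column(s) excluded: ",
            paste(rx[sds == 0], collapse = ", "))
    sub <- sub[, sds > 0, drop = FALSE]
  }
  stats::cor(sub)
}

#' Greedy correlation pruning of SNP-flux pairs
#'
#' Removes redundant reaction fluxes before multiplicity adjustment.
#' Pairs are ranked by the maximum of the two tests' p-values
#' (ascending; ties broken lexicographically by reaction then SNP name).
#' Walking down the ranking, the reaction of the most significant
#' not-yet-removed pair is retained and every same-organ reaction with
#' \eqn{|r|} above `r_threshold` to it is removed together with all of
#' its pairs; the process repeats until the ranking is exhausted. All
#' retained same-organ reactions end up pairwise at or below the
#' threshold.
#'
#' @param pairs data.frame with columns `snp`, `reaction`, `organ`,
#'   `p_interaction`, `p_dosage` (other columns carried through).
#' @param correlations named list of per-organ correlation matrices (as
#'   from [flux_correlation()]); every reaction in `pairs` must appear in
#'   its organ's matrix.
#' @param r_threshold correlation magnitude above which two reactions are
#'   considered redundant (default 0.5). Applied to \eqn{|r|}.
#' @return list: `pairs` (retained rows), `reactions` (retained reaction
#'   names), `log` (data.frame: `removed`, `kept_by`, `r`, `step`).
#' @export
prune_pairs <- function(pairs, correlations, r_threshold = 0.5) {
  pairs <- as.data.frame(pairs)
  need <- c("snp", "reaction", "organ", "p_interaction", "p_dosage")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("pairs missing column(s): ",
                         paste(miss, collapse = ", "))
  # every reaction must have a correlation entry within its organ
  for (i in seq_len(nrow(pairs))) {
    cm <- correlations[[pairs$organ[i]]]
    if (is.null(cm) || !pairs$reaction[i] %in% rownames(cm))
      stop("no correlation entry for reaction '", pairs$reaction[i],
           "' in organ '", pairs$organ[i], "'")
  }
  org_of <- tapply(pairs$organ, pairs$reaction, function(x) {
    u <- unique(x)
    if (length(u) > 1) stop("reaction mapped to multiple organs")
    u
  })

  max_p <- pmax(pairs$p_interaction, pairs$p_dosage)
  ord <- order(max_p, pairs$reaction, pairs$snp)

  removed <- character(0)
  kept <- character(0)
  log <- list()
  step <- 0L
  for (i in ord) {
    rx <- pairs$reaction[i]
    if (rx %in% removed) next
    if (!rx %in% kept) {
      kept <- c(kept, rx)
      step <- step + 1L
      cm <- correlations[[pairs$organ[i]]]
      others <- setdiff(rownames(cm), c(kept, removed))
      hits <- others[abs(cm[rx, others]) > r_threshold]
      if (length(hits)) {
        removed <- c(removed, hits)
        log[[length(log) + 1]] <- data.frame(
          removed = hits, kept_by = rx,
          r = unname(cm[rx, hits]), step = step)
      }
    }
  }
  keep_row <- !(pairs$reaction %in% removed)
  list(pairs = pairs[keep_row, , drop = FALSE],
       reactions = kept,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(removed = character(0), kept_by = character(0),
                             r = numeric(0), step = integer(0)))
}

#' Univariate flux effects on disease risk (fluxome-wide screen)
#'
#' One stratified Cox fit per reaction (flux as sole exposure, genetic
#' PCs as covariates, sex/array strata), BH-FDR across reactions. Used
#' after pruning to report which retained fluxes carry a marginal
#' association of their own.
#'
#' @param cohort cohort table.
#' @param fluxes flux matrix (columns = reactions); may have zero
#'   columns, giving an empty result.
#' @return data.frame: `reaction`, `beta`, `se`, `p`, `fdr`.
#' @export
univariate_flux_screen <- function(cohort, fluxes) {
  rx <- colnames(fluxes)
  if (is.null(rx) || length(rx) == 0)
    return(data.frame(reaction = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), fdr = numeric(0)))
  Z <- cohort_covariates(cohort)
  s <- cohort_strata(cohort)
  rows <- lapply(rx, function(r) {
    X <- cbind(Flux = fluxes[, r])
    if (!is.null(Z)) X <- cbind(X, Z)
    fit <- tryCatch(fit_cox(cohort$age, cohort$event, X, strata = s),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(reaction = r, beta = NA_real_, se = NA_real_,
                        p = NA_real_))
    data.frame(reaction = r, beta = unname(fit$coef["Flux"]),
               se = unname(fit$se["Flux"]), p = wald_p(fit, "Flux"))
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out
}

#' Univariate SNP screen at genome-wide significance
#'
#' One stratified Cox fit per SNP (dosage as sole exposure, genetic PCs
#' as covariates, sex/array strata); SNPs with Wald p below `threshold`
#' are selected as candidate risk variants for interaction testing.
#' Monomorphic SNPs are excluded with a warning.
#'
#' @param cohort cohort table.
#' @param genotypes dosage matrix (columns = SNPs).
#' @param threshold selection p-value threshold (default genome-wide
#'   5e-8).
#' @return data.frame: `snp`, `beta`, `se`, `p`, `selected`.
#' @export
univariate_snp_screen <- function(cohort, genotypes, threshold = 5e-8) {
  snps <- colnames(genotypes)
  Z <- cohort_covariates(cohort)
  s <- cohort_strata(cohort)
  rows <- lapply(snps, function(v) {
    g <- genotypes[, v]
    if (stats::var(g) == 0) {
      warning("monomorphic SNP excluded: ", v)
      return(NULL)
    }
    X <- cbind(SNP = g)
    if (!is.null(Z)) X <- cbind(X, Z)
    fit <- tryCatch(fit_cox(cohort$age, cohort$event, X, strata = s),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(snp = v, beta = NA_real_, se = NA_real_,
                        p = NA_real_, selected = FALSE))
    p <- wald_p(fit, "SNP")
    data.frame(snp = v, beta = unname(fit$coef["SNP"]),
               se = unname(fit$se["SNP"]), p = p,
               selected = is.finite(p) && p < threshold)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(snp = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), selected = logical(0))
  out
}
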