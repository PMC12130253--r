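#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1), applied
#' across all post-pruning SNP-flux pairs for each of the two tests
#' separately. Validates the input range, then delegates to
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\] (NAs allowed,
#'   propagated).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call buffering/amplification events from the dual-test FDR values
#'
#' A pair is `significant` when BOTH the interaction effect size test and
#' the dosage-specific test pass FDR < `alpha`; `borderline` when both
#' pass FDR < `borderline` without being significant; otherwise `null`.
#' Direction is `amplification` for a positive interaction effect size
#' and `buffering` for a negative one. Pairs with a missing FDR value get
#' an `NA` call (flagged, not dropped).
#'
#' @param results data.frame with columns `beta_interaction`,
#'   `p_interaction`, `p_dosage` (and any identifier columns, carried
#'   through). If `fdr_interaction`/`fdr_dosage` are absent they are
#'   computed here with [bh_adjust()] over all rows.
#' @param alpha significance level on the FDR scale (default 0.05).
#' @param borderline borderline level (default 0.25).
#' @return the input with `fdr_interaction`, `fdr_dosage`, `call`,
#'   `direction` columns added.
#' @export
call_pairs <- function(results, alpha = 0.05, borderline = 0.25) {
  results <- as.data.frame(results)
  if (is.null(results$fdr_interaction))
    results$fdr_interaction <- bh_adjust(results$p_interaction)
  if (is.null(results$fdr_dosage))
    results$fdr_dosage <- bh_adjust(results$p_dosage)
  f1 <- results$fdr_interaction
  f2 <- results$fdr_dosage
  call <- rep(NA_character_, nrow(results))
  ok <- !is.na(f1) & !is.na(f2)
  call[ok] <- "null"
  call[ok & f1 < borderline & f2 < borderline] <- "borderline"
  call[ok & f1 < alpha & f2 < alpha] <- "significant"
  if (any(!ok))
    warning(sum(!ok), " pair(s) with missing FDR values: call set to NA")
  results$call <- call
  results$direction <- ifelse(results$beta_interaction > 0,
                              "amplification", "buffering")
  results
}
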