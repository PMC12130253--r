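#' Fit a stratified Cox proportional-hazards model
#'
#' Thin, contract-enforcing wrapper around [survival::coxph()] with age as
#' the timescale: Efron tie correction, Newton iteration to a relative
#' log-likelihood tolerance of 1e-9 (at most 100 iterations), stratified
#' baseline hazards. Degenerate designs (a column constant within every
#' stratum) and event-free data raise errors rather than returning NA
#' coefficients; non-convergence and infinite-coefficient warnings are
#' captured into a `converged` flag, never silently dropped.
#'
#' @param time positive event/censoring ages.
#' @param event 0/1 event indicators.
#' @param design numeric matrix with named columns.
#' @param strata optional stratum labels (factor or character).
#' @param entry optional left-truncation entry ages (delayed entry);
#'   `NULL` for age measured from birth with no delayed entry.
#' @return object of class `cox_fit`: list with `coef`, `se`, `z`, `p`,
#'   `vcov`, `loglik`, `n`, `n_events`, `converged`.
#' @export
fit_cox <- function(time, event, design, strata = NULL, entry = NULL) {
  design <- as.matrix(design)
  if (is.null(colnames(design)) || any(colnames(design) == ""))
    stop("design must have named columns")
  n <- length(time)
  if (length(event) != n || nrow(design) != n)
    stop("time, event and design are not conformable")
  if (!all(event %in% c(0, 1))) stop("event must be a 0/1 indicator")
  if (sum(event) < 1) stop("no events: Cox model cannot be fitted")
  s <- if (is.null(strata)) factor(rep.int(1L, n)) else as.factor(strata)

  # columns constant within every stratum carry no partial-likelihood
  # information; their coefficients are undefined
  for (j in seq_len(ncol(design))) {
    within_var <- tapply(design[, j], s, function(x) stats::var(x))
    if (all(within_var == 0 | is.na(within_var)))
      stop("degenerate design: column '", colnames(design)[j],
           "' is constant within all strata")
  }

  surv <- if (is.null(entry)) survival::Surv(time, event)
          else survival::Surv(entry, time, event)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(surv ~ design + survival::strata(s),
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|Ran out of iterations|singular",
                conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })

  beta <- stats::coef(fit)
  names(beta) <- colnames(design)
  V <- stats::vcov(fit)
  dimnames(V) <- list(colnames(design), colnames(design))
  # a negative variance diagonal marks a failed fit; the NaN is caught by
  # the converged flag below
  se <- suppressWarnings(sqrt(diag(V)))
  if (any(!is.finite(beta)) || any(!is.finite(se))) converged <- FALSE
  z <- beta / se
  structure(list(
    coef = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    vcov = V,
    loglik = fit$loglik[length(fit$loglik)],
    n = fit$n, n_events = fit$nevent,
    converged = converged
  ), class = "cox_fit")
}

#' Two-tailed Wald p-value for one model term
#'
#' \eqn{p = 2\Phi(-|\beta/SE|)} against the standard normal reference.
#'
#' @param fit a [fit_cox()] result.
#' @param term design column name.
#' @return two-tailed p-value.
#' @export
wald_p <- function(fit, term) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!term %in% names(fit$coef)) stop("unknown model term: ", term)
  unname(2 * stats::pnorm(-abs(fit$coef[term] / fit$se[term])))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Stratified Cox fit:", x$n, "subjects,", x$n_events, "events",
      if (!x$converged) "[NOT CONVERGED]", "\n")
  print(data.frame(coef = x$coef, se = x$se, z = x$z, p = x$p))
  invisible(x)
}
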