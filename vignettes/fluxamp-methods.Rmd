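---
title: "Detecting flux buffering and amplification of risk alleles: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting flux buffering and amplification of risk alleles: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxamp)
```

## The scientific problem

Genome-wide association studies identify risk alleles, but alleles act
inside biological networks. A metabolic reaction flux — the rate at which
a reaction converts substrates to products in a given organ — can modulate
how strongly a risk allele translates into disease risk: a flux that
*amplifies* an allele's effect makes carriers with high flux values more
susceptible, while a *buffering* flux attenuates the allele's penetrance.
fluxamp implements a survival-analysis pipeline that detects such
SNP-by-flux interactions on a time-to-event disease outcome (the motivating
application is coronary artery disease with genetically personalized
organ-specific fluxes), together with a synthetic cohort generator so that
every stage can be validated against known ground truth without access to
restricted individual-level biobank data.

## The dual interaction test

Both tests use Cox proportional hazards with **age as the timescale**
(the time axis is attained age, not time on study), stratified by sex and
genotyping array (each stratum keeps its own baseline hazard), with
genetic principal components as covariates.

**Interaction effect size test.** For a SNP with dosage $SNP \in [0,2]$
and a standardized flux $Flux$, the model is

$$h(t) = h_0(t)\,\exp\!\big(\beta_{SNP}\,SNP + \beta_{Flux}\,Flux +
\beta_{SNP^2}\,SNP^2 + \beta_{Flux^2}\,Flux^2 +
\beta_{SNP:Flux}\,SNP \cdot Flux\big),$$

and $\beta_{SNP:Flux}$ is evaluated with a two-tailed Wald test. The
second-order terms absorb curvature in dosage and flux that a linear
product term would otherwise soak up. Before fitting, the flux is
**adjusted**: ordinary-least-squares residuals of flux on (intercept,
dosage) replace the raw flux (`adjust_flux_for_snp()`). Genetically
predicted fluxes can correlate with the risk allele itself (shared eQTL
drivers), and that dependence would manufacture spurious interactions;
the projection removes it exactly in-sample. The residuals are *not*
re-standardized — the adjustment is a projection, not a rescaling, so
interaction effect sizes stay commensurate across pairs.

**Dosage-specific test.** Individuals are split by hard-called dosage
(nearest integer, ties at .5 rounding up), and within each dosage group
$i$ the flux effect is estimated with its own baseline hazard:

$$h_{SNP_i}(t) = h_{0,SNP_i}(t)\,\exp(\beta_{Flux,SNP_i}\,Flux).$$

Heterogeneity of $(\beta_{Flux,SNP_0}, \beta_{Flux,SNP_1},
\beta_{Flux,SNP_2})$ is tested with **Welch's ANOVA**, the
heteroscedasticity-robust one-way ANOVA, applied at the estimate level:
the group "mean" is $\hat\beta_i$, its squared standard error $SE_i^2$
stands in for $s_i^2/n_i$, weights are $w_i = 1/SE_i^2$, and the group
size enters only the Welch–Satterthwaite degrees-of-freedom correction.
This is the only reading consistent with testing "differences between
effect sizes across dosages" when the per-group inputs are Cox estimates
rather than raw observations; the implementation is verified in the test
suite against `stats::oneway.test()` by feeding both the raw groups and
their summary statistics. For comparability with the interaction model,
the dosage-specific result is summarized by the **inverse-variance
weighted slope** of $\hat\beta_i$ on dosage $i$ (weights $1/SE_i^2$),
whose standard error comes from the fixed-weight normal equations (no
residual-variance rescaling — the weights are known, as in fixed-effect
meta-regression). Unadjusted flux is used here: dosage is constant within
each group, so the adjustment would be a no-op. Dosage groups with fewer
than `min_events` (default 10) events are flagged absent; the test
requires at least two present groups. The default guards against unstable
estimates in rare homozygote groups.

Within the generator's proportional-hazards world the two summaries
estimate the same quantity, and because both are computed from the same
cohort their sampling errors are strongly correlated; across simulated
pairs the two estimates correlate at r > 0.999 (recomputed by
`scripts/acceptance.R`), mirroring the near-perfect agreement the
approach shows on real data.

**Covariate sensitivity.** Both tests optionally add BMI, systolic blood
pressure, LDL-cholesterol, HDL-cholesterol and triglycerides
(`cardiometabolic_covariates()`). When the generator draws these
independently of the interaction, their inclusion moves the interaction
estimate by well under half a standard error (tested).

## Multiplicity and the calling rule

The two tests' p-values are each BH-adjusted **across all post-pruning
SNP–flux pairs** (`bh_adjust()`, separately per test). A pair is called
**significant** only when *both* FDR values are below 0.05 — the
intersection rule is conservative by construction at every level — and
**borderline** when both are below 0.25. Direction is read off the sign
of $\beta_{SNP:Flux}$: positive = amplification, negative = buffering.

## Pruning correlated fluxes

Metabolic fluxes are heavily correlated (stoichiometric coupling, shared
carriers). To avoid counting one signal many times, pairs are ranked by
the *maximum* of their two p-values (ascending; ties broken
lexicographically by reaction then SNP so runs are reproducible).
Walking down the ranking, the reaction of the best not-yet-removed pair
is kept and every same-organ reaction with $|r| > 0.5$ to it is removed
together with all of its pairs. The threshold is applied to $|r|$:
stoichiometric coupling can be negative, and sign-blind removal is the
conservative choice. After pruning, all retained same-organ reactions
are pairwise at or below the threshold (asserted in code and tests).
Reactions without gene annotation are excluded up front via a boolean
reaction attribute; annotation itself is an input, not something the
package recomputes. The retained reactions also get a univariate
fluxome-wide screen (`univariate_flux_screen()`).

## Risk loci from LD blocks

Candidate SNPs come from a univariate Cox screen
(`univariate_snp_screen()`, default threshold $5\times10^{-8}$). LD is
the squared Pearson correlation of dosage vectors — the matching
statistic for a dosage-based data model. Blocks are single-linkage
("friends of friends") clusters of $1-R^2$ cut at height 0.4, i.e.
connected components of the graph joining pairs with $R^2 > 0.6$
strictly; a distance of exactly 0.4 does not join (the implementation
cuts the tree at $0.4 - 10^{-9}$ to express strictness through
`stats::cutree`, which otherwise merges at heights $\le h$). The
cut-equals-components identity is asserted against an independent
union-find oracle on random instances. Significant SNP-level calls are
then collapsed to distinct (block, reaction) combinations —
risk locus–flux pairs — with member counts and a direction summary.

## Quartile profiles and replication

For visualization-style summaries, individuals are quartile-binned by
flux (boundaries at the 0.25/0.5/0.75 sample quantiles, ties to the
lower quartile by rank, so bins differ by at most one) and the variant
effect $\beta_{SNP,Flux_q}$ is estimated per quartile; a trend line of
$\hat\beta_q$ on $q$ weighted by $1/SE_q^2$ summarizes
amplification/buffering. The $1/SE^2$ weighting matches the
dosage-specific slope; the choice is recorded in the output metadata.
`compare_cohorts()` implements the replication logic: restrict to shared
pairs, correlate interaction estimates and dosage slopes, report the
sign-consistency fraction, and re-run BH within the replication's tested
pair set (a pair replicates when either test passes).

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes —
not the biology that produces it.

* **Genotypes**: each haplotype is a thresholded multivariate normal
  (allele = 1 when the latent variable is below $\Phi^{-1}(\text{MAF})$),
  dosage = sum of two independent haplotypes. Each SNP is in
  Hardy–Weinberg equilibrium and pairwise LD is tuned by the latent
  correlation. The model gives realistic pairwise $R^2$, not haplotype
  realism; note that a latent correlation of 0.9 yields a dosage $R^2$
  of only ≈0.49 (the attenuation of the threshold model, verified
  against a numerical bivariate-normal oracle), so configurations that
  need $R^2 > 0.6$ use latent correlations ≥0.97. Dosages are integers;
  imputation uncertainty is not emulated (hard-calling is still
  exercised on fractional inputs in tests).
* **Fluxes**: per-dosage eQTL shifts plus within-organ correlated
  Gaussian noise, then column standardization to mean 0 / variance 1,
  the convention for genetically personalized log2 flux values.
* **Survival**: inverse-transform sampling from a per-stratum Weibull
  baseline under the exponentiated linear predictor (first-order,
  second-order and interaction terms per configured pair, plus PC
  effects), administrative censoring at `censor_age`. The defaults —
  Weibull shape 6, scale 95 years, censoring at 80 — give a lifetime
  cumulative incidence of ≈30% by age 80, a realistic shape for an
  age-accumulating cardiovascular endpoint. Age is measured from birth
  with no delayed entry; enrolment-conditioned sampling of prevalent
  cases is deliberately not modelled (the fitting contract accepts an
  entry-age vector so left truncation can be added without interface
  change).
* **Seeds**: one master seed deterministically spawns per-stage
  substreams; identical configuration + seed reproduces every output
  bit-for-bit.

What passing tests on this generator do *not* show: robustness to
non-proportional hazards, to informative censoring, to fractional
imputed dosages, to non-Gaussian flux distributions, or to
population stratification beyond linear PC adjustment.

## Numerical and engineering choices

* Cox fitting is backed by `survival::coxph` with the Efron tie
  correction (standard for heavily tied age-scale data), Newton
  iteration to a relative log-likelihood tolerance of $10^{-9}$, at most
  100 iterations. Non-convergence and infinite-coefficient warnings are
  converted into an explicit `converged` flag; degenerate designs
  (columns constant within every stratum) and event-free data are
  errors, not NA coefficients. The contract is validated against
  brute-force maximization of written-out partial likelihoods on tiny
  datasets.
* Batch pair testing isolates per-pair failures: a failed fit is logged
  into the run's error table and the pair is emitted as missing, rather
  than aborting the batch.
* The demonstration configuration (`demo_config()`) plants one
  amplification interaction (effect 0.35) among 72 SNP–reaction pairs at
  n = 5000, with an LD pair among null SNPs, a redundant correlated
  reaction to exercise pruning, and an eQTL-driven flux to exercise
  adjustment. Its SNP screen is run at threshold 1 because the demo
  emulates a study whose candidate variants are pre-established by an
  external GWAS; at n = 5000 a $5\times10^{-8}$ screen would test the
  screen's power, not the interaction pipeline.
* Simulation sizes used by the validation suite — 500 pairs at
  n = 20,000 for method agreement, 1,000 null replicates at n = 10,000
  for calibration, 200 replicates for recovery, 20 seeds of the demo
  study — are the package's chosen study conditions and are stated in
  the test and script code; nuisance dimension is kept at two principal
  components in these simulations.

## Worked example

```{r demo, eval = FALSE}
run <- run_pipeline(demo_config(seed = 3), snp_threshold = 1)
run
subset(run$pair_results, call == "significant",
       select = c(snp, reaction, beta_interaction,
                  fdr_interaction, fdr_dosage, direction))
run$locus_pairs
```

## Known limitations

* The generator's proportional-hazards world is exactly the fitted
  model's world; model misspecification is out of scope.
* Flux computation itself (metabolic modelling, transcript imputation)
  is out of scope: fluxes enter as a standardized matrix.
* LD is dosage-correlation based; reference-panel or phased-haplotype
  r² and genomic coordinates are not handled.
* Welch's ANOVA degrees-of-freedom use the per-group subject counts; if
  effective sample size per group differs materially from subject count
  (heavy censoring imbalance), the df correction is approximate. With
  the group sizes this pipeline targets, df₂ is large and the
  correction is immaterial.
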