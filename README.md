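# fluxamp

Detection of metabolic-flux **buffering and amplification** of disease
risk alleles.

## The problem

Risk alleles found by GWAS do not act in isolation: the metabolic network
they sit in can modulate their penetrance. A reaction flux — the rate of
a biochemical conversion or transport process in a given organ — may
*amplify* an allele's effect on disease risk (carriers with high flux are
at disproportionately higher risk) or *buffer* it. fluxamp is for
statistical geneticists and systems biologists who want to scan SNP–flux
pairs for such non-additive effects on a time-to-event outcome (the
motivating application is coronary artery disease with genetically
personalized organ-specific fluxes in biobank cohorts), and who need
every stage of that scan to be testable against simulated ground truth.

## The method

Two complementary tests per SNP–flux pair, both stratified Cox
proportional-hazards models with **age as the timescale** (sex/array
strata, genetic PCs as covariates):

1. **Interaction effect size test** — fit

   *h(t) = h₀(t) · exp(β₁·SNP + β₂·Flux + β₃·SNP² + β₄·Flux² +
   β₅·SNP·Flux)*

   after regressing the SNP out of the flux (OLS residualization, which
   removes spurious interactions from shared genetic drivers), and Wald-test
   β₅.
2. **Dosage-specific test** — hard-call dosages to 0/1/2, estimate the
   flux effect β(i) within each dosage group with its own baseline
   hazard, test heterogeneity with **Welch's ANOVA** on the estimates
   (SE² standing in for s²/n), and summarize with the 1/SE²-weighted
   slope of β(i) on i.

P-values from both tests are BH-FDR adjusted across all pairs that
survive greedy correlation pruning (same-organ reactions with |r| > 0.5
collapsed behind the most significant pair); a pair is **called** only
when both FDRs are < 0.05 (borderline at 0.25), with direction
(amplification/buffering) from the sign of β₅. Significant SNP-level
calls are aggregated into **risk locus–flux pairs** via LD blocks:
single-linkage clusters of 1−R² cut at 0.4 (R² > 0.6 chaining).
A synthetic cohort generator (latent-Gaussian haplotype LD, eQTL-driven
standardized fluxes, stratified Weibull survival) provides ground truth
for every stage.

## Worked example

The bundled demonstration study simulates 5,000 individuals, 6 SNPs and
12 organ-labelled reactions with one planted amplification interaction
(`rs1` × `HEART_R1`, true effect 0.35):

```r
library(fluxamp)
run <- run_pipeline(demo_config(seed = 3), snp_threshold = 1)
run
#> fluxamp pipeline run
#>   individuals: 5000
#>   SNPs screened/selected: 6 / 6
#>   pairs tested/retained: 72 / 66
#>   significant pairs: 1
#>   risk locus-flux pairs: 1

subset(run$pair_results, call == "significant",
       select = c(snp, reaction, beta_interaction,
                  fdr_interaction, fdr_dosage, direction))
#>  snp reaction beta_interaction fdr_interaction   fdr_dosage     direction
#>  rs1 HEART_R1        0.3453716    6.808713e-17 1.830654e-15 amplification
```

The interaction estimate (0.345, log-HR per dosage × flux-SD) recovers
the planted 0.35; both tests agree, the redundant correlated heart
reaction was pruned (72 → 66 pairs), and the call survives the
both-tests FDR rule. The per-flux-quartile profile of the variant effect
shows the amplification directly — the allele's log hazard ratio rises
from −0.37 in the lowest flux quartile to 0.66 in the highest, trend
slope 0.30 (SE 0.035) per quartile:

```r
run$quartiles[["rs1:HEART_R1"]]$per_quartile
#>  quartile       beta         se    n events
#>         1 -0.3657368 0.10052899 1250    283
#>         2  0.1964035 0.07877494 1250    366
#>         3  0.2360687 0.07151171 1250    437
#>         4  0.6578851 0.06265846 1250    537
```

Null SNPs `rs5`/`rs6` (simulated at dosage R² ≈ 0.71) collapse into a
single LD block, so the 6 SNPs map to 5 independent loci.

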