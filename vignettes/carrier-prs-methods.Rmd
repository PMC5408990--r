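---
title: "Modelling PRS-modified cancer risks in BRCA1/BRCA2 carriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PRS-modified cancer risks in BRCA1/BRCA2 carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierprs)
```

## The scientific problem

Women carrying a pathogenic BRCA1 or BRCA2 mutation face high lifetime risks
of breast and ovarian cancer, and decisions such as the timing of
risk-reducing salpingo-oophorectomy or mastectomy hinge on those risks.
Common susceptibility variants discovered in population GWAS modify risk in
carriers too; combined into a polygenic risk score (PRS) they can shift a
carrier's absolute risk enough to matter clinically. `carrierprs` implements
the full analysis chain needed to quantify that modification from a
retrospective, clinic-recruited carrier cohort:

1. PRS construction from a SNP weight table and genotype dosages;
2. sampling weights that correct outcome-dependent ascertainment;
3. weighted Cox regression of age at diagnosis on the standardized PRS
   (continuous, percentile categories, age-group effects, PRS-by-age
   interaction, pairwise SNP interaction scans);
4. a multiplicative polygenic model giving theoretical percentile hazard
   ratios and absolute-risk (penetrance) projections by PRS percentile;
5. Harrell's concordance for discrimination.

A synthetic cohort generator with known truth exercises every stage.

## The polygenic risk score

For individual $i$ with dosages $g_{li} \in [0, 2]$ of the effect allele of
variant $l$ and per-allele log risk ratios $\beta_l$,
$$\mathrm{PRS}_i = \sum_{l=1}^{k} \beta_l\, g_{li}.$$
Weight tables are harmonized to the genotype source by variant id and
allele labels: dosages counted on the other allele are flipped to $2-g$;
strand-ambiguous (A/T, C/G) variants cannot be oriented from labels alone
and are used as-is but flagged. Missing dosages are imputed at their
Hardy-Weinberg expectation $2f$ — the standard PRS convention — and the
imputation count is reported per individual, with a configurable flag at
10% missingness.

Scores are standardized to mean 0, SD 1 using the unweighted sample moments
of the whole analysis cohort (affected and unaffected together). Whether the
original analyses standardized within gene-specific cohorts is not
documented; we standardize per analysis cohort and record the fitted
moments. Percentile category boundaries are quantiles of the *fitted normal*
$N(\hat\mu, \hat\sigma^2)$, not empirical quantiles, so category occupancy
equals the nominal percents only insofar as the PRS is normal; an
empirical-quantile mode exists behind a flag. The default categories are
0–5, 5–10, 10–20, 20–40, 40–60 (reference), 60–80, 80–90, 90–95, 95–100.

## Ascertainment and the weighted-cohort fit

Clinic-recruited carriers are sampled conditionally on disease status:
affected carriers are far more likely to enter the cohort. A naive Cox fit
on such a cohort is biased. The weighted-cohort approach stratifies records
by gene and by the 5-year age band containing the age at which follow-up
ends, and weights affected and unaffected records so that the weighted
affected proportion in each stratum equals the proportion $p$ expected from
the average carrier incidence. With observed proportion $q$, the raw
stratum weights are $p/q$ (affected) and $(1-p)/(1-q)$ (unaffected).

Two refinements matter in practice and are part of this implementation:

* **Stratum anchoring.** The raw construction fixes each stratum's weighted
  size at its observed size. Because status-based oversampling changes the
  *age composition* of the cohort as well as the case mix, that leaves a
  stratum-level distortion. Since the sampling mechanism depends on status
  only, we rescale each stratum so affected carriers carry equal weight
  everywhere (then renormalize the total to the cohort size). This leaves
  the restored stratum proportions untouched — they are invariant to
  per-stratum scaling — and makes the weights converge to the true inverse
  sampling probabilities as the cohort grows.
* **Design-aware expected proportions.** The generic rule evaluates the
  cumulative risk $F$ at the band midpoint. That approximates the affected
  share among records *ending* in the band only loosely, because censored
  records end at observation ages with their own distribution. When the
  observation design is known — as in simulations, where censoring ages are
  uniform on a stated range — `expected_cohort_proportions()` computes the
  exact model-implied share, and `build_weights(..., censor_range = )` uses
  it. Parameter-recovery simulations need this: with midpoint proportions
  the recovered per-SD hazard ratios are attenuated by several percent,
  with the design-aware anchored weights they are unbiased to within
  Monte-Carlo error.

Strata with observed proportions of exactly 0 or 1 (e.g. ages below the
youngest possible censoring age, where everyone observed is affected) are
pooled with the nearest mixed band. Weights are capped at 50 after
renormalization, with a message, to keep single records from dominating
small synthetic cohorts. Weights are treated as fixed constants downstream;
the cluster-robust variance covers their sampling noise along with familial
clustering.

## The weighted Cox engine

Time scale is age, with delayed entry at `age_entry` (default 18, the
eligibility age). Ties use the Breslow approximation — adequate for
continuous ages. The engine maximizes the weighted partial likelihood by
Newton–Raphson to a gradient norm below `1e-8` (with standard
numerical-floor escapes: a Newton increment below 1e-9, or a relative
log-likelihood change below 1e-11 on two successive steps, both of which
indicate the round-off floor of the gradient at large cohort sizes).
Monotone likelihoods (separation) are detected and reported rather than
returned as huge finite estimates. Baseline hazards are stratified by study;
robust covariance aggregates score residuals by family.

Time-varying terms come in two forms: the PRS-by-age interaction uses the
covariate $z \cdot t$ evaluated at each event age $t$ (age in raw years,
anchored at 0, so the main effect is the extrapolated hazard ratio at age 0
and the interaction is a per-year multiplicative change), and age-group
models switch the PRS column on within attained-age bands. Rather than
rescanning the risk set at every event age — $O(n \cdot d)$ exponentials,
prohibitive at $n = 20{,}000$ with thousands of events — the engine splits
the age axis into windows over which $|\gamma_i (t - t_0)| \le 0.1$, where
$\gamma_i$ is the time-proportional part of the linear predictor, and
assembles the risk-set sums $S_0, S_1, S_2$ from Taylor series of the
risk-set moments in $\gamma$ (order 12, truncation error below $10^{-20}$
relative). Windows also break at every age-band boundary. Score residuals
use the analogous per-segment prefix-sum expansion (order 25, segments kept
short enough that series cancellation stays below $20\times$ machine
epsilon). A direct per-event rescan is retained internally and the test
suite verifies both routes agree to $10^{-10}$, as well as agreement with
`survival::coxph` (including its `tt()` route) to $10^{-6}$.

One-sided p-values are reported for the directional hypothesis that a
higher PRS increases risk (used for the continuous per-SD terms); all other
tests are two-sided. Confidence intervals are
$\exp(\hat\beta \pm 1.96\,\mathrm{SE}_\text{robust})$.

The pairwise interaction scan fits, for every SNP pair, a weighted Cox model
with both dosages and their product, tests the product term (Wald, robust,
two-sided), and applies Bonferroni correction across the
$K(K-1)/2$ tests at family level 0.05. Monomorphic SNPs are skipped with a
warning.

## The multiplicative polygenic model

Conditional on the standardized score $z \sim N(0,1)$, the hazard is
$$\lambda(t \mid z) = \lambda_0(t)\, e^{\beta(t) z},$$
so the relative risk across carriers is lognormal. $\beta(t)$ may be
constant, piecewise by age band (from age-group fits), or continuously
decaying ($\log \mathrm{HR}(t) = \log \mathrm{HR}_0 + t \log(\text{decay})$).

**Theoretical category hazard ratios.** Ignoring risk-set depletion, the
hazard ratio of percentile category $(a, b)$ relative to the middle band is
a ratio of truncated-lognormal means, with the closed form
$E[e^{\beta Z}; a<Z<b] = e^{\beta^2/2}\{\Phi(b-\beta) - \Phi(a-\beta)\}$.
Depletion attenuates empirical category estimates at late ages relative to
these baseline values; the simulation tests assert that ordering.

**Absolute risks.** The average carrier incidence $\bar\lambda(t)$ is an
input file, never a built-in constant: published penetrance curves carry
their own provenance and should be supplied by the analyst. (A synthetic
example curve, calibrated so ovarian cancer risk reaches 2.8% by age 40,
ships with the package for demonstrations and is labelled synthetic.) The
baseline $\lambda_0$ is pinned down by the marginal-incidence constraint:
on a yearly grid, $\lambda_{0,k}$ solves
$$E_z\!\left[S(t_k \mid z)\, e^{-\lambda_{0,k} e^{\beta_k z} \Delta}\right]
  = e^{-\bar\Lambda(t_{k+1})},$$
so the PRS-averaged survival reproduces the marginal survival *exactly at
every grid age* (the instantaneous-hazard form of the constraint holds in
the grid limit). Expectations over $z$ use 64-node Gauss–Hermite
quadrature; each interval equation is monotone in $\lambda_{0,k}$ and is
solved by safeguarded Newton from the small-risk starting value
$\bar\lambda e^{-\beta^2/2}$, sequentially in age since earlier intervals
determine the survivor distribution. Conservation — marginalized projected
risk equals the input marginal risk to $10^{-6}$ at all grid ages — is a
tested property, as are the $\beta = 0$ degeneracy ($\lambda_0 \equiv
\bar\lambda$) and the small-risk analytic limit (within 2% while cumulative
risk is below 3%).

Percentile projections use the point quantile $z_p = \Phi^{-1}(p/100)$,
matching how percentile risk curves are usually drawn; a category-mean mode
is available via the theoretical category machinery. Threshold utilities
invert the projected curve: `age_reaching_risk()` (linear interpolation;
`Inf` with a warning when never attained) and `risk_quantile_share()`
(bisection on $z$, since risk is monotone in $z$). One subtlety the naive
lognormal intuition misses: the median-PRS curve lies below the marginal
risk only while cumulative risk is modest; deep in the high-penetrance
regime survivor depletion can invert the relation. The package computes,
it does not assume.

## Discrimination

`harrells_c()` computes the rank concordance between a score and age at
diagnosis under right censoring and delayed entry: pairs are comparable
when one member is diagnosed while the other is still at risk at that age;
score ties count 1/2; optional sampling weights enter as $w_i w_j$. The
confidence interval is a 200-replicate individual-level bootstrap with a
fixed seed (the analytic alternative was not specified in the source
analyses; the bootstrap is assumption-light). An exhaustive $O(n^2)$ pairs
oracle backs the implementation in the tests.

## The synthetic cohort generator

`gen_cohort()` emulates a clinic-ascertained retrospective carrier cohort:

* Hardy–Weinberg genotypes at unlinked SNPs (Binomial(2, f));
* the PRS standardized by its theoretical moments
  ($\mu = \sum 2 f_l \beta_l$, $\sigma^2 = \sum 2 f_l (1-f_l) \beta_l^2$),
  so the generating per-SD effect is exact rather than sample-dependent;
* event ages drawn by exact inverse-CDF sampling on the piecewise-constant
  baseline — with an age-decaying effect the within-interval integral
  $\int e^{czu}\,du$ has a closed form, so no root finding is involved;
* uniform censoring (interview) ages on a stated range (default 35–80,
  reflecting adult carriers ascertained from ongoing clinic series);
* optional shared lognormal family frailty (to exercise the cluster-robust
  variance) and Bernoulli retention by affection status (default in the
  validation studies: affected kept with probability 1, unaffected 0.4,
  a strong clinic-style oversampling).

What it deliberately does not emulate: linkage disequilibrium between SNPs,
population stratification, genotyping error, family-history-based (rather
than status-based) ascertainment, competing mortality, and risk-reducing
surgery. Passing recovery tests therefore show the estimator chain is
correct under the stated sampling model, not that real-cohort complications
are handled; the weighting corrects status-based oversampling only.

## Problem sizes and numerical settings

The validation studies use 50 replicate cohorts of $n = 20{,}000$ carriers
and 50 SNPs per configuration (100 replicates of $n = 8{,}000$ for the
low-event-count ovarian design), with recovery judged against three
Monte-Carlo standard errors of the replicate mean; the test suite uses
smaller cohorts under the same criterion so the whole suite runs in under a
minute. Grids are yearly from age 18 to 80; Gauss–Hermite order 64;
weight-scheme bands 5-year; Newton tolerance $10^{-8}$ on the gradient norm
with at most 100 iterations. Rarer-outcome designs calibrate the baseline
scale to a stated post-ascertainment affected fraction with
`scale_baseline_to_affected()` (15% for the BRCA1-ovarian-like design,
7.5% for the BRCA2-ovarian-like design, matching the affected shares of
the corresponding carrier cohorts).

## Known limitations

* The weighting corrects oversampling by status; richer (family-based)
  ascertainment requires retrospective-likelihood methods out of scope
  here.
* Breslow ties are the default (Efron handling is not implemented); with
  continuous ages the difference is negligible.
* Absolute-risk projections inherit the input incidence curve's authority;
  the package ships only synthetic demonstration curves, so published
  figures are reproduced in mechanism, not numerically.
* Competing risks (mortality, risk-reducing surgery) are not modelled; the
  projections are net risks.
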