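---
title: "Liability-threshold twin models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold twin models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinherit)
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the tunable parameters, the numerical choices,
and the places where a design decision was genuinely open.

## The liability-threshold model

A binary disease indicator is modelled through a latent standard-normal
liability: person $i$ is affected iff $L_i > \tau$, so the threshold is
$\tau = \Phi^{-1}(1 - \text{prevalence})$. For a twin pair, $(L_1, L_2)$ is
bivariate normal with correlation $r$ that depends on zygosity. The model
assumes (i) a single underlying continuum — reasonable for complex,
polygenic-plus-environment disease, not for strongly Mendelian subtypes;
(ii) equal thresholds for both pair members (twin ordering is arbitrary, so
the pair table is symmetric by construction); and (iii) lifetime liability
that does not change with age — age enters only through *observation* of the
disease, which is what the censoring machinery below addresses.

`fit_tetrachoric()` maximises the trinomial likelihood of the three pair
cells over $(\tau, r)$. Because the symmetric trinomial has two degrees of
freedom, the model is saturated: at the optimum the fitted marginal
prevalence $\bar\Phi(\tau)$ equals the observed individual-level prevalence
$(2C + D)/2N$ — a property the test suite checks to $10^{-6}$.

## Variance decomposition

The classical twin decomposition writes liability variance as
$a^2 + c^2 + d^2 + e^2 = 1$ with cross-twin correlations
$r_{MZ} = a^2 + c^2 + d^2$ and $r_{DZ} = a^2/2 + c^2 + d^2/4$: monozygotic
pairs share all additive and dominance genetic variance and the common
environment; dizygotic pairs share half the additive and a quarter of the
dominance variance. `fit_biometric()` maximises the summed trinomial
log-likelihood of the MZ and DZ tables under a shared threshold. C and D are
not jointly identifiable from twin data alone, so the model grid is
ACE / ADE / AE / CE / E, compared by AIC ($2k - 2\ell$, $k$ = threshold +
free components); `select_model()` breaks ties toward fewer parameters and,
when an ADE fit sits within $\Delta\mathrm{AIC} \le 2$ of AE, also reports
the broad-sense share $a^2 + d^2$, which is more stable than its split.

Numerical choices:

* components live on the unit simplex through a softmax-style transform;
  estimates within $10^{-6}$ of a boundary are reported exactly at 0 or 1;
* initialisation is the Falconer start $a^2_0 = 2(\hat r_{MZ} - \hat r_{DZ})$
  from the per-zygosity tetrachorics, clipped to the simplex, with neutral
  fallback starts; convergence tolerance is $10^{-12}$ relative on the
  log-likelihood (BFGS);
* confidence intervals are profile-likelihood at the $\chi^2_1$ cutoff,
  which respects the $[0, 1]$ boundaries (a delta-method interval would not:
  estimates like 0.97 would get intervals crossing 1); the profile search
  brackets $r$ in $[-0.999, 0.999]$ and flags $|r| \ge 1 - 10^{-3}$ as a
  boundary estimate.

## Bivariate-normal orthant probabilities

Every likelihood above needs $P(L_1 > h, L_2 > k; \rho)$.
`bvn_upper_orthant()` integrates the correlation-path identity
$$P = \bar\Phi(h)\bar\Phi(k) + \frac{1}{2\pi} \int_0^{\arcsin\rho}
\exp\!\Big(\!-\frac{h^2 - 2hk\sin\theta + k^2}{2\cos^2\theta}\Big)\,
d\theta$$
with fixed-order Gauss–Legendre quadrature (48 nodes exported, 32 inside
iterative fits). After the $\sin\theta$ substitution the integrand is
analytic up to $|\rho| = 1$, so no separate high-correlation branch is
needed; the suite checks absolute agreement with an independent
implementation and with adaptive 2-D quadrature to well below $10^{-7}$.

## Truncation, censoring, and weighting

Registry data observe a disease only inside a calendar window and while the
person is alive. Two consequences matter:

* **right censoring** — a person censored before their (latent) onset is
  recorded unaffected, biasing prevalence and, asymmetrically by zygosity
  composition, the variance components;
* **left truncation** — persons whose onset predates their entry into
  observation can *never* be recorded as incident cases.

`build_windows()` derives per-person delayed-entry windows on the age scale
(entry at the later of birth and registry start; exit at the earliest of
onset, death, registry end; onset at or before entry is kept as a flagged
prevalent case, consistent with register-based prevalence logic, with a
sensitivity option to drop such persons). `estimate_censoring()` fits a
product-limit model of the probability $S_c(a)$ of still being under
observation at age $a$, treating any non-disease exit as the event and
disease onset as censoring for that process.

`fit_liability_ipw()` then maximises a weighted pairwise composite
likelihood: each pair contributes its bivariate-probit cell probability with
person-specific thresholds $\tau_i = \tau_0 + x_i'\beta$ (sex indicator,
birth-year category), each term weighted by the product of member weights —
$1/S_c(\text{onset age})$ for an observed case, 1 for unaffected members.
Case weights are truncated at their 99th percentile to stabilise variance.
This scheme is a deliberately simple, defensible approximation to full
likelihood approaches that model the censoring process jointly: up-weighting
the cases that were least likely to be observed compensates the
misclassification of censored cases as unaffected. It is exact in two
limits the tests exercise: with no censoring it reproduces the pair-table
fit to $10^{-4}$, and with all weights forced to 1 it is identical to the
unweighted fit. Standard errors for this estimator are available by
pair-level bootstrap (`nboot`); the composite likelihood itself must not be
fed into likelihood-ratio machinery.

Birth-year adjustment uses 10-year bins by default — coarse enough to keep
category counts stable over a 120-year birth range, fine enough to absorb
the secular trend in observation coverage; the width is a parameter of
`covariate_spec()`.

## Co-aggregation on the age scale

`build_episodes()` turns each twin into delayed-entry risk episodes in which
the exposure is the co-twin's diagnosis of an index disease: unexposed from
entry until the co-twin's diagnosis, exposed strictly afterwards. Outcomes
are the person's own diagnosis of the same disease, of a *different*
studied disease, or of any studied disease. When both twins are diagnosed
the same day, the exposed episode would have zero length and is dropped —
the event counts as unexposed. Beginning exposure strictly after the
co-twin's diagnosis avoids immortal-time artifacts; dates are day-granular,
so same-day ties are resolved by rule, not by jitter.

`fit_cox()` fits the partial likelihood with Efron tie handling (Breslow by
flag) and reports both model-based and pair-clustered sandwich standard
errors; the robust one is the default for inference since co-twins share
unmeasured liability. Adjustment is by sex and birth-year category as
covariates (a stratified variant is a one-line change in the formula and is
deliberately not the default, matching the adjusted-covariate convention of
the aggregation analyses this package mirrors).

One pathology deserves emphasis: with a birth range far wider than the
registry window, risk sets at older ages contain people whose latent onset
predated entry and who can never have a recorded event. This "immune"
contamination is shared within pairs and biases even a *null* cohort's
hazard ratio away from 1; birth-year adjustment absorbs only part of it.
The package's null-calibration tests therefore simulate births inside the
observation window, and analyses of real data with early birth cohorts
should treat same-disease HRs as reference points rather than causal
contrasts — which is also why heritability here comes from the liability
model, not from the Cox fits.

## The synthetic cohort generator

`simulate_cohort()` generates complete twin pairs under exactly the model
the fitters assume: per-pair additive scores correlated 1 (MZ) / 0.5 (DZ)
across twins, shared-environment scores correlated 1, dominance scores
correlated 1 / 0.25, independent unique environment; multiple traits with a
cross-trait genetic correlation matrix applied to the additive and dominance
streams (lower-triangular mixing, so appending a trait never perturbs
earlier traits' draws — each component also draws from its own derived seed
stream). Affected persons get a lognormal onset age truncated to [0, 100],
drawn independently of liability magnitude — the simplest model consistent
with a time-invariant liability (an option to couple onset to liability is a
natural extension for sensitivity work, not a default). Diagnoses reach the
simulated register only if the person is alive at onset and the date falls
inside the patient-register window; traits can carry an ATC code (two
dispensations emitted for cases alive after 2005) and a diabetes-register
tag, so the ascertainment engine, including its drug rule, is exercised
end to end. Death follows a coarse per-decade table
(`default_death_model()`), sufficient to drive the alive-in-1976 rule and
death censoring, with no claim of demographic calibration.

`default_traits()` fixes the generator's defaults to the reference cohort's
conditions: the seven diseases at their bundled prevalences (25–2400 per
100 000), female-excess threshold shifts derived from the bundled sex-
stratified counts, AE heritabilities at the bundled best-fit values, birth
years 1886–2006, one third MZ pairs, patient-register coverage 1964–2015
and drug-register coverage from mid-2005. Onset-age medians (18–62 years by
disease) are typical clinical onset ages; they are stated per trait and are
the one set of generator inputs not derivable from the bundled tables.

What the generator does *not* emulate: non-normal liability, sex-limited or
age-varying genetic effects, diagnostic miscoding (events are emitted
without noise), surveillance bias between zygosity groups, and
infection-triggered etiologies. Passing recovery tests therefore shows the
estimators are correct *under the model's own assumptions* — it cannot
certify robustness to violations real register data may contain.

## Problem sizes used by the test suite

Simulation-based checks are sized to finish in minutes on one CPU while
keeping Monte-Carlo error well inside the asserted tolerances: heritability
recovery uses 20 000 pairs per zygosity with 50 replicates per parameter
combination (mean-bias tolerance ±0.05); the censoring-weight comparison
uses 10 replicates at the same size; co-aggregation direction checks use
15 000 pairs × 50 replicates, and null calibration 4 000 pairs × 100
replicates; grid-search oracle comparisons use 20 small tables at a final
grid resolution of $10^{-3}$ (coarse scan plus local refinement). Where a
single replicate's sampling error is comparable to a tolerance (the DZ
tetrachoric at 1.5% prevalence, the sex-shift contrast at 25 000 pairs),
tests average a few replicates or assert against the realised simulated
quantity in addition to the population value, with the sampling-error
arithmetic noted inline.

## Known limitations

* Covariate-adjusted tetrachorics are not provided (the adjusted route is
  `fit_liability_ipw()`); bivariate cross-trait variance decomposition is
  out of scope — the generator supports cross-trait correlation so that a
  future bivariate fitter can be validated against it.
* The composite-likelihood AIC from `fit_liability_ipw()` is comparable
  across models on the same data but is not a true-likelihood AIC.
* The probandwise Wilson interval treats probands as independent; the two
  probands of a concordant pair are not, so the interval is slightly
  liberal. Printed reference intervals for such quantities are reproduced
  only approximately and are not asserted by the tests.
* Pair-level exclusion rules assume complete pairs at input; singleton
  handling is a validation error by design.
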