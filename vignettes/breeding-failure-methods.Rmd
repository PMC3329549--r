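---
title: "Methods: breeding-failure risk, weighted trait estimation and cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breeding-failure risk, weighted trait estimation and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedfail)
```

## The scientific setting

During the demographic transitions, European populations moved from high
fertility (five or more children per mother) with high child mortality to
low fertility with near-universal child survival, and — later — to
postponed first births. `breedfail` implements a life-history reading of
this shift for Finnish church-register-style cohorts (mothers with first
births 1880–1979, about 2,000 mothers in three parishes): the *maternal
risk of breeding failure*, the probability that none of a mother's
children reaches adulthood (age 15 here), links offspring quantity to
offspring quality and provides a common currency for comparing
reproductive strategies across the century.

The package has four layers:

1. a **cohort model** — mother/offspring tables, trait derivation
   (AFR, ALR, reproductive span, fertility, birth interval);
2. **weighted trait estimators** robust to incompletely tracked
   offspring records;
3. the **breeding-failure risk statistic** and its consequences;
4. **decade-stratified weighted GLMs** with backward stepwise
   simplification;

plus a **synthetic cohort generator** calibrated so that every layer is
testable without access to the original (non-public) register data.

## The risk statistic

With lifetime fertility $q$ and per-offspring survival probability $s$
(independence across siblings), the risk of breeding failure is

$$P_{\text{fail}} = (1 - s)^q .$$

The displayed formula in the source literature is an inline image; the
implemented form is reconstructed from the verbal definition of its
determinants (offspring quantity and offspring survival rate) and its
cited precursor, and is stated prominently here for that reason. It is
strictly decreasing in both arguments (`failure_risk()`), and two derived
quantities matter for interpretation:

* **required fertility** (`required_fertility(s, alpha)`): the smallest
  $q$ with $(1-s)^q \le \alpha$. At the 1880s survival rate $s = 0.73$
  and $\alpha = 0.05$ this is 3 children; at $s \ge 0.95$ a single child
  suffices. (The "required fertility of four children" sometimes quoted
  for the 1880s derives from fitted decade-specific model curves, not
  from the analytic formula; `risk_table()` reports the analytic value,
  and fitted curves can be obtained from the models layer.)
* **cohort expected failure** (`cohort_expected_failure(mu, s)`): with
  fertility following a zero-truncated Poisson with mean $\mu$,
  $E[(1-s)^q \mid q \ge 1] =
  (e^{-\lambda s} - e^{-\lambda})/(1 - e^{-\lambda})$ where
  $\lambda/(1 - e^{-\lambda}) = \mu$. This closed form is the oracle the
  simulation tests check against; by Jensen's inequality it always lies
  above $(1-s)^\mu$.

## Weighted estimation from incomplete records

Church-register follow-up is incomplete: some offspring cannot be traced
to age 15 (survival) or through their reproductive life (breeding). The
estimators treat each mother as one observation with a `(value, weight)`
pair:

| response | value | weight |
|---|---|---|
| survival | survivors / known statuses | known / $q$ |
| breeding | bred / known censuses | known / $q$ |
| LRS | $q \times$ breeding value | known / $q$ |
| failure | 0 if a survivor is known, else 1 | 1 if success certain, else known / $q$ |

A mother with four offspring of whom two were tracked for breeding and
one bred therefore contributes breeding probability 0.5 with weight 0.5,
and lifetime reproductive success $4 \times 0.5 = 2.0$ — possibly a
non-integer, which is why the Gaussian LRS models operate on a Box-Cox
scale. Mothers with no usable record get weight 0 and are retained with
an exclusion flag rather than dropped, so the "missing records"
accounting stays auditable.

Under masking that is independent of the true statuses (MCAR), the
weighted mean $\sum w_i v_i / \sum w_i$ is unbiased for the generating
rate; the test suite verifies recovery of the 1880s survival (0.73) and
marginal breeding probability (0.37) over hundreds of replicate masked
cohorts. The failure indicator is the one estimator with an inherent
asymmetry: a mother whose observed offspring all died is scored as a
failure at reduced weight even if an untracked sibling survived, so raw
weighted failure proportions sit slightly above the frailty-free closed
form in heavily masked cohorts. This mirrors the estimator's definition,
not a bug, and disappears as completeness approaches 100%.

The standard error of a weighted mean uses the Kish effective sample
size $n_{\text{eff}} = (\sum w)^2 / \sum w^2$:
$\mathrm{SE} = \sqrt{\tfrac{\sum w (v - \bar v_w)^2}{\sum w \,(n_{\text{eff}} - 1)}}$.
The exact formula used for the original published tables is not public;
the Kish form is adopted because it reduces to the classical SE at unit
weights and is invariant to uniform weight rescaling. Published SEs are
therefore *not* treated as reproduction targets. Time-trend correlations
restrict weighted traits to weight-1 (fully tracked) mothers, so the
Pearson coefficient is computed on exact values; with 86.60% survival
completeness on 1947 mothers this gives the characteristic
$df = 1686 - 2 = 1684$.

## The synthetic cohort generator

`default_calibration()` encodes, per first-birth decade: the sample
size, mean and SD of age at first reproduction (SD recovered from the
published standard errors as $SE\sqrt{n}$), mean fertility, offspring
survival probability, and the *marginal* per-offspring breeding
probability. Generation (`generate_cohort()`) proceeds as:

* AFR from a normal truncated below at 15 years, rounded to whole years
  (all ages are year-resolution, matching the printed tables; the
  truncation shifts decade means upward by well under 0.1 years);
* fertility from a zero-truncated Poisson whose mean is the decade mean
  shifted by `afr_fertility_slope` × (AFR − decade mean AFR), floored at
  1. The default slope of −0.15 children/year reproduces the sign and
  rough strength of the within-decade fertility–AFR association; the
  source reports only test statistics for it, so the value is a package
  choice;
* birth years: the first at the first-birth year, later ones at gaps
  uniform on 1–4 whole years (an output of convenience for the trait
  arithmetic, not a calibrated quantity);
* survival to 15: Bernoulli with log-odds
  $\mathrm{logit}(s) + \text{class shift} + \text{family frailty}$.
  Frailty (a family-level normal random intercept, SD `frailty_sd`)
  defaults to 0, which reproduces the independence assumption behind
  $(1-s)^q$; setting it positive lets users reproduce the gap between
  raw failure proportions and the formula (tested at SD 1);
* breeding: among survivors, Bernoulli with conditional probability
  (marginal breeding)/(survival), so the marginal per-offspring breeding
  probability equals the calibrated value; offspring who died before 15
  are confirmed childless.

Class effects (a fertility multiplier and a survival log-odds shift for
non-lower-class mothers) default to *neutral* so that decade marginals
equal the calibration exactly; the class proportions default to the
published 569/1947 lower-class share with the non-lower remainder split
2:1 middle:upper (the split itself is not published). Non-neutral values
are used by the class-collapse simulations. Parish is assigned uniformly
and carries no effect by default.

Record masking (`apply_missingness()`) assigns each mother to a
complete/incomplete/missing stratum per variable (survival:
86.60/11.45/1.95; breeding: 33.74/45.05/21.21), then masks offspring
statuses within incomplete families independently (tracking probability
0.5 by default, constrained to leave at least one observed and one
masked offspring). Masking is MCAR — the weakest mechanism consistent
with the weighting correction. Mothers with a single offspring cannot be
"incomplete"; they exchange stratum labels with a multi-offspring
complete family, preserving both the stratum counts and MCAR-ness with
respect to outcome values. Pre-masking truth is preserved in audit
columns for testing.

What the generator does **not** emulate: within-family correlation of
breeding outcomes, non-random (informative) record loss, migration,
marriage patterns, parish geography, secular trends *within* a decade,
or month-level age arithmetic. Passing tests therefore demonstrate the
estimators' and models' correctness under the stated assumptions, not
robustness of the historical conclusions to, say, informative
missingness.

## Models and simplification

`fit_weighted_glm()` maximizes the weight-multiplied log-likelihood
$\sum_i w_i \log f(y_i \mid x_i, \beta)$ by IRLS (convergence at a
maximum coefficient change below $10^{-8}$, at most 100 iterations;
non-convergence is flagged). Binomial responses may be fractional
proportions — exactly what the weighted estimators produce. Tests pin
the implementation to three independent references: closed forms for
intercept-only models, `stats::glm`/`lm` at matching weights, and a
gradient-based numerical maximizer of the same likelihood (50 random
instances, $10^{-6}$ tolerance).

A maximum model for one association contains the focal covariate
(fertility or AFR), optionally its quadratic on the mean-centred scale
(`center()`; centring is a pure reparameterization — fitted values and
likelihoods are unchanged, which a test verifies), decade (10 levels),
socio-economic class (3 levels), all their interactions, and parish as
an additive control. `backward_stepwise()` repeatedly removes the least
significant *removable* term — one not protected by a retained
higher-order interaction or quadratic — while its LRT p-value exceeds
0.05, with ties broken by reverse lexicographic term name so elimination
logs replay identically. Borderline retention (e.g. a class effect with
a Wald p slightly above 0.05 but a significant LRT) falls out of the
same rule, with no special-casing. After simplification, if `ses_class`
survives only as a main effect, `ses_collapse_check()` tests merging
middle and upper classes into "non-lower" and collapses when the
three-level coding adds nothing at the 5% level.

Two deliberate deviations from the original modelling choices, both
documented here as package design decisions: parish enters as a fixed
effect rather than a random effect (with three levels a variance
component is weakly identified, and nothing else in the package needs
mixed-model machinery), and non-parametric GAM shape exploration is
replaced by the centred quadratic terms that the parametric models use
anyway. Lifetime reproductive success is shifted by +1 before Box-Cox
transformation (`boxcox_select()` maximizes the intercept-only profile
likelihood over exponents −2…2 in steps of 0.01); the shift is recorded
alongside the selected exponent in every model output.

Breeding and LRS analyses exclude mothers with first births in the
1960s–1970s by default (`exclude_recent_breeding`), since their
offspring's reproductive censuses are incomplete; the decade summary
still prints those decades, and the flag can be turned off.

## Numerical choices and problem sizes

* Zero-truncated Poisson rates solve $\lambda/(1-e^{-\lambda}) = \mu$ by
  damped Newton iteration (checked against `uniroot`); sampling uses
  exact quantile inversion. $\mu = 1$ maps to the degenerate
  single-child distribution.
* Quasi-separation (decades with survival near 1) can make the observed
  information singular; Wald SEs are then computed from a
  ridge-stabilized inverse and the fit is flagged, while likelihoods and
  LRTs — which drive the stepwise procedure — are unaffected.
* Degenerate inputs error loudly and specifically: all-zero weights,
  rank-deficient designs, non-nested LRTs, out-of-window first-birth
  years, constant inputs to correlations, non-positive values under a
  Box-Cox shift.
* Test problem sizes are chosen to make Monte-Carlo bands decisive at
  three MC standard errors while keeping the default suite fast:
  200 replicate 1880s cohorts for estimator recovery, $10^6$ draws for
  the ZTP closed form, 1000 null replicates for LRT type-I calibration,
  $10^5$ families for the frailty inflation check, and 30–40 replicates
  for the selection-consistency and class-collapse simulations.
* Under sequential 5%-level testing, backward stepwise keeps a true
  decade effect essentially always, but eliminating *every* spurious
  term simultaneously happens in only roughly half of replicates
  (multiplicity); the tests assert exactly that, rather than a stricter
  rate the procedure cannot deliver.

## Known limitations

The failure-outcome estimator is conservative under heavy masking (see
above). The Box-Cox exponent is selected marginally (intercept-only),
not per fitted model. The generator's uniform 1–4-year birth intervals
reproduce the *scale* of printed birth intervals but not their decade
pattern. Printed decade SEs are not reproduction targets because the
original weighted-SE formula is unpublished. Real register data would
additionally require month-resolution ages and informative-missingness
sensitivity analyses, both out of scope here.
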