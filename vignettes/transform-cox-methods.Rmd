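---
title: "Discovering covariate transformations for Cox models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering covariate transformations for Cox models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symcox)
```

## The problem

The Cox proportional-hazards model

$$h(t \mid x) = h_0(t)\, e^{b_1 x_1 + \dots + b_p x_p}$$

ties a unit change in a covariate to a fixed multiplicative change in the
hazard, $e^{b_j}$, no matter where the change starts: moving serum
creatinine from 1.0 to 1.1 mg/dL is modelled as exactly as dangerous as
moving from 5.0 to 5.1. For many clinical quantities that is wrong in an
interpretable way. Ejection fraction (EF) is the canonical example: a drop
from 30% to 25% matters far more than a drop from 60% to 55%.

Replacing $x$ by a transformed covariate $x_T = f(x)$ keeps the Cox
machinery intact while making the relative hazard origin-dependent:

$$\frac{h'(t)}{h(t)} = e^{\,b\,(f(x+\delta) - f(x))}.$$

`symcox` discovers such an $f$ per covariate by a restricted symbolic
regression: it searches logistic-wrapped expressions
$\hat{Y} = 1/(1 + e^{-f(x)})$ over a small unary function basis
($1/u$, $e^u$, $\log u$, $\sqrt{u}$, plus the identity baseline), scores
them by mean Bernoulli log-loss against the recorded death indicator, and
then fits Cox models on the winning transformed covariates. The package
targets the 299-patient heart-failure cohort (NYHA class III–IV, follow-up
4–285 days) in which this approach selects an exponential of age, the
reciprocal ejection fraction, and the reciprocal serum creatinine.

## The expression family and its canonical form

Every candidate is an affine-wrapped single base,

$$f(x) = a + b\,g(c\,x + d),$$

which is exactly the shape of the published transformations. The family is
redundant as written: for $g \in \{1/u, \log u, \sqrt{u}\}$ the inner scale
$c$ can be absorbed into $(a, b, d)$, and for $g = e^u$ the inner offset
$d$ folds into $b$. `canonicalize()` removes the redundancy — the shifted
bases keep only a sign $c = \pm 1$ and a free offset $d$, the exponential
keeps its growth rate — so the optimizer never wanders along a flat
reparameterization ridge, and every base ends up with three free
parameters (identity: two).

During fitting the inner offset is reparameterized as
$d = -\min(c\,x) + e^{\delta}$ with $\delta \in \mathbb{R}$, which keeps
the base's argument strictly inside its domain for every candidate the
optimizer can express; a hard domain check still runs at evaluation time
and names the offending value.

## Fitting and ranking transformations

`fit_transform()` minimizes the mean log-loss with BFGS using analytic
gradients, 16 random restarts per sign family (both signs are tried for
the shifted bases) drawn from ranges scaled to the data, plus one
deterministic start at the intercept-only solution — which guarantees no
returned fit is ever worse than the constant-probability model. The
incumbent is polished by a restarted BFGS pass; a fit counts as converged
when the gradient infinity norm falls below $10^{-8}$. Restart draws are
seeded per (base, sign), so `search_transforms()` is deterministic and
invariant to the order in which bases are tried. Ranking is by mean
log-loss; ties break alphabetically.

Two caveats are deliberate design positions:

* **Censoring is ignored at this stage.** The binary target is the
  recorded death indicator regardless of follow-up length, replicating the
  published procedure. A subject censored at day 10 counts as a
  "survivor", which biases the per-covariate probability model; the
  subsequent Cox stage, which does handle censoring, is where inference
  happens. Transformation selection should be read as shape selection
  only.
* **Near-boundary identifiability.** Families in this basis overlap: a
  reflected logarithm $\log(d - x)$ with its singularity parked just past
  the sample maximum can imitate an exponential to within $\sim 10^{-3}$
  nats on a truncated covariate such as age. At realistic signal strengths
  the true base wins most samples, but single-sample rankings near the
  truncation boundary are close calls; the test suite therefore asserts
  exponential recovery as a majority across replicate cohorts rather than
  at one seed.

## The study pipeline and its stability guards

`run_study()` chains the stages: Mann–Whitney screening against the death
indicator (tie-corrected normal approximation, 0.5 continuity correction
by default, p-ties broken by name), keep the top 3, search transformations
per kept covariate, then fit transformed and untransformed Cox models on
identical `(time, event)` data and compare C-index, horizon AUC, the
likelihood-ratio statistic and partial AIC.

A nonlinear base replaces the raw covariate only when two guards pass:

* `min_gain` (default $10^{-3}$ nats): the winner must beat the identity
  baseline's log-loss by a minimal margin. Unpenalized search on a
  covariate with no real signal otherwise "wins" by a few $10^{-4}$ nats
  of pure tail overfit.
* `max_spread` (default 10): no transformed value may sit more than 10 SDs
  from the column mean. Degenerate fits that bend only a handful of
  extreme subjects (an exponential with $b \sim 10^{-21}$, a reciprocal
  pole adjacent to the sample minimum) produce columns whose variation
  lives in two or three patients; such columns carry no population signal
  and can make the Cox partial likelihood monotone. Genuine clinical
  transforms in this cohort stay below ~9 SDs.

With the search restricted to the identity basis both arms of the report
are identical, which the tests use as a degenerate-configuration check.

## The Cox solver

`cox_fit()` maximizes the log partial likelihood by Newton–Raphson with
step-halving (up to 20 halvings), Efron's ties correction by default and
Breslow's optionally; the two coincide exactly on untied event times.
Convergence is a score infinity-norm below $10^{-8}$. A monotone partial
likelihood (risk-set separation) is detected when any standardized
coefficient exceeds 50 and is reported as `converged = FALSE` with a
diagnostic rather than silent divergence. The covariance is the inverse
observed information; Wald hazard-ratio tables use
$e^{b \pm z_{\alpha/2}\mathrm{se}}$. The baseline hazard is never
estimated — only relative hazards and rank metrics are used downstream.

On the comparison report the "log-likelihood" of a model is summarized by
the likelihood-ratio statistic $2(\ell_{\text{model}} - \ell_{\text{null}})$,
printed alongside $\ell_{\text{model}}$ and $\ell_{\text{null}}$
themselves. Published comparisons of this cohort print positive
"log-likelihood" values (83.8 and 66.5) which are arithmetically the LR
statistics: both models share one null likelihood
($\ell_{\text{null}} \approx -509.3$ implied by the printed partial AICs),
and the partial-AIC gap equals minus the LR gap at equal coefficient
counts ($958 - 941 \approx 83.8 - 66.5$). The report therefore labels the
LR statistic as the comparable quantity instead of guessing silently.

Units matter for reciprocal EF. The fitted per-covariate expression for EF
uses percent (its pole at $E = 13.5$ sits just below the observed minimum
of 14), but a Cox coefficient of 0.537 on "1/E" is only arithmetically
consistent with EF entered as a fraction: in percent units $1/E$ spans
just $[0.0125, 0.071]$, too narrow to carry a $z$ of 5.6 at that
coefficient size. `hf_transforms()` therefore uses $100/E_{\%}$
(equivalently $1/E_{\text{fraction}}$) for the Cox stage, with the outer
affine constants of the logistic fits dropped because the Cox coefficient
and baseline absorb them.

## Survival metrics

* **Harrell's C** (`concordance_index()`): proportion of admissible pairs
  ordered correctly by the risk score; a pair is admissible when one
  subject's event is observed strictly before the other's follow-up ends
  (or at the same time as the other's censoring); tied scores count 0.5.
  Exhaustive pair enumeration is the test oracle.
* **Horizon AUC** (`auc_at_horizon()`): cumulative/dynamic estimator.
  Cases are events by the horizon, controls are subjects under observation
  at the horizon, subjects censored strictly earlier are excluded; the
  statistic is then the two-sample rank (Mann–Whitney) AUC between the
  groups. An inverse-probability-of-censoring-weighted variant sits behind
  `ipcw = TRUE`. Note that with the horizon at the maximum follow-up time
  of a continuously-censored cohort the control group can shrink to a
  handful of subjects, so synthetic-cohort comparisons in this package use
  an interior horizon (250 days) by convention; published AUCs on the real
  cohort (0.82 vs 0.78 at 285 days) depend on the estimator variant, which
  is why they are treated as soft checks.
* **Kaplan–Meier** (`kaplan_meier()`): product-limit estimate over all
  observed times, Greenwood variance, and a log(−log) 95% band by default
  (linear bands optional). A subject censored at an event time counts as
  at risk through that time. `km_by_stratum()` cuts a covariate into
  half-open bins `(lo, hi]` for figures such as survival stratified by EF.

## The synthetic cohort generator

`generate_cohort()` exists so that every pipeline stage can be exercised,
and parameter recovery proven, without the clinical data file. Its
defaults are fixed at the study conditions:

* n = 299; covariates drawn independently with marginals matched to the
  cohort's baseline table — age and EF as range-truncated normals
  ([40, 95] and [14, 80]) whose underlying parameters are solved so the
  *truncated* draws reproduce the published mean/SD (60.8/11.9 and
  38.1/11.8; naive truncation would shift the age mean to ~61.5);
  creatinine and CPK as moment-matched log-normals (both strongly
  right-skewed); sodium and platelets as normals (platelets truncated at
  zero); binaries as Bernoulli at the published prevalences.
* Event times from the proportional-hazards mechanism itself: latent death
  time exponential with rate
  $\lambda_0 \exp(\sum_j \beta_j f_j(x_j))$, with the three reference
  transformations and their published coefficients (0.014 on
  $e^{0.056A}$, 0.537 on $100/E$, −1.515 on $1/C$) as ground truth.
  The constant baseline (exponential) is chosen for invertibility; Cox
  estimation is baseline-agnostic, so recovery tests are unaffected.
* Administrative censoring uniform on [4, 285] days, mirroring the
  observed follow-up range; the real cohort's censoring law is not
  published, so uniform is a declared assumption.
* $\lambda_0 = 0.00131935$/day, calibrated once by
  `calibrate_baseline_rate()` (bisection on a 50,000-subject simulation
  with the latent exponential draws held fixed, making the event fraction
  exactly monotone in the rate) against the cohort's 32.1% death share.

What the generator does *not* emulate: covariate correlations (the
baseline table gives none; age–EF–creatinine dependence in real patients
is nonzero), integer-day follow-up times, informative censoring, and
measurement heaping (EF recorded in steps of 5). Passing recovery tests
on this generator therefore demonstrate correctness of the estimators and
the search under the stated mechanism — not that the discovered
transformations are clinically optimal for any real cohort. At n = 299
the screening stage is honest about sampling noise: in some synthetic
replicates age (true but weak, hazard spread ~2.7× across the range)
fails to reach the top 3, just as a real 299-patient sample may misrank
weak risk factors.

## Numerical choices, sizes and limitations

Tolerances: $10^{-8}$ gradient norms for both optimizers; $10^{-4}$
agreement with a brute-force grid for the Cox coefficient oracle; exact
agreement with pair-enumeration oracles for U, C and AUC; quartiles by
linear interpolation (type 7); SDs with the $n-1$ denominator. Test
problem sizes were chosen to keep the full suite in a few minutes on one
CPU: pair-enumeration oracles at n = 20–40, solver cross-checks at
n = 400–500, recovery at n = 5000 with 4–6 restarts per base, the
pipeline acceptance example at n = 2000.

Known limitations: single-covariate expressions only (no interactions, no
nested compositions — matching the restricted search the package
replicates); no baseline-hazard estimate, hence no absolute risk
prediction; the per-covariate search's censoring blindness above; and the
deposited clinical CSV must be supplied by the user (place it at
`inst/extdata/heart_failure_clinical_records.csv`) for the real-data
reproduction tests, since it is not redistributable with the package.
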