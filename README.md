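# symcox

Nonlinear covariate transformations for Cox proportional-hazards models,
discovered by restricted symbolic regression — with a from-scratch survival
stack (Cox partial likelihood with Efron/Breslow ties, Harrell's C-index,
time-horizon ROC AUC, Kaplan–Meier with Greenwood bands, Mann–Whitney
screening) and a synthetic heart-failure cohort generator so the whole
pipeline is testable without any data download.

## The problem

In a Cox model `h(t|x) = h0(t) · exp(b'x)`, a unit change in a covariate
multiplies the hazard by `exp(b)` regardless of where the change starts:
a serum-creatinine rise from 1.0 to 1.1 mg/dL is modelled as exactly as
dangerous as one from 5.0 to 5.1. Clinically that is often wrong. Replacing
a covariate by a transformed version `f(x)` keeps the Cox machinery but
makes the relative hazard origin-dependent:

    h'(t) / h(t) = exp( b · (f(x + δ) − f(x)) )

`symcox` finds such an `f` per covariate by searching logistic-wrapped
expressions `P(death|x) = 1 / (1 + exp(−f(x)))` with
`f(x) = a + b·g(c·x + d)` over the unary basis `1/u`, `exp(u)`, `log(u)`,
`sqrt(u)` (plus an identity baseline), ranked by mean log-loss against the
death indicator. The transformed covariates then feed a Cox model, which is
compared head-to-head against the untransformed model on C-index, horizon
AUC, likelihood-ratio statistic and partial AIC.

The package is built around the public 299-patient heart-failure cohort
(NYHA III–IV, follow-up 4–285 days), for which this approach selects an
exponential of age (`exp(0.056·age)`), the reciprocal ejection fraction and
the reciprocal serum creatinine as risk factors. Audience: biostatisticians
and clinical-ML researchers who want interpretable nonlinearity in survival
regression rather than a black-box risk score.

## Worked example

```r
library(symcox)

# a synthetic cohort at the study conditions (n = 299, Table-style
# marginals, proportional-hazards event times, ~32% deaths)
cohort <- generate_cohort(simulation_config(n = 299, seed = 1))

# full pipeline with the reference transformations applied
report <- run_study(cohort, transforms = hf_transforms(),
                    horizon = 250, seed = 1)
print(report, digits = 3)
```

```
== Covariate-transformation study ==
cohort: n = 299, events = 94; AUC horizon = 250 days; ties = efron

-- screening (Mann-Whitney U vs death indicator) --
           covariate     u       z        p n_event n_no_event rank
1   serum_creatinine 13358  5.3632 8.18e-08      94        205    1
2  ejection_fraction  6693 -4.2380 2.26e-05      94        205    2
3          platelets 10999  1.9645 4.95e-02      94        205    3
...

-- transformed model --
                     term      coef    hr hr_lower hr_upper      z        p
1    1/(serum_creatinine) -1.19e+00 0.305    0.195    0.477 -5.199 2.00e-07
2 100/(ejection_fraction)  4.94e-01 1.638    1.392    1.929  5.927 3.09e-09
3               platelets  8.95e-07 1.000    1.000    1.000  0.813 4.16e-01

-- comparison --
          model c_index auc_horizon ll_model ll_null lr_statistic partial_aic
1   transformed   0.717       0.846     -447    -480         64.4         901
2 untransformed   0.692       0.755     -458    -480         44.0         921
```

Reading it: screening ranks covariates by Mann–Whitney association with
death (at n = 299 the weak age effect happens to miss the top 3 in this
replicate — honest sampling noise). The transformed arm beats the
untransformed arm on every metric: higher concordance (0.717 vs 0.692),
higher 250-day AUC (0.846 vs 0.755), larger likelihood-ratio statistic
(64.4 vs 44.0) and smaller partial AIC (901 vs 921), using the same three
covariates — the entire gain comes from the transformations. The hazard
ratio 0.305 on `1/creatinine` means a *higher* reciprocal (i.e. healthier,
lower creatinine) cuts the hazard; because `1/x` flattens at high `x`, the
same creatinine increment matters far more in a near-normal patient than
in one already at 5 mg/dL.

Other entry points: `search_transforms(x, y)` ranks the bases for one
covariate; `fit_transform()` fits one base; `cox_fit()`, `wald_summary()`,
`tidy()`/`glance()` for the survival model; `kaplan_meier()` /
`km_by_stratum()` with `autoplot()` for survival curves;
`concordance_index()`, `auc_at_horizon()` for metrics;
`calibrate_baseline_rate()` and `write_sim_config()` for the simulator.
A thin CLI over these functions ships at `inst/cli/symcox.R`
(subcommands `run`, `screen`, `search`, `fit`, `km`, `simulate`).

## Method details

See the methods vignette
(`vignettes/transform-cox-methods.Rmd`) for the expression family and its
canonical parameterization, optimizer and convergence choices, the
stability guards on transformation adoption, ties handling, the horizon-AUC
estimator, the generator's calibration, and known limitations.
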