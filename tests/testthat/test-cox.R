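test_that("toy-data coefficient matches a 1-D grid/optimize search of the partial likelihood", {
  # six subjects, one binary covariate, untied times
  x <- c(1, 0, 1, 0, 1, 0)
  time <- c(2, 4, 6, 9, 11, 13)
  event <- c(1, 1, 0, 1, 1, 0)
  fit <- cox_fit(matrix(x, dimnames = list(NULL, "grp")), time, event)

  bhat <- stats::optimize(function(b) oracle_cox_ll(b, x, time, event),
                          c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(coef(fit)), bhat$maximum, tolerance = 1e-4)
  expect_equal(fit$ll_model, bhat$objective, tolerance = 1e-10)
  expect_equal(fit$ll_null, oracle_cox_ll(0, x, time, event))
  expect_true(fit$converged)

  # Wald SE against the curvature of the independent likelihood formula
  se_num <- 1 / sqrt(-oracle_d2(function(b) oracle_cox_ll(b, x, time, event),
                                unname(coef(fit))))
  expect_equal(unname(fit$se), se_num, tolerance = 1e-3)
})

test_that("fits agree with survival::coxph under both ties corrections", {
  coh <- generate_cohort(simulation_config(n = 500, seed = 8))
  coh$time <- ceiling(coh$time)  # force heavy ties, as in day-resolution data
  X <- as.matrix(coh[, c("age", "ejection_fraction", "serum_creatinine")])
  for (ties in c("efron", "breslow")) {
    ours <- cox_fit(X, coh$time, coh$event, ties = ties)
    ref <- survival::coxph(
      survival::Surv(time, event) ~ age + ejection_fraction + serum_creatinine,
      data = coh, ties = ties)
    expect_equal(coef(ours), coef(ref), tolerance = 1e-7)
    expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
    expect_equal(ours$ll_model, ref$loglik[2], tolerance = 1e-8)
    expect_equal(ours$ll_null, ref$loglik[1], tolerance = 1e-8)
  }
})

test_that("likelihood identities hold: lr >= 0, aic bookkeeping, efron=breslow untied", {
  coh <- toy_cohort(n = 60, seed = 5)
  coh$time <- coh$time + seq_len(60) / 97  # break all ties
  X <- as.matrix(coh[, c("age", "serum_creatinine")])
  fe <- cox_fit(X, coh$time, coh$event, ties = "efron")
  fb <- cox_fit(X, coh$time, coh$event, ties = "breslow")
  expect_equal(coef(fe), coef(fb), tolerance = 1e-10)
  expect_equal(fe$ll_model, fb$ll_model, tolerance = 1e-10)

  expect_gte(fe$lr_statistic, 0)
  expect_gte(fe$ll_model, fe$ll_null)
  expect_equal(fe$lr_statistic, 2 * (fe$ll_model - fe$ll_null))
  expect_equal(fe$partial_aic, -2 * fe$ll_model + 2 * ncol(X))
  expect_equal(glance(fe)$partial_aic, fe$partial_aic)

  # covariance is symmetric positive definite
  expect_equal(fe$vcov, t(fe$vcov))
  expect_true(all(eigen(fe$vcov, symmetric = TRUE)$values > 0))
})

test_that("rescaling a covariate rescales its coefficient and changes no metric", {
  coh <- generate_cohort(simulation_config(n = 400, seed = 13))
  X1 <- as.matrix(coh[, c("age", "ejection_fraction", "serum_creatinine")])
  X2 <- X1
  X2[, "age"] <- (X2[, "age"] - 60) / 12
  f1 <- cox_fit(X1, coh$time, coh$event)
  f2 <- cox_fit(X2, coh$time, coh$event)
  expect_equal(coef(f2)[["age"]], coef(f1)[["age"]] * 12, tolerance = 1e-8)
  expect_equal(f1$ll_model, f2$ll_model, tolerance = 1e-8)
  expect_equal(f1$lr_statistic, f2$lr_statistic, tolerance = 1e-8)
  r1 <- predict(f1, X1); r2 <- predict(f2, X2)
  expect_equal(concordance_index(r1, coh$time, coh$event),
               concordance_index(r2, coh$time, coh$event), tolerance = 1e-8)
  expect_equal(auc_at_horizon(r1, coh$time, coh$event, 200),
               auc_at_horizon(r2, coh$time, coh$event, 200), tolerance = 1e-8)
})

test_that("score test at b = 0 reproduces the log-rank statistic for a binary covariate", {
  coh <- toy_cohort(n = 30, seed = 17)
  coh$time <- coh$time + seq_len(30) / 53  # untied
  x <- matrix(coh$sex, dimnames = list(NULL, "sex"))
  prep <- symcox:::cox_prepare(x, coh$time, coh$event)
  s0 <- symcox:::cox_loglik(0, prep, "efron")
  score_stat <- s0$grad^2 / s0$info[1, 1]
  lr <- survival::survdiff(survival::Surv(time, event) ~ sex, data = coh)
  expect_equal(as.numeric(score_stat), lr$chisq, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected and separation is flagged, not diverged", {
  coh <- toy_cohort(n = 20, seed = 23)
  Xc <- cbind(age = coh$age, flat = rep(1, 20))
  expect_error(cox_fit(Xc, coh$time, coh$event), "flat",
               class = "symcox_error_constant")
  expect_error(cox_fit(matrix(coh$age, dimnames = list(NULL, "age")),
                       coh$time, rep(0, 20)), "events")
  expect_error(cox_fit(matrix(coh$age, dimnames = list(NULL, "age")),
                       -coh$time, coh$event), "positive")

  # risk sets separate perfectly: earlier deaths always have higher x
  n <- 20
  time <- seq_len(n)
  event <- rep(1, n)
  x <- matrix(-time + withr::with_seed(1, stats::rnorm(n, 0, 1e-6)),
              dimnames = list(NULL, "x"))
  fit <- cox_fit(x, time, event)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "monotone|separate")
  expect_error(wald_summary(fit), class = "symcox_error_converge")
})

test_that("wald summary, tidiers and relative hazards are internally consistent", {
  coh <- generate_cohort(simulation_config(n = 400, seed = 29))
  X <- as.matrix(coh[, c("age", "serum_creatinine")])
  fit <- cox_fit(X, coh$time, coh$event)
  w <- wald_summary(fit, conf_level = 0.95)
  expect_equal(w$hr, exp(w$coef))
  expect_true(all(w$hr_lower < w$hr & w$hr < w$hr_upper))
  expect_equal(w$z, w$coef / unname(fit$se))
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))

  td <- tidy(fit)
  expect_identical(td$term, w$term)
  expect_equal(td$estimate, w$coef)
  expect_equal(exp(td$conf.low), w$hr_lower)
  td_hr <- tidy(fit, exponentiate = TRUE)
  expect_equal(td_hr$estimate, w$hr)

  # untransformed relative hazard is origin-independent; delta = 0 is exactly 1
  b <- coef(fit)[["serum_creatinine"]]
  expect_equal(relative_hazard(fit, "serum_creatinine", 1.0, 0.1),
               relative_hazard(fit, "serum_creatinine", 5.0, 0.1))
  expect_equal(relative_hazard(fit, "serum_creatinine", 1.0, 0.1), exp(0.1 * b))
  expect_equal(relative_hazard(fit, "age", 60, 0), 1)

  # transformed relative hazard depends on the origin: hand arithmetic for 1/x
  inv <- transform_spec("inverse")
  rh_low <- relative_hazard(fit, "serum_creatinine", 20, 5, transform = inv)
  rh_high <- relative_hazard(fit, "serum_creatinine", 60, 5, transform = inv)
  expect_equal(rh_low, exp(b * (1 / 25 - 1 / 20)))
  expect_equal(rh_high, exp(b * (1 / 65 - 1 / 60)))
  # with b < 0 here, 1/x falling faster at low x makes the low-origin change larger
  expect_gt(abs(log(rh_low)), abs(log(rh_high)))
  expect_error(relative_hazard(fit, "cpk", 1, 1), "not in the model")
})
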