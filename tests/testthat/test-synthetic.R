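test_that("generation is bit-identical for a fixed seed and leaves the caller's RNG alone", {
  cfg <- simulation_config(n = 200, seed = 101)
  a <- generate_cohort(cfg)
  set.seed(999)
  before <- .Random.seed
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(.Random.seed, before)
  expect_identical(runif(1), withr::with_seed(999, runif(1)))

  empty <- generate_cohort(simulation_config(n = 0, seed = 1))
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), cohort_columns())
})

test_that("marginals reproduce the baseline-table moments at n = 10000", {
  coh <- generate_cohort(simulation_config(n = 10000, seed = 103))
  se3 <- function(sd) 3 * sd / sqrt(10000)
  expect_lt(abs(mean(coh$age) - 60.8), se3(11.9))
  expect_lt(abs(mean(coh$ejection_fraction) - 38.1), se3(11.8))
  expect_lt(abs(mean(coh$serum_creatinine) - 1.4), se3(1.0))
  expect_lt(abs(mean(coh$serum_sodium) - 136.6), se3(4.4))
  expect_lt(abs(mean(coh$sex) - 0.649), se3(0.48))
  expect_true(all(coh$age >= 40 & coh$age <= 95))
  expect_true(all(coh$ejection_fraction >= 14 & coh$ejection_fraction <= 80))
  # default baseline rate was calibrated to the 32.1% death share
  expect_lt(abs(mean(coh$event) - 0.321), 0.02)
  expect_silent(validate_cohort(coh))
})

test_that("null coefficients give null-consistent Cox z statistics (permutation check)", {
  cfg <- simulation_config(n = 1200, seed = 107, true_transforms = list(),
                           true_betas = c(), baseline_rate = 0.004)
  coh <- generate_cohort(cfg)
  X <- as.matrix(coh[, c("age", "ejection_fraction", "serum_creatinine")])
  zval <- function(Xm) {
    f <- cox_fit(Xm, coh$time, coh$event)
    max(abs(coef(f) / f$se))
  }
  z_obs <- zval(X)
  z_perm <- withr::with_seed(11, {
    vapply(1:60, function(i) zval(X[sample(nrow(X)), , drop = FALSE]),
           numeric(1))
  })
  # observed max |z| should be unremarkable among permutation replicates
  expect_gt(mean(z_perm >= z_obs), 0.02)
})

test_that("the event fraction is monotone in the baseline rate and reaches 1 in the limit", {
  fracs <- vapply(c(5e-4, 2e-3, 8e-3, 5e-2), function(r) {
    mean(generate_cohort(simulation_config(n = 3000, seed = 109,
                                           baseline_rate = r))$event)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  everyone <- generate_cohort(simulation_config(n = 500, seed = 109,
                                                baseline_rate = 1e4))
  expect_equal(mean(everyone$event), 1)
})

test_that("baseline-rate calibration hits its target and rejects bad brackets", {
  cfg <- simulation_config(n = 299, seed = 113)
  rate <- calibrate_baseline_rate(cfg, 0.321, n_sim = 20000, tol = 0.005)
  check <- generate_cohort(simulation_config(n = 20000, seed = 127,
                                             baseline_rate = as.numeric(rate)))
  expect_lt(abs(mean(check$event) - 0.321), 0.01)

  expect_error(
    calibrate_baseline_rate(cfg, 0.99, bounds = c(1e-7, 2e-7), n_sim = 2000),
    class = "symcox_error_bracket")
  expect_error(calibrate_baseline_rate(cfg, 1.2), "strictly in")
})

test_that("a known 1/x effect is recovered by a Cox fit on the true transformed scale", {
  cfg <- simulation_config(
    n = 5000, seed = 131,
    true_transforms = list(serum_creatinine = transform_spec("inverse")),
    true_betas = c(serum_creatinine = -1.5),
    baseline_rate = 0.004
  )
  coh <- generate_cohort(cfg)
  xt <- matrix(1 / coh$serum_creatinine, dimnames = list(NULL, "inv_creat"))
  fit <- cox_fit(xt, coh$time, coh$event)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[[1]] - (-1.5)), 3 * fit$se[[1]])
})

test_that("an undefined true transform on a drawn value errors informatively", {
  cfg <- simulation_config(
    n = 50, seed = 137,
    true_transforms = list(age = transform_spec("log", d = -100)),
    true_betas = c(age = 1)
  )
  expect_error(generate_cohort(cfg), "age", class = "symcox_error_domain")
})

test_that("simulation configs round-trip through the key = value text format", {
  cfg <- simulation_config(n = 123, seed = 7, baseline_rate = 0.0021,
                           censor_window = c(10, 200))
  path <- withr::local_tempfile(fileext = ".cfg")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n, cfg$n)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$baseline_rate, cfg$baseline_rate)
  expect_equal(back$censor_window, cfg$censor_window)
  expect_equal(back$true_betas, cfg$true_betas)
  expect_equal(back$covariate_params, cfg$covariate_params)
  expect_identical(purrr::map(back$true_transforms, unclass),
                   purrr::map(cfg$true_transforms, unclass))
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})
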