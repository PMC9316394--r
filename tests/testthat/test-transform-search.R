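test_that("the identity-base fit equals ordinary logistic regression", {
  withr::with_seed(139, {
    x <- rnorm(400, 1, 2)
    y <- rbinom(400, 1, plogis(0.8 * x - 0.5))
  })
  fit <- fit_transform(x, y, "identity", n_restarts = 4, seed = 2)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_true(fit$converged)
  expect_equal(fit$spec$a, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(fit$spec$b, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(fit$mean_log_loss,
               -mean(y * log(fitted(ref)) + (1 - y) * log(1 - fitted(ref))),
               tolerance = 1e-9)
})

test_that("a planted reciprocal signal is recovered with near-true predictions", {
  withr::with_seed(149, {
    x <- runif(5000, 0.5, 5)
    y <- rbinom(5000, 1, plogis(2 / x - 1))
  })
  fit <- fit_transform(x, y, "inverse", n_restarts = 6, seed = 3)
  expect_true(fit$converged)

  # the truth lies in the family, so the fit cannot be worse on the sample
  truth <- transform_spec("inverse", a = -1, b = 2, c = 1, d = 0)
  mll_truth <- -mean(y * log(predict_probability(truth, x)) +
                     (1 - y) * log(1 - predict_probability(truth, x)))
  expect_lte(fit$mean_log_loss, mll_truth + 1e-9)

  # fitted probabilities track the generating curve
  grid <- seq(0.6, 4.9, length.out = 50)
  expect_lt(max(abs(predict_probability(fit$spec, grid) - plogis(2 / grid - 1))),
            0.05)

  # profile-grid oracle: no (a, b) near the optimum beats the optimizer
  d_hat <- fit$spec$d
  s_hat <- fit$spec$c
  grid_mll <- outer(
    seq(fit$spec$a - 0.5, fit$spec$a + 0.5, length.out = 21),
    seq(fit$spec$b - 0.5, fit$spec$b + 0.5, length.out = 21),
    Vectorize(function(a, b) {
      sp <- transform_spec("inverse", a = a, b = b, c = s_hat, d = d_hat)
      p <- predict_probability(sp, x)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    })
  )
  expect_lte(fit$mean_log_loss, min(grid_mll) + 1e-8)
})

test_that("no fitted base ever loses to the intercept-only model", {
  withr::with_seed(151, {
    for (i in 1:5) {
      x <- exp(rnorm(80, 1, 0.7))
      y <- rbinom(80, 1, 0.2 + 0.5 * (x > median(x)))
      entropy <- -mean(y) * log(mean(y)) - (1 - mean(y)) * log(1 - mean(y))
      s <- search_transforms(x, y, n_restarts = 3, seed = i)
      expect_true(all(s$mean_log_loss <= entropy + 1e-6))
      expect_true(all(s$mean_log_loss >= 0))
    }
  })
})

test_that("search results are deterministic and invariant to base order", {
  withr::with_seed(157, {
    x <- runif(300, 1, 10)
    y <- rbinom(300, 1, plogis(1 - 3 / x))
  })
  s1 <- search_transforms(x, y, bases = c("inverse", "exp", "log", "sqrt"),
                          n_restarts = 4, seed = 5)
  s2 <- search_transforms(x, y, bases = c("sqrt", "log", "exp", "inverse"),
                          n_restarts = 4, seed = 5)
  expect_equal(tibble::as_tibble(s1), tibble::as_tibble(s2))
  s3 <- search_transforms(x, y, bases = c("inverse", "exp", "log", "sqrt"),
                          n_restarts = 4, seed = 5)
  expect_equal(tibble::as_tibble(s1), tibble::as_tibble(s3))
  # identity baseline always present and ranks carry 1..k
  expect_true("identity" %in% s1$base)
  expect_identical(s1$rank, seq_len(nrow(s1)))
  expect_true(!is.unsorted(s1$mean_log_loss))
})

test_that("degenerate and invalid inputs are handled explicitly", {
  y <- rep(c(0, 1), 10)
  x <- rep(2, 20)
  fit <- fit_transform(x, y, "log", n_restarts = 2, seed = 1)
  # constant covariate: the fit degrades to the outcome-rate entropy
  expect_equal(fit$mean_log_loss, log(2), tolerance = 1e-6)

  expect_error(fit_transform(1:20, rep(1, 20), "exp"),
               class = "symcox_error_single_class")
  expect_error(fit_transform(1:5, rep(c(0, 1), 2)[1:5], "exp"), "10")
  expect_error(search_transforms(1:20, y, bases = character(0)), "nonempty")
  expect_error(search_transforms(1:20, y, bases = "cosine"), "unknown")
})

test_that("a planted log-shaped signal ranks the log base first at n = 5000", {
  withr::with_seed(163, {
    x <- runif(5000, 0.2, 20)
    y <- rbinom(5000, 1, plogis(1.5 * log(x) - 1.5))
  })
  s <- search_transforms(x, y, n_restarts = 6, seed = 7)
  expect_identical(s$base[1], "log")
})
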