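test_that("identity spec reproduces its input and printed forms match hand arithmetic", {
  id <- transform_spec("identity", a = 0, b = 1)
  x <- c(-3, 0, 2.5, 40)
  expect_identical(evaluate(id, x), x)

  # exponential-of-age form: f(A) = 0.02 * exp(0.056 A) - 1.5
  age_spec <- transform_spec("exp", a = -1.5, b = 0.02, c = 0.056, d = 0)
  expect_equal(evaluate(age_spec, 40), 0.02 * exp(0.056 * 40) - 1.5)
  expect_equal(evaluate(age_spec, 95), 0.02 * exp(0.056 * 95) - 1.5)

  # reciprocal ejection-fraction form at the cohort mean EF
  ef_spec <- transform_spec("inverse", a = -2.1, b = 1.6, c = 0.066, d = -0.89)
  expect_equal(evaluate(ef_spec, 38.1), -2.1 + 1.6 / (0.066 * 38.1 - 0.89))

  # reciprocal creatinine form
  cr_spec <- transform_spec("inverse", a = 1.5, b = -0.91, c = 0.42, d = -0.084)
  expect_equal(evaluate(cr_spec, 1.1), 1.5 - 0.91 / (0.42 * 1.1 - 0.084))
})

test_that("logistic wrapper is a probability strictly in (0,1), monotone in f", {
  zero <- transform_spec("identity", a = 0, b = 0)
  expect_equal(predict_probability(zero, c(1, 10, 100)), rep(0.5, 3))

  age_spec <- transform_spec("exp", a = -1.5, b = 0.02, c = 0.056, d = 0)
  ages <- seq(40, 95, by = 5)
  p <- predict_probability(age_spec, ages)
  expect_true(all(p > 0 & p < 1))
  # f is increasing in age here, so the wrapped probability must be too
  expect_true(all(diff(p) > 0))
  expect_equal(p, plogis(0.02 * exp(0.056 * ages) - 1.5))

  # extreme f values stay inside the open interval
  big <- transform_spec("identity", a = 0, b = 1000)
  expect_true(all(predict_probability(big, c(-5, 5)) > 0))
  expect_true(all(predict_probability(big, c(-5, 5)) < 1))
})

test_that("string serialization round-trips exactly over random specs", {
  withr::with_seed(42, {
    for (i in 1:40) {
      base <- sample(c("identity", "inverse", "exp", "log", "sqrt"), 1)
      spec <- if (base == "identity") {
        transform_spec("identity", a = runif(1, -5, 5), b = runif(1, -5, 5))
      } else {
        transform_spec(base,
                       a = runif(1, -5, 5), b = runif(1, -5, 5),
                       c = runif(1, -3, 3) + 4, d = runif(1, -5, 5))
      }
      txt <- format_transform(spec)
      expect_identical(unclass(parse_transform(txt)), unclass(spec))
    }
    # a non-canonical identity parses back to its canonical equivalent
    nc <- transform_spec("identity", a = 2, b = 3, c = 4, d = -1)
    x <- runif(10, -2, 2)
    expect_equal(evaluate(parse_transform(format_transform(nc)), x),
                 evaluate(nc, x))
  })
  # field-style strings parse too
  p <- parse_transform("-2.1 + 1.6/(0.066*x - 0.89)")
  expect_identical(p$base, "inverse")
  expect_equal(evaluate(p, 38.1), -2.1 + 1.6 / (0.066 * 38.1 - 0.89))
  p2 <- parse_transform("0.02*exp(0.056*A) - 1.5", var = "A")
  expect_identical(p2$base, "exp")
  expect_equal(evaluate(p2, 60), 0.02 * exp(0.056 * 60) - 1.5)
})

test_that("canonicalization keeps predictions identical to 1e-10", {
  x <- seq(15, 80, length.out = 50)
  specs <- list(
    transform_spec("inverse", a = -2.1, b = 1.6, c = 0.066, d = -0.89),
    transform_spec("log", a = 1, b = -2, c = 3, d = 5),
    transform_spec("sqrt", a = 0.5, b = 2, c = 0.25, d = 1),
    transform_spec("exp", a = -1.5, b = 0.02, c = 0.056, d = 0.3),
    transform_spec("identity", a = 2, b = 3, c = 4, d = -1)
  )
  for (spec in specs) {
    can <- canonicalize(spec)
    expect_lt(max(abs(evaluate(can, x) - evaluate(spec, x))), 1e-10)
    if (can$base %in% c("inverse", "log", "sqrt")) {
      expect_true(can$c %in% c(-1, 1))
    }
    if (can$base %in% c("exp", "identity")) expect_identical(can$d, 0)
  }
})

test_that("out-of-domain evaluation errors name the offending value", {
  lg <- transform_spec("log", a = 0, b = 1, c = 1, d = 0)
  expect_error(evaluate(lg, c(2, -3)), "-3", class = "symcox_error_domain")
  inv <- transform_spec("inverse", a = 0, b = 1, c = 1, d = -5)
  expect_error(evaluate(inv, 5), class = "symcox_error_domain")
  sq <- transform_spec("sqrt", a = 0, b = 1, c = 1, d = 0)
  expect_error(evaluate(sq, -1), class = "symcox_error_domain")
  expect_silent(evaluate(sq, 0))  # sqrt is defined at zero
})

test_that("key-value records round-trip", {
  spec <- transform_spec("log", a = 1.25, b = -0.5, c = -1, d = 7)
  rec <- transform_record(spec)
  expect_identical(rec$base, "log")
  expect_identical(unclass(transform_from_record(rec)), unclass(spec))
})
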