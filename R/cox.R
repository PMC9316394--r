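#' Cox proportional-hazards fit by partial likelihood
#'
#' Fits the proportional-hazards model `h(t) = h0(t) * exp(b'x)` by
#' maximizing the log partial likelihood with Newton-Raphson and
#' step-halving. Tied event times are handled by the Efron correction by
#' default (Breslow optional); the two agree exactly when no event times are
#' tied. The baseline hazard is left unestimated: only relative hazards and
#' rank-based metrics are needed downstream.
#'
#' Convergence is declared when the infinity norm of the score vector drops
#' below `tol`. A monotone partial likelihood (complete separation of risk
#' sets) is detected by divergence of the standardized coefficients and
#' reported through `converged = FALSE` plus a diagnostic message rather
#' than a silent runaway.
#'
#' @param covariates Numeric matrix or data frame of covariates (one column
#'   per term, named). Constant columns are an error.
#' @param time Positive follow-up times.
#' @param event Death indicator, 0/1.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the score infinity norm.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `cox_model`: a list with `coefficients`,
#'   `se`, `vcov` (inverse observed information), `ll_model`, `ll_null`,
#'   `lr_statistic` (`2 * (ll_model - ll_null)`), `partial_aic`
#'   (`-2 * ll_model + 2 * k`), `n`, `n_events`, `ties`, `converged`,
#'   `iterations`, and `diagnostic`.
#' @seealso [wald_summary()], [tidy.cox_model()], [concordance_index()]
#' @export
cox_fit <- function(covariates, time, event,
                    ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (!is.numeric(X)) stop_symcox("`covariates` must be numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  time <- as.numeric(time); event <- as.numeric(event)
  n <- nrow(X); p <- ncol(X)
  if (length(time) != n || length(event) != n) {
    stop_symcox("`covariates`, `time` and `event` must have matching lengths")
  }
  if (anyNA(X) || anyNA(time) || anyNA(event)) {
    stop_symcox("missing values are not allowed")
  }
  if (any(time <= 0)) stop_symcox("`time` must be strictly positive")
  if (!all(event %in% c(0, 1))) stop_symcox("`event` must be 0/1")
  sdx <- apply(X, 2L, stats::sd)
  if (any(sdx == 0)) {
    stop_symcox(sprintf("constant covariate column(s): %s",
                        paste(colnames(X)[sdx == 0], collapse = ", ")),
                class = "symcox_error_constant")
  }
  n_events <- sum(event)
  if (n_events < p) {
    stop_symcox(sprintf("need at least as many events (%d) as coefficients (%d)",
                        n_events, p))
  }

  prep <- cox_prepare(X, time, event)
  beta <- rep(0, p)
  state <- cox_loglik(beta, prep, ties)
  ll_null <- state$ll
  converged <- FALSE
  diagnostic <- NA_character_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(state$grad)) < tol) { converged <- TRUE; break }
    delta <- tryCatch(solve(state$info, state$grad), error = function(e) NULL)
    if (is.null(delta)) {
      diagnostic <- "observed information is singular"
      break
    }
    step <- 1
    for (h in seq_len(21L)) {
      cand <- beta + step * delta
      cand_state <- cox_loglik(cand, prep, ties)
      if (is.finite(cand_state$ll) && cand_state$ll >= state$ll - 1e-12) break
      step <- step / 2
    }
    beta <- cand
    state <- cand_state
    if (any(abs(beta) * sdx > 50)) {
      diagnostic <- "monotone partial likelihood: coefficients diverge (risk sets separate)"
      break
    }
  }
  if (!converged && max(abs(state$grad)) < tol) converged <- TRUE
  if (!converged && is.na(diagnostic)) {
    diagnostic <- sprintf("score norm %.3g after %d iterations", max(abs(state$grad)), iter)
  }
  vcov <- tryCatch(solve(state$info), error = function(e) matrix(NA_real_, p, p))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  ll_model <- state$ll
  structure(
    list(
      coefficients = setNames(as.numeric(beta), colnames(X)),
      se = setNames(sqrt(pmax(diag(vcov), 0)), colnames(X)),
      vcov = vcov,
      ll_model = ll_model,
      ll_null = ll_null,
      lr_statistic = 2 * (ll_model - ll_null),
      partial_aic = -2 * ll_model + 2 * p,
      n = n, n_events = n_events,
      ties = ties,
      converged = converged,
      iterations = iter,
      diagnostic = diagnostic,
      covariate_names = colnames(X)
    ),
    class = "cox_model"
  )
}

# sort once, descending in time, and index risk sets / tie groups
cox_prepare <- function(X, time, event) {
  o <- order(time, decreasing = TRUE)
  Xo <- X[o, , drop = FALSE]
  to <- time[o]
  eo <- event[o]
  ev_times <- sort(unique(to[eo == 1]))
  groups <- lapply(ev_times, function(t) which(eo == 1 & to == t))
  risk_k <- vapply(ev_times, function(t) sum(to >= t), integer(1))
  p <- ncol(Xo)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  list(X = Xo, p = p, groups = groups, risk_k = risk_k, pairs = pairs)
}

cox_loglik <- function(beta, prep, ties) {
  X <- prep$X; p <- prep$p
  eta <- drop(X %*% beta)
  eta_c <- eta - max(eta)          # centering cancels in ll up to a constant shift
  w <- exp(eta_c)
  cw0 <- cumsum(w)
  wX <- X * w
  cw1 <- apply(wX, 2L, cumsum)
  if (is.null(dim(cw1))) cw1 <- matrix(cw1, nrow = 1L)
  np <- nrow(prep$pairs)
  cw2 <- matrix(0, nrow(X), np)
  for (m in seq_len(np)) {
    j <- prep$pairs[m, 1L]; l <- prep$pairs[m, 2L]
    cw2[, m] <- cumsum(wX[, j] * X[, l])
  }
  ll <- 0
  grad <- rep(0, p)
  info <- matrix(0, p, p)
  expand_s2 <- function(v) {
    s2 <- matrix(0, p, p)
    s2[cbind(prep$pairs[, 1L], prep$pairs[, 2L])] <- v
    s2[cbind(prep$pairs[, 2L], prep$pairs[, 1L])] <- v
    s2
  }
  for (g in seq_along(prep$groups)) {
    D <- prep$groups[[g]]
    k <- prep$risk_k[g]
    d <- length(D)
    S0 <- cw0[k]
    S1 <- cw1[k, ]
    S2 <- expand_s2(cw2[k, ])
    ll <- ll + sum(eta_c[D])
    grad <- grad + colSums(X[D, , drop = FALSE])
    if (ties == "breslow" || d == 1L) {
      ll <- ll - d * log(S0)
      grad <- grad - d * S1 / S0
      info <- info + d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {
      wD <- w[D]
      s0d <- sum(wD)
      s1d <- colSums(X[D, , drop = FALSE] * wD)
      s2d <- expand_s2(colSums(matrix(
        (X[D, prep$pairs[, 1L], drop = FALSE] *
         X[D, prep$pairs[, 2L], drop = FALSE]) * wD, nrow = d)))
    for (kk in seq_len(d) - 1L) {
        f <- kk / d
        den <- S0 - f * s0d
        v1 <- S1 - f * s1d
        v2 <- S2 - f * s2d
        ll <- ll - log(den)
        grad <- grad - v1 / den
        info <- info + v2 / den - tcrossprod(v1 / den)
      }
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' @export
coef.cox_model <- function(object, ...) object$coefficients

#' @export
vcov.cox_model <- function(object, ...) object$vcov

#' @export
logLik.cox_model <- function(object, ...) {
  structure(object$ll_model, df = length(object$coefficients), class = "logLik")
}

#' @export
print.cox_model <- function(x, digits = 4, ...) {
  cat(sprintf("<cox_model> n = %d, events = %d, ties = %s%s\n",
              x$n, x$n_events, x$ties,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!x$converged) cat("  diagnostic:", x$diagnostic, "\n")
  print(round(rbind(coef = x$coefficients, se = x$se), digits))
  cat(sprintf("ll_model = %.4f, ll_null = %.4f, LR = %.4f, partial AIC = %.4f\n",
              x$ll_model, x$ll_null, x$lr_statistic, x$partial_aic))
  invisible(x)
}

#' Wald summary table for a Cox model
#'
#' One row per coefficient with the hazard ratio `exp(b)`, its confidence
#' interval `exp(b +/- z * se)`, the Wald `z = b / se`, and the two-sided
#' normal p-value.
#'
#' @param model A converged [cox_fit()] object.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return A tibble with columns `term`, `coef`, `hr`, `hr_lower`,
#'   `hr_upper`, `z`, `p`.
#' @export
wald_summary <- function(model, conf_level = 0.95) {
  stopifnot(inherits(model, "cox_model"))
  if (!model$converged) {
    stop_symcox(sprintf("model did not converge (%s); Wald summary unavailable",
                        model$diagnostic),
                class = "symcox_error_converge")
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  b <- model$coefficients
  se <- model$se
  z <- b / se
  tibble::tibble(
    term = names(b),
    coef = unname(b),
    hr = exp(unname(b)),
    hr_lower = exp(unname(b) - zq * unname(se)),
    hr_upper = exp(unname(b) + zq * unname(se)),
    z = unname(z),
    p = 2 * pnorm(-abs(unname(z)))
  )
}

#' Broom-style tidier for Cox models
#'
#' @param x A [cox_fit()] object.
#' @param exponentiate Report hazard ratios instead of log-hazard
#'   coefficients.
#' @param conf.int,conf.level Include a Wald confidence interval.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` and optionally `conf.low`, `conf.high`.
#' @export
tidy.cox_model <- function(x, exponentiate = FALSE, conf.int = TRUE,
                           conf.level = 0.95, ...) {
  w <- wald_summary(x, conf_level = conf.level)
  out <- tibble::tibble(
    term = w$term,
    estimate = if (exponentiate) w$hr else w$coef,
    std.error = x$se[w$term],
    statistic = w$z,
    p.value = w$p
  )
  if (conf.int) {
    lo <- log(w$hr_lower); hi <- log(w$hr_upper)
    if (exponentiate) { lo <- exp(lo); hi <- exp(hi) }
    out$conf.low <- lo
    out$conf.high <- hi
  }
  out
}

#' One-row model summary
#'
#' @param x A [cox_fit()] object.
#' @param ... Unused.
#' @return A tibble with `n`, `n_events`, `ll_model`, `ll_null`,
#'   `lr_statistic`, `partial_aic`, `ties`, `converged`, `iterations`.
#' @export
glance.cox_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events,
    ll_model = x$ll_model, ll_null = x$ll_null,
    lr_statistic = x$lr_statistic, partial_aic = x$partial_aic,
    ties = x$ties, converged = x$converged, iterations = x$iterations
  )
}

#' Linear predictor (risk score) of a Cox model
#'
#' @param object A [cox_fit()] object.
#' @param newdata Matrix or data frame containing the model's covariate
#'   columns.
#' @param ... Unused.
#' @return Numeric vector `x %*% b`.
#' @export
predict.cox_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$covariate_names, drop = FALSE]
  drop(X %*% object$coefficients)
}

#' Relative hazard for a covariate change
#'
#' The multiplicative change in hazard when covariate `covariate` moves from
#' `x_from` to `x_from + delta`, all other covariates held fixed. Without a
#' transformation this is `exp(b * delta)`, independent of `x_from` — the
#' origin-independence limitation of the plain Cox model. With a
#' transformation `f` it is `exp(b * (f(x_from + delta) - f(x_from)))`,
#' which does depend on the starting point: that origin dependence is the
#' very point of transforming covariates.
#'
#' @param model A [cox_fit()] object.
#' @param covariate Name of a model term. When `transform` is supplied this
#'   is the term fitted on the transformed scale.
#' @param x_from Starting covariate value (on the original scale when
#'   `transform` is given).
#' @param delta Change in the covariate.
#' @param transform Optional [transform_spec()] mapping the original scale
#'   to the fitted scale.
#' @return The hazard ratio, a single number.
#' @export
relative_hazard <- function(model, covariate, x_from, delta, transform = NULL) {
  stopifnot(inherits(model, "cox_model"))
  if (!covariate %in% names(model$coefficients)) {
    stop_symcox(sprintf("covariate `%s` is not in the model", covariate))
  }
  b <- model$coefficients[[covariate]]
  if (is.null(transform)) {
    return(exp(b * delta))
  }
  df <- evaluate(transform, x_from + delta) - evaluate(transform, x_from)
  exp(b * df)
}
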