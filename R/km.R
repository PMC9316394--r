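#' Kaplan-Meier survival curve with Greenwood confidence bands
#'
#' Product-limit estimate of the survival function. The grid contains every
#' observed time (events and censorings) so that the at-risk accounting is
#' explicit; the survival probability only drops at event times. A subject
#' censored at an event time is counted as at risk through that time (the
#' standard convention). Greenwood's formula gives the variance; the
#' confidence band uses the log(-log S) transformation by default, which
#' keeps the band inside [0, 1] (a plain linear band is available).
#'
#' @param time Positive follow-up times.
#' @param event Death indicator, 0/1.
#' @param conf_level Confidence level of the band (default 0.95).
#' @param conf_type `"log-log"` (default) or `"plain"`.
#' @return An object of class `survival_curve`: a tibble with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `std_err` (Greenwood
#'   standard error of S), `lower`, `upper`, starting from an implicit
#'   S(0) = 1. Attributes `conf_level` and `conf_type` record the band.
#' @export
kaplan_meier <- function(time, event, conf_level = 0.95,
                         conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  time <- as.numeric(time); event <- as.numeric(event)
  n <- length(time)
  if (n < 1L) stop_symcox("need at least one subject")
  stopifnot(length(event) == n)
  if (anyNA(time) || anyNA(event)) stop_symcox("missing values")
  if (any(time <= 0)) stop_symcox("`time` must be positive")
  if (!all(event %in% c(0, 1))) stop_symcox("`event` must be 0/1")

  grid <- sort(unique(time))
  n_event <- vapply(grid, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(grid, function(t) sum(time == t & event == 0), numeric(1))
  n_risk <- vapply(grid, function(t) sum(time >= t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw_inc <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), Inf)
  gw <- cumsum(gw_inc)
  std_err <- surv * sqrt(gw)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  if (conf_type == "plain") {
    lower <- pmax(surv - zq * std_err, 0)
    upper <- pmin(surv + zq * std_err, 1)
  } else {
    lower <- upper <- surv
    ok <- surv > 0 & surv < 1 & is.finite(gw)
    se_ll <- sqrt(gw[ok]) / abs(log(surv[ok]))
    lower[ok] <- surv[ok]^exp(zq * se_ll)
    upper[ok] <- surv[ok]^exp(-zq * se_ll)
    lower[surv == 0] <- 0
  }
  std_err[!is.finite(std_err)] <- NA_real_
  out <- tibble::tibble(
    time = grid, n_risk = n_risk, n_event = n_event, n_censor = n_censor,
    surv = surv, std_err = std_err, lower = lower, upper = upper
  )
  structure(out, class = c("survival_curve", class(out)),
            conf_level = conf_level, conf_type = conf_type, n = n)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n = %d, %.0f%% %s band\n",
              attr(x, "n"), 100 * attr(x, "conf_level"), attr(x, "conf_type")))
  NextMethod()
}

#' Survival probability of a curve at arbitrary times
#'
#' Step-function lookup: S(t) is the product-limit estimate at the latest
#' grid time less than or equal to `t`; S(t) = 1 before the first observed
#' time.
#'
#' @param curve A [kaplan_meier()] object.
#' @param t Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
surv_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  s <- c(1, curve$surv)
  s[findInterval(t, curve$time) + 1L]
}

#' Kaplan-Meier curves by covariate stratum
#'
#' Splits the cohort into half-open bins `(lower, upper]` of a covariate
#' and fits one product-limit curve per nonempty bin. The bin edges must
#' cover the observed covariate range. Empty bins are dropped with a
#' warning.
#'
#' @param cohort A validated cohort tibble.
#' @param covariate Covariate column to stratify on.
#' @param bin_edges Increasing numeric vector of bin edges.
#' @param conf_level Confidence level of the Greenwood bands.
#' @return A named list of `survival_curve` objects (names like
#'   `"(25,40]"`), of class `survival_curve_set`.
#' @export
km_by_stratum <- function(cohort, covariate, bin_edges, conf_level = 0.95) {
  cohort <- validate_cohort(cohort)
  if (!covariate %in% names(cohort)) {
    stop_symcox(sprintf("unknown covariate `%s`", covariate))
  }
  x <- cohort[[covariate]]
  bin_edges <- sort(as.numeric(bin_edges))
  if (length(bin_edges) < 2L) stop_symcox("need at least two bin edges")
  if (min(x) <= bin_edges[1L] || max(x) > bin_edges[length(bin_edges)]) {
    stop_symcox(sprintf(
      "bin edges [%g, %g] do not cover the observed range (%g, %g] of `%s`",
      bin_edges[1L], bin_edges[length(bin_edges)], min(x), max(x), covariate))
  }
  bins <- cut(x, breaks = bin_edges, include.lowest = FALSE, right = TRUE)
  curves <- list()
  for (lev in levels(bins)) {
    idx <- which(bins == lev)
    if (!length(idx)) {
      warn(sprintf("stratum %s of `%s` is empty; omitted", lev, covariate))
      next
    }
    curves[[lev]] <- kaplan_meier(cohort$time[idx], cohort$event[idx],
                                  conf_level = conf_level)
  }
  structure(curves, class = "survival_curve_set",
            covariate = covariate, edges = bin_edges)
}

#' @export
print.survival_curve_set <- function(x, ...) {
  cat(sprintf("<survival_curve_set> %d strata of `%s`\n",
              length(x), attr(x, "covariate")))
  for (nm in names(x)) {
    cat(sprintf("  %s: n = %d, events = %d\n", nm, attr(x[[nm]], "n"),
                sum(x[[nm]]$n_event)))
  }
  invisible(x)
}

#' Long-format tibble of a set of stratified curves
#'
#' @param x A [km_by_stratum()] result.
#' @param ... Unused.
#' @return A tibble with a `stratum` column ahead of the curve columns.
#' @export
tidy.survival_curve_set <- function(x, ...) {
  purrr::imap_dfr(unclass(x)[names(x)], function(curve, nm) {
    dplyr::mutate(tibble::as_tibble(curve), stratum = nm, .before = 1)
  })
}
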