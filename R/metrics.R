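#' Harrell's concordance index
#'
#' The proportion of admissible subject pairs in which the subject with the
#' higher risk score fails earlier. A pair is admissible when the ordering
#' of failure is known despite censoring: one subject has an observed event
#' strictly before the other's follow-up ends, or at the same time as the
#' other's censoring. Pairs of events at exactly the same time are not
#' comparable. Tied risk scores in a comparable pair count 0.5.
#'
#' @param risk_scores Numeric risk scores (higher = riskier).
#' @param time Positive follow-up times.
#' @param event Death indicator, 0/1.
#' @return The concordance proportion in [0, 1].
#' @export
concordance_index <- function(risk_scores, time, event) {
  r <- as.numeric(risk_scores)
  time <- as.numeric(time); event <- as.numeric(event)
  n <- length(r)
  stopifnot(length(time) == n, length(event) == n)
  if (anyNA(r) || anyNA(time) || anyNA(event)) stop_symcox("missing values")
  if (any(time <= 0)) stop_symcox("`time` must be positive")
  conc <- 0; comp <- 0
  for (i in which(event == 1)) {
    comparable <- (time > time[i]) | (time == time[i] & event == 0)
    comparable[i] <- FALSE
    m <- sum(comparable)
    if (!m) next
    comp <- comp + m
    conc <- conc + sum(r[i] > r[comparable]) + 0.5 * sum(r[i] == r[comparable])
  }
  if (comp == 0) {
    stop_symcox("no comparable pairs", class = "symcox_error_pairs")
  }
  conc / comp
}

auc_groups <- function(time, event, horizon) {
  cases <- event == 1 & time <= horizon
  controls <- !cases & time >= horizon
  excluded <- event == 0 & time < horizon
  list(cases = cases, controls = controls, excluded = excluded)
}

#' ROC AUC for survival status at a time horizon
#'
#' Cumulative/dynamic estimator: cases are subjects with an observed event
#' by the horizon; controls are subjects still under observation at the
#' horizon; subjects censored strictly before the horizon are excluded from
#' the default estimator (set `ipcw = TRUE` for inverse
#' probability-of-censoring weights instead of exclusion). The AUC is the
#' Mann-Whitney statistic of the risk scores between cases and controls,
#' with tied scores counting 0.5.
#'
#' @inheritParams concordance_index
#' @param horizon Time horizon in the units of `time` (days here).
#' @param ipcw Weight subjects by the inverse Kaplan-Meier estimate of the
#'   censoring distribution rather than excluding earlier-censored subjects.
#' @return The AUC in [0, 1].
#' @export
auc_at_horizon <- function(risk_scores, time, event, horizon, ipcw = FALSE) {
  r <- as.numeric(risk_scores)
  time <- as.numeric(time); event <- as.numeric(event)
  n <- length(r)
  stopifnot(length(time) == n, length(event) == n)
  if (anyNA(r) || anyNA(time) || anyNA(event)) stop_symcox("missing values")
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stop_symcox("`horizon` must be a single positive time")
  }
  g <- auc_groups(time, event, horizon)
  if (!any(g$cases) || !any(g$controls)) {
    stop_symcox("need at least one case and one control at the horizon",
                class = "symcox_error_pairs")
  }
  if (!ipcw) {
    wc <- rep(1, sum(g$cases)); wn <- rep(1, sum(g$controls))
  } else {
    cens_km <- kaplan_meier(time, 1 - event)
    Gmin <- function(t) {
      s <- c(1, cens_km$surv)
      idx <- findInterval(t - 1e-12, c(0, cens_km$time))
      pmax(s[idx], .Machine$double.eps)
    }
    wc <- 1 / Gmin(time[g$cases])
    wn <- rep(1 / max(Gmin(horizon), .Machine$double.eps), sum(g$controls))
  }
  rc <- r[g$cases]; rn <- r[g$controls]
  num <- 0; den <- 0
  for (i in seq_along(rc)) {
    num <- num + wc[i] * sum(wn * ((rc[i] > rn) + 0.5 * (rc[i] == rn)))
    den <- den + wc[i] * sum(wn)
  }
  num / den
}

#' ROC curve for survival status at a time horizon
#'
#' Sensitivity/specificity pairs over all risk-score thresholds, using the
#' same case/control definition as [auc_at_horizon()].
#'
#' @inheritParams auc_at_horizon
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_at_horizon <- function(risk_scores, time, event, horizon) {
  r <- as.numeric(risk_scores)
  g <- auc_groups(as.numeric(time), as.numeric(event), horizon)
  if (!any(g$cases) || !any(g$controls)) {
    stop_symcox("need at least one case and one control at the horizon",
                class = "symcox_error_pairs")
  }
  thr <- c(Inf, sort(unique(r), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    tpr = purrr::map_dbl(thr, ~ mean(r[g$cases] >= .x)),
    fpr = purrr::map_dbl(thr, ~ mean(r[g$controls] >= .x))
  )
}
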