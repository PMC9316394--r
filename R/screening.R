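#' Mann-Whitney U test between event and non-event groups
#'
#' Rank-based two-sample test used to screen covariates against the death
#' indicator. `U` is the statistic of the first (event) group computed from
#' rank sums with midranks for ties; `z` uses the tie-corrected normal
#' variance, by default with a 0.5 continuity correction toward the null;
#' `p` is the two-sided normal-approximation p-value.
#'
#' @param values_event Covariate values of subjects with the event.
#' @param values_no_event Covariate values of subjects without the event.
#' @param continuity_correction Apply the 0.5 continuity correction
#'   (default `TRUE`).
#' @return A one-row tibble with columns `u`, `z`, `p`, `n_event`,
#'   `n_no_event`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(values_event, values_no_event,
                         continuity_correction = TRUE) {
  x <- as.numeric(values_event)
  y <- as.numeric(values_no_event)
  if (!length(x) || !length(y)) {
    stop_symcox("both groups must be nonempty", class = "symcox_error_empty")
  }
  if (anyNA(x) || anyNA(y)) stop_symcox("groups contain missing values")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) {
    z <- 0; p <- 1
  } else {
    dev <- u - mu
    if (continuity_correction && dev != 0) dev <- dev - sign(dev) * 0.5
    z <- dev / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  tibble::tibble(u = u, z = z, p = p, n_event = n1, n_no_event = n2)
}

#' Screen covariates by association with the death indicator
#'
#' Runs [mann_whitney()] for each named covariate, splitting the cohort by
#' `event`, and returns the covariates sorted by ascending p-value (ties in
#' p broken alphabetically by covariate name for reproducibility). Binary
#' covariates are screened identically; the rank test then degrades
#' gracefully to a comparison of proportions.
#'
#' @param cohort A validated cohort tibble.
#' @param covariate_names Covariate columns to screen; defaults to all ten
#'   risk factors.
#' @param continuity_correction Passed to [mann_whitney()].
#' @return A tibble with columns `covariate`, `u`, `z`, `p`, `rank`.
#' @export
rank_covariates <- function(cohort, covariate_names = cohort_covariates(),
                            continuity_correction = TRUE) {
  cohort <- validate_cohort(cohort)
  unknown <- setdiff(covariate_names, names(cohort))
  if (length(unknown)) {
    stop_symcox(sprintf("unknown covariate(s): %s",
                        paste(unknown, collapse = ", ")),
                class = "symcox_error_columns")
  }
  ev <- cohort$event == 1
  if (!any(ev) || all(ev)) {
    stop_symcox("cohort must contain both deaths and survivors to screen")
  }
  res <- purrr::map_dfr(covariate_names, function(cov) {
    dplyr::mutate(
      mann_whitney(cohort[[cov]][ev], cohort[[cov]][!ev],
                   continuity_correction = continuity_correction),
      covariate = cov, .before = 1
    )
  })
  res <- dplyr::arrange(res, .data$p, .data$covariate)
  dplyr::mutate(res, rank = dplyr::row_number())
}
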