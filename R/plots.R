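#' Plot a Kaplan-Meier curve
#'
#' Step curve with the Greenwood confidence ribbon.
#'
#' @param object A [kaplan_meier()] curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_curve <- function(object, ...) {
  df <- km_step_frame(tibble::as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

# prepend the S(0) = 1 anchor so the step starts at the origin
km_step_frame <- function(df, stratum = NULL) {
  anchor <- tibble::tibble(time = 0, n_risk = NA_real_, n_event = 0,
                           n_censor = 0, surv = 1, std_err = 0,
                           lower = 1, upper = 1)
  out <- dplyr::bind_rows(anchor, df[, names(anchor)])
  if (!is.null(stratum)) out$stratum <- stratum
  out
}

#' Plot stratified Kaplan-Meier curves
#'
#' One step curve per covariate stratum with confidence ribbons, in the
#' style of the ejection-fraction-stratified survival figure for the
#' heart-failure cohort.
#'
#' @param object A [km_by_stratum()] result.
#' @param ribbon Draw the Greenwood bands (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_curve_set <- function(object, ribbon = TRUE, ...) {
  df <- purrr::imap_dfr(unclass(object)[names(object)], function(curve, nm) {
    km_step_frame(tibble::as_tibble(curve), stratum = nm)
  })
  df$stratum <- factor(df$stratum, levels = names(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                        colour = .data$stratum,
                                        fill = .data$stratum))
  if (ribbon) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                               ymax = .data$upper),
                                  alpha = 0.15, colour = NA)
  }
  p +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up (days)", y = "Survival probability",
                  colour = attr(object, "covariate"),
                  fill = attr(object, "covariate")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted transformation's death-probability curve
#'
#' The logistic-wrapped fitted curve `P(y = 1 | x)` over the observed
#' covariate range, with the empirical event rate in ten quantile bins
#' overlaid for reference.
#'
#' @param object A [fit_transform()] object.
#' @param x,y The covariate and outcome the fit was made on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transform_fit <- function(object, x, y, ...) {
  grid <- seq(min(x), max(x), length.out = 200L)
  curve <- tibble::tibble(x = grid, p = predict_probability(object$spec, grid))
  bins <- dplyr::group_by(
    tibble::tibble(x = x, y = y,
                   bin = dplyr::ntile(x, 10L)), .data$bin)
  pts <- dplyr::summarise(bins, x = mean(.data$x), p = mean(.data$y),
                          .groups = "drop")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(data = pts, shape = 1, size = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Covariate", y = "P(death)",
                  title = format(object$spec, digits = 4)) +
    ggplot2::theme_minimal()
}

#' Hazard-ratio forest plot of a Cox model
#'
#' @param object A converged [cox_fit()] object.
#' @param conf_level Confidence level of the intervals.
#' @param ... Unused.
#' @return A ggplot object (log-scaled hazard-ratio axis).
#' @export
autoplot.cox_model <- function(object, conf_level = 0.95, ...) {
  w <- wald_summary(object, conf_level)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$hr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hr_lower,
                                         xmax = .data$hr_upper),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve plot at a horizon
#'
#' @param risk_scores,time,event,horizon As in [auc_at_horizon()].
#' @return A ggplot object annotated with the AUC.
#' @export
plot_roc_at_horizon <- function(risk_scores, time, event, horizon) {
  roc <- roc_at_horizon(risk_scores, time, event, horizon)
  auc <- auc_at_horizon(risk_scores, time, event, horizon)
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f at %g days", auc, horizon)) +
    ggplot2::theme_minimal()
}
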