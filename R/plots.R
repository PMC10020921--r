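#' Plot an SPA scan trace
#'
#' Signal against position with the true baseline as a dashed rule.
#'
#' @param object an `spa_trace`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot spa_trace
#' @export
autoplot.spa_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = attr(object, "baseline_true"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position (mm)",
                  y = expression(signal ~ (mg/cm^2)),
                  title = "SPA line scan") +
    ggplot2::theme_minimal()
}

#' Plot a fitted trajectory model
#'
#' Per-sex scatter of the observed trait against age, overlaid with the
#' fitted cohort trajectories and pointwise confidence bands (antilogged
#' from the log scale), mirroring the conventional presentation of
#' cohort-comparison growth data.
#'
#' @param object a `trend_fit`.
#' @param conf.level band level.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, conf.level = object$conf.level, ...) {
  obs <- tibble::tibble(
    age = object$data$age_c + object$age_origin,
    y = exp(object$data$log_y),
    sex = as.character(object$data$sex_f),
    cohort = as.character(object$data$cohort_f)
  )
  curves <- fitted_curves(object,
                          ages = seq(min(obs$age), max(obs$age), length.out = 80),
                          conf.level = conf.level)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$age, colour = .data$cohort,
                                       fill = .data$cohort)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$y),
                        alpha = 0.35, size = 0.8) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "age (years)", y = object$outcome,
                  title = sprintf("%s trajectory by cohort (Model %d)",
                                  object$outcome, object$model)) +
    ggplot2::theme_minimal()
}
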