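# ggplot2 displays for fitted models and screening results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Baseline cumulative hazard / survival of a fitted model
#'
#' Plots the spline-based baseline (all covariates at zero / reference)
#' on the scale requested.
#'
#' @param object An [rp_fit()].
#' @param t_max Upper end of the time axis in years.
#' @param scale `"cumhaz"`, `"survival"` or `"log_cumhaz"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rp_fit <- function(object, t_max = 10,
                            scale = c("cumhaz", "survival", "log_cumhaz"),
                            ...) {
  scale <- match.arg(scale)
  tt <- exp(seq(log(0.05), log(t_max), length.out = 200))
  p_base <- 1L + if (is.null(object$time_spec)) 1L else object$time_spec$df
  gamma <- object$coefficients[seq_len(p_base)]
  eta0 <- drop(cbind(1, time_basis(log(tt), object$time_spec)$basis) %*% gamma)
  df <- tibble::tibble(
    time = tt,
    value = switch(scale, cumhaz = exp(eta0),
                   survival = exp(-exp(eta0)), log_cumhaz = eta0)
  )
  ylab <- switch(scale, cumhaz = "Baseline cumulative hazard",
                 survival = "Baseline survival",
                 log_cumhaz = "Baseline log cumulative hazard")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Years since cohort entry", y = ylab) +
    ggplot2::theme_minimal()
}

#' Distribution of predicted risks across scenarios
#'
#' @param risks Named list of predicted-risk vectors (one per
#'   scenario) on a common subset.
#' @param threshold Optional referral threshold to mark.
#' @return A ggplot of the risk distributions on a log axis.
#' @export
plot_risk_distribution <- function(risks, threshold = NULL) {
  df <- purrr::imap_dfr(risks, function(r, nm) {
    tibble::tibble(scenario = nm, risk = as.numeric(r))
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$risk,
                                        colour = .data$scenario)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Predicted risk", y = "Density",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  }
  p
}

#' Cost per case detected against the referral threshold
#'
#' @param sens Output of [threshold_sensitivity()].
#' @return A ggplot.
#' @export
plot_threshold_sensitivity <- function(sens) {
  ggplot2::ggplot(sens, ggplot2::aes(x = 100 * .data$threshold,
                                     y = .data$cost_per_case)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Referral threshold (% predicted risk)",
                  y = "Cost per case detected (GBP)") +
    ggplot2::theme_minimal()
}
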