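#' Plot a switch-stay table
#'
#' Grouped bar chart of the group-mean stay probabilities by previous-trial
#' transition and outcome, faceted by any grouping columns.
#'
#' @param object A `twostep_switch_stay`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twostep_switch_stay <- function(object, ...) {
  g <- object$group
  ggplot2::ggplot(g, ggplot2::aes(x = .data$rewarded, y = .data$mean_stay,
                                  fill = .data$transition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_stay - .data$sem,
                   ymax = .data$mean_stay + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::facet_grid(
      stats::reformulate(intersect(c("condition", "day"), names(g)), "group")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "previous outcome", y = "P(stay)",
                  fill = "previous transition") +
    ggplot2::theme_minimal()
}

#' Plot lagged regression coefficients
#'
#' Group-mean model-free and model-based coefficients by lag with SEM bars.
#'
#' @param object A `twostep_lag_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twostep_lag_fit <- function(object, ...) {
  gs <- object$group_stats
  gs <- gs[gs$term != "(Intercept)", ]
  gs$system <- ifelse(substr(gs$term, 1, 2) == "MF",
                      "model-free", "model-based")
  gs$lag <- substring(gs$term, 3)
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$lag, y = .data$mean,
                                   fill = .data$system)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = "trials back", y = "coefficient (group mean)") +
    ggplot2::theme_minimal()
}

#' Plot group-level parameter estimates of a hierarchical fit
#'
#' Natural-scale subject estimates (points) with group means per parameter.
#'
#' @param object A `twostep_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twostep_fit <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$parameter, y = .data$estimate)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 3) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "estimate (natural scale)") +
    ggplot2::theme_minimal()
}
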