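# ggplot2 display methods for result objects

#' Forest plot of per-marker hazard ratios
#'
#' @param object A `hazard_screen` tibble from [screen_markers()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hazard_screen
#' @export
autoplot.hazard_screen <- function(object, ...) {
  df <- object |>
    filter(!.data$failed) |>
    mutate(marker = stats::reorder(.data$marker, .data$hr_per_sd))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr_per_sd, y = .data$marker)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio per +1 SD (95% CI)", y = NULL)
}

#' Plot a cutpoint scan
#'
#' Standardized log-rank statistic across candidate AgeDev cutpoints, with
#' the maximizer marked.
#'
#' @param object A `cutpoint_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cutpoint_scan
#' @export
autoplot.cutpoint_scan <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$cutpoint, y = abs(.data$statistic))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best_cutpoint"),
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "AgeDev cutpoint (years)",
                  y = "|standardized log-rank statistic|")
}

#' Plot incident/dynamic AUC over time
#'
#' @param object A `roc_result` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$auc_by_time,
                  ggplot2::aes(x = .data$time, y = .data$auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_cases), alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$auc, colour = "red") +
    ggplot2::scale_size_continuous(guide = "none") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Age (years)", y = "Incident/dynamic AUC(t)")
}

#' Plot predicted conditional survival curves
#'
#' @param object A `survival_prediction` tibble from [predict_survival()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot survival_prediction
#' @export
autoplot.survival_prediction <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$survival)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Age (years)", y = "Conditional survival probability")
}

#' Plot AgeDev trajectories by diet group
#'
#' @param object A `diet_comparison` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diet_comparison
#' @export
autoplot.diet_comparison <- function(object, ...) {
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(x = .data$age, y = .data$agedev_smooth,
                               colour = .data$diet)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$onset_age, linetype = 3) +
    ggplot2::labs(x = "Age (years)", y = "AgeDev (years)", colour = "Diet")
}

#' CV deviance curve of a LASSO-Cox path
#'
#' @param object A `lasso_path` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lasso_path
#' @export
autoplot.lasso_path <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(x = log(.data$lambda))) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$deviance, ymin = .data$deviance - .data$se,
                   ymax = .data$deviance + .data$se),
      size = 0.2
    ) +
    ggplot2::geom_vline(xintercept = log(object$lambda_selected),
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "log(lambda)", y = "CV partial-likelihood deviance")
}
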