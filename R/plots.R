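#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision-recall curve
#'
#' Precision against recall along the ranked-support sweep, with the
#' prevalence (random-ranking) baseline as a dashed line.
#'
#' @param object `scggm_pr` object from [precision_recall()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot scggm_pr
#' @export
autoplot.scggm_pr <- function(object, ...) {
  df <- object$points
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall,
                                   y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_hline(yintercept = object$prevalence,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("Support recovery (AUPRC = %.3f)", object$auprc),
      subtitle = sprintf("prevalence baseline %.3f", object$prevalence)) +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation error surface
#'
#' @param object `scggm_cv` object.
#' @param ... unused.
#' @return A ggplot object: tile map of mean CV error over the penalty
#'   grid, with the selected pair marked.
#' @method autoplot scggm_cv
#' @export
autoplot.scggm_cv <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = factor(signif(.data$lambda_perturb, 3)),
                                   y = factor(signif(.data$lambda_net, 3)),
                                   fill = .data$mean_error)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = df[df$lambda_net == object$best$lambda_net &
                  df$lambda_perturb == object$best$lambda_perturb, ],
      shape = 21, size = 4, fill = "white") +
    ggplot2::labs(x = "lambda_perturb", y = "lambda_net",
                  fill = "CV error",
                  title = "Cross-validation error surface") +
    ggplot2::theme_minimal()
}

#' Plot the cumulative degree distribution on log-log axes
#'
#' @param fit result of [powerlaw_fit()].
#' @return A ggplot object with the OLS line overlaid.
#' @export
plot_degree_distribution <- function(fit) {
  df <- fit$points
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$degree),
                                   y = log10(.data$cumulative_fraction))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 weighted degree",
      y = "log10 P(degree ≥ d)",
      title = sprintf("Cumulative degree distribution (slope %.2f, R² %.2f)",
                      fit$slope, fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot the objective trace of a fit
#'
#' @param model fitted `scggm` object.
#' @return A ggplot object of accepted objective values per iteration.
#' @export
plot_objective_trace <- function(model) {
  tr <- model$fit_info$objective_trace
  if (is.null(tr)) stop("model carries no objective trace")
  df <- tibble::tibble(iteration = seq_along(tr) - 1L, objective = tr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Accepted iteration", y = "Penalized objective",
                  title = "Optimization trace") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
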