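#' Plot a simulated concentration-time profile
#'
#' @param object A `pbpk_sim`.
#' @param log_y Log-scale the concentration axis (default `TRUE`).
#' @param observed Optional data frame (`time`, `conc`) of observations to
#'   overlay as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pbpk_sim
#' @export
autoplot.pbpk_sim <- function(object, log_y = TRUE, observed = NULL, ...) {
  tc <- filter(object$timecourse, .data$conc > 0 | !log_y)
  p <- ggplot2::ggplot(tc, ggplot2::aes(x = .data$time, y = .data$conc)) +
    ggplot2::geom_line(colour = "#2b6cb0") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(data = as_tibble(observed),
                                 ggplot2::aes(x = .data$time,
                                              y = .data$conc),
                                 inherit.aes = FALSE, colour = "black")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot population concentration bands
#'
#' Mean curve with the empirical 2.5th-97.5th percentile ribbon.
#'
#' @param object A `pbpk_popresult`.
#' @param log_y Log-scale the concentration axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pbpk_popresult
#' @export
autoplot.pbpk_popresult <- function(object, log_y = TRUE, ...) {
  b <- object$band
  if (log_y) b <- filter(b, .data$p2.5 > 0)
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p2.5, ymax = .data$p97.5),
                         fill = "#90cdf4", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "#2b6cb0") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Fold-error diagnostic plot
#'
#' Per-point fold errors on a log scale with the 2-fold (dashed) and 3-fold
#' (solid) acceptance bands.
#'
#' @param ev A `pbpk_evaluation` (or the tibble from
#'   [fold_error_points()]).
#' @return A ggplot object.
#' @export
plot_fold_errors <- function(ev) {
  pts <- if (inherits(ev, "pbpk_evaluation")) ev$points else as_tibble(ev)
  x <- if ("time" %in% names(pts)) pts$time else seq_len(nrow(pts))
  df <- mutate(pts, x = x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$fe)) +
    ggplot2::geom_hline(yintercept = c(1 / 3, 3), colour = "black") +
    ggplot2::geom_hline(yintercept = c(0.5, 2), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60") +
    ggplot2::geom_point(colour = "#2b6cb0") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = if ("time" %in% names(pts)) "Time (h)" else "Point",
                  y = "Fold error (predicted / observed)") +
    ggplot2::theme_minimal()
}

#' Tornado plot of sensitivity coefficients
#'
#' @param results Tibble from [local_sensitivity()] (optionally ranked).
#' @param metric Metric to display.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(results, metric = "auc_day1") {
  df <- filter(results, .data$metric == !!metric) |>
    arrange(abs(.data$s))
  df$parameter <- factor(df$parameter, levels = df$parameter)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$parameter)) +
    ggplot2::geom_col(fill = "#2b6cb0") +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Sensitivity coefficient S", y = NULL,
                  title = metric) +
    ggplot2::theme_minimal()
}
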