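# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for phasing results
#'
#' `tidy()` on a `phasing_result` returns the per-iteration metrics trace;
#' `glance()` returns a one-row summary. On a `phasing_trials` ensemble,
#' `tidy()` returns the per-trial summary and `glance()` the ensemble
#' success statistics.
#'
#' @param x A `phasing_result` or `phasing_trials` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.phasing_result <- function(x, ...) x$trace

#' @rdname tidy.phasing_result
#' @export
glance.phasing_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$cfg$algorithm, scheme = x$cfg$scheme, trial = x$trial,
    n_iter = x$n_iter_run, converged = x$converged,
    converged_iter = x$converged_iter, failed = x$failed,
    r_work = x$final$r_work, r_free = x$final$r_free,
    phase_error = x$final$phase_error, iou = x$final$iou)
}

#' @rdname tidy.phasing_result
#' @export
tidy.phasing_trials <- function(x, ...) x$summary

#' @rdname tidy.phasing_result
#' @export
glance.phasing_trials <- function(x, ...) {
  tibble::tibble(
    algorithm = x$cfg$algorithm, scheme = x$cfg$scheme,
    n_trials = x$n_trials, success_rate = x$success_rate,
    median_iterations = x$median_iterations)
}

#' Plot the convergence trace of a phasing run
#'
#' Line plots of the recorded metrics (R factors, mean phase error, envelope
#' IoU, regional density deviations) against iteration, one facet per
#' metric.
#'
#' @param object A `phasing_result`.
#' @param metrics Which trace columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phasing_result <- function(object,
                                    metrics = c("r_work", "r_free", "phase_error",
                                                "iou", "dev_protein", "dev_solvent"),
                                    ...) {
  tr <- object$trace
  keep <- intersect(metrics, names(tr))
  long <- do.call(rbind, lapply(keep, function(m)
    data.frame(iter = tr$iter, metric = m, value = tr[[m]])))
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = sprintf("%s / %s", object$cfg$algorithm, object$cfg$scheme)) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble of phasing trials
#'
#' Overlays one metric's trace for every trial; successful trials are
#' highlighted.
#'
#' @param object A `phasing_trials` object.
#' @param metric Trace column to plot (default `r_free`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phasing_trials <- function(object, metric = "r_free", ...) {
  long <- do.call(rbind, lapply(object$results, function(r) {
    data.frame(iter = r$trace$iter, value = r$trace[[metric]],
               trial = factor(r$trial),
               success = isTRUE(object$summary$success[object$summary$trial == r$trial]))
  }))
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value,
                                     group = .data$trial,
                                     colour = .data$success)) +
    ggplot2::geom_line(linewidth = 0.25, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey60")) +
    ggplot2::labs(x = "iteration", y = metric,
                  title = sprintf("%s / %s (%d trials)", object$cfg$algorithm,
                                  object$cfg$scheme, object$n_trials)) +
    ggplot2::theme_minimal()
}
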