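#' Tidy and glance methods for simulation runs
#'
#' `tidy()` returns the long trajectory tibble (`t`, `agent`, `opinion`);
#' `glance()` returns a one-row summary of the final opinion distribution
#' with the run's headline parameters.
#'
#' @param x An `activity_run` or `selective_run`.
#' @param ... Unused.
#' @return A tibble.
#' @name run-tidiers
NULL

#' @rdname run-tidiers
#' @method tidy activity_run
#' @export
tidy.activity_run <- function(x, ...) {
  x$trajectory
}

#' @rdname run-tidiers
#' @method tidy selective_run
#' @export
tidy.selective_run <- function(x, ...) {
  x$trajectory
}

#' @rdname run-tidiers
#' @method glance activity_run
#' @export
glance.activity_run <- function(x, ...) {
  cfg <- x$config
  dplyr::bind_cols(
    summarize_opinions(x$final_opinions),
    tibble(
      N = cfg$N, T = cfg$T, beta = cfg$beta, K = cfg$K, alpha = cfg$alpha,
      nudge = x$nudge$variant, D = x$nudge$D, seed = cfg$seed
    )
  )
}

#' @rdname run-tidiers
#' @method glance selective_run
#' @export
glance.selective_run <- function(x, ...) {
  cfg <- x$config
  dplyr::bind_cols(
    summarize_opinions(x$final_opinions),
    tibble(
      N = cfg$N, E = cfg$E, steps = max(x$trajectory$t),
      eps_conf = cfg$eps_conf, mu = cfg$mu,
      nudge = x$nudge$variant, D = x$nudge$D, seed = cfg$seed,
      unstable = x$unstable
    )
  )
}

#' Plot opinion trajectories of a run
#'
#' One line per agent over time, the standard view in which echo chambers
#' appear as two diverging opinion branches. Nudge windows, if any, are
#' shaded.
#'
#' @param object An `activity_run` or `selective_run`.
#' @param alpha Line transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot activity_run
#' @export
autoplot.activity_run <- function(object, alpha = 0.05, ...) {
  plot_trajectories(object, alpha, xlab = "time")
}

#' @rdname autoplot.activity_run
#' @method autoplot selective_run
#' @export
autoplot.selective_run <- function(object, alpha = 0.3, ...) {
  plot_trajectories(object, alpha, xlab = "step")
}

plot_trajectories <- function(object, alpha, xlab) {
  p <- ggplot2::ggplot(
    object$trajectory,
    ggplot2::aes(x = .data$t, y = .data$opinion, group = .data$agent)
  ) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = xlab, y = "opinion x") +
    ggplot2::theme_minimal()
  if (nrow(object$schedule) > 0) {
    p <- p + ggplot2::annotate("rect",
      xmin = object$schedule$t_on, xmax = object$schedule$t_off,
      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "steelblue"
    )
  }
  p
}

#' Plot an opinion distribution with its detected peaks
#'
#' Histogram plus kernel density estimate, with the positive- and negative-
#' side peak positions (when defined) marked; the annotated distance between
#' them is the peak distance.
#'
#' @param opinions Numeric opinion vector.
#' @param binwidth Histogram bin width (default: [bin_width()] of the data).
#' @return A ggplot object.
#' @export
plot_opinion_distribution <- function(opinions, binwidth = NULL) {
  if (is.null(binwidth)) {
    binwidth <- tryCatch(bin_width(opinions),
      rdnudge_error_degenerate = function(e) NULL
    )
  }
  ps <- peak_distance(opinions)
  df <- tibble(opinion = opinions)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$opinion)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      binwidth = binwidth, fill = "grey80", colour = "grey50"
    ) +
    ggplot2::geom_density(bw = binwidth %||% "nrd0", colour = "black") +
    ggplot2::labs(
      x = "opinion x", y = "density",
      subtitle = if (is.na(ps$lambda_x)) {
        sprintf("peaks: %d (peak distance undefined)", ps$n_peaks)
      } else {
        sprintf("peaks: %d, peak distance %.2f", ps$n_peaks, ps$lambda_x)
      }
    ) +
    ggplot2::theme_minimal()
  if (!is.na(ps$lambda_x)) {
    p <- p + ggplot2::geom_vline(
      xintercept = unname(ps$peak_positions),
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' Plot nearest-neighbour mean opinion against own opinion
#'
#' The echo-chamber diagnostic view: each point is an agent, positioned by
#' its opinion and the interaction-weighted mean opinion of the agents it
#' heard from. Echo chambers appear as two clusters on the diagonal.
#'
#' @param run An `activity_run` with a recorded interaction log.
#' @return A ggplot object.
#' @export
plot_nn_mean <- function(run) {
  if (is.null(run$interactions)) {
    stop_param("run has no interaction log; set record_interactions = TRUE")
  }
  df <- nn_mean_opinion(run$final_opinions, run$interactions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$opinion, y = .data$nn_mean)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "opinion x", y = "nearest-neighbour mean opinion") +
    ggplot2::theme_minimal()
}
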