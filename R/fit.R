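#' Fit the run-and-tumble segmentation to an ensemble of trajectories
#'
#' The central fitting function: pools the alignment-index / scaled-speed
#' points of all trajectories, estimates the joint density P(A,S), fits the
#' maximum line S*(A), locates the run/tumble threshold along it, classifies
#' every trajectory, and computes per-cell phase summaries.
#'
#' @param tracks a `"trajectory_list"` (or list of [trajectory] objects).
#' @param window alignment half-window, frames.
#' @param a_bins,s_bins,s_max,bandwidth density-estimation controls, see
#'   [estimate_density()].
#' @param min_segment minimum segment length in frames, see
#'   [classify_phases()].
#' @return An object of class `"rt_fit"`: list with `tracks`, `series`,
#'   `density` (threshold and maximum line filled in), `annotations`,
#'   `summaries` (per-cell `"phase_summary"`), and `call`. Methods:
#'   [print.rt_fit()], [summary.rt_fit()], [coef.rt_fit()], [plot.rt_fit()],
#'   [residuals.rt_fit()].
#' @examples
#' p <- rt_params_control(seed = 42)
#' trks <- simulate(p, nsim = 6, duration = 120)
#' fit <- rt_fit(trks)
#' fit
#' coef(fit)
#' summary(fit)
#' @export
rt_fit <- function(tracks, window = 1, a_bins = 41, s_bins = 41, s_max = 3,
                   bandwidth = 1.5, min_segment = 1) {
  if (inherits(tracks, "trajectory")) tracks <- list(tracks)
  if (!inherits(tracks, "trajectory_list"))
    tracks <- new_trajectory_list(tracks)
  series <- lapply(unclass(tracks), as_series, window = window)
  d <- estimate_density(series, a_bins = a_bins, s_bins = s_bins,
                        s_max = s_max, bandwidth = bandwidth)
  d <- fit_maximum_line(d)
  d <- find_threshold(d)
  ann <- lapply(unclass(tracks), classify_phases, d = d, window = window,
                min_segment = min_segment)
  summ <- Map(phase_statistics, unclass(tracks), ann)
  structure(list(tracks = tracks, series = series, density = d,
                 annotations = ann, summaries = summ,
                 params = list(window = window, a_bins = a_bins,
                               s_bins = s_bins, s_max = s_max,
                               bandwidth = bandwidth,
                               min_segment = min_segment),
                 call = match.call()),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat("Run-and-tumble segmentation fit:", length(x$tracks), "trajectories\n")
  print(x$density)
  s <- summary(x)
  cat(sprintf("  tumble/run time ratio %.3f +/- %.3f (mean +/- SD, n = %d)\n",
              s$tumble_run_time_ratio, s$tumble_run_time_ratio_sd, s$n_cells))
  cat(sprintf("  speed ratio %.2f; persistence %.3f; inter-run angle %.1f deg\n",
              s$speed_ratio, s$persistence, s$mean_inter_run_angle))
  invisible(x)
}

#' Coefficients of the segmentation fit
#'
#' @param object an `"rt_fit"`.
#' @param ... unused.
#' @return Named numeric vector: maximum-line `slope` and `intercept`, and
#'   the `threshold_A` abscissa.
#' @export
coef.rt_fit <- function(object, ...) {
  c(slope = object$density$max_line$slope,
    intercept = object$density$max_line$intercept,
    threshold_A = object$density$threshold$threshold_A)
}

#' Ensemble-level summary of a segmentation fit
#'
#' Aggregates the per-cell phase summaries: per-cell tumble-to-run time
#' ratios and persistence (mean +/- SD across cells), pooled run and tumble
#' durations and speeds, the pooled run/tumble speed ratio, and the mean
#' inter-run angle pooled over all consecutive-run pairs.
#'
#' @param object an `"rt_fit"`.
#' @param ... unused.
#' @return A list of class `"summary.rt_fit"`.
#' @export
summary.rt_fit <- function(object, ...) {
  su <- object$summaries
  ratios <- vapply(su, `[[`, 0, "tumble_run_time_ratio")
  ratios_f <- ratios[is.finite(ratios)]
  pers <- vapply(su, `[[`, 0, "persistence")
  run_d <- unlist(lapply(su, `[[`, "run_durations"))
  tum_d <- unlist(lapply(su, `[[`, "tumble_durations"))
  angles <- unlist(lapply(su, `[[`, "inter_run_angles"))
  run_sp <- unlist(lapply(su, function(s) s$speeds$run))
  tum_sp <- unlist(lapply(su, function(s) s$speeds$tumble))
  out <- list(
    n_cells = length(su),
    tumble_run_time_ratio = mean(ratios_f),
    tumble_run_time_ratio_sd = stats::sd(ratios_f),
    mean_run_duration = mean(run_d),
    mean_tumble_duration = mean(tum_d),
    n_runs = length(run_d), n_tumbles = length(tum_d),
    run_speed = mean(run_sp), tumble_speed = mean(tum_sp),
    speed_ratio = mean(run_sp) / mean(tum_sp),
    mean_inter_run_angle = if (length(angles)) mean(angles) else NA_real_,
    persistence = mean(pers), persistence_sd = stats::sd(pers),
    threshold_A = object$density$threshold$threshold_A,
    threshold_fallback = object$density$threshold$fallback)
  class(out) <- "summary.rt_fit"
  out
}

#' @export
print.summary.rt_fit <- function(x, ...) {
  cat("Ensemble summary (", x$n_cells, "cells )\n")
  cat(sprintf("  runs: %d segments, mean duration %.2f min\n",
              x$n_runs, x$mean_run_duration))
  cat(sprintf("  tumbles: %d segments, mean duration %.2f min\n",
              x$n_tumbles, x$mean_tumble_duration))
  cat(sprintf("  tumble/run time ratio: %.3f +/- %.3f (mean +/- SD)\n",
              x$tumble_run_time_ratio, x$tumble_run_time_ratio_sd))
  cat(sprintf("  run speed %.2f, tumble speed %.2f um/min (ratio %.2f)\n",
              x$run_speed, x$tumble_speed, x$speed_ratio))
  cat(sprintf("  mean inter-run angle: %.1f deg\n", x$mean_inter_run_angle))
  cat(sprintf("  persistence: %.3f +/- %.3f\n", x$persistence,
              x$persistence_sd))
  cat(sprintf("  threshold_A = %.3f%s\n", x$threshold_A,
              if (x$threshold_fallback) " (unimodal fallback)" else ""))
  invisible(x)
}

#' Residual projection coordinates of a segmentation fit
#'
#' For diagnostics: per trajectory, the signed distance (in the
#' standardised (A,S) plane) of each interior frame's projection from the
#' threshold point; positive values are run-classified frames.
#'
#' @param object an `"rt_fit"`.
#' @param ... unused.
#' @return A list (per cell) of numeric vectors.
#' @export
residuals.rt_fit <- function(object, ...) {
  d <- object$density
  dir_ <- c(1 / d$sd_a, d$max_line$slope / d$sd_s)
  dir_ <- dir_ / sqrt(sum(dir_^2))
  thr_a <- d$threshold$threshold_A
  t0 <- (thr_a / d$sd_a) * dir_[1] +
    ((d$max_line$intercept + d$max_line$slope * thr_a) / d$sd_s) * dir_[2]
  lapply(object$series, function(s)
    (s$A / d$sd_a) * dir_[1] + (s$S / d$sd_s) * dir_[2] - t0)
}

#' Plot a segmentation fit
#'
#' Left: the P(A,S) density with the maximum line (blue) and the
#' perpendicular threshold line (red). Right: the 1D cross-section of the
#' density along the maximum line with the threshold abscissa marked.
#'
#' @param x an `"rt_fit"` or `"as_density"`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.rt_fit <- function(x, ...) {
  plot_as_density(x$density, ...)
  invisible(x)
}

#' @rdname plot.rt_fit
#' @export
plot_as_density <- function(x, ...) {
  d <- if (inherits(x, "rt_fit")) x$density else x
  stopifnot(inherits(d, "as_density"))
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(d$a_grid, d$s_grid, d$density, xlab = "alignment index A",
                  ylab = "scaled speed S", main = "P(A,S)",
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE), ...)
  if (!is.null(d$max_line))
    graphics::abline(d$max_line$intercept, d$max_line$slope,
                     col = "blue", lty = 2, lwd = 2)
  if (!is.null(d$threshold)) {
    thr_a <- d$threshold$threshold_A
    s0 <- d$max_line$intercept + d$max_line$slope * thr_a
    ## perpendicular in the standardised plane, drawn in raw coordinates
    m_perp <- -(d$sd_s^2 / d$sd_a^2) / d$max_line$slope
    graphics::abline(s0 - m_perp * thr_a, m_perp, col = "red", lty = 2, lwd = 2)
    cs <- d$threshold$cross_section
    graphics::plot(cs$a, cs$p, type = "l", xlab = "A (along maximum line)",
                   ylab = "P", main = "cross-section S*(A)")
    graphics::abline(v = thr_a, col = "red", lty = 2)
  }
  invisible(x)
}
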