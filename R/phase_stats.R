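#' Per-phase summary statistics of an annotated trajectory
#'
#' Computes the quantities used to characterise run-and-tumble migration:
#' segment durations, instantaneous per-phase speeds at the sampling
#' interval, the run/tumble speed ratio, angles between net displacements of
#' consecutive run segments, the tumble-to-run total-time ratio, and the
#' directional persistence (net displacement over path length).
#'
#' @param traj a [trajectory].
#' @param ann its `"phase_annotation"`.
#' @return An object of class `"phase_summary"`: list with
#'   `tumble_run_time_ratio`, `mean_run_duration`, `mean_tumble_duration`,
#'   `run_durations`, `tumble_durations`, `run_speed`, `tumble_speed`,
#'   `speed_ratio`, `inter_run_angles` (degrees), `persistence`, `n_runs`,
#'   `n_tumbles`, plus the per-frame `speeds` split by phase.
#' @export
phase_statistics <- function(traj, ann) {
  stopifnot(inherits(traj, "trajectory"), inherits(ann, "phase_annotation"))
  nf <- nrow(traj$pos) - 1L
  if (length(ann$phase) != nf ||
      max(abs(ann$frame_time - traj$time[seq_len(nf)])) > 1e-8)
    stop("annotation does not match trajectory '", traj$cell_id, "'")
  v <- diff(traj$pos)
  dts <- diff(traj$time)
  speed <- sqrt(rowSums(v^2)) / dts
  seg <- ann$segments
  run_seg <- seg[seg$phase == "run", , drop = FALSE]
  tum_seg <- seg[seg$phase == "tumble", , drop = FALSE]
  run_time <- sum(run_seg$duration)
  tumble_time <- sum(tum_seg$duration)
  is_run <- ann$phase == "run"
  run_speed <- if (any(is_run)) mean(speed[is_run]) else NA_real_
  tumble_speed <- if (any(!is_run)) mean(speed[!is_run]) else NA_real_
  ## net-displacement vector of each run segment (3D)
  net <- traj$pos[run_seg$end_frame + 1L, , drop = FALSE] -
    traj$pos[run_seg$start_frame, , drop = FALSE]
  angles <- if (nrow(run_seg) >= 2)
    vapply(seq_len(nrow(run_seg) - 1),
           function(k) angle_between(net[k, ], net[k + 1, ]), 0)
  else numeric(0)
  path <- sum(sqrt(rowSums(v^2)))
  net_disp <- sqrt(sum((traj$pos[nrow(traj$pos), ] - traj$pos[1, ])^2))
  structure(list(
    cell_id = traj$cell_id,
    tumble_run_time_ratio = if (run_time > 0) tumble_time / run_time else Inf,
    mean_run_duration = if (nrow(run_seg)) mean(run_seg$duration) else NA_real_,
    mean_tumble_duration = if (nrow(tum_seg)) mean(tum_seg$duration) else NA_real_,
    run_durations = run_seg$duration,
    tumble_durations = tum_seg$duration,
    run_time = run_time, tumble_time = tumble_time,
    run_speed = run_speed, tumble_speed = tumble_speed,
    speed_ratio = if (is.finite(run_speed) && is.finite(tumble_speed) &&
                      tumble_speed > 0) run_speed / tumble_speed else NA_real_,
    inter_run_angles = angles,
    persistence = if (path > 0) net_disp / path else 0,
    n_runs = nrow(run_seg), n_tumbles = nrow(tum_seg),
    speeds = split(speed, ifelse(is_run, "run", "tumble"))),
    class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat("Phase summary for", x$cell_id, "\n")
  cat(sprintf("  %d runs (mean %.2f min), %d tumbles (mean %.2f min)\n",
              x$n_runs, x$mean_run_duration, x$n_tumbles,
              x$mean_tumble_duration))
  cat(sprintf("  tumble/run time ratio %.3f, speed ratio %.2f, persistence %.3f\n",
              x$tumble_run_time_ratio, x$speed_ratio, x$persistence))
  invisible(x)
}

#' Maximum-likelihood exponential fit of phase durations
#'
#' Run and tumble durations are expected to be exponentially distributed
#' (standard deviation of the order of the mean). The ML estimate of the
#' exponential mean is the sample mean; a bootstrap percentile interval and
#' the SD/mean ratio (close to 1 under exponentiality) are returned as
#' diagnostics.
#'
#' @param durations positive durations, minutes.
#' @param n_boot bootstrap resamples for the confidence interval.
#' @param conf confidence level.
#' @return List with `mean`, `ci` (length 2), `sd_over_mean`, `n`.
#' @export
fit_exponential_durations <- function(durations, n_boot = 1000, conf = 0.95) {
  if (!length(durations)) stop("no durations supplied")
  if (any(durations <= 0)) stop("durations must be positive")
  if (length(durations) < 5)
    warning("fewer than 5 durations; estimate is unreliable")
  m <- mean(durations)
  ci <- if (length(durations) > 1) {
    boot <- vapply(seq_len(n_boot), function(i)
      mean(sample(durations, replace = TRUE)), 0)
    stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  } else c(NA_real_, NA_real_)
  list(mean = m, ci = ci,
       sd_over_mean = if (length(durations) > 1) stats::sd(durations) / m
       else NA_real_,
       n = length(durations))
}
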