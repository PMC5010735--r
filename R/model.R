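#' Parameters of the run-and-tumble pursuit model
#'
#' Cells are modelled as active Brownian particles in the plane switching
#' stochastically between run and tumble states (durations i.i.d.
#' exponential with means `tau_r` and `tau_t`). At each run start the cell
#' perceives the bearing to the current target position with a Gaussian
#' angular error of SD `sigma_eps`; during the run the heading fluctuates
#' around that bearing as an Ornstein-Uhlenbeck process on the angle
#' (relaxation time `tau_rel`, stationary SD `sqrt(D_theta)`), while the
#' speed is redrawn every `dt` from a zero-truncated normal. During tumbles
#' the heading is redrawn uniformly at every step and the speed follows the
#' (slower) tumble distribution. The target starts at `(d0, 0)` and moves
#' along +x at `v_target`.
#'
#' Default parameter values are the control calibration shipped with the
#' package (see [rt_params_control()]); `d0` and `v_target` are not
#' identified by the summary statistics and default to values at which the
#' pursuit feedback operates within `t_e` (see the methods vignette).
#'
#' @param tau_r,tau_t mean run and tumble durations, minutes.
#' @param v_run_mean,v_run_sd run-speed distribution, micrometres/min.
#' @param v_tumble_mean,v_tumble_sd tumble-speed distribution.
#' @param D_theta stationary variance of the heading fluctuation during
#'   runs, rad^2.
#' @param tau_rel relaxation time of the heading fluctuation, minutes.
#' @param sigma_eps SD of the target-detection angular error at run start,
#'   radians.
#' @param v_target target speed, micrometres/min.
#' @param d0 initial cell-target distance, micrometres.
#' @param t_e evaluation time for pursuit read-outs, minutes.
#' @param dt integration step, minutes.
#' @param sample_interval output sampling interval, minutes.
#' @param n_cells ensemble size.
#' @param seed master seed; per-cell substreams are derived from it so the
#'   ensemble is reproducible independent of evaluation order.
#' @param tumble_mode `"redraw"` (isotropic heading redraw each step,
#'   default) or `"diffusion"` (rotational diffusion with coefficient
#'   `D_tumble` rad^2/min).
#' @param D_tumble rotational diffusion coefficient of the `"diffusion"`
#'   tumble variant.
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(tau_r = 2.337, tau_t = 1.548,
                       v_run_mean = 4.15, v_run_sd = 1.66,
                       v_tumble_mean = 8.16, v_tumble_sd = 4.08,
                       D_theta = 0.757, tau_rel = 1, sigma_eps = 0.375,
                       v_target = 0.4, d0 = 140, t_e = 90, dt = 0.1,
                       sample_interval = 1.5, n_cells = 23, seed = 1,
                       tumble_mode = c("redraw", "diffusion"),
                       D_tumble = 2) {
  p <- list(tau_r = tau_r, tau_t = tau_t, v_run_mean = v_run_mean,
            v_run_sd = v_run_sd, v_tumble_mean = v_tumble_mean,
            v_tumble_sd = v_tumble_sd, D_theta = D_theta, tau_rel = tau_rel,
            sigma_eps = sigma_eps, v_target = v_target, d0 = d0, t_e = t_e,
            dt = dt, sample_interval = sample_interval,
            n_cells = as.integer(n_cells), seed = seed,
            tumble_mode = match.arg(tumble_mode), D_tumble = D_tumble)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  pos <- c("tau_r", "tau_t", "v_run_mean", "v_tumble_mean", "v_target",
           "d0", "t_e", "dt", "sample_interval", "tau_rel")
  for (f in pos)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop("sim_params: '", f, "' must be a positive number")
  nonneg <- c("v_run_sd", "v_tumble_sd", "D_theta", "sigma_eps", "D_tumble")
  for (f in nonneg)
    if (!is.numeric(p[[f]]) || p[[f]] < 0)
      stop("sim_params: '", f, "' must be non-negative")
  if (p$dt > p$sample_interval / 3 + 1e-12)
    stop("sim_params: dt must be <= sample_interval/3")
  if (abs(p$t_e / p$sample_interval - round(p$t_e / p$sample_interval)) > 1e-9)
    stop("sim_params: t_e must be a multiple of sample_interval")
  if (p$n_cells < 1) stop("sim_params: n_cells must be >= 1")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Run-and-tumble model parameters:\n")
  cat(sprintf("  tau_r = %.3g min, tau_t = %.3g min\n", x$tau_r, x$tau_t))
  cat(sprintf("  run speed %.3g +/- %.3g, tumble speed %.3g +/- %.3g um/min\n",
              x$v_run_mean, x$v_run_sd, x$v_tumble_mean, x$v_tumble_sd))
  cat(sprintf("  D_theta = %.3g rad^2 (tau_rel %.3g min), sigma_eps = %.3g rad\n",
              x$D_theta, x$tau_rel, x$sigma_eps))
  cat(sprintf("  target: v = %.3g um/min, d0 = %.3g um; t_e = %.3g min\n",
              x$v_target, x$d0, x$t_e))
  cat(sprintf("  dt = %.3g min, sampling %.3g min, n_cells = %d, seed = %.0f\n",
              x$dt, x$sample_interval, x$n_cells, x$seed))
  invisible(x)
}

#' Modify simulation parameters
#'
#' @param object a `"sim_params"`.
#' @param ... named fields to replace.
#' @return A revalidated `"sim_params"`.
#' @export
update.sim_params <- function(object, ...) {
  mods <- list(...)
  bad <- setdiff(names(mods), names(object))
  if (length(bad)) stop("unknown sim_params field(s): ",
                        paste(bad, collapse = ", "))
  object[names(mods)] <- mods
  if (!is.null(mods$n_cells)) object$n_cells <- as.integer(object$n_cells)
  validate_sim_params(object)
  structure(object, class = "sim_params")
}

## Target position at elapsed time t (minutes).
target_position <- function(p, t) cbind(p$d0 + p$v_target * t, 0)

#' Simulate one run-and-tumble cell
#'
#' Integrates the model of [sim_params()] for `duration` minutes at step
#' `dt` and returns the trajectory subsampled at `sample_interval`, with
#' exact ground-truth labels (per sampled frame, the state occupying the
#' majority of that interval) and the true continuous segment list.
#'
#' @param p a `"sim_params"`.
#' @param cell_index index of the cell's RNG substream.
#' @param duration simulated time, minutes; defaults to `p$t_e`.
#' @return A [trajectory] (z = 0) with attributes `labels` (a
#'   `"phase_annotation"` of the ground truth) and `true_segments`
#'   (data.frame of continuous state durations).
#' @export
simulate_cell <- function(p, cell_index = 1, duration = p$t_e) {
  stopifnot(inherits(p, "sim_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(p$seed, cell_index))
  n_steps <- round(duration / p$dt)
  dt <- p$dt
  theta <- numeric(n_steps); v <- numeric(n_steps)
  state <- character(0); seg_dur <- numeric(0)
  step_state <- integer(n_steps)        # 1 = run, 2 = tumble
  xy <- matrix(0, n_steps + 1, 2)
  filled <- 0L
  pos <- c(0, 0)
  alpha <- 1 - dt / p$tau_rel
  sd_step <- sqrt(2 * p$D_theta * dt / p$tau_rel)
  cur <- if (stats::runif(1) < p$tau_r / (p$tau_r + p$tau_t)) 1L else 2L
  while (filled < n_steps) {
    dur <- stats::rexp(1, 1 / (if (cur == 1L) p$tau_r else p$tau_t))
    k <- max(1L, round(dur / dt))
    k <- min(k, n_steps - filled)
    idx <- (filled + 1L):(filled + k)
    if (cur == 1L) {
      bearing <- atan2(0 - pos[2],
                       p$d0 + p$v_target * (filled * dt) - pos[1])
      mu <- bearing + stats::rnorm(1, 0, p$sigma_eps)
      eps <- stats::rnorm(k, 0, sd_step)
      dev <- as.numeric(stats::filter(eps, alpha, method = "recursive"))
      theta[idx] <- mu + dev
      v[idx] <- rtruncnorm0(k, p$v_run_mean, p$v_run_sd)
    } else {
      if (p$tumble_mode == "redraw") {
        theta[idx] <- stats::runif(k, -pi, pi)
      } else {
        th0 <- stats::runif(1, -pi, pi)
        theta[idx] <- th0 + cumsum(stats::rnorm(k, 0, sqrt(2 * p$D_tumble * dt)))
      }
      v[idx] <- rtruncnorm0(k, p$v_tumble_mean, p$v_tumble_sd)
    }
    step_state[idx] <- cur
    dxy <- cbind(v[idx] * cos(theta[idx]), v[idx] * sin(theta[idx])) * dt
    xy[idx + 1L, 1] <- pos[1] + cumsum(dxy[, 1])
    xy[idx + 1L, 2] <- pos[2] + cumsum(dxy[, 2])
    pos <- xy[filled + k + 1L, ]
    state <- c(state, if (cur == 1L) "run" else "tumble")
    seg_dur <- c(seg_dur, k * dt)
    filled <- filled + k
    cur <- 3L - cur
  }
  ## subsample at the output interval
  stride <- round(p$sample_interval / dt)
  samp <- seq(1L, n_steps + 1L, by = stride)
  times <- (samp - 1L) * dt
  tr <- trajectory(paste0("sim", cell_index), times,
                   xy[samp, 1], xy[samp, 2], 0, condition = "simulated")
  ## majority state per sampled frame
  nfr <- length(samp) - 1L
  frame_lab <- vapply(seq_len(nfr), function(i) {
    s <- step_state[(samp[i]):(samp[i + 1L] - 1L)]
    if (mean(s == 1L) >= 0.5) "run" else "tumble"
  }, "")
  ann <- new_phase_annotation(tr$cell_id, frame_time = times[seq_len(nfr)],
                              phase = frame_lab, dt = p$sample_interval,
                              traj_time = times)
  attr(tr, "labels") <- ann
  attr(tr, "true_segments") <- data.frame(phase = state, duration = seg_dur)
  tr
}

#' Simulate an ensemble of model cells
#'
#' @param object a `"sim_params"`.
#' @param nsim number of cells; defaults to `object$n_cells`.
#' @param seed optional master-seed override.
#' @param duration simulated minutes per cell (default `object$t_e`).
#' @param ... unused.
#' @return A `"trajectory_list"` with attributes `labels` (list of
#'   ground-truth `"phase_annotation"`) and `true_segments` (one pooled
#'   data.frame with a `cell` column).
#' @export
simulate.sim_params <- function(object, nsim = object$n_cells, seed = NULL,
                                duration = object$t_e, ...) {
  if (!is.null(seed)) object <- update(object, seed = seed)
  cells <- lapply(seq_len(nsim), function(i)
    simulate_cell(object, i, duration))
  labels <- lapply(cells, attr, "labels")
  segs <- do.call(rbind, lapply(seq_along(cells), function(i) {
    s <- attr(cells[[i]], "true_segments"); s$cell <- i; s
  }))
  cells <- lapply(cells, function(tr) {
    attr(tr, "labels") <- NULL; attr(tr, "true_segments") <- NULL; tr
  })
  out <- new_trajectory_list(cells)
  attr(out, "labels") <- labels
  names(attr(out, "labels")) <- names(out)
  attr(out, "true_segments") <- segs
  out
}

#' Distance-to-target and dispersion of an ensemble
#'
#' @param trajs a `"trajectory_list"` of simulated cells.
#' @param p the `"sim_params"` used (for the target path).
#' @param t_e evaluation time, minutes (default `p$t_e`).
#' @return List with `mean_distance` (mean Euclidean distance to the target
#'   at `t_e`, micrometres) and `dispersion` (unbiased var(x) + var(y) of
#'   the positions at `t_e`, micrometres^2).
#' @export
evaluate_ensemble <- function(trajs, p, t_e = p$t_e) {
  stopifnot(inherits(trajs, "trajectory_list"))
  if (length(trajs) < 2) stop("dispersion needs at least 2 cells")
  fin <- t(vapply(unclass(trajs), function(tr) {
    if (max(tr$time) < t_e - 1e-9)
      stop("trajectory ", tr$cell_id, " does not reach t_e")
    i <- which.min(abs(tr$time - t_e))
    tr$pos[i, 1:2]
  }, numeric(2)))
  tp <- target_position(p, t_e)
  list(mean_distance = mean(sqrt((fin[, 1] - tp[1])^2 + (fin[, 2] - tp[2])^2)),
       dispersion = stats::var(fin[, 1]) + stats::var(fin[, 2]))
}

#' Sweep the mean run time and measure migration precision
#'
#' Scales `tau_r` by each factor, simulates `n_reps` independent ensembles
#' of `p$n_cells` cells per factor, and records the mean distance to target
#' and the positional dispersion at `t_e`, averaged over replicates. With a
#' fixed master seed the whole sweep is bit-reproducible.
#'
#' @param p a `"sim_params"`.
#' @param factors positive multipliers of `tau_r`.
#' @param n_reps replicate ensembles per factor.
#' @return A data.frame of class `"sweep_result"` with columns `factor`,
#'   `tau_r`, `mean_distance`, `dispersion`, `n_reps`.
#' @export
sweep_run_time <- function(p, factors = c(0.2, 0.5, 1, 2, 5), n_reps = 100) {
  stopifnot(inherits(p, "sim_params"))
  if (any(factors <= 0)) stop("factors must be positive")
  rows <- lapply(seq_along(factors), function(fi) {
    f <- factors[fi]
    pf <- update(p, tau_r = p$tau_r * f)
    res <- vapply(seq_len(n_reps), function(r) {
      pr <- update(pf, seed = derive_seed(p$seed, fi * 100000 + r))
      ens <- simulate.sim_params(pr)
      ev <- evaluate_ensemble(ens, pr)
      c(ev$mean_distance, ev$dispersion)
    }, numeric(2))
    data.frame(factor = f, tau_r = pf$tau_r,
               mean_distance = mean(res[1, ]), dispersion = mean(res[2, ]),
               n_reps = n_reps)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Run-time sweep (", x$n_reps[1], "replicates per point ):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
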