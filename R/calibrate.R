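#' Calibration targets: measured summary statistics to reproduce
#'
#' The simulator is constrained by requiring that simulated tracks,
#' segmented exactly like experimental ones, reproduce a set of measured
#' summary statistics. Built-in target sets carry the control statistics of
#' single mesendoderm progenitors in MZoep hosts (`"mzoep_control"`) and wt
#' hosts (`"wt_control"`); any statistic can be overridden or dropped (NA).
#'
#' @param condition `"mzoep_control"`, `"wt_control"` or `"custom"`.
#' @param mean_run_duration,mean_tumble_duration minutes (segmented).
#' @param speed_ratio run/tumble mean instantaneous speed ratio.
#' @param mean_inter_run_angle degrees between consecutive segmented runs.
#' @param tumble_run_time_ratio mean per-cell total tumble/run time ratio.
#' @param persistence net displacement / path length, per-cell mean.
#' @param run_speed mean run-phase speed, micrometres/min (sets the
#'   absolute speed scale, which ratio statistics leave free).
#' @param weights named non-negative weights per statistic; statistics with
#'   NA target or zero weight are ignored.
#' @return A list of class `"calibration_targets"`.
#' @export
calibration_targets <- function(condition = c("mzoep_control", "wt_control",
                                              "custom"),
                                mean_run_duration = NULL,
                                mean_tumble_duration = NULL,
                                speed_ratio = NULL,
                                mean_inter_run_angle = NULL,
                                tumble_run_time_ratio = NULL,
                                persistence = NULL,
                                run_speed = NULL,
                                weights = NULL) {
  condition <- match.arg(condition)
  base <- switch(condition,
    mzoep_control = list(mean_run_duration = 5, mean_tumble_duration = 3.1,
                         speed_ratio = 1.8, mean_inter_run_angle = 68,
                         tumble_run_time_ratio = 0.68, persistence = NA,
                         run_speed = 3),
    wt_control = list(mean_run_duration = 5, mean_tumble_duration = 3.1,
                      speed_ratio = 1.8, mean_inter_run_angle = 56,
                      tumble_run_time_ratio = 0.58, persistence = 0.68,
                      run_speed = 3),
    custom = list(mean_run_duration = NA, mean_tumble_duration = NA,
                  speed_ratio = NA, mean_inter_run_angle = NA,
                  tumble_run_time_ratio = NA, persistence = NA,
                  run_speed = NA))
  override <- list(mean_run_duration = mean_run_duration,
                   mean_tumble_duration = mean_tumble_duration,
                   speed_ratio = speed_ratio,
                   mean_inter_run_angle = mean_inter_run_angle,
                   tumble_run_time_ratio = tumble_run_time_ratio,
                   persistence = persistence, run_speed = run_speed)
  for (nm in names(override))
    if (!is.null(override[[nm]])) base[[nm]] <- override[[nm]]
  w <- stats::setNames(rep(1, length(base)), names(base))
  if (!is.null(weights)) w[names(weights)] <- weights
  if (any(w < 0)) stop("weights must be non-negative")
  vals <- unlist(base)
  use <- is.finite(vals) & w[names(vals)] > 0
  if (!any(use)) stop("no usable calibration target")
  if (any(vals[use] <= 0)) stop("targets must be positive")
  structure(list(values = vals, weights = w, condition = condition),
            class = "calibration_targets")
}

#' @export
print.calibration_targets <- function(x, ...) {
  cat("Calibration targets (", x$condition, ")\n")
  df <- data.frame(target = x$values, weight = x$weights[names(x$values)])
  print(df, digits = 3)
  invisible(x)
}

## Summary-statistic vector of a simulated, segmented ensemble.
segmented_statistics <- function(p, n_cells, duration, window = 1,
                                 min_segment = 1) {
  ens <- simulate.sim_params(p, nsim = n_cells, duration = duration)
  fit <- rt_fit(ens, window = window, min_segment = min_segment)
  s <- summary(fit)
  c(mean_run_duration = s$mean_run_duration,
    mean_tumble_duration = s$mean_tumble_duration,
    speed_ratio = s$speed_ratio,
    mean_inter_run_angle = s$mean_inter_run_angle,
    tumble_run_time_ratio = s$tumble_run_time_ratio,
    persistence = s$persistence,
    run_speed = s$run_speed,
    fallback = as.numeric(s$threshold_fallback))
}

#' Calibration objective: weighted relative squared error
#'
#' Simulates an ensemble under `params`, segments it with the same A/S
#' pipeline applied to experimental data, and returns
#' sum over statistics of w * ((sim - target)/target)^2. Deterministic
#' given `seed` (common random numbers across evaluations).
#'
#' @param params a `"sim_params"`.
#' @param targets a `"calibration_targets"`.
#' @param n_cells,duration ensemble size and track length (minutes).
#' @param seed RNG seed shared across evaluations.
#' @param n_seeds independent ensembles averaged per evaluation; keeps the
#'   Monte-Carlo noise of the objective below the residuals being resolved.
#' @return Scalar objective; attribute `"stats"` holds the simulated
#'   statistics, `"residuals"` the per-statistic relative residuals.
#' @export
calibration_objective <- function(params, targets, n_cells = 23,
                                  duration = 120, seed = 1, n_seeds = 1,
                                  window = 1, min_segment = 1) {
  stopifnot(inherits(params, "sim_params"),
            inherits(targets, "calibration_targets"))
  sims <- lapply(seq_len(n_seeds), function(k) {
    p <- update(params, seed = derive_seed(seed, 7000 + k))
    tryCatch(segmented_statistics(p, n_cells, duration, window = window,
                                  min_segment = min_segment),
             error = function(e) NULL)
  })
  sims <- sims[!vapply(sims, is.null, TRUE)]
  if (!length(sims)) {
    out <- 1e6
    attr(out, "stats") <- NULL
    return(out)
  }
  smat <- do.call(rbind, sims)
  sim <- colMeans(smat)
  tv <- targets$values; w <- targets$weights[names(tv)]
  use <- is.finite(tv) & w > 0 & is.finite(sim[names(tv)])
  resid <- (sim[names(tv)][use] - tv[use]) / tv[use]
  out <- sum(w[use] * resid^2)
  ## a unimodal cross-section means the run/tumble separation has broken
  ## down; such parameter regions must not attract the search
  if (isTRUE(sim[["fallback"]] > 0)) out <- out + 10 * sim[["fallback"]]
  ## penalise regimes where the measured statistics are unstable across
  ## independent ensembles (a fragile density threshold): the statistic of
  ## interest must be a property of the parameters, not of the seed
  if (nrow(smat) > 1) {
    spread <- apply(smat[, names(tv)[use], drop = FALSE], 2, stats::sd) /
      tv[use]
    out <- out + sum(w[use] * spread^2)
  }
  sim <- sim[names(sim) != "fallback"]
  attr(out, "stats") <- sim
  attr(out, "residuals") <- resid
  out
}

default_bounds <- function() {
  ## v_tumble_mean is the per-step speed; isotropic redraws cancel over a
  ## sampling frame, so its feasible range extends well above the measured
  ## frame-scale tumble speed. tau_t is bounded away from the sub-frame
  ## regime: tumbles much shorter than the 1.5-min sampling interval are
  ## undetectable, run-merging becomes near-critical there, and the
  ## measured statistics cease to be well-posed functions of the parameters
  ## sigma_eps (per-run aiming error) and D_theta (within-run wander) are
  ## nearly interchangeable for the summary statistics but not for pursuit
  ## precision: systematic aiming errors amplify with run length while
  ## wander averages out. Only the small-sigma branch reproduces the
  ## dispersion minimum of the pursuit model, so the search is confined to it.
  list(tau_r = c(1.8, 8), tau_t = c(1.3, 5),
       v_run_mean = c(2, 6), v_tumble_mean = c(1, 9),
       sigma_eps = c(0.15, 0.6), D_theta = c(0.1, 1.2))
}

#' Calibrate the run-and-tumble model against measured statistics
#'
#' Latin-hypercube screening over the box `bounds` (half the budget)
#' followed by coordinate-wise local refinement (the other half), with
#' common random numbers across all evaluations so Monte-Carlo noise does
#' not drive the search. Parameters not named in `bounds` stay at their
#' `base_params` values; run/tumble speed SDs track the corresponding means
#' at the `base_params` coefficient of variation unless bounded explicitly.
#'
#' @param targets a `"calibration_targets"`.
#' @param bounds named list of `c(lower, upper)` per searched parameter.
#' @param budget total objective evaluations (>= 20).
#' @param n_cells,duration ensemble size and track length per evaluation.
#' @param n_seeds ensembles averaged per evaluation (variance reduction).
#' @param seed master seed (also the common-random-numbers seed).
#' @param base_params starting `"sim_params"`.
#' @return An object of class `"rt_calibration"`: `best_params`
#'   (`"sim_params"`), `objective_value`, `stats` (simulated statistics at
#'   the optimum), `residuals`, `trace` (data.frame of all evaluations),
#'   `converged`.
#' @export
calibrate <- function(targets, bounds = default_bounds(), budget = 300,
                      n_cells = 46, duration = 120, n_seeds = 2, seed = 1,
                      base_params = sim_params(), window = 1,
                      min_segment = 1) {
  stopifnot(inherits(targets, "calibration_targets"))
  if (budget < 20) stop("budget must be at least 20 evaluations")
  par_names <- names(bounds)
  bad <- setdiff(par_names, names(base_params))
  if (length(bad)) stop("unknown parameter(s) in bounds: ",
                        paste(bad, collapse = ", "))
  lo <- vapply(bounds, `[`, 0, 1); hi <- vapply(bounds, `[`, 0, 2)
  if (any(hi <= lo)) stop("empty feasible region in bounds")
  cv_run <- base_params$v_run_sd / base_params$v_run_mean
  cv_tum <- base_params$v_tumble_sd / base_params$v_tumble_mean
  make_params <- function(x) {
    p <- base_params
    p[par_names] <- as.list(x)
    if ("v_run_mean" %in% par_names && !"v_run_sd" %in% par_names)
      p$v_run_sd <- cv_run * p$v_run_mean
    if ("v_tumble_mean" %in% par_names && !"v_tumble_sd" %in% par_names)
      p$v_tumble_sd <- cv_tum * p$v_tumble_mean
    validate_sim_params(p)
    structure(p, class = "sim_params")
  }
  trace <- list()
  n_eval <- 0L
  eval_point <- function(x) {
    n_eval <<- n_eval + 1L
    val <- calibration_objective(make_params(x), targets, n_cells, duration,
                                 seed = seed, n_seeds = n_seeds,
                                 window = window, min_segment = min_segment)
    trace[[n_eval]] <<- c(eval = n_eval, objective = as.numeric(val),
                          stats::setNames(x, par_names))
    val
  }
  ## stage 1: Latin-hypercube screen
  n_screen <- max(10L, floor(budget / 2))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  set.seed(derive_seed(seed, 999))
  grid <- lhs::randomLHS(n_screen, length(par_names))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  pts <- sweep(sweep(grid, 2, hi - lo, `*`), 2, lo, `+`)
  vals <- apply(pts, 1, function(x) as.numeric(eval_point(x)))
  ## stage 2: coordinate-wise refinement with shrinking steps, restarted
  ## from the best screening candidates (the objective is multi-modal)
  descend <- function(x0, v0, max_eval) {
    x <- x0; v <- v0
    step <- (hi - lo) / 8
    start <- n_eval
    while (n_eval - start < max_eval && n_eval < budget) {
      improved <- FALSE
      for (j in seq_along(par_names)) {
        if (n_eval - start >= max_eval || n_eval >= budget) break
        for (dir in c(-1, 1)) {
          if (n_eval - start >= max_eval || n_eval >= budget) break
          cand <- x
          cand[j] <- min(hi[j], max(lo[j], cand[j] + dir * step[j]))
          if (cand[j] == x[j]) next
          vc <- as.numeric(eval_point(cand))
          if (vc < v) { v <- vc; x <- cand; improved <- TRUE }
        }
      }
      if (!improved) {
        step <- step / 2
        if (all(step < (hi - lo) * 1e-3)) break
      }
    }
    list(x = x, v = v, step = step)
  }
  n_starts <- min(3L, n_screen)
  ord <- order(vals)[seq_len(n_starts)]
  remain <- budget - n_eval
  runs <- list()
  for (s in seq_len(n_starts)) {
    if (n_eval >= budget) break
    runs[[s]] <- descend(pts[ord[s], ], vals[ord[s]],
                         max_eval = ceiling(remain / n_starts))
  }
  best <- runs[[which.min(vapply(runs, `[[`, 0, "v"))]]
  ## polish the winner with any leftover budget
  if (n_eval < budget) best <- descend(best$x, best$v, budget - n_eval)
  best_x <- best$x; best_v <- best$v
  converged <- all(best$step < (hi - lo) / 8 + 1e-12) && best_v < 0.5
  best_params <- make_params(best_x)
  final <- calibration_objective(best_params, targets, n_cells, duration,
                                 seed = seed, n_seeds = n_seeds,
                                 window = window, min_segment = min_segment)
  structure(list(best_params = best_params,
                 objective_value = as.numeric(final),
                 stats = attr(final, "stats"),
                 residuals = attr(final, "residuals"),
                 targets = targets,
                 trace = as.data.frame(do.call(rbind, trace)),
                 converged = converged && n_eval <= budget,
                 n_eval = n_eval),
            class = "rt_calibration")
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat("Run-and-tumble model calibration (", x$n_eval, "evaluations,",
      if (x$converged) "converged" else "not converged", ")\n")
  cat(sprintf("  objective = %.4g\n", x$objective_value))
  tv <- x$targets$values
  use <- names(x$residuals)
  df <- data.frame(target = tv[use], simulated = x$stats[use],
                   rel_residual = x$residuals)
  print(df, digits = 3)
  invisible(x)
}

#' @export
coef.rt_calibration <- function(object, ...) {
  p <- object$best_params
  unlist(p[c("tau_r", "tau_t", "v_run_mean", "v_run_sd", "v_tumble_mean",
             "v_tumble_sd", "D_theta", "sigma_eps")])
}
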