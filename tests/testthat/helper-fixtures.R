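## Shared fixtures, built in code.

## A straight constant-speed track along +x.
straight_track <- function(n = 20, dt = 1.5, speed = 2) {
  trajectory("straight", time = seq(0, by = dt, length.out = n),
             x = seq(0, by = speed * dt, length.out = n), y = 0)
}

## A track reversing direction every frame.
zigzag_track <- function(n = 20, dt = 1.5, step = 3) {
  trajectory("zigzag", time = seq(0, by = dt, length.out = n),
             x = rep(c(0, step), length.out = n), y = 0)
}

## Small well-formed track table on disk; returns the path.
write_demo_tracks <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    cell_id = rep(c("a", "b"), each = 3),
    time_min = rep(c(0, 1.5, 3), 2),
    x_um = c(0, 1, 2, 5, 6, 8),
    y_um = c(0, 0.5, 1, 0, 0, 1),
    z_um = 0,
    condition = "control")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

## An as_density with hand-set line/threshold for classification tests.
manual_density <- function(slope = 0, intercept = 1, threshold_A = 0.5) {
  set.seed(1)
  pts <- data.frame(A = runif(600, -1, 1), S = runif(600, 0, 2))
  d <- suppressWarnings(estimate_density(list(pts)))
  d$sd_a <- 1; d$sd_s <- 1
  d$max_line <- list(slope = slope, intercept = intercept)
  d$threshold <- list(threshold_A = threshold_A, fallback = FALSE)
  d
}

## Well-separated two-state parameters: strong speed and alignment
## contrast, segments long against the sampling interval so transition
## frames (whose evidence genuinely straddles both states) are rare.
## (the generative tumble speed is per-dt; isotropic redraws cancel over a
## frame, so the measured tumble frame speed is ~3x below the run speed)
separated_params <- function(...) {
  sim_params(tau_r = 15, tau_t = 10, v_run_mean = 5, v_run_sd = 1,
             v_tumble_mean = 6, v_tumble_sd = 3, D_theta = 0.05,
             sigma_eps = 0.6, ...)
}
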