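test_that("alignment and scaled speed match their definitions", {
  ## straight constant-speed motion: A = 1 everywhere, S = 1 everywhere
  ser <- as_series(straight_track(20), window = 2)
  expect_true(all(abs(ser$A - 1) < 1e-12))
  expect_true(all(abs(ser$S - 1) < 1e-12))

  ## frame-to-frame reversals: perfectly anti-aligned
  ser <- as_series(zigzag_track(20), window = 1)
  expect_true(all(abs(ser$A + 1) < 1e-12))

  ## independent brute-force evaluation of the definition on a rough track
  set.seed(42)
  n <- 100; dt <- 1.5; w <- 2
  pos <- apply(matrix(rnorm(3 * n), n, 3), 2, cumsum)
  tr <- trajectory("r", seq(0, by = dt, length.out = n),
                   pos[, 1], pos[, 2], pos[, 3])
  ser <- as_series(tr, window = w)
  v <- diff(pos)
  speeds <- sqrt(rowSums(v^2)) / dt
  for (row in c(1, 25, 95)) {
    i <- ser$frame[row]
    cosines <- sapply(setdiff((i - w):(i + w), i), function(k) {
      sum(v[i, ] * v[k, ]) /
        (sqrt(sum(v[i, ]^2)) * sqrt(sum(v[k, ]^2)))
    })
    expect_equal(ser$A[row], mean(cosines), tolerance = 1e-12)
    expect_equal(ser$S[row], speeds[i] / mean(speeds), tolerance = 1e-12)
  }

  ## contract errors
  expect_error(as_series(straight_track(3), window = 2), "too short")
  tr_bad <- trajectory("nu", c(0, 1.5, 3.2, 4.5), 1:4, 0)
  expect_error(as_series(tr_bad), "non-uniform")
})

test_that("the A/S density is a unit-mass estimate that is flat for uniform input", {
  set.seed(7)
  n <- 1e5
  pts <- data.frame(A = runif(n, -1, 1), S = runif(n, 0, 3))
  d <- estimate_density(list(pts), bandwidth = 0)   # raw histogram for the test
  da <- diff(d$a_grid)[1]; ds <- diff(d$s_grid)[1]
  expect_equal(sum(d$density) * da * ds, 1, tolerance = 1e-9)
  counts <- d$density * n * da * ds
  chi2 <- sum((counts - n / length(counts))^2 / (n / length(counts)))
  p <- pchisq(chi2, df = length(counts) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)

  ## smoothing preserves unit mass
  d2 <- estimate_density(list(pts), bandwidth = 1.5)
  expect_equal(sum(d2$density) * da * ds, 1, tolerance = 1e-9)

  ## two well-separated clusters produce two local maxima along the A axis
  set.seed(8)
  cl <- data.frame(A = c(rnorm(5000, -0.5, 0.07), rnorm(5000, 0.7, 0.07)),
                   S = c(rnorm(5000, 0.5, 0.1), rnorm(5000, 1.5, 0.1)))
  d3 <- estimate_density(list(cl))
  marg <- apply(d3$density, 1, max)
  dd <- sign(diff(marg)); dd[dd == 0] <- 1
  n_max <- sum(diff(dd) < 0)
  expect_equal(n_max, 2)

  expect_error(estimate_density(list(data.frame(A = numeric(),
                                                S = numeric()))), "no \\(A,S\\)")
  same <- data.frame(A = rep(0.5, 600), S = rep(1, 600))
  expect_error(estimate_density(list(same)), "degenerate")
})

test_that("the maximum line recovers a planted ridge", {
  set.seed(9)
  a <- runif(20000, -0.9, 0.9)
  s <- 0.5 * a + 0.8 + rnorm(20000, 0, 0.05)
  d <- estimate_density(list(data.frame(A = a, S = pmax(s, 0))))
  d <- fit_maximum_line(d)
  expect_lt(abs(d$max_line$slope - 0.5), 0.05)
  expect_lt(abs(d$max_line$intercept - 0.8), 0.05)

  ## isotropic blob: slope ~ 0
  set.seed(10)
  blob <- data.frame(A = rnorm(20000, 0, 0.15), S = rnorm(20000, 1.5, 0.15))
  db <- fit_maximum_line(estimate_density(list(blob)))
  expect_lt(abs(db$max_line$slope), 0.1)

  ## all mass in one A column cannot support a line
  set.seed(11)
  onecol <- data.frame(A = rep(0.495, 5000), S = runif(5000, 0, 3))
  expect_error(fit_maximum_line(estimate_density(list(onecol),
                                                 bandwidth = 0)),
               "fewer than 2")
})

test_that("the threshold sits at the valley of a planted bimodal cross-section", {
  ## mass concentrated on the S = 1 line with bimodal A: the cross-section
  ## is the analytic two-Gaussian mixture whose minimum is at A = 0.5
  set.seed(12)
  n <- 40000
  a <- c(rnorm(n / 2, 0.2, 0.1), rnorm(n / 2, 0.8, 0.1))
  d <- estimate_density(list(data.frame(A = a, S = rnorm(n, 1, 0.08))))
  d <- fit_maximum_line(d)
  d <- find_threshold(d)
  expect_false(d$threshold$fallback)
  expect_equal(d$threshold$threshold_A, 0.5, tolerance = 0.05)
  expect_true(is.data.frame(d$threshold$cross_section))

  ## unimodal profile falls back and says so
  set.seed(13)
  uni <- data.frame(A = rnorm(20000, 0.6, 0.12), S = rnorm(20000, 1, 0.1))
  du <- find_threshold(fit_maximum_line(estimate_density(list(uni))))
  expect_true(du$threshold$fallback)
})

test_that("phase classification follows the perpendicular threshold rule", {
  d <- manual_density(slope = 0, intercept = 1, threshold_A = 0.5)
  ## straight fast track: every frame projects above the threshold -> run
  ann <- classify_phases(straight_track(20), d)
  expect_equal(nrow(ann$segments), 1)
  expect_equal(ann$segments$phase, "run")
  ## segments tile the track exactly
  expect_equal(sum(ann$segments$duration), 19 * 1.5)

  ## slow unaligned track (A ~ -1 from reversals) -> single tumble
  ann2 <- classify_phases(zigzag_track(20), d)
  expect_equal(ann2$segments$phase, "tumble")
  expect_equal(sum(ann2$segments$duration), 19 * 1.5)
})

test_that("segmentation recovers ground-truth labels on well-separated tracks", {
  p <- separated_params(seed = 33)
  ens <- simulate(p, nsim = 20, duration = 120)
  fit <- rt_fit(ens)
  truth <- attr(ens, "labels")
  agree <- mean(unlist(Map(function(a, b)
    as.character(a$phase) == as.character(b$phase),
    fit$annotations, truth)))
  expect_gte(agree, 0.9)

  ## segmentation is deterministic given identical inputs
  fit2 <- rt_fit(ens)
  expect_identical(lapply(fit$annotations, `[[`, "phase"),
                   lapply(fit2$annotations, `[[`, "phase"))

  ## recovered mean durations within 20% of the frame-level ground truth
  s <- summary(fit)
  gt <- Map(phase_statistics, unclass(ens), truth)
  gt_run <- mean(unlist(lapply(gt, `[[`, "run_durations")))
  gt_tum <- mean(unlist(lapply(gt, `[[`, "tumble_durations")))
  expect_lt(abs(s$mean_run_duration - gt_run) / gt_run, 0.2)
  expect_lt(abs(s$mean_tumble_duration - gt_tum) / gt_tum, 0.2)
})

test_that("the short-track 45-degree rule implements the persistence criterion", {
  dt <- 1 / 6  # ten-second frames
  ## straight: one run, no tumbles
  tr <- trajectory("s", seq(0, by = dt, length.out = 30),
                   seq(0, by = 1, length.out = 30), 0)
  ann <- classify_phases_short(tr)
  expect_equal(ann$segments$phase, "run")

  ## 90-degree turn sustained 6 frames, then straight: run/tumble/run
  steps <- rbind(matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE),
                 matrix(rep(c(0, 1), 6), ncol = 2, byrow = TRUE),
                 matrix(rep(c(0, 1), 10), ncol = 2, byrow = TRUE))
  pos <- rbind(c(0, 0), apply(steps, 2, cumsum))
  tr2 <- trajectory("t", seq(0, by = dt, length.out = nrow(pos)),
                    pos[, 1], pos[, 2])
  ann2 <- classify_phases_short(tr2)
  expect_equal(ann2$segments$phase, c("run", "tumble", "run"))

  ## 90-degree deviation for only 3 frames: stays a single run
  steps3 <- rbind(matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE),
                  matrix(rep(c(0, 1), 3), ncol = 2, byrow = TRUE),
                  matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE))
  pos3 <- rbind(c(0, 0), apply(steps3, 2, cumsum))
  tr3 <- trajectory("u", seq(0, by = dt, length.out = nrow(pos3)),
                    pos3[, 1], pos3[, 2])
  ann3 <- classify_phases_short(tr3)
  expect_equal(unique(ann3$segments$phase), "run")

  expect_error(classify_phases_short(straight_track(4)), "persist_frames")
})

test_that("phase statistics compute the documented ratios and angles", {
  ## one 10-min run then one 5-min tumble, constant speeds
  dt <- 1
  n_run <- 10; n_tum <- 5
  x <- c(seq(0, by = 2, length.out = n_run + 1),
         seq(20.3, by = 0.3, length.out = n_tum))
  tr <- trajectory("m", seq(0, by = dt, length.out = n_run + n_tum + 1), x, 0)
  ann <- runtumble:::new_phase_annotation("m", frame_time = tr$time[1:(n_run + n_tum)],
                              phase = rep(c("run", "tumble"),
                                          c(n_run, n_tum)),
                              dt = dt, traj_time = tr$time)
  s <- phase_statistics(tr, ann)
  expect_equal(s$tumble_run_time_ratio, 0.5)
  expect_equal(s$mean_run_duration, 10)
  expect_equal(s$mean_tumble_duration, 5)
  expect_equal(s$run_speed, 2)
  expect_equal(s$tumble_speed, 0.3)

  ## two runs along +x then +y separated by a tumble: inter-run angle 90
  seg_phase <- rep(c("run", "tumble", "run"), c(5, 3, 5))
  dx <- c(rep(2, 5), rep(0.1, 3), rep(0, 5))
  dy <- c(rep(0, 5), rep(0.1, 3), rep(2, 5))
  tr2 <- trajectory("a", 0:13, cumsum(c(0, dx)), cumsum(c(0, dy)))
  ann2 <- runtumble:::new_phase_annotation("a", frame_time = 0:12, phase = seg_phase,
                               dt = 1, traj_time = tr2$time)
  s2 <- phase_statistics(tr2, ann2)
  expect_equal(s2$inter_run_angles, 90)

  ## straight constant-speed trajectory has persistence exactly 1
  s3 <- phase_statistics(straight_track(15),
                         classify_phases_short(straight_track(15)))
  expect_equal(s3$persistence, 1)
})

test_that("exponential duration fits return the ML mean with diagnostics", {
  f <- fit_exponential_durations(c(2, 2, 2), n_boot = 50)
  expect_equal(f$mean, 2)
  expect_equal(f$sd_over_mean, 0)

  set.seed(14)
  f2 <- fit_exponential_durations(rexp(1e4, 1 / 5), n_boot = 200)
  expect_equal(f2$mean, 5, tolerance = 0.1 / 5)
  expect_equal(f2$sd_over_mean, 1, tolerance = 0.05)
  expect_lt(f2$ci[1], f2$mean)
  expect_gt(f2$ci[2], f2$mean)

  expect_error(fit_exponential_durations(numeric()), "no durations")
  expect_error(fit_exponential_durations(c(1, -1, 2, 3, 4)), "positive")
})

test_that("persistence lies in [0,1] and grows with generative run time", {
  ## bound property over assorted simulated tracks
  p <- rt_params_control(seed = 2)
  ens <- simulate(p, nsim = 10, duration = 60)
  pers <- vapply(unclass(ens), function(tr) {
    v <- diff(tr$pos)
    sqrt(sum((tr$pos[nrow(tr$pos), ] - tr$pos[1, ])^2)) /
      sum(sqrt(rowSums(v^2)))
  }, 0)
  expect_true(all(pers >= 0 & pers <= 1))

  ## Spearman correlation between tau_r and measured persistence; the
  ## target is placed far away so the motion pattern, not target capture
  ## (orbiting caps net displacement), drives the statistic
  taus <- seq(1.5, 12, length.out = 25)
  mp <- vapply(seq_along(taus), function(i) {
    pi_ <- update(rt_params_control(seed = 100 + i), tau_r = taus[i],
                  d0 = 800)
    e <- simulate(pi_, nsim = 4, duration = 90)
    mean(vapply(unclass(e), function(tr) {
      v <- diff(tr$pos)
      sqrt(sum((tr$pos[nrow(tr$pos), ] - tr$pos[1, ])^2)) /
        sum(sqrt(rowSums(v^2)))
    }, 0))
  }, 0)
  expect_gt(cor(taus, mp, method = "spearman"), 0)
})
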