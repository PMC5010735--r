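test_that("parameter validation rejects invalid configurations", {
  expect_error(sim_params(tau_r = -1), "positive")
  expect_error(sim_params(dt = 1, sample_interval = 1.5), "dt must be")
  expect_error(sim_params(t_e = 91), "multiple")
  expect_error(update(sim_params(), bogus = 1), "unknown")
  p <- update(sim_params(), tau_r = 7)
  expect_equal(p$tau_r, 7)
})

test_that("zero-noise pursuit matches the analytic chase distance", {
  ## sigma_eps = 0, no rotational noise, no speed noise, negligible
  ## tumbling: the cell closes on the target at v_run - v_target
  p <- sim_params(tau_r = 1e6, tau_t = 0.001, v_run_mean = 3, v_run_sd = 0,
                  v_tumble_mean = 0.001, v_tumble_sd = 0, D_theta = 0,
                  sigma_eps = 0, v_target = 1, d0 = 300, t_e = 90, seed = 4)
  ens <- simulate(p, nsim = 3)
  ev <- evaluate_ensemble(ens, p)
  analytic <- max(0, p$d0 - (p$v_run_mean - p$v_target) * p$t_e)
  expect_equal(ev$mean_distance, analytic, tolerance = 0.02)
  expect_lt(ev$dispersion, 1e-6)
})

test_that("the tumble-dominated limit reproduces a simple random walk", {
  ## tau_r -> 0: motion is isotropic redraw every dt, i.e. a random walk
  ## whose MSD after time T is E[v^2] * dt * T
  p <- sim_params(tau_r = 0.001, tau_t = 1e6, v_tumble_mean = 3,
                  v_tumble_sd = 1, t_e = 90, seed = 5)
  ens <- simulate(p, nsim = 150)
  fin <- t(vapply(unclass(ens), function(tr) tr$pos[nrow(tr$pos), 1:2],
                  numeric(2)))
  msd <- mean(rowSums(fin^2))
  ## brute-force oracle: independent steps drawn from the same generator
  set.seed(99)
  n_steps <- p$t_e / p$dt
  oracle <- replicate(300, {
    v <- runtumble:::rtruncnorm0(n_steps, p$v_tumble_mean, p$v_tumble_sd)
    th <- runif(n_steps, -pi, pi)
    sum(v * cos(th) * p$dt)^2 + sum(v * sin(th) * p$dt)^2
  })
  expect_equal(msd, mean(oracle), tolerance = 0.15)
})

test_that("simulation is bit-reproducible and order-independent", {
  p <- rt_params_control(seed = 77)
  a <- simulate_cell(p, 3, duration = 30)
  b <- simulate_cell(p, 3, duration = 30)
  expect_identical(a$pos, b$pos)
  ## the same cell index gives the same track inside a larger ensemble
  ens <- simulate(p, nsim = 4, duration = 30)
  expect_identical(ens[["sim3"]]$pos, a$pos)

  ## ground-truth labels and segments come along
  expect_s3_class(attr(simulate(p, nsim = 2, duration = 30), "labels")[[1]],
                  "phase_annotation")
})

test_that("simulated phase durations are exponential with the right means", {
  p <- rt_params_control(seed = 8)
  ens <- simulate(p, nsim = 80, duration = 120)
  segs <- attr(ens, "true_segments")
  ## drop each cell's final segment (truncated by the observation window)
  last <- unlist(lapply(split(seq_len(nrow(segs)), segs$cell), max))
  segs <- segs[-last, ]
  runs <- segs$duration[segs$phase == "run"]
  expect_gt(length(runs), 800)
  ## segment durations are stored on the dt grid; de-discretise before the
  ## continuous KS comparison
  set.seed(1)
  jit <- runs + runif(length(runs), -p$dt / 2, p$dt / 2)
  ks <- suppressWarnings(ks.test(jit[jit > 0], "pexp", 1 / p$tau_r))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(runs), p$tau_r, tolerance = 0.1)
})

test_that("ensemble read-outs implement the distance and dispersion contracts", {
  mk <- function(id, x, y) trajectory(id, c(0, 90), c(x, x), c(y, y))
  p <- sim_params(d0 = 10, v_target = 1, t_e = 90)
  ## both cells sitting on the target position at t_e (= d0 + v_target*t_e)
  at_target <- runtumble:::new_trajectory_list(list(mk("a", 100, 0),
                                                    mk("b", 100, 0)))
  ev <- evaluate_ensemble(at_target, p)
  expect_equal(ev$mean_distance, 0)
  expect_equal(ev$dispersion, 0)
  ## (n-1) variance arithmetic: points (0,0) and (2,0) -> var_x = 2
  two <- runtumble:::new_trajectory_list(list(mk("a", 0, 0), mk("b", 2, 0)))
  expect_equal(evaluate_ensemble(two, p)$dispersion, 2)
  expect_error(evaluate_ensemble(two[1], p), "at least 2")
})

test_that("the run-time sweep is reproducible and well-formed", {
  p <- rt_params_control(seed = 10, n_cells = 6)
  s1 <- sweep_run_time(p, factors = 1, n_reps = 2)
  s2 <- sweep_run_time(p, factors = 1, n_reps = 2)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 1)
  expect_error(sweep_run_time(p, factors = c(-1, 1)), "positive")
})
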