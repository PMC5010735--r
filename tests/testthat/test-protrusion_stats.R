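test_that("feature-based protrusion classification applies the actin/curvature rules", {
  f <- data.frame(actin_present_throughout = c(TRUE, FALSE, FALSE, TRUE),
                  peak_curvature = c(2, 0.4, 1.5, 0.4),
                  initial_actin = c(TRUE, FALSE, FALSE, TRUE))
  expect_warning(kinds <- classify_protrusion(f, curvature_threshold = 1),
                 "unclassified")
  expect_equal(kinds, c("actin_rich", "bleb", "unclassified", "unclassified"))
  expect_error(classify_protrusion(f[1:2, ]), "curvature_threshold")

  ## threshold calibration separates labelled synthetic features
  set.seed(21)
  n <- 200
  feats <- data.frame(
    actin_present_throughout = rep(c(TRUE, FALSE), each = n),
    peak_curvature = c(rnorm(n, 2, 0.3), rnorm(n, 0.8, 0.3)),
    initial_actin = rep(c(TRUE, FALSE), each = n))
  feats$peak_curvature <- pmax(feats$peak_curvature, 0)
  labels <- rep(c("actin_rich", "bleb"), each = n)
  th <- calibrate_curvature_threshold(feats, labels)
  expect_gt(attr(th, "accuracy"), 0.9)
  expect_gt(th, 0.8); expect_lt(th, 2)
})

test_that("the polar order parameter matches closed forms and symmetries", {
  ev <- function(angle, w = 1, cell = "c1")
    data.frame(cell_id = cell, time = seq_along(angle), kind = "bleb",
               angle = angle, weight = w)
  ## perfect focus
  expect_equal(polar_order_parameter(ev(rep(0, 8)))$pop, 1)
  ## four-fold symmetry cancels exactly
  expect_equal(polar_order_parameter(ev(c(0, 90, 180, -90)))$pop, 0,
               tolerance = 1e-12)

  ## von Mises sample against the Bessel-ratio closed form
  set.seed(22)
  th <- rvonmises(1e4, 0, 2)
  pop <- polar_order_parameter(ev(th))$pop
  expect_equal(pop, pop_from_kappa(2), tolerance = 0.01)

  ## global rotation invariance
  set.seed(23)
  base <- rvonmises(500, 10, 1.2)
  p1 <- polar_order_parameter(ev(base))$pop
  p2 <- polar_order_parameter(ev(runtumble:::wrap_angle(base + 137)))$pop
  expect_equal(p1, p2, tolerance = 1e-12)

  ## equal weights reproduce the unweighted value exactly; uniform angles
  ## decay towards zero order
  e <- ev(base, w = 3.3)
  expect_equal(polar_order_parameter(e, weighted = TRUE)$pop,
               polar_order_parameter(e, weighted = FALSE)$pop,
               tolerance = 1e-12)
  set.seed(24)
  u <- ev(runif(1e4, -180, 180))
  expect_lt(polar_order_parameter(u)$pop, 0.05)

  ## histogram mass equals total weight
  s <- polar_order_parameter(ev(base, w = 2), weighted = TRUE)
  expect_equal(sum(s$angle_histogram), 2 * length(base))

  e_bad <- ev(base); e_bad$weight <- NA
  expect_error(polar_order_parameter(e_bad, weighted = TRUE), "weights")
})

test_that("POP values are compared by SEM overlap", {
  ev <- function(angle, cell) data.frame(cell_id = cell, angle = angle,
                                         weight = 1)
  set.seed(25)
  focused <- do.call(rbind, lapply(1:6, function(i)
    ev(rvonmises(60, 0, 6), paste0("f", i))))
  diffuse <- do.call(rbind, lapply(1:6, function(i)
    ev(rvonmises(60, 0, 0.2), paste0("d", i))))
  a <- polar_order_parameter(focused)
  b <- polar_order_parameter(diffuse)
  expect_true(pop_different(a, b))
  expect_false(pop_different(a, a))
})

test_that("phase frequency ratios divide per-minute formation rates", {
  ## 4 blebs in 2 min of tumbling vs 2 blebs in 4 min of running -> 4.0
  ann <- runtumble:::new_phase_annotation("c1", frame_time = 0:5,
                              phase = rep(c("run", "tumble"), c(4, 2)),
                              dt = 1)
  ev <- data.frame(cell_id = "c1",
                   time = c(1, 3, 4.2, 4.4, 4.6, 4.8),
                   kind = "bleb", angle = 0, weight = 1)
  r <- phase_frequency_ratio(ev, list(c1 = ann))
  expect_equal(r$per_cell$ratio, 4)

  ## equal per-minute rates give ratio 1
  ev2 <- data.frame(cell_id = "c1", time = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5),
                    kind = "bleb", angle = 0, weight = 1)
  r2 <- phase_frequency_ratio(ev2, list(c1 = ann))
  expect_equal(r2$per_cell$ratio, 1)

  ## events outside the annotated span are rejected
  ev3 <- data.frame(cell_id = "c1", time = 9, kind = "bleb", angle = 0,
                    weight = 1)
  expect_error(phase_frequency_ratio(ev3, list(c1 = ann)), "outside")

  ## Poisson events at generative tumble:run rate 3:1 recover ratio ~ 3,
  ## and the estimate is invariant to time-unit rescaling
  set.seed(26)
  spec <- generator_spec("control",
                         rates = list(bleb = c(run = 0.2, tumble = 0.6),
                                      actin_rich = c(run = 0.4,
                                                     tumble = 0.4)),
                         seed = 5)
  g <- generate_labeled_tracks(spec, n_cells = 60, duration = 120)
  evs <- generate_protrusion_events(spec, g$tracks, g$labels)
  rr <- phase_frequency_ratio(evs, g$labels)
  bleb <- rr$summary[rr$summary$kind == "bleb", ]
  expect_equal(bleb$mean, 3, tolerance = 3 * bleb$sem / 3 + 0.15)
  evs2 <- evs; evs2$time <- evs2$time * 60
  labs2 <- lapply(g$labels, function(a) {
    a$frame_time <- a$frame_time * 60
    a$segments[c("t_start", "t_end", "duration")] <-
      a$segments[c("t_start", "t_end", "duration")] * 60
    a
  })
  rr2 <- phase_frequency_ratio(evs2, labs2)
  expect_equal(rr2$summary$mean, rr$summary$mean, tolerance = 1e-12)
})

test_that("front classification and bleb-size normalisation are exact", {
  all_front <- data.frame(cell_id = "c", angle = rep(0, 5))
  expect_equal(front_classification(all_front)$pooled, 1)
  boundary <- data.frame(cell_id = "c", angle = 90)
  expect_equal(front_classification(boundary)$pooled, 0)
  set.seed(27)
  u <- data.frame(cell_id = "c", angle = runif(1e4, -180, 180))
  expect_equal(front_classification(u)$pooled, 0.5, tolerance = 0.02)

  expect_equal(bleb_size_normalized(10, 100), 0.1)
  expect_equal(bleb_size_normalized(7, 7), 1)
  expect_error(bleb_size_normalized(10, 0), "positive")
})
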