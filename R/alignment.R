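#' Alignment index and scaled speed series of a trajectory
#'
#' For each interior frame i (the displacement from point i to i+1) the
#' alignment index A_i is the mean cosine of the angles between the
#' displacement vector at i and the displacement vectors in a +/- `window`
#' frame neighbourhood; A_i is 1 for locally straight motion and -1 for
#' frame-to-frame reversals. The scaled speed S_i is the instantaneous speed
#' |v_i|/dt divided by the trajectory's mean instantaneous speed. Frames with
#' zero displacement carry A = 0 and S = 0 and are flagged.
#'
#' @param traj a [trajectory].
#' @param window half-width of the alignment neighbourhood, frames.
#' @return A data.frame of class `"as_series"` with columns `frame`, `time`,
#'   `A`, `S`, `zero_disp`; attributes `cell_id`, `dt`, `mean_speed`,
#'   `window`, `n_frames` (total displacement frames of the trajectory).
#' @export
as_series <- function(traj, window = 1) {
  stopifnot(inherits(traj, "trajectory"))
  w <- as.integer(window)
  if (w < 1) stop("window must be a positive integer")
  n <- nrow(traj$pos)
  if (n < w + 2)
    stop("trajectory too short: ", n, " points for window ", w)
  dts <- diff(traj$time)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 0.01 * dt)
    stop("non-uniform sampling (beyond 1% tolerance); resample first")
  v <- diff(traj$pos)                       # (n-1) x 3 displacement vectors
  nv <- sqrt(rowSums(v^2))
  speed <- nv / dt
  mean_speed <- mean(speed)
  if (mean_speed == 0) stop("trajectory is entirely stationary")
  S <- speed / mean_speed
  nf <- n - 1L
  idx <- seq.int(w + 1L, nf - w)
  if (length(idx) < 1) stop("trajectory too short for interior frames")
  ## unit vectors; zero steps contribute cosine 0 ("stationary ~ unaligned")
  u <- v / ifelse(nv > 0, nv, 1)
  u[nv == 0, ] <- 0
  ## mean_{k != i, |k-i| <= w} cos(v_i, v_k) = ((sum_window u_k) . u_i - 1)/2w
  ## via running window sums (u_i . u_i = 1 whenever the step is non-zero)
  win <- matrix(0, length(idx), 3)
  for (j in 1:3) {
    cs <- cumsum(c(0, u[, j]))
    win[, j] <- cs[idx + w + 1L] - cs[idx - w]
  }
  A <- (rowSums(win * u[idx, , drop = FALSE]) - 1) / (2 * w)
  A[nv[idx] == 0] <- 0
  out <- data.frame(frame = idx, time = traj$time[idx], A = A, S = S[idx],
                    zero_disp = nv[idx] == 0)
  structure(out, class = c("as_series", "data.frame"),
            cell_id = traj$cell_id, dt = dt, mean_speed = mean_speed,
            window = w, n_frames = nf)
}

#' Estimate the joint density P(A,S) of alignment and scaled speed
#'
#' Pools the (A, S) points of one or more series into a 2D histogram over
#' A in \[-1, 1\] and S in \[0, `s_max`\] (larger S clamped into the top bin),
#' smooths it with a separable Gaussian kernel and normalises it to unit
#' mass. The bimodal structure of this density separates run from tumble
#' behaviour and drives the unbiased phase threshold.
#'
#' @param series an `"as_series"` or list of them.
#' @param a_bins,s_bins number of bins along A and S.
#' @param s_max upper edge of the S grid.
#' @param bandwidth Gaussian smoothing bandwidth in bins.
#' @return An object of class `"as_density"`: list with `a_grid`, `s_grid`
#'   (bin centres), `density` (a_bins x s_bins matrix, unit mass),
#'   `sd_a`, `sd_s` (pooled standard deviations used to standardise the
#'   plane for thresholding), `n_points`, and `params`. The maximum line and
#'   threshold slots are filled by [fit_maximum_line()] / [find_threshold()].
#' @export
estimate_density <- function(series, a_bins = 41, s_bins = 41, s_max = 3,
                             bandwidth = 1.5) {
  if (inherits(series, "as_series")) series <- list(series)
  a <- unlist(lapply(series, `[[`, "A"))
  s <- unlist(lapply(series, `[[`, "S"))
  if (!length(a)) stop("no (A,S) points supplied")
  if (stats::sd(a) == 0 && stats::sd(s) == 0)
    stop("degenerate input: all (A,S) points identical")
  if (length(a) < 500)
    warning("only ", length(a), " pooled points; density will be noisy")
  a_edges <- seq(-1, 1, length.out = a_bins + 1)
  s_edges <- seq(0, s_max, length.out = s_bins + 1)
  ai <- pmin(pmax(findInterval(a, a_edges, rightmost.closed = TRUE), 1), a_bins)
  si <- pmin(pmax(findInterval(s, s_edges, rightmost.closed = TRUE), 1), s_bins)
  h <- matrix(tabulate(ai + (si - 1L) * a_bins, nbins = a_bins * s_bins),
              a_bins, s_bins)
  h <- smooth_gauss2(h, bandwidth)
  da <- diff(a_edges)[1]; ds <- diff(s_edges)[1]
  h <- h / (sum(h) * da * ds)
  structure(list(a_grid = (a_edges[-1] + a_edges[-(a_bins + 1)]) / 2,
                 s_grid = (s_edges[-1] + s_edges[-(s_bins + 1)]) / 2,
                 density = h, sd_a = stats::sd(a), sd_s = stats::sd(s),
                 n_points = length(a),
                 params = list(a_bins = a_bins, s_bins = s_bins,
                               s_max = s_max, bandwidth = bandwidth),
                 max_line = NULL, threshold = NULL),
            class = "as_density")
}

## Separable Gaussian smoothing of a matrix, zero-padded, kernel renormalised.
smooth_gauss2 <- function(m, bw) {
  if (bw <= 0) return(m)
  r <- max(1L, ceiling(4 * bw))
  k <- stats::dnorm(seq(-r, r), sd = bw)
  k <- k / sum(k)
  smooth1 <- function(mat) {
    nr <- nrow(mat)
    apply(mat, 2, function(col) {
      padded <- c(numeric(r), col, numeric(r))
      vapply(seq_len(nr), function(i) sum(padded[i:(i + 2 * r)] * k), 0)
    })
  }
  t(smooth1(t(smooth1(m))))
}

#' @export
print.as_density <- function(x, ...) {
  cat("P(A,S) density:", x$params$a_bins, "x", x$params$s_bins, "bins,",
      x$n_points, "points\n")
  if (!is.null(x$max_line))
    cat(sprintf("  maximum line: S*(A) = %.3f + %.3f A\n",
                x$max_line$intercept, x$max_line$slope))
  if (!is.null(x$threshold))
    cat(sprintf("  threshold_A = %.3f%s\n", x$threshold$threshold_A,
                if (x$threshold$fallback) " (unimodal fallback)" else ""))
  invisible(x)
}

#' Fit the maximum line S*(A) of a density
#'
#' Least-squares line through the per-A density maxima, using only A columns
#' whose peak mass exceeds 5% of the global maximum.
#'
#' @param d an `"as_density"`.
#' @param mass_floor minimum peak mass relative to the global maximum for an
#'   A column to enter the fit.
#' @return `d` with the `max_line` slot filled (`slope`, `intercept`,
#'   `a_used`, `s_peak`).
#' @export
fit_maximum_line <- function(d, mass_floor = 0.05) {
  stopifnot(inherits(d, "as_density"))
  peak_val <- apply(d$density, 1, max)
  keep <- peak_val > mass_floor * max(peak_val)
  if (sum(keep) < 2)
    stop("fewer than 2 usable A columns for the maximum-line fit")
  if (sum(keep) < 5)
    warning("only ", sum(keep), " A columns above the mass floor")
  s_peak <- d$s_grid[apply(d$density, 1, which.max)]
  fit <- stats::lm.fit(cbind(1, d$a_grid[keep]), s_peak[keep])
  d$max_line <- list(intercept = unname(fit$coefficients[1]),
                     slope = unname(fit$coefficients[2]),
                     a_used = d$a_grid[keep], s_peak = s_peak[keep])
  d
}

## Bilinear interpolation of the density at arbitrary (a, s).
interp_density <- function(d, a, s) {
  ag <- d$a_grid; sg <- d$s_grid
  a <- pmin(pmax(a, ag[1]), ag[length(ag)])
  s <- pmin(pmax(s, sg[1]), sg[length(sg)])
  ia <- pmin(findInterval(a, ag), length(ag) - 1)
  is <- pmin(findInterval(s, sg), length(sg) - 1)
  fa <- (a - ag[ia]) / (ag[ia + 1] - ag[ia])
  fs <- (s - sg[is]) / (sg[is + 1] - sg[is])
  d$density[cbind(ia, is)] * (1 - fa) * (1 - fs) +
    d$density[cbind(ia + 1, is)] * fa * (1 - fs) +
    d$density[cbind(ia, is + 1)] * (1 - fa) * fs +
    d$density[cbind(ia + 1, is + 1)] * fa * fs
}

## Indices of strict-ish local maxima/minima of a numeric profile. The
## profile ends count as maxima when the profile falls away from them (a
## mode pressed against the sampled range is still a mode).
local_extrema <- function(p) {
  pp <- c(-Inf, p, -Inf)
  d <- sign(diff(pp))
  ## collapse plateaus: carry the previous non-zero slope forward
  for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
  turn <- diff(d)
  list(maxima = which(turn < 0), minima = which(turn > 0))
}

#' Locate the run/tumble threshold along the maximum line
#'
#' Samples P(A,S) along the fitted maximum line, then places the threshold
#' at the local minimum between the global maximum of the cross-section and
#' the nearest distinct local maximum. If the cross-section is unimodal the
#' threshold falls back to the point of maximum curvature between the mode
#' and the high-A tail, and the result is flagged.
#'
#' @param d an `"as_density"` with a fitted maximum line.
#' @param n_samples number of cross-section samples.
#' @return `d` with the `threshold` slot filled: `threshold_A`,
#'   `cross_section` (data.frame `a`, `s`, `p`) and `fallback`.
#' @export
find_threshold <- function(d, n_samples = 201) {
  stopifnot(inherits(d, "as_density"))
  if (is.null(d$max_line)) stop("fit the maximum line first")
  a <- seq(d$a_grid[1], d$a_grid[length(d$a_grid)], length.out = n_samples)
  s <- d$max_line$intercept + d$max_line$slope * a
  ok <- s >= d$s_grid[1] & s <= d$s_grid[length(d$s_grid)]
  a <- a[ok]; s <- s[ok]
  if (length(a) < 5) stop("cross-section shorter than 5 samples")
  p <- interp_density(d, a, s)
  ## light running-mean smoothing so micro-wiggles of the sampled profile
  ## do not register as modes
  k <- max(3L, 2L * floor(length(p) / 80) + 1L)
  half <- k %/% 2
  pp <- c(rep(p[1], half), p, rep(p[length(p)], half))
  ps <- vapply(seq_along(p), function(i) mean(pp[i:(i + k - 1L)]), 0)
  g <- which.max(ps)
  ext <- local_extrema(ps)
  ## distinct local maxima: a second behavioural state sits well away from
  ## the global mode along A (the run/tumble alignment contrast is large),
  ## is non-negligible, and rises clearly out of the valley separating it
  ## from the global mode -- narrow noise bumps near the main mode fail the
  ## separation test, shallow bumps fail the valley-rise test
  cand <- ext$maxima[abs(a[ext$maxima] - a[g]) >= 0.25]
  rise <- vapply(cand, function(m) {
    lo <- min(g, m); hi <- max(g, m)
    valley <- min(ps[lo:hi])
    if (valley <= 0 || ps[m] < 0.12 * ps[g]) return(0)
    (ps[m] - valley) / valley
  }, 0)
  fallback <- FALSE
  cand <- cand[rise >= 0.05]
  ## projection coordinate of the density mass, for the mass-balance guard
  ## and the Otsu fallback
  dir_ <- c(1 / d$sd_a, d$max_line$slope / d$sd_s)
  dir_ <- dir_ / sqrt(sum(dir_^2))
  tg <- outer(d$a_grid / d$sd_a * dir_[1], d$s_grid / d$sd_s * dir_[2], `+`)
  proj_of_a <- function(aa) {
    (aa / d$sd_a) * dir_[1] +
      ((d$max_line$intercept + d$max_line$slope * aa) / d$sd_s) * dir_[2]
  }
  thr_a <- NA_real_
  if (length(cand)) {
    ## the nearest qualifying mode: a farther candidate would place the
    ## threshold beyond an intervening state
    m2 <- cand[which.min(abs(cand - g))]
    lo <- min(g, m2); hi <- max(g, m2)
    thr_i <- (lo:hi)[which.min(ps[lo:hi])]
    thr_a <- a[thr_i]
    ## mass-balance guard: a threshold that assigns almost the whole
    ## ensemble to one phase cannot separate two behavioural states and
    ## indicates a spurious far-tail mode
    frac_run <- sum(d$density[tg > proj_of_a(thr_a)]) / sum(d$density)
    if (frac_run < 0.05 || frac_run > 0.95) thr_a <- NA_real_
  }
  if (is.na(thr_a)) {
    ## no articulated second mode (shoulder, unimodal profile, or a
    ## rejected degenerate split): fall back to an Otsu split of the full
    ## projection-coordinate mass of the density -- the same scalar the
    ## classifier thresholds -- flagged so downstream analyses know the
    ## bimodal rule did not apply
    fallback <- TRUE
    t_star <- otsu_threshold(as.vector(tg), as.vector(d$density))
    ## map the projection split back to an abscissa on the maximum line
    denom <- dir_[1] / d$sd_a + d$max_line$slope * dir_[2] / d$sd_s
    thr_a <- (t_star - d$max_line$intercept * dir_[2] / d$sd_s) / denom
    thr_a <- min(max(thr_a, a[1]), a[length(a)])
  }
  d$threshold <- list(threshold_A = thr_a,
                      cross_section = data.frame(a = a, s = s, p = p),
                      fallback = fallback)
  d
}

## Weighted Otsu split: the threshold maximising the between-class variance
## of a weighted 1D distribution.
otsu_threshold <- function(values, weights) {
  o <- order(values)
  v <- values[o]; w <- weights[o]
  w <- w / sum(w)
  cw <- cumsum(w)
  cm <- cumsum(w * v)
  mu <- cm[length(cm)]
  ok <- cw > 1e-9 & cw < 1 - 1e-9
  between <- (mu * cw - cm)^2 / (cw * (1 - cw))
  between[!ok] <- -Inf
  i <- which.max(between)
  (v[i] + v[min(i + 1, length(v))]) / 2
}
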