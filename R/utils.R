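## Internal helpers shared across modules.

## Angle between two vectors in degrees, in [0, 180]. Works in 2D or 3D.
angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

## Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

## Truncated-normal sampler on [0, Inf) via inverse CDF; vectorised in n.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(0, mean), n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

## Deterministic per-stream seed derivation: mixes a master seed with a
## stream index so that cell-level substreams never depend on evaluation
## order. Result stays inside the 32-bit signed range.
derive_seed <- function(master, stream) {
  ((abs(as.numeric(master)) %% 65011) * 33029 +
     (as.numeric(stream) %% 65011) * 7919 + 17) %% 2147483629 + 1
}

## Sample mean +/- standard error of the mean, dropping NAs.
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  c(mean = if (n) mean(x) else NA_real_,
    sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
    n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
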