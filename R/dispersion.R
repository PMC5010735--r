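#' Positional variance of a cell group
#'
#' The migration-precision metric: the sum of the unbiased variances of the
#' x and y positions of a group of co-transplanted cells. Rotation of the
#' coordinate frame leaves the value unchanged, so the axis convention is
#' irrelevant. Groups of fewer than three cells are rejected, matching the
#' inclusion criterion used for transplantation experiments.
#'
#' @param positions n x 2 matrix or data.frame of final positions,
#'   micrometres.
#' @return Scalar variance, micrometres^2.
#' @export
positional_variance <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3)
    stop("need at least three cells per group")
  if (ncol(positions) < 2) stop("positions must have x and y columns")
  stats::var(positions[, 1]) + stats::var(positions[, 2])
}

#' Dispersion of experimental cells normalised to internal controls
#'
#' Per embryo, the positional variance of the experimental group divided by
#' that of the co-transplanted control group in the same embryo; embryos
#' lacking either group (or with fewer than three cells in one) are skipped
#' with a warning. The per-embryo ratios are tested against 1 with a
#' one-sided t test (alternative: ratios exceed 1).
#'
#' @param endpoints data.frame with columns `embryo_id`, `condition`,
#'   `x`, `y` (micrometres).
#' @param control label identifying the internal-control condition.
#' @param alternative direction of the one-sided test (`"greater"` when
#'   asking whether dispersion is increased).
#' @return An object of class `"dispersion_result"`: data.frame `ratios`
#'   (embryo_id, condition, control_variance, variance, ratio), plus
#'   `t_statistic`, `p_value`, `mean_ratio`, `degenerate` (TRUE when the
#'   ratios have zero variance so the t test is undefined).
#' @export
normalized_dispersion <- function(endpoints, control = "control",
                                  alternative = c("greater", "less",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  need <- c("embryo_id", "condition", "x", "y")
  miss <- setdiff(need, names(endpoints))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (em in unique(endpoints$embryo_id)) {
    d <- endpoints[endpoints$embryo_id == em, ]
    ctrl <- d[d$condition == control, c("x", "y")]
    for (cond in setdiff(unique(d$condition), control)) {
      ex <- d[d$condition == cond, c("x", "y")]
      if (nrow(ctrl) < 3 || nrow(ex) < 3) {
        warning("embryo ", em, " skipped (needs >= 3 cells in both groups)")
        next
      }
      vc <- positional_variance(ctrl)
      ve <- positional_variance(ex)
      rows[[length(rows) + 1]] <- data.frame(
        embryo_id = em, condition = cond, control_variance = vc,
        variance = ve, ratio = ve / vc)
    }
  }
  if (!length(rows)) stop("no embryo with both groups meeting the >=3 rule")
  ratios <- do.call(rbind, rows)
  degenerate <- nrow(ratios) < 2 ||
    stats::sd(ratios$ratio) < 1e-10 * max(1, abs(mean(ratios$ratio)))
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
    warning("ratios are degenerate (zero variance or n < 2); ",
            "t test undefined")
  } else {
    tt <- stats::t.test(ratios$ratio, mu = 1, alternative = alternative)
  }
  structure(list(ratios = ratios,
                 mean_ratio = mean(ratios$ratio),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 alternative = alternative,
                 degenerate = degenerate),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Normalised dispersion over", nrow(x$ratios), "embryos\n")
  cat(sprintf("  mean ratio %.3f; one-sided t = %.3f, p = %.4g%s\n",
              x$mean_ratio, x$t_statistic, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
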