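#' Classify protrusions from morphological features
#'
#' Actin-rich protrusions contain actin throughout their expansion and have
#' higher surface curvature than blebs; blebs start devoid of actin. Events
#' whose features contradict each other (high curvature without sustained
#' actin) are left unclassified with a warning.
#'
#' @param features data.frame with logical columns
#'   `actin_present_throughout`, `initial_actin` and numeric
#'   `peak_curvature` (1/micrometre, non-negative).
#' @param curvature_threshold curvature above which a sustained-actin
#'   protrusion counts as actin-rich, 1/micrometre. No universal default
#'   exists; calibrate on labelled data with
#'   [calibrate_curvature_threshold()].
#' @return Character vector: `"actin_rich"`, `"bleb"` or `"unclassified"`.
#' @export
classify_protrusion <- function(features, curvature_threshold) {
  stopifnot(is.data.frame(features),
            all(c("actin_present_throughout", "peak_curvature",
                  "initial_actin") %in% names(features)))
  if (any(features$peak_curvature < 0)) stop("curvature must be >= 0")
  if (missing(curvature_threshold) || !is.numeric(curvature_threshold))
    stop("curvature_threshold is required (see calibrate_curvature_threshold)")
  high <- features$peak_curvature >= curvature_threshold
  contradiction <- high & !features$actin_present_throughout
  out <- ifelse(features$actin_present_throughout & high, "actin_rich",
                ifelse(!features$initial_actin & !high, "bleb",
                       "unclassified"))
  out[contradiction] <- "unclassified"
  if (any(contradiction))
    warning(sum(contradiction), " event(s) with high curvature but no ",
            "sustained actin left unclassified")
  out
}

#' Choose a curvature threshold from labelled features
#'
#' Scans candidate thresholds (midpoints between sorted curvatures) and
#' returns the one maximising classification accuracy of
#' [classify_protrusion()] against known labels.
#'
#' @param features feature data.frame as in [classify_protrusion()].
#' @param labels true kinds (`"bleb"` / `"actin_rich"`).
#' @return The selected threshold (1/micrometre), with attribute
#'   `"accuracy"`.
#' @export
calibrate_curvature_threshold <- function(features, labels) {
  stopifnot(nrow(features) == length(labels))
  cv <- sort(unique(features$peak_curvature))
  if (length(cv) < 2) stop("need at least two distinct curvature values")
  cand <- (cv[-1] + cv[-length(cv)]) / 2
  acc <- vapply(cand, function(th) {
    pred <- suppressWarnings(classify_protrusion(features, th))
    mean(pred == labels)
  }, 0)
  best <- cand[which.max(acc)]
  attr(best, "accuracy") <- max(acc)
  best
}

#' Polar order parameter of protrusion orientation
#'
#' For each cell the POP is the length of the (weight-)averaged unit vector
#' of that cell's protrusion angles: POP = |sum w_i u(theta_i)| / sum w_i,
#' 1 for perfectly focused protrusion formation and 0 for isotropic. The
#' across-cell mean +/- SEM is reported, following the convention that two
#' POP values differ significantly when their SEM intervals do not overlap
#' (see [pop_different()]).
#'
#' @param events a `"protrusion_events"` data.frame (or any data.frame with
#'   `cell_id`, `angle` in degrees, and `weight`).
#' @param weighted if `TRUE`, weight each event (e.g. by total Lifeact
#'   intensity); blebs conventionally carry weight 1.
#' @param bin_width angular histogram bin width, degrees.
#' @return An object of class `"orientation_summary"`: `pop`, `pop_sem`,
#'   `per_cell` (named vector), `n_cells`, `n_events`, `weighted`, and
#'   `angle_histogram` (weight sums per bin; the bin masses total the
#'   pooled weight).
#' @export
polar_order_parameter <- function(events, weighted = FALSE, bin_width = 20) {
  stopifnot(is.data.frame(events), nrow(events) >= 1)
  w <- if (weighted) {
    if (is.null(events$weight) || anyNA(events$weight))
      stop("weighted POP requires complete weights")
    as.numeric(events$weight)
  } else rep(1, nrow(events))
  if (any(w < 0)) stop("negative weights")
  th <- events$angle * pi / 180
  per_cell <- vapply(split(seq_len(nrow(events)), events$cell_id),
                     function(i) {
    tw <- sum(w[i])
    if (tw == 0) return(NA_real_)
    sqrt(sum(w[i] * cos(th[i]))^2 + sum(w[i] * sin(th[i]))^2) / tw
  }, 0)
  if (anyNA(per_cell))
    warning("cell(s) with zero total weight excluded from the POP")
  ms <- mean_sem(per_cell)
  breaks <- seq(-180, 180, by = bin_width)
  bin <- cut(wrap_angle(events$angle), breaks, include.lowest = TRUE)
  hist_w <- tapply(w, bin, sum, default = 0)
  structure(list(pop = unname(ms["mean"]), pop_sem = unname(ms["sem"]),
                 per_cell = per_cell[!is.na(per_cell)],
                 n_cells = unname(ms["n"]), n_events = nrow(events),
                 weighted = weighted,
                 angle_histogram = hist_w, breaks = breaks),
            class = "orientation_summary")
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat(sprintf("POP = %.3f +/- %.3f (mean +/- SEM, %d cells, %d events%s)\n",
              x$pop, x$pop_sem, x$n_cells, x$n_events,
              if (x$weighted) ", weighted" else ""))
  invisible(x)
}

#' Compare two polar order parameters by SEM overlap
#'
#' @param a,b `"orientation_summary"` objects.
#' @return `TRUE` when the mean +/- SEM intervals do not overlap.
#' @export
pop_different <- function(a, b) {
  stopifnot(inherits(a, "orientation_summary"),
            inherits(b, "orientation_summary"))
  (a$pop - a$pop_sem) > (b$pop + b$pop_sem) ||
    (b$pop - b$pop_sem) > (a$pop + a$pop_sem)
}

#' Rose plot of protrusion orientation
#'
#' @param x an `"orientation_summary"`.
#' @param main plot title.
#' @param col sector colour.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.orientation_summary <- function(x, main = "protrusion orientation",
                                     col = "steelblue", ...) {
  h <- as.numeric(x$angle_histogram)
  n <- length(h)
  r <- h / max(h, 1e-12)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  mid <- (x$breaks[-1] + x$breaks[-(n + 1)]) / 2
  half <- diff(x$breaks)[1] / 2
  for (i in seq_len(n)) {
    ang <- seq(mid[i] - half, mid[i] + half, length.out = 8) * pi / 180
    graphics::polygon(c(0, r[i] * cos(ang)), c(0, r[i] * sin(ang)),
                      col = col, border = "grey30")
  }
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey60")
  graphics::arrows(0, 0, 0.5, 0, length = 0.08, lwd = 2)
  invisible(x)
}

#' Tumble-versus-run protrusion formation frequency ratio
#'
#' For each cell and protrusion kind, the formation rate during tumbles
#' (events per minute of tumble time) divided by the rate during runs.
#' Cells with zero run or tumble time are excluded with a warning.
#'
#' @param events a `"protrusion_events"` data.frame.
#' @param annotations named list of `"phase_annotation"` per `cell_id`.
#' @return A list with `per_cell` (data.frame: cell_id, kind, ratio) and
#'   `summary` (mean +/- SEM per kind).
#' @export
phase_frequency_ratio <- function(events, annotations) {
  stopifnot(is.data.frame(events))
  out <- list()
  skipped <- character(0)
  for (cid in unique(events$cell_id)) {
    ann <- annotations[[cid]]
    if (is.null(ann)) stop("no annotation for cell ", cid)
    ev <- events[events$cell_id == cid, ]
    span <- c(ann$segments$t_start[1],
              ann$segments$t_end[nrow(ann$segments)])
    if (any(ev$time < span[1] - 1e-9 | ev$time > span[2] + 1e-9))
      stop("event outside annotated span for cell ", cid)
    seg <- ann$segments
    t_run <- sum(seg$duration[seg$phase == "run"])
    t_tum <- sum(seg$duration[seg$phase == "tumble"])
    if (t_run == 0 || t_tum == 0) { skipped <- c(skipped, cid); next }
    ## phase at event time: the segment whose interval contains it
    idx <- findInterval(ev$time, seg$t_start, rightmost.closed = FALSE)
    idx[idx < 1] <- 1
    ph <- seg$phase[idx]
    for (kind in unique(ev$kind)) {
      sel <- ev$kind == kind
      r_tum <- sum(sel & ph == "tumble") / t_tum
      r_run <- sum(sel & ph == "run") / t_run
      out[[length(out) + 1]] <- data.frame(
        cell_id = cid, kind = kind,
        ratio = if (r_run > 0) r_tum / r_run else Inf)
    }
  }
  if (length(skipped))
    warning("cell(s) without both phases excluded: ",
            paste(skipped, collapse = ", "))
  per_cell <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = character(), kind = character(), ratio = numeric())
  summ <- do.call(rbind, lapply(split(per_cell, per_cell$kind), function(d) {
    ms <- mean_sem(d$ratio)
    data.frame(kind = d$kind[1], mean = ms["mean"], sem = ms["sem"],
               n = ms["n"])
  }))
  rownames(summ) <- NULL
  list(per_cell = per_cell, summary = summ)
}

#' Fraction of protrusions forming towards the cell front
#'
#' An event forms towards the front when its angle to the local migration
#' direction is strictly within 90 degrees (boundary events count as rear).
#'
#' @param events a `"protrusion_events"` data.frame.
#' @return List with `pooled` fraction and `per_cell` named vector.
#' @export
front_classification <- function(events) {
  stopifnot(is.data.frame(events), !is.null(events$angle))
  front <- abs(wrap_angle(events$angle)) < 90
  list(pooled = mean(front),
       per_cell = vapply(split(front, events$cell_id), mean, 0))
}

#' Bleb size normalised to cell size
#'
#' @param projected_area bleb projected area at maximal extension,
#'   micrometres^2.
#' @param cell_projected_area whole-cell projected area, micrometres^2.
#' @return Dimensionless area ratio.
#' @export
bleb_size_normalized <- function(projected_area, cell_projected_area) {
  if (any(!is.finite(projected_area)) || any(!is.finite(cell_projected_area)))
    stop("areas must be finite")
  if (any(projected_area <= 0) || any(cell_projected_area <= 0))
    stop("areas must be positive")
  projected_area / cell_projected_area
}
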