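## Phase annotations: per-frame run/tumble labels plus the contiguous
## segment list. A "frame" is the displacement interval [t_i, t_{i+1});
## segments therefore tile the track duration exactly.

new_phase_annotation <- function(cell_id, frame_time, phase, dt,
                                 traj_time = NULL) {
  phase <- factor(as.character(phase), levels = c("run", "tumble"))
  if (anyNA(phase)) stop("phase labels must be 'run' or 'tumble'")
  nf <- length(phase)
  stopifnot(length(frame_time) == nf)
  r <- rle(as.integer(phase))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  t_end_of <- function(i) {
    if (!is.null(traj_time)) traj_time[i + 1L] else frame_time[i] + dt
  }
  segments <- data.frame(
    phase = levels(phase)[r$values],
    start_frame = starts, end_frame = ends,
    t_start = frame_time[starts],
    t_end = vapply(ends, t_end_of, 0))
  segments$duration <- segments$t_end - segments$t_start
  structure(list(cell_id = cell_id, frame_time = frame_time, phase = phase,
                 segments = segments,
                 segment_of_frame = rep(seq_along(r$lengths), r$lengths),
                 dt = dt),
            class = "phase_annotation")
}

#' @export
print.phase_annotation <- function(x, ...) {
  ns <- table(x$segments$phase)
  cat("Phase annotation", x$cell_id, "-", length(x$phase), "frames;",
      ns[["run"]] %||% 0, "runs,", ns[["tumble"]] %||% 0, "tumbles\n")
  invisible(x)
}

## Merge segments shorter than min_segment frames into the longer
## neighbour (tie -> preceding), repeatedly until stable.
merge_short_segments <- function(labels, min_segment) {
  if (min_segment <= 1) return(labels)
  repeat {
    r <- rle(labels)
    if (length(r$lengths) == 1) return(labels)
    short <- which(r$lengths < min_segment)
    if (!length(short)) return(labels)
    ## merge the shortest offender first for determinism
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1) r$lengths[i - 1] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1] else -1L
    into <- if (left >= right) i - 1L else i + 1L
    r$values[i] <- r$values[into]
    labels <- inverse.rle(r)
  }
}

#' Segment a trajectory into run and tumble phases
#'
#' Each interior frame's (A, S) point is projected onto the maximum line of
#' the density (in coordinates standardised by the pooled SDs of A and S, so
#' that the perpendicular threshold line is well defined across the mixed
#' units); frames projecting beyond the threshold point are runs, the rest
#' tumbles. Boundary frames inherit the nearest classified label, and
#' segments shorter than `min_segment` frames are merged into their longer
#' neighbour to suppress single-frame flicker.
#'
#' @param traj a [trajectory].
#' @param d an `"as_density"` with maximum line and threshold set.
#' @param window alignment window passed to [as_series()].
#' @param min_segment minimum segment length in frames.
#' @return A `"phase_annotation"`.
#' @export
classify_phases <- function(traj, d, window = 1, min_segment = 1) {
  stopifnot(inherits(d, "as_density"))
  if (is.null(d$max_line) || is.null(d$threshold))
    stop("density needs a fitted maximum line and threshold")
  ser <- as_series(traj, window)
  ## signed arclength coordinate along the maximum line, standardised plane
  dir_ <- c(1 / d$sd_a, d$max_line$slope / d$sd_s)
  dir_ <- dir_ / sqrt(sum(dir_^2))
  proj <- function(a, s) (a / d$sd_a) * dir_[1] + (s / d$sd_s) * dir_[2]
  thr_a <- d$threshold$threshold_A
  t0 <- proj(thr_a, d$max_line$intercept + d$max_line$slope * thr_a)
  lab_int <- ifelse(proj(ser$A, ser$S) > t0, "run", "tumble")
  nf <- attr(ser, "n_frames")
  labels <- rep(NA_character_, nf)
  labels[ser$frame] <- lab_int
  ## boundary frames inherit the nearest classified label
  labels[seq_len(ser$frame[1] - 1)] <- lab_int[1]
  tail_n <- nf - ser$frame[length(ser$frame)]
  if (tail_n > 0) labels[(nf - tail_n + 1):nf] <- lab_int[length(lab_int)]
  labels <- merge_short_segments(labels, min_segment)
  new_phase_annotation(traj$cell_id, frame_time = traj$time[seq_len(nf)],
                       phase = labels, dt = attr(ser, "dt"),
                       traj_time = traj$time)
}


#' Segment short high-resolution tracks by the 45-degree rule
#'
#' For short tracks (~10-25 s sampling) a run continues while the direction
#' of motion stays within `angle_threshold` of the run's initial direction,
#' or while a larger deviation persists for fewer than `persist_frames`
#' frames. A deviation beyond the threshold that persists for at least
#' `persist_frames` frames opens a tumble; the tumble ends when a stable new
#' direction (`persist_frames` consecutive frames within the threshold of
#' the first of them) begins a new run.
#'
#' @param traj a [trajectory].
#' @param angle_threshold maximum deviation from the run's initial
#'   direction, degrees.
#' @param persist_frames frames a deviation must persist to count as a
#'   tumble.
#' @return A `"phase_annotation"`.
#' @export
classify_phases_short <- function(traj, angle_threshold = 45,
                                  persist_frames = 5) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$pos)
  if (n < persist_frames + 1)
    stop("trajectory needs more than persist_frames points")
  v <- diff(traj$pos)
  nf <- n - 1L
  dev_from <- function(ref, i) {
    a <- angle_between(v[i, ], ref)
    if (is.na(a)) 0 else a            # zero step: no evidence of deviation
  }
  labels <- character(nf)
  i <- 1L
  run_dir <- v[1, ]
  state <- "run"
  while (i <= nf) {
    if (state == "run") {
      if (dev_from(run_dir, i) <= angle_threshold) {
        labels[i] <- "run"; i <- i + 1L
      } else {
        ## look ahead: how long does the deviation persist?
        j <- i
        while (j <= nf && dev_from(run_dir, j) > angle_threshold) j <- j + 1L
        if (j - i >= persist_frames) {
          state <- "tumble"
        } else {
          labels[i:(j - 1)] <- "run"; i <- j
        }
      }
    } else {
      ## search the earliest stable new direction; the deviating frames that
      ## opened the tumble stay part of it, so a new run can begin only
      ## after persist_frames tumble frames
      k <- i + persist_frames
      started <- FALSE
      while (k + persist_frames - 1L <= nf) {
        ref <- v[k, ]
        stable <- all(vapply(k:(k + persist_frames - 1L),
                             function(m) dev_from(ref, m) <= angle_threshold,
                             TRUE))
        if (stable && sum(ref^2) > 0) { started <- TRUE; break }
        k <- k + 1L
      }
      if (started) {
        if (k > i) labels[i:(k - 1)] <- "tumble"
        run_dir <- v[k, ]
        state <- "run"
        i <- k
      } else {
        labels[i:nf] <- "tumble"
        i <- nf + 1L
      }
    }
  }
  dts <- diff(traj$time)
  new_phase_annotation(traj$cell_id, frame_time = traj$time[seq_len(nf)],
                       phase = labels, dt = stats::median(dts),
                       traj_time = traj$time)
}
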