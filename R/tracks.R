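#' Construct a single-cell trajectory
#'
#' A trajectory is the atomic analysis unit: time-stamped 3D positions of one
#' tracked cell. Times are minutes, positions micrometres; `z` may be constant
#' (or omitted) for planar or simulated data.
#'
#' @param cell_id character scalar identifying the cell.
#' @param time numeric vector of time points, minutes, strictly increasing.
#' @param x,y,z numeric coordinate vectors, micrometres. `z` defaults to 0.
#' @param condition character condition label (e.g. `"control"`,
#'   `"ezrin_MO"`, `"CAEzrin"`).
#' @return An object of class `"trajectory"`: a list with elements `cell_id`,
#'   `condition`, `time` and `pos` (an n x 3 matrix with columns x, y, z).
#' @examples
#' tr <- trajectory("c1", time = seq(0, 15, by = 1.5),
#'                  x = seq(0, 30, by = 3), y = 0)
#' tr
#' @export
trajectory <- function(cell_id, time, x, y, z = 0, condition = "control") {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 2) stop("a trajectory needs at least 2 points")
  pos <- cbind(x = as.numeric(x), y = as.numeric(y),
               z = rep_len(as.numeric(z), n))
  if (nrow(pos) != n) stop("time and coordinates differ in length")
  if (any(!is.finite(time)) || any(!is.finite(pos)))
    stop("non-finite time or coordinate in trajectory '", cell_id, "'")
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing in trajectory '", cell_id, "'")
  structure(list(cell_id = as.character(cell_id),
                 condition = as.character(condition),
                 time = time, pos = pos),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory", x$cell_id, sprintf("(%s)", x$condition), "-",
      nrow(x$pos), "points,",
      sprintf("%.1f-%.1f min\n", x$time[1], x$time[length(x$time)]))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(cell_id = x$cell_id, time_min = x$time,
             x_um = x$pos[, 1], y_um = x$pos[, 2], z_um = x$pos[, 3],
             condition = x$condition, stringsAsFactors = FALSE)
}

new_trajectory_list <- function(lst) {
  names(lst) <- vapply(lst, `[[`, "", "cell_id")
  structure(lst, class = "trajectory_list")
}

#' @export
print.trajectory_list <- function(x, ...) {
  cat("Trajectory list:", length(x), "cells\n")
  invisible(x)
}

#' @export
`[.trajectory_list` <- function(x, i) new_trajectory_list(unclass(x)[i])

#' @export
as.data.frame.trajectory_list <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

## Normalise tracking-table headers: case-insensitive, units suffixes
## (_min, _um, _um2, _deg) optional.
canonical_names <- function(nms) {
  out <- tolower(nms)
  out <- sub("_(min|um2|um|deg|sec)$", "", out)
  out
}

read_table_dialect <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read cell trajectories from a tracking export table
#'
#' Expects columns `cell_id`, `time` (minutes), `x`, `y` (micrometres) and
#' optionally `z` (defaults to 0) and `condition` (defaults to "control").
#' Headers are case-insensitive and unit suffixes (`time_min`, `x_um`, ...)
#' are accepted. Rows are sorted by time within each cell on load.
#'
#' @param path path to the table.
#' @param dialect `"csv"` (comma) or `"tsv"` (tab) separated.
#' @return A `"trajectory_list"` with one [trajectory] per `cell_id`.
#' @export
read_tracks <- function(path, dialect = c("csv", "tsv")) {
  df <- read_table_dialect(path, dialect)
  names(df) <- canonical_names(names(df))
  need <- c("cell_id", "time", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("track table lacks mandatory column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$z)) df$z <- 0
  if (is.null(df$condition)) df$condition <- "control"
  dup <- duplicated(df[c("cell_id", "time")])
  if (any(dup))
    stop("duplicate (cell_id, time) at row ", which(dup)[1])
  split_df <- split(df, df$cell_id)
  new_trajectory_list(lapply(split_df, function(d) {
    d <- d[order(d$time), ]
    trajectory(d$cell_id[1], d$time, d$x, d$y, d$z, d$condition[1])
  }))
}

#' Write trajectories to a CSV/TSV table
#'
#' Inverse of [read_tracks()]; `read_tracks(write_tracks(x, p), ...)` restores
#' every field.
#'
#' @param tracks a `"trajectory_list"` or single [trajectory].
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (inherits(tracks, "trajectory")) tracks <- new_trajectory_list(list(tracks))
  df <- as.data.frame(tracks)
  utils::write.table(df, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read protrusion-event tables
#'
#' Accepts either pre-computed angles (columns `cell_id`, `time`, `kind`,
#' `angle` in degrees relative to the local migration direction, optional
#' `weight`, `area`, `cell_area`) or the raw-vector variant with cell
#' centre-of-mass (`cx,cy,cz`), protrusion centre-of-mass (`px,py,pz`) and
#' local migration direction (`dx,dy,dz`), from which the angle is computed.
#' For planar data (all z components zero) the angle is signed in
#' (-180, 180]; for true 3D vectors only the magnitude is defined and the
#' angle lies in [0, 180].
#'
#' @param path path to the table.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A data.frame of class `"protrusion_events"` with columns
#'   `cell_id`, `time`, `kind`, `angle`, `weight`, `area`, `cell_area`.
#' @export
read_protrusions <- function(path, dialect = c("csv", "tsv")) {
  df <- read_table_dialect(path, dialect)
  names(df) <- canonical_names(names(df))
  need <- c("cell_id", "time")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("protrusion table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$kind)) df$kind <- "unclassified"
  bad_kind <- !df$kind %in% c("bleb", "actin_rich", "unclassified")
  if (any(bad_kind))
    stop("unknown protrusion kind: ", df$kind[which(bad_kind)[1]])
  if (is.null(df$angle)) {
    raw <- c("cx", "cy", "cz", "px", "py", "pz", "dx", "dy", "dz")
    if (!all(raw %in% names(df)))
      stop("protrusion table needs an 'angle' column or the raw CoM/direction",
           " columns ", paste(raw, collapse = ","))
    df$angle <- vapply(seq_len(nrow(df)), function(i) {
      u <- c(df$px[i] - df$cx[i], df$py[i] - df$cy[i], df$pz[i] - df$cz[i])
      v <- c(df$dx[i], df$dy[i], df$dz[i])
      planar <- u[3] == 0 && v[3] == 0
      a <- angle_between(u, v)
      if (is.na(a)) stop("zero-length CoM or direction vector at row ", i)
      if (planar) {
        s <- sign(v[1] * u[2] - v[2] * u[1])   # z of cross product
        a <- if (s < 0) -a else a
      }
      wrap_angle(a)
    }, 0)
  }
  df$angle <- wrap_angle(as.numeric(df$angle))
  if (is.null(df$weight)) df$weight <- 1
  if (any(df$weight < 0))
    stop("negative protrusion weight at row ", which(df$weight < 0)[1])
  if (any(df$kind == "actin_rich" & df$weight <= 0))
    stop("actin_rich events require positive weight")
  if (is.null(df$area)) df$area <- NA_real_
  if (is.null(df$cell_area)) df$cell_area <- NA_real_
  out <- df[c("cell_id", "time", "kind", "angle", "weight", "area", "cell_area")]
  class(out) <- c("protrusion_events", "data.frame")
  out
}

#' Write phase annotations to a long-format table
#'
#' One row per trajectory frame (the interval starting at `time`), with
#' columns `cell_id`, `time`, `phase`, `segment_index`. Round-trips through
#' [read_annotations()] losslessly.
#'
#' @param annotations a single `"phase_annotation"` or list of them.
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (inherits(annotations, "phase_annotation")) annotations <- list(annotations)
  rows <- lapply(annotations, function(a) {
    stopifnot(inherits(a, "phase_annotation"))
    data.frame(cell_id = a$cell_id, time = a$frame_time,
               phase = as.character(a$phase),
               segment_index = a$segment_of_frame,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), time = numeric(),
               phase = character(), segment_index = integer())
  utils::write.table(df, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read phase annotations written by [write_annotations()]
#'
#' @param path path to the table.
#' @param dialect `"csv"` or `"tsv"`.
#' @return A list of `"phase_annotation"` objects (without trailing
#'   trajectory time points, which annotations do not store).
#' @export
read_annotations <- function(path, dialect = c("csv", "tsv")) {
  df <- read_table_dialect(path, dialect)
  names(df) <- canonical_names(names(df))
  need <- c("cell_id", "time", "phase", "segment_index")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$time), ]
    dt <- if (nrow(d) > 1) stats::median(diff(d$time)) else NA_real_
    new_phase_annotation(d$cell_id[1], frame_time = d$time,
                         phase = d$phase, dt = dt)
  })
}
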