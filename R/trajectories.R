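# trajectory_set: tidy per-cell tracks with a fixed frame interval.

#' Construct a trajectory set
#'
#' A `trajectory_set` stores time-stamped positions (and, where available,
#' unit orientations) of tracked or simulated cells. It is the common currency
#' between the swimmer simulators, the tracker and the motility statistics.
#'
#' @param data data frame with columns `track_id`, `frame`, `time_s`, `x_um`,
#'   `z_um` and optionally `px`, `pz` (unit orientation components).
#' @param frame_interval frame interval (s).
#' @param domain optional [domain_spec()] the positions live in.
#' @return An object of class `"trajectory_set"`.
#' @export
trajectory_set <- function(data, frame_interval, domain = NULL) {
  need <- c("track_id", "frame", "time_s", "x_um", "z_um")
  if (!all(need %in% names(data)))
    stop_invalid("trajectory data must have columns ",
                 paste(need, collapse = ", "))
  check_positive(frame_interval, "frame_interval")
  data <- data[order(data$track_id, data$frame), , drop = FALSE]
  rownames(data) <- NULL
  if (any(tapply(data$frame, data$track_id, function(f) any(diff(f) <= 0))))
    stop_invalid("per-track frame numbers must be strictly increasing")
  if (all(c("px", "pz") %in% names(data))) {
    nrm <- data$px^2 + data$pz^2
    if (any(abs(nrm - 1) > 1e-9))
      stop_invalid("orientation components must be unit vectors (|p| = 1)")
  }
  structure(list(data = data, frame_interval = frame_interval, domain = domain),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d tracks, %d records, dt = %g s\n",
              length(unique(x$data$track_id)), nrow(x$data), x$frame_interval))
  invisible(x)
}

#' @export
summary.trajectory_set <- function(object, ...) {
  len <- tapply(object$data$frame, object$data$track_id, length)
  cat(sprintf("Trajectory set: %d tracks, dt = %g s\n", length(len),
              object$frame_interval))
  cat(sprintf("  track length (frames): min %d / median %g / max %d\n",
              min(len), median(len), max(len)))
  cat(sprintf("  time span: %g .. %g s\n", min(object$data$time_s),
              max(object$data$time_s)))
  invisible(object)
}

#' @export
plot.trajectory_set <- function(x, n_tracks = 25, ...) {
  ids <- head(unique(x$data$track_id), n_tracks)
  d <- x$data[x$data$track_id %in% ids, ]
  plot(d$x_um, d$z_um, type = "n", xlab = "x (um)", ylab = "z (um)", ...)
  for (id in ids) {
    di <- d[d$track_id == id, ]
    lines(di$x_um, di$z_um, col = gray(0.2 + 0.6 * (id %% 7) / 7))
  }
  invisible(x)
}

#' Write / read trajectory CSV
#'
#' Plain CSV with header `track_id,frame,time_s,x_um,z_um,px,pz` (orientation
#' columns present only when the set carries them).
#'
#' @param ts a [trajectory_set()].
#' @param path file path.
#' @return `write_trajectories` returns `path` invisibly; `read_trajectories`
#'   returns a [trajectory_set()].
#' @export
write_trajectories <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  write.csv(ts$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param frame_interval frame interval (s); inferred from the time stamps
#'   when omitted.
#' @export
read_trajectories <- function(path, frame_interval = NULL) {
  d <- read.csv(path)
  if (is.null(frame_interval)) {
    dt <- diff(sort(unique(d$time_s)))
    frame_interval <- median(dt)
  }
  trajectory_set(d, frame_interval)
}
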