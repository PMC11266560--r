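#' Trajectory set
#'
#' A collection of time-ordered 2-D single-molecule trajectories sharing one
#' frame interval. Coordinates are in nm; `frame_interval` in seconds.
#'
#' @param tracks Tibble/data.frame with columns `track_id`, `frame`, `x`,
#'   `y`. Frames must be strictly increasing within each track and every
#'   track must have at least 2 positions.
#' @param frame_interval Frame duration, s (> 0).
#' @return An object of class `"trajectory_set"`.
#' @export
trajectory_set <- function(tracks, frame_interval) {
  frame_interval <- check_scalar(frame_interval, "frame_interval", min = 0,
                                 strict_min = TRUE)
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("tracks is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tracks <- tibble::as_tibble(tracks)[, union(need, names(tracks))]
  tracks$frame <- as.integer(tracks$frame)
  if (anyNA(tracks$x) || anyNA(tracks$y) || anyNA(tracks$frame))
    stop("tracks contain missing coordinates or frames", call. = FALSE)
  for (id in unique(tracks$track_id)) {
    fr <- tracks$frame[tracks$track_id == id]
    if (length(fr) < 2)
      stop(sprintf("track '%s' has fewer than 2 positions", id), call. = FALSE)
    if (any(diff(fr) <= 0))
      stop(sprintf("frames are not strictly increasing within track '%s'", id),
           call. = FALSE)
  }
  structure(list(tracks = tracks, frame_interval = frame_interval),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  ids <- unique(x$tracks$track_id)
  cat(sprintf("<trajectory_set> %d trajectories, %d positions, dt = %g s\n",
              length(ids), nrow(x$tracks), x$frame_interval))
  invisible(x)
}

#' Number of trajectories in a set
#' @param set A [trajectory_set].
#' @export
n_trajectories <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  length(unique(set$tracks$track_id))
}

# list of per-track tibbles, in first-appearance order
track_split <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  idx <- split(seq_len(nrow(set$tracks)),
               factor(set$tracks$track_id, levels = unique(set$tracks$track_id)))
  lapply(idx, function(i) set$tracks[i, , drop = FALSE])
}
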