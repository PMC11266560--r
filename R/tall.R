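# Detection of temporary arrest of lateral diffusion (TALL): transient
# dwells of a tracked molecule inside a small detection circle lasting
# longer than a threshold period.

#' TALL detection parameters
#'
#' @param detection_radius Radius of the detection circle, nm (default 50).
#' @param threshold_trapped_period Minimum dwell duration counted as a TALL
#'   event, s. Defaults to 0.032 (32 ms), the value for 4 ms/frame
#'   recordings; use 0.008 (8 ms) for 1 ms/frame recordings.
#' @param min_trajectory_length Trajectories must be longer than this many
#'   frames to be analysed (default 10).
#' @param immobile_reference_sd Positional standard deviation of the fixed
#'   immobile-probe standard, nm (default 22.2, a probe fixed on glass
#'   imaged at 4 ms/frame). A trajectory whose single merged event spans
#'   >= 90% of its duration and whose overall radius of gyration does not
#'   exceed this bound is classified immobile rather than TALL.
#' @return A list of class `"tall_params"`.
#' @export
tall_params <- function(detection_radius = 50, threshold_trapped_period = 0.032,
                        min_trajectory_length = 10,
                        immobile_reference_sd = localization_precision_presets[["tdStayGold_4ms"]]) {
  structure(list(
    detection_radius = check_scalar(detection_radius, "detection_radius",
                                    min = 0, strict_min = TRUE),
    threshold_trapped_period = check_scalar(threshold_trapped_period,
                                            "threshold_trapped_period",
                                            min = 0, strict_min = TRUE),
    min_trajectory_length = check_count(min_trajectory_length,
                                        "min_trajectory_length", min = 3),
    immobile_reference_sd = check_scalar(immobile_reference_sd,
                                         "immobile_reference_sd", min = 0)
  ), class = "tall_params")
}

# greedy maximal run from each start: extend while every position of the
# window lies within `radius` of the window's (recomputed) centroid
.tall_candidates <- function(x, y, radius) {
  N <- length(x)
  r2 <- radius^2
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= N) {
    j <- i
    sx <- x[i]; sy <- y[i]
    while (j < N) {
      sx2 <- sx + x[j + 1]; sy2 <- sy + y[j + 1]
      k <- j + 1 - i + 1
      cx <- sx2 / k; cy <- sy2 / k
      seg <- i:(j + 1)
      if (max((x[seg] - cx)^2 + (y[seg] - cy)^2) > r2) break
      j <- j + 1L
      sx <- sx2; sy <- sy2
    }
    if (j > i) { starts <- c(starts, i); ends <- c(ends, j) }
    i <- i + 1L
  }
  cbind(start = starts, end = ends)
}

# merge intervals that overlap or are separated by fewer than `gap` frames
.merge_intervals <- function(iv, gap = 2L) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[k, 1] - out[last, 2] < gap) {
      out[last, 2] <- max(out[last, 2], iv[k, 2])
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  out
}

#' Detect TALL events in one trajectory
#'
#' A TALL candidate is a maximal run of consecutive positions that all lie
#' within `detection_radius` of the run's own centroid (greedy expansion
#' from each start). Candidates spanning less than
#' `threshold_trapped_period` are discarded; surviving candidates that
#' overlap or are separated by fewer than 2 frames are merged into events.
#' A trajectory whose single merged event covers at least 90% of its frames
#' and whose overall radius of gyration is within the immobile-probe bound
#' is classified `immobile`; otherwise it is `mobile` with zero or more TALL
#' events.
#'
#' @param track Trajectory tibble (`x`, `y` in nm, optional gap-free
#'   `frame`) or two-column matrix.
#' @param params A [tall_params].
#' @param frame_interval Frame duration, s.
#' @return A list of class `"tall_result"`: `status` (`"analyzed"` or
#'   `"skipped"`), `classification` (`"mobile"`/`"immobile"`), `events`
#'   (tibble: `start`, `end`, `n_frames`, `duration` s, `cx`, `cy`,
#'   `gyration_radius` nm), `n_frames`, `frame_interval`.
#' @export
detect_tall <- function(track, params = tall_params(), frame_interval = 0.004) {
  stopifnot(inherits(params, "tall_params"))
  frame_interval <- check_scalar(frame_interval, "frame_interval", min = 0,
                                 strict_min = TRUE)
  if (params$threshold_trapped_period < 2 * frame_interval)
    stop("threshold_trapped_period must be at least two frame intervals",
         call. = FALSE)
  xy <- .track_xy(track)
  N <- nrow(xy)
  empty_events <- tibble::tibble(start = integer(), end = integer(),
                                 n_frames = integer(), duration = numeric(),
                                 cx = numeric(), cy = numeric(),
                                 gyration_radius = numeric())
  if (N <= params$min_trajectory_length) {
    return(structure(list(status = "skipped", reason = "trajectory too short",
                          classification = NA_character_, events = empty_events,
                          n_frames = N, frame_interval = frame_interval),
                     class = "tall_result"))
  }
  cand <- .tall_candidates(xy[, 1], xy[, 2], params$detection_radius)
  if (nrow(cand)) {
    span_ok <- (cand[, 2] - cand[, 1]) * frame_interval >=
      params$threshold_trapped_period
    cand <- cand[span_ok, , drop = FALSE]
  }
  merged <- .merge_intervals(cand)
  events <- empty_events
  if (nrow(merged)) {
    rows <- lapply(seq_len(nrow(merged)), function(k) {
      seg <- merged[k, 1]:merged[k, 2]
      cx <- mean(xy[seg, 1]); cy <- mean(xy[seg, 2])
      tibble::tibble(start = merged[k, 1], end = merged[k, 2],
                     n_frames = length(seg),
                     duration = (merged[k, 2] - merged[k, 1]) * frame_interval,
                     cx = cx, cy = cy,
                     gyration_radius = sqrt(mean((xy[seg, 1] - cx)^2 +
                                                   (xy[seg, 2] - cy)^2)))
    })
    events <- do.call(rbind, rows)
  }
  rg_all <- sqrt(mean((xy[, 1] - mean(xy[, 1]))^2 + (xy[, 2] - mean(xy[, 2]))^2))
  immobile <- nrow(events) == 1 && events$n_frames[1] >= 0.9 * N &&
    rg_all <= params$immobile_reference_sd
  structure(list(status = "analyzed", reason = NULL,
                 classification = if (immobile) "immobile" else "mobile",
                 events = events, n_frames = N,
                 frame_interval = frame_interval),
            class = "tall_result")
}

#' Pool TALL results into set-level time fractions and lifetimes
#'
#' Time fractions are pooled over the frames of all analysed trajectories:
#' frames of immobile trajectories count as immobile, frames inside TALL
#' events of mobile trajectories as TALL, the rest as mobile. The TALL
#' lifetime `tau_TALL` is the mean duration of the merged events of mobile
#' trajectories (`NA` when there is none).
#'
#' @param results List of [detect_tall] results (skipped ones are ignored).
#' @return One-row tibble: `n_trajectories`, `n_frames`,
#'   `fraction_mobile`, `fraction_tall`, `fraction_immobile` (sum to 1),
#'   `n_events`, `tau_tall` (s) and `tau_defined`.
#' @export
tall_summary <- function(results) {
  if (inherits(results, "tall_result")) results <- list(results)
  results <- Filter(function(r) inherits(r, "tall_result") &&
                      r$status == "analyzed", results)
  if (!length(results))
    stop("no analysed trajectories; TALL summary is empty", call. = FALSE)
  total <- 0L; tall_f <- 0L; immob_f <- 0L
  durations <- numeric(0)
  for (r in results) {
    total <- total + r$n_frames
    if (identical(r$classification, "immobile")) {
      immob_f <- immob_f + r$n_frames
    } else if (nrow(r$events)) {
      tall_f <- tall_f + sum(r$events$n_frames)
      durations <- c(durations, r$events$duration)
    }
  }
  tibble::tibble(
    n_trajectories = length(results),
    n_frames = total,
    fraction_mobile = (total - tall_f - immob_f) / total,
    fraction_tall = tall_f / total,
    fraction_immobile = immob_f / total,
    n_events = length(durations),
    tau_tall = if (length(durations)) mean(durations) else NA_real_,
    tau_defined = length(durations) > 0
  )
}

#' TALL analysis of a whole trajectory set
#'
#' Convenience wrapper: runs [detect_tall] on every trajectory of a set and
#' pools the results with [tall_summary].
#'
#' @param set A [trajectory_set].
#' @param params A [tall_params].
#' @return List with `results` (per-trajectory) and `summary`.
#' @export
tall_analysis <- function(set, params = tall_params()) {
  stopifnot(inherits(set, "trajectory_set"))
  results <- lapply(track_split(set), detect_tall, params = params,
                    frame_interval = set$frame_interval)
  list(results = results, summary = tall_summary(results))
}
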