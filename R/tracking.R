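# Mean-square displacement analysis of single-molecule trajectories and
# effective diffusion coefficients from window fits of MSD-dt curves.

# coerce a single trajectory to an (x, y) matrix in nm and check uniform,
# gap-free frame spacing
.track_xy <- function(track) {
  if (is.matrix(track)) {
    stopifnot(ncol(track) >= 2)
    return(track[, 1:2, drop = FALSE])
  }
  stopifnot(all(c("x", "y") %in% names(track)))
  if ("frame" %in% names(track) && nrow(track) > 1) {
    df <- diff(track$frame)
    if (any(df != 1))
      stop("trajectory has non-uniform frame spacing; split tracks at gaps ",
           "before MSD analysis", call. = FALSE)
  }
  cbind(track$x, track$y)
}

#' Mean-square displacement of a single trajectory
#'
#' Overlapping-window MSD: for each lag `n` (`1 <= n <= N - 1`), the mean of
#' the `N - n` available squared displacements of `n` steps,
#' `MSD(n dt) = mean_j [x(j+n) - x(j)]^2 + [y(j+n) - y(j)]^2`.
#' Coordinates are in nm; the curve is returned in um^2.
#'
#' @param track Trajectory: a tibble with `x`, `y` (nm) and optionally
#'   `frame` (must be gap-free), or a two-column matrix.
#' @param frame_interval Frame duration, s.
#' @return An `"msd_curve"` tibble: `lag`, `dt` (s), `msd` (um^2), `se`
#'   (um^2; nominal SE across the overlapping windows, which are
#'   correlated — ensemble SEs across trajectories are the honest ones),
#'   `n_segments`.
#' @export
msd <- function(track, frame_interval) {
  frame_interval <- check_scalar(frame_interval, "frame_interval", min = 0,
                                 strict_min = TRUE)
  xy <- .track_xy(track)
  N <- nrow(xy)
  if (N < 2) stop("trajectory must have at least 2 positions", call. = FALSE)
  lags <- seq_len(N - 1)
  msd_v <- numeric(N - 1); se_v <- numeric(N - 1); nseg <- integer(N - 1)
  for (n in lags) {
    dx <- xy[(1 + n):N, 1] - xy[1:(N - n), 1]
    dy <- xy[(1 + n):N, 2] - xy[1:(N - n), 2]
    d2 <- (dx^2 + dy^2) / 1e6        # nm^2 -> um^2
    msd_v[n] <- mean(d2)
    nseg[n] <- N - n
    se_v[n] <- if (N - n > 1) stats::sd(d2) / sqrt(N - n) else NA_real_
  }
  out <- tibble::tibble(lag = lags, dt = lags * frame_interval, msd = msd_v,
                        se = se_v, n_segments = nseg)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("msd_curve", class(out))
  out
}

#' Ensemble-averaged MSD-dt curve
#'
#' Averages the per-trajectory MSD values at each lag across all
#' trajectories of at least `min_length` positions. By default the average
#' is weighted by the number of contributing displacement segments
#' (`N - n` per trajectory); `weighted = FALSE` gives the plain mean. The
#' SE is computed across trajectories, not across the (correlated)
#' overlapping windows.
#'
#' @param set A [trajectory_set].
#' @param min_length Minimum trajectory length (positions) to include.
#' @param weighted Weight trajectories by contributing segment counts.
#' @return An `"msd_curve"` tibble: `lag`, `dt`, `msd`, `se`,
#'   `n_segments` (total), `n_trajectories` per lag.
#' @export
ensemble_msd <- function(set, min_length = 2, weighted = TRUE) {
  stopifnot(inherits(set, "trajectory_set"))
  tracks <- track_split(set)
  tracks <- tracks[vapply(tracks, nrow, 0L) >= min_length]
  if (!length(tracks))
    stop("no trajectory meets min_length; the ensemble curve is empty",
         call. = FALSE)
  curves <- lapply(tracks, msd, frame_interval = set$frame_interval)
  max_lag <- max(vapply(curves, nrow, 0L))
  rows <- vector("list", max_lag)
  for (n in seq_len(max_lag)) {
    vals <- unlist(lapply(curves, function(cv) if (n <= nrow(cv)) cv$msd[n] else NULL))
    wts <- unlist(lapply(curves, function(cv) if (n <= nrow(cv)) cv$n_segments[n] else NULL))
    m <- if (weighted) sum(vals * wts) / sum(wts) else mean(vals)
    se <- if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0
    rows[[n]] <- tibble::tibble(lag = n, dt = n * set$frame_interval, msd = m,
                                se = se, n_segments = sum(wts),
                                n_trajectories = length(vals))
  }
  out <- do.call(rbind, rows)
  attr(out, "frame_interval") <- set$frame_interval
  class(out) <- c("msd_curve", class(out))
  out
}

# named fit windows: timepoints (s) at which the MSD-dt curve is fitted
.deff_windows <- list(
  "12ms@4ms" = c(8, 12, 16) * 1e-3,
  "24ms@4ms" = seq(8, 40, by = 4) * 1e-3,
  "3ms@1ms"  = c(2, 3, 4) * 1e-3,
  "10ms@1ms" = seq(2, 10, by = 1) * 1e-3
)

#' Effective diffusion coefficient from an MSD-dt window fit
#'
#' Ordinary least-squares line through the MSD-dt curve at the window
#' timepoints; the effective diffusion coefficient is the slope divided
#' by 4 (2-D diffusion). The intercept — which absorbs the localization
#' error offset `4 sigma^2` — is reported, never subtracted.
#'
#' Named windows: `"12ms@4ms"` fits at 8, 12, 16 ms (single-molecule window
#' at 4 ms resolution), `"24ms@4ms"` at 8-40 ms (ensemble window),
#' `"3ms@1ms"` at 2, 3, 4 ms and `"10ms@1ms"` at 2-10 ms (1 ms
#' resolution). A numeric vector of timepoints (s) may be given instead.
#'
#' @param curve An `"msd_curve"`.
#' @param window Window label (see above) or numeric timepoints in s.
#' @return A list of class `"diffusion_estimate"`: `D_eff` (um^2/s),
#'   `slope`, `intercept` (um^2), `r_squared`, `window`, `timepoints`,
#'   `non_diffusive` (`TRUE` when the fitted slope was negative and
#'   `D_eff` was reported as 0).
#' @export
fit_deff <- function(curve, window = "12ms@4ms") {
  stopifnot(inherits(curve, "msd_curve"))
  if (is.character(window)) {
    if (!window %in% names(.deff_windows))
      stop("unknown window '", window, "'; available: ",
           paste(names(.deff_windows), collapse = ", "), call. = FALSE)
    tp <- .deff_windows[[window]]
    label <- window
  } else {
    tp <- as.numeric(window)
    label <- paste0(paste(signif(tp * 1e3, 3), collapse = "/"), "ms")
  }
  if (length(tp) < 2) stop("window needs at least 2 timepoints", call. = FALSE)
  idx <- vapply(tp, function(t) {
    i <- which(abs(curve$dt - t) < 1e-9)
    if (length(i) != 1) NA_integer_ else i
  }, 0L)
  if (anyNA(idx))
    stop(sprintf("window timepoint %.3g ms is not on the MSD curve",
                 tp[which(is.na(idx))[1]] * 1e3), call. = FALSE)
  x <- curve$dt[idx]; y <- curve$msd[idx]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]; intercept <- fit$coefficients[1]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  non_diffusive <- slope < 0
  structure(list(D_eff = if (non_diffusive) 0 else unname(slope) / 4,
                 slope = unname(slope), intercept = unname(intercept),
                 r_squared = r2, window = label, timepoints = tp,
                 non_diffusive = non_diffusive),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D_eff = %.4g um^2/s (window %s%s)\n",
              x$D_eff, x$window, if (x$non_diffusive) ", non-diffusive" else ""))
  invisible(x)
}

# relative-deviation statistic: MSD at a long lag relative to the simple
# Brownian prediction extrapolated from the short-time diffusion
# coefficient D_short = MSD(dt) / (4 dt). The single-point estimator stays
# finite on saturated (confined) curves, where a short-window slope fit
# degenerates to zero.
.rd_stat <- function(curve, n_star) {
  if (curve$msd[1] <= 0) return(0)  # static trajectory: suppressed
  curve$msd[n_star] / (n_star * curve$msd[1])
}

#' Brownian calibration envelope for motion classification
#'
#' Simulates `n_sim` pure Brownian trajectories matched to the observed
#' trajectories in length and frame interval, computes the
#' relative-deviation statistic RD = MSD(n* dt) / (4 D_short n* dt) for
#' each (with the short-time coefficient D_short = MSD(dt) / (4 dt)), and
#' returns its 2.5th/97.5th percentile envelope. Trajectories whose RD
#' falls below/above the envelope are classified as suppressed/directed;
#' the envelope brackets about 95% of true Brownian trajectories by
#' construction.
#'
#' @param n_frames Trajectory length the envelope is built for.
#' @param frame_interval Frame duration, s.
#' @param n_sim Number of simulated Brownian trajectories (>= 1000
#'   recommended).
#' @param D Diffusion coefficient of the calibration simulation, um^2/s
#'   (RD is scale-free; this only sets the simulated regime).
#' @param localization_precision_sd Localization error of the calibration,
#'   nm.
#' @param n_star Long lag (frames) at which RD is evaluated; default
#'   `floor((n_frames - 1) / 2)`.
#' @param probs Envelope percentiles.
#' @param seed Integer seed.
#' @return A list of class `"motion_calibration"`.
#' @export
brownian_calibration <- function(n_frames, frame_interval, n_sim = 1000,
                                 D = 1, localization_precision_sd = 0,
                                 n_star = NULL,
                                 probs = c(0.025, 0.975), seed = NULL) {
  n_frames <- check_count(n_frames, "n_frames", min = 10)
  if (is.null(n_star)) n_star <- floor((n_frames - 1) / 2)
  stopifnot(n_star > 1, n_star <= n_frames - 1)
  set <- gen_trajectories(
    trajectory_model("brownian", D = D, frame_interval = frame_interval,
                     n_frames = n_frames,
                     localization_precision_sd = localization_precision_sd,
                     seed = seed),
    n_trajectories = n_sim)
  rd <- vapply(track_split(set), function(tr)
    .rd_stat(msd(tr, frame_interval), n_star), 0)
  q <- stats::quantile(rd, probs, names = FALSE)
  structure(list(n_frames = n_frames, frame_interval = frame_interval,
                 n_star = n_star,
                 lower = q[1], upper = q[2], n_sim = n_sim, rd = rd),
            class = "motion_calibration")
}

#' Classify a trajectory's motion mode
#'
#' Compares the trajectory's relative-deviation statistic with the Brownian
#' percentile envelope of a matched [brownian_calibration]: below the lower
#' percentile is `"suppressed"` (sub-diffusive/confined), above the upper is
#' `"directed"`, in between is `"simple-brownian"`.
#'
#' @param track A trajectory (tibble with `x`, `y`, optionally `frame`).
#' @param calibration A [brownian_calibration] with matching length and
#'   frame interval.
#' @return One of `"suppressed"`, `"simple-brownian"`, `"directed"`.
#' @export
classify_motion <- function(track, calibration) {
  stopifnot(inherits(calibration, "motion_calibration"))
  xy <- .track_xy(track)
  if (nrow(xy) < calibration$n_frames)
    stop("trajectory shorter than the calibration length", call. = FALSE)
  cv <- msd(xy[seq_len(calibration$n_frames), , drop = FALSE],
            calibration$frame_interval)
  rd <- .rd_stat(cv, calibration$n_star)
  if (rd < calibration$lower) "suppressed"
  else if (rd > calibration$upper) "directed"
  else "simple-brownian"
}
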