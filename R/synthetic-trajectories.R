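#' Trajectory model parameters
#'
#' Generative models for 2-D single-molecule trajectories:
#' * `brownian`: free diffusion; per-axis Gaussian steps of variance
#'   `2 D dt`. The reference regime for plasma-membrane lipid probes is
#'   around 1 um^2/s at 4 ms/frame.
#' * `confined`: Brownian motion reflected at a circle of radius
#'   `confinement_radius` about the starting point.
#' * `hop`: Brownian motion in a square compartment grid of side
#'   `compartment_size` (58 nm by default, the mean actin-skeleton
#'   compartment size reported for COS cell membranes); each boundary
#'   encounter is transmitted with probability `hop_probability`, otherwise
#'   the step reflects specularly.
#' * `immobile`: a static point.
#'
#' All positions are finally perturbed by Gaussian localization error of
#' standard deviation `localization_precision_sd`.
#'
#' @param model One of `"brownian"`, `"confined"`, `"hop"`, `"immobile"`.
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param frame_interval Frame duration, s (default 0.004).
#' @param n_frames Positions per trajectory (>= 2).
#' @param confinement_radius Radius of the reflecting circle, nm.
#' @param compartment_size Side of the square hop compartments, nm.
#' @param hop_probability Per-boundary-encounter transmission probability.
#' @param localization_precision_sd Localization error sd, nm.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `"trajectory_model"`.
#' @export
trajectory_model <- function(model = c("brownian", "confined", "hop", "immobile"),
                             D = 1, frame_interval = 0.004, n_frames = 50,
                             confinement_radius = 100, compartment_size = 58,
                             hop_probability = 0.1,
                             localization_precision_sd = 0, seed = NULL) {
  if (!is.character(model) || !model[1] %in% c("brownian", "confined", "hop", "immobile"))
    stop("unknown trajectory model: ", model[1], call. = FALSE)
  structure(list(
    model = match.arg(model),
    D = check_scalar(D, "D", min = 0),
    frame_interval = check_scalar(frame_interval, "frame_interval", min = 0,
                                  strict_min = TRUE),
    n_frames = check_count(n_frames, "n_frames", min = 2),
    confinement_radius = check_scalar(confinement_radius, "confinement_radius",
                                      min = 0, strict_min = TRUE),
    compartment_size = check_scalar(compartment_size, "compartment_size",
                                    min = 0, strict_min = TRUE),
    hop_probability = check_scalar(hop_probability, "hop_probability",
                                   min = 0, max = 1),
    localization_precision_sd = check_scalar(localization_precision_sd,
                                             "localization_precision_sd", min = 0),
    seed = if (is.null(seed)) NULL else check_count(seed, "seed")
  ), class = "trajectory_model")
}

# propagate one axis through the compartment grid, reflecting rejected
# boundary crossings; returns the final coordinate
.hop_axis <- function(x, dx, L, p) {
  pos <- x
  rem <- dx
  for (guard in 1:1000) {
    if (rem == 0) return(pos)
    target <- pos + rem
    if (rem > 0) {
      b <- (floor(pos / L + 1e-9) + 1) * L
      if (target < b) return(target)
    } else {
      b <- (ceiling(pos / L - 1e-9) - 1) * L
      if (target > b) return(target)
    }
    rem <- target - b
    if (stats::runif(1) < p) {        # transmitted
      pos <- b + sign(rem) * 1e-9
    } else {                          # reflected
      pos <- b - sign(rem) * 1e-9
      rem <- -rem
    }
  }
  pos
}

# fold a radial distance into [0, R] by repeated reflection
.reflect_radius <- function(rr, R) {
  s <- rr %% (2 * R)
  ifelse(s > R, 2 * R - s, s)
}

.gen_one_trajectory <- function(params, x0, y0) {
  n <- params$n_frames
  dt <- params$frame_interval
  step_sd <- sqrt(2 * params$D * dt) * 1000  # nm
  model <- params$model
  if (model == "immobile" || step_sd == 0) {
    x <- rep(x0, n); y <- rep(y0, n)
  } else if (model == "brownian") {
    x <- x0 + c(0, cumsum(stats::rnorm(n - 1, 0, step_sd)))
    y <- y0 + c(0, cumsum(stats::rnorm(n - 1, 0, step_sd)))
  } else if (model == "confined") {
    R <- params$confinement_radius
    x <- numeric(n); y <- numeric(n)
    x[1] <- x0; y[1] <- y0
    for (i in 2:n) {
      px <- x[i - 1] + stats::rnorm(1, 0, step_sd)
      py <- y[i - 1] + stats::rnorm(1, 0, step_sd)
      rr <- sqrt((px - x0)^2 + (py - y0)^2)
      if (rr > R) {
        rf <- .reflect_radius(rr, R)
        scale <- if (rr > 0) rf / rr else 0
        px <- x0 + (px - x0) * scale
        py <- y0 + (py - y0) * scale
      }
      x[i] <- px; y[i] <- py
    }
  } else { # hop
    L <- params$compartment_size
    p <- params$hop_probability
    x <- numeric(n); y <- numeric(n)
    x[1] <- x0; y[1] <- y0
    for (i in 2:n) {
      x[i] <- .hop_axis(x[i - 1], stats::rnorm(1, 0, step_sd), L, p)
      y[i] <- .hop_axis(y[i - 1], stats::rnorm(1, 0, step_sd), L, p)
    }
  }
  sdp <- params$localization_precision_sd
  if (sdp > 0) {
    x <- x + stats::rnorm(n, 0, sdp)
    y <- y + stats::rnorm(n, 0, sdp)
  }
  cbind(x, y)
}

#' Generate synthetic single-molecule trajectories
#'
#' Simulates `n_trajectories` trajectories under a [trajectory_model],
#' starting at positions uniform in the ROI. Deterministic given the model
#' seed.
#'
#' @param params A [trajectory_model].
#' @param n_trajectories Number of trajectories (>= 1).
#' @param roi An [roi] for the starting positions.
#' @return A [trajectory_set].
#' @examples
#' set <- gen_trajectories(trajectory_model("brownian", D = 1, seed = 1), 10)
#' @export
gen_trajectories <- function(params, n_trajectories, roi = default_roi()) {
  stopifnot(inherits(params, "trajectory_model"))
  n_trajectories <- check_count(n_trajectories, "n_trajectories", min = 1)
  r <- as_roi(roi)
  with_seed(params$seed, {
    n <- params$n_frames
    ids <- sprintf("T%04d", seq_len(n_trajectories))
    pieces <- vector("list", n_trajectories)
    for (k in seq_len(n_trajectories)) {
      x0 <- stats::runif(1, r["x_min"], r["x_max"])
      y0 <- stats::runif(1, r["y_min"], r["y_max"])
      xy <- .gen_one_trajectory(params, x0, y0)
      pieces[[k]] <- tibble::tibble(track_id = ids[k], frame = seq_len(n),
                                    x = xy[, 1], y = xy[, 2])
    }
    trajectory_set(do.call(rbind, pieces), params$frame_interval)
  })
}
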