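# Independent oracles and small fixture builders used across the suite.

# naive double-loop MSD, the reference for the vectorized implementation
brute_msd <- function(x, y, frame_interval) {
  N <- length(x)
  sapply(seq_len(N - 1), function(n) {
    acc <- 0
    for (j in seq_len(N - n)) {
      acc <- acc + (x[j + n] - x[j])^2 + (y[j + n] - y[j])^2
    }
    acc / (N - n) / 1e6
  })
}

# circle-equivalent extent of a labelled point cluster: twice the 95th
# percentile of radial distances about the centroid (the 95%-mass circle of
# a Gaussian domain)
oracle_diameter <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  2 * stats::quantile(sqrt((x - cx)^2 + (y - cy)^2), 0.95, names = FALSE)
}

# Monte Carlo estimate of disk-rectangle intersection area
mc_disk_rect_area <- function(cx, cy, r, rect, n = 2e5, seed = 1) {
  withr::with_seed(seed, {
    px <- stats::runif(n, rect[["x_min"]], rect[["x_max"]])
    py <- stats::runif(n, rect[["y_min"]], rect[["y_max"]])
    mean((px - cx)^2 + (py - cy)^2 <= r^2) * roi_area(rect)
  })
}

# trajectory with a confinement episode planted between free segments:
# n1 Brownian steps, n_conf positions uniform in a disk of radius r_conf,
# then n2 Brownian steps (D in um^2/s, dt in s)
make_planted_track <- function(seed, n1 = 20, n_conf = 12, n2 = 18,
                               r_conf = 28, D = 1, dt = 0.004) {
  withr::with_seed(seed, {
    step_sd <- sqrt(2 * D * dt) * 1000
    x <- cumsum(c(0, stats::rnorm(n1 - 1, 0, step_sd)))
    y <- cumsum(c(0, stats::rnorm(n1 - 1, 0, step_sd)))
    ang <- stats::runif(n_conf, 0, 2 * pi)
    rr <- sqrt(stats::runif(n_conf)) * r_conf
    xc <- x[n1] + rr * cos(ang)
    yc <- y[n1] + rr * sin(ang)
    x2 <- xc[n_conf] + cumsum(stats::rnorm(n2, 0, step_sd))
    y2 <- yc[n_conf] + cumsum(stats::rnorm(n2, 0, step_sd))
    list(xy = cbind(c(x, xc, x2), c(y, yc, y2)),
         conf_start = n1 + 1, conf_end = n1 + n_conf)
  })
}

# localization table from bare coordinates
loc_table <- function(x, y, frame = 1L, uncertainty = 20, intensity = 1000) {
  tibble::tibble(frame = as.integer(rep_len(frame, length(x))), x = x, y = y,
                 uncertainty = rep_len(uncertainty, length(x)),
                 intensity = rep_len(intensity, length(x)))
}
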