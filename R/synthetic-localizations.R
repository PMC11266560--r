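#' Localization precision presets
#'
#' Single-molecule localization precisions (standard deviation of repeated
#' position fits of a stationary emitter, in nm) for the fluorophores and
#' conditions this package is calibrated against: the photoactivatable
#' protein mEos4b (26.3 nm), the organic dye SF650B (22.0 nm), and
#' tdStayGold probes imaged at 4 ms (22.2 nm) and 1 ms (17.3 nm) per frame.
#'
#' @format Named numeric vector, nm.
#' @export
localization_precision_presets <- c(
  mEos4b = 26.3,
  SF650B = 22.0,
  tdStayGold_4ms = 22.2,
  tdStayGold_1ms = 17.3
)

#' Scene configuration for clustered localization patterns
#'
#' Parameters of the generative model for a single-channel localization map:
#' `n_clusters` domain centres uniform in the ROI, each with
#' `locs_per_cluster` member emitters scattered as an isotropic 2-D Gaussian
#' of standard deviation `cluster_radius_sd` about the centre, plus
#' `background_locs` emitters in complete spatial randomness. Every emitter
#' blinks `1 + Poisson(mean_blink_repeats - 1)` times; each blink is
#' re-localized with fresh Gaussian error of standard deviation
#' `localization_precision_sd`, emulating multi-blink overcounting.
#'
#' A Gaussian domain with `cluster_radius_sd` of 45-60 nm (before
#' localization error) produces apparent domains in the 150-250 nm diameter
#' range typical of sphingomyelin/raft nanodomain maps.
#'
#' @param n_clusters Number of clustered domains (count, >= 0).
#' @param cluster_radius_sd In-cluster Gaussian spread, nm.
#' @param locs_per_cluster Emitters per cluster (count, >= 0).
#' @param background_locs Background emitters (count, >= 0).
#' @param localization_precision_sd Localization error sd, nm (see
#'   [localization_precision_presets]).
#' @param mean_blink_repeats Mean localizations per emitter (>= 1).
#' @param seed Integer seed or `NULL`.
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(n_clusters = 20, cluster_radius_sd = 45,
                         locs_per_cluster = 50, background_locs = 1000,
                         localization_precision_sd = localization_precision_presets[["SF650B"]],
                         mean_blink_repeats = 1, seed = NULL) {
  cfg <- list(
    n_clusters = check_count(n_clusters, "n_clusters"),
    cluster_radius_sd = check_scalar(cluster_radius_sd, "cluster_radius_sd", min = 0),
    locs_per_cluster = check_count(locs_per_cluster, "locs_per_cluster"),
    background_locs = check_count(background_locs, "background_locs"),
    localization_precision_sd = check_scalar(localization_precision_sd,
                                             "localization_precision_sd", min = 0),
    mean_blink_repeats = check_scalar(mean_blink_repeats, "mean_blink_repeats", min = 1),
    seed = if (is.null(seed)) NULL else check_count(seed, "seed")
  )
  structure(cfg, class = "scene_config")
}

# canonical empty localization table
empty_localizations <- function() {
  tibble::tibble(frame = integer(), x = numeric(), y = numeric(),
                 uncertainty = numeric(), intensity = numeric())
}

new_localizations <- function(frame, x, y, uncertainty, intensity) {
  tibble::tibble(frame = as.integer(frame), x = as.numeric(x), y = as.numeric(y),
                 uncertainty = as.numeric(uncertainty),
                 intensity = as.numeric(intensity))
}

#' Generate a completely spatially random (CSR) localization pattern
#'
#' Homogeneous Poisson-style null pattern: `n` localizations i.i.d. uniform
#' over the ROI, with frame numbers uniform over `frame_range`. This is the
#' null model used for the Monte Carlo cluster threshold and for
#' computer-generated random-random colocalization controls.
#'
#' @param n Number of localizations (count, >= 0).
#' @param roi An [roi].
#' @param seed Integer seed or `NULL`.
#' @param frame_range Integer range for frame assignment (default
#'   `c(1, 2000)`, mirroring 4 ms/frame acquisition for 2000 frames).
#' @param uncertainty Uncertainty value recorded per localization, nm.
#' @return A localization table (tibble with columns `frame`, `x`, `y`,
#'   `uncertainty`, `intensity`).
#' @examples
#' locs <- gen_csr(1000, roi(0, 0, 5000, 5000), seed = 1)
#' @export
gen_csr <- function(n, roi = default_roi(), seed = NULL,
                    frame_range = c(1L, 2000L),
                    uncertainty = localization_precision_presets[["SF650B"]]) {
  n <- check_count(n, "n")
  r <- as_roi(roi)
  if (n == 0) return(empty_localizations())
  with_seed(seed, {
    new_localizations(
      frame = sample.int(frame_range[2] - frame_range[1] + 1L, n, replace = TRUE) +
        frame_range[1] - 1L,
      x = stats::runif(n, r["x_min"], r["x_max"]),
      y = stats::runif(n, r["y_min"], r["y_max"]),
      uncertainty = rep(uncertainty, n),
      intensity = stats::rlnorm(n, log(1000), 0.4)
    )
  })
}

# sample k member offsets about a centre by rejection against the roi;
# warns when the acceptance fraction drops below 1 %.
.sample_members <- function(k, cx, cy, sd, r) {
  if (k == 0) return(cbind(numeric(0), numeric(0)))
  out_x <- numeric(0); out_y <- numeric(0)
  tried <- 0L; got <- 0L
  while (got < k && tried < 1e6) {
    m <- max(k - got, 32L)
    px <- stats::rnorm(m, cx, sd); py <- stats::rnorm(m, cy, sd)
    keep <- in_roi(px, py, r)
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
    got <- got + sum(keep); tried <- tried + m
  }
  if (got < k) stop("could not place cluster members inside roi", call. = FALSE)
  if (got / tried < 0.01)
    warning("fewer than 1% of cluster member draws fell inside the roi; ",
            "points were clipped by rejection", call. = FALSE)
  cbind(out_x[seq_len(k)], out_y[seq_len(k)])
}

#' Generate a clustered localization scene with ground truth
#'
#' Simulates the generative model described in [scene_config] and returns
#' both the observed localization table (after blinking and localization
#' error) and the ground truth (cluster centres and per-localization labels)
#' needed to validate downstream segmentation.
#'
#' @param config A [scene_config].
#' @param roi An [roi].
#' @param frame_range Frame range for random frame assignment.
#' @return A list with elements:
#'   * `localizations`: localization tibble with extra ground-truth columns
#'     `cluster` (0 for background) and `emitter` (true emitter id);
#'   * `centers`: tibble of true cluster centres (`cluster`, `x`, `y`);
#'   * `config`, `roi`.
#' @export
gen_clustered_scene <- function(config, roi = default_roi(),
                                frame_range = c(1L, 2000L)) {
  stopifnot(inherits(config, "scene_config"))
  r <- as_roi(roi)
  with_seed(config$seed, {
    kc <- config$n_clusters
    centers <- tibble::tibble(
      cluster = seq_len(kc),
      x = stats::runif(kc, r["x_min"], r["x_max"]),
      y = stats::runif(kc, r["y_min"], r["y_max"])
    )
    em_x <- numeric(0); em_y <- numeric(0); em_cl <- integer(0)
    for (i in seq_len(kc)) {
      mm <- .sample_members(config$locs_per_cluster, centers$x[i], centers$y[i],
                            config$cluster_radius_sd, r)
      em_x <- c(em_x, mm[, 1]); em_y <- c(em_y, mm[, 2])
      em_cl <- c(em_cl, rep(i, nrow(mm)))
    }
    nb <- config$background_locs
    em_x <- c(em_x, stats::runif(nb, r["x_min"], r["x_max"]))
    em_y <- c(em_y, stats::runif(nb, r["y_min"], r["y_max"]))
    em_cl <- c(em_cl, rep(0L, nb))
    n_em <- length(em_x)
    # blinking: every emitter yields 1 + Poisson(mean - 1) localizations
    reps <- 1L + stats::rpois(n_em, config$mean_blink_repeats - 1)
    idx <- rep(seq_len(n_em), reps)
    n_loc <- length(idx)
    sdp <- config$localization_precision_sd
    locs <- new_localizations(
      frame = sample.int(frame_range[2] - frame_range[1] + 1L, n_loc,
                         replace = TRUE) + frame_range[1] - 1L,
      x = em_x[idx] + stats::rnorm(n_loc, 0, sdp),
      y = em_y[idx] + stats::rnorm(n_loc, 0, sdp),
      uncertainty = rep(sdp, n_loc),
      intensity = stats::rlnorm(n_loc, log(1000), 0.4)
    )
    locs$cluster <- em_cl[idx]
    locs$emitter <- idx
    list(localizations = locs, centers = centers, config = config, roi = r)
  })
}

#' Generate coupled two-channel localization patterns
#'
#' Emulates dual-colour PALM/dSTORM input. A fraction `coloc_fraction` of the
#' channel-B cluster centres is copied from channel-A centres (shared
#' domains); the remaining B clusters, and all member/background draws, are
#' independent.
#'
#' @param config_a,config_b [scene_config]s for the two channels.
#' @param coloc_fraction Fraction of B clusters sharing centres with A
#'   clusters, in `[0, 1]`.
#' @param roi An [roi].
#' @param seed Integer seed; fully determines both channels.
#' @return List with `channel_a` and `channel_b` (each as returned by
#'   [gen_clustered_scene]) and `shared_clusters` (B-cluster ids whose
#'   centres are shared).
#' @export
gen_paired_channels <- function(config_a, config_b, coloc_fraction, roi = default_roi(),
                                seed = NULL) {
  stopifnot(inherits(config_a, "scene_config"), inherits(config_b, "scene_config"))
  coloc_fraction <- check_scalar(coloc_fraction, "coloc_fraction", min = 0, max = 1)
  r <- as_roi(roi)
  with_seed(seed, {
    cfg_a <- config_a; cfg_a$seed <- NULL
    cfg_b <- config_b; cfg_b$seed <- NULL
    a <- gen_clustered_scene(cfg_a, r)
    b <- gen_clustered_scene(cfg_b, r)
    n_shared <- round(coloc_fraction * cfg_b$n_clusters)
    shared <- integer(0)
    if (n_shared > 0 && cfg_a$n_clusters > 0) {
      shared <- seq_len(min(n_shared, cfg_b$n_clusters))
      src <- rep_len(sample.int(cfg_a$n_clusters), length(shared))
      # rebuild the shared B clusters about the A centres
      for (j in seq_along(shared)) {
        cl <- shared[j]
        b$centers$x[cl] <- a$centers$x[src[j]]
        b$centers$y[cl] <- a$centers$y[src[j]]
        sel <- which(b$localizations$cluster == cl)
        if (length(sel)) {
          mm <- .sample_members(length(sel), b$centers$x[cl], b$centers$y[cl],
                                cfg_b$cluster_radius_sd, r)
          sdp <- cfg_b$localization_precision_sd
          b$localizations$x[sel] <- mm[, 1] + stats::rnorm(length(sel), 0, sdp)
          b$localizations$y[sel] <- mm[, 2] + stats::rnorm(length(sel), 0, sdp)
        }
      }
    }
    list(channel_a = a, channel_b = b, shared_clusters = shared)
  })
}

#' Randomly shift localizations (pseudo-localization control)
#'
#' Translates every localization by an independent random direction
#' (uniform on the circle) and random distance (uniform on
#' `[0, max_shift]`), wrapping the result toroidally into the ROI so the
#' localization count and overall density are preserved. This produces the
#' pseudo-localization coordinates used as the randomized null for the
#' degree-of-colocalization statistic.
#'
#' @param table Localization table.
#' @param max_shift Maximum shift distance, nm (default 1000 = 2 R_max).
#' @param roi An [roi] into which shifted coordinates are wrapped.
#' @param seed Integer seed or `NULL`.
#' @return Localization table of identical size.
#' @export
random_shift <- function(table, max_shift = 1000, roi = default_roi(), seed = NULL) {
  max_shift <- check_scalar(max_shift, "max_shift", min = 0, strict_min = TRUE)
  r <- as_roi(roi)
  n <- nrow(table)
  if (n == 0) return(table)
  with_seed(seed, {
    ang <- stats::runif(n, 0, 2 * pi)
    d <- stats::runif(n, 0, max_shift)
    wx <- r["x_max"] - r["x_min"]; wy <- r["y_max"] - r["y_min"]
    out <- table
    out$x <- r[["x_min"]] + (table$x + d * cos(ang) - r[["x_min"]]) %% wx
    out$y <- r[["y_min"]] + (table$y + d * sin(ang) - r[["y_min"]]) %% wy
    out
  })
}
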