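test_that("MSD handles the closed-form base cases", {
  still <- matrix(rep(c(10, 20), each = 8), ncol = 2)
  cv <- msd(still, 0.004)
  expect_true(all(cv$msd == 0))

  two <- matrix(c(0, 300, 0, 400), ncol = 2)  # displacement 500 nm
  cv2 <- msd(two, 0.004)
  expect_equal(nrow(cv2), 1L)
  expect_equal(cv2$msd, 500^2 / 1e6)
  expect_equal(cv2$n_segments, 1L)
})

test_that("MSD equals the brute-force double-loop oracle on random trajectories", {
  for (s in 1:20) {
    withr::with_seed(s, {
      N <- sample(5:30, 1)
      x <- cumsum(stats::rnorm(N, 0, 80))
      y <- cumsum(stats::rnorm(N, 0, 80))
    })
    cv <- msd(cbind(x, y), 0.004)
    expect_equal(cv$msd, brute_msd(x, y, 0.004), tolerance = 1e-12)
  }
})

test_that("MSD rejects gapped trajectories", {
  tr <- tibble::tibble(frame = c(1L, 2L, 4L), x = c(0, 1, 2), y = c(0, 0, 0))
  expect_error(msd(tr, 0.004), "gap")
})

test_that("an ensemble of identical trajectories reproduces the single curve with zero SE", {
  one <- gen_trajectories(trajectory_model("brownian", D = 1, n_frames = 20,
                                           seed = 1), 1)
  tr <- one$tracks
  trip <- rbind(tr, transform(tr, track_id = "T0002"),
                transform(tr, track_id = "T0003"))
  set <- trajectory_set(trip, 0.004)
  ens <- ensemble_msd(set)
  single <- msd(tr, 0.004)
  expect_equal(ens$msd, single$msd)
  expect_true(all(ens$se == 0))
  expect_error(ensemble_msd(set, min_length = 100), "min_length")
})

test_that("ensemble fits recover the generator diffusion coefficient within 5%", {
  set <- gen_trajectories(trajectory_model("brownian", D = 1,
                                           frame_interval = 0.004,
                                           n_frames = 50, seed = 2), 500)
  f <- fit_deff(ensemble_msd(set), "24ms@4ms")
  expect_lt(abs(f$D_eff - 1), 0.05)

  # with 22-nm localization error the slope is unchanged and the intercept
  # reports 4 sigma^2
  noisy <- gen_trajectories(trajectory_model("brownian", D = 1,
                                             frame_interval = 0.004,
                                             n_frames = 50,
                                             localization_precision_sd = 22,
                                             seed = 3), 500)
  cv <- ensemble_msd(noisy)
  fn <- fit_deff(cv, "24ms@4ms")
  expect_lt(abs(fn$D_eff - 1), 0.05)
  expect_lt(abs(fn$intercept - 4 * 22^2 / 1e6), 3e-3)
  # first ensemble point matches 4 D dt + 4 sigma^2 within 3 SE
  expect_lt(abs(cv$msd[1] - (4 * 1 * 0.004 + 4 * 22^2 / 1e6)), 3 * cv$se[1])
})

test_that("window fits are exact on synthetic lines and invariant to offsets", {
  mk_curve <- function(dt, msd_v) {
    out <- tibble::tibble(lag = seq_along(msd_v), dt = dt * seq_along(msd_v),
                          msd = msd_v, se = 0, n_segments = 100L)
    attr(out, "frame_interval") <- dt
    class(out) <- c("msd_curve", class(out))
    out
  }
  dts <- 0.004 * (1:12)
  exact <- mk_curve(0.004, 4 * 0.9 * dts)
  for (w in c("12ms@4ms", "24ms@4ms"))
    expect_equal(fit_deff(exact, w)$D_eff, 0.9, tolerance = 1e-12)

  offset <- mk_curve(0.004, 4 * 0.9 * dts + 0.02)
  f <- fit_deff(offset, "24ms@4ms")
  expect_equal(f$D_eff, 0.9, tolerance = 1e-12)
  expect_equal(f$intercept, 0.02, tolerance = 1e-12)

  # time rescaling: same msd values on a stretched clock scale D by 1/s
  slow <- mk_curve(0.008, 4 * 0.9 * dts)
  expect_equal(fit_deff(slow, c(16, 24, 32) * 1e-3)$D_eff, 0.45,
               tolerance = 1e-12)

  dec <- mk_curve(0.004, 0.05 - 0.001 * (1:12))
  fneg <- fit_deff(dec, "12ms@4ms")
  expect_true(fneg$non_diffusive)
  expect_equal(fneg$D_eff, 0)

  expect_error(fit_deff(mk_curve(0.004, dts[1:2]), "12ms@4ms"), "not on the MSD curve")
  expect_error(fit_deff(exact, "7ms@oops"), "unknown window")
})

test_that("motion classification separates Brownian, confined and directed sets", {
  cal <- brownian_calibration(50, 0.004, n_sim = 1000, seed = 7)
  classify_set <- function(set)
    vapply(track_split(set), classify_motion, "", calibration = cal)

  br <- gen_trajectories(trajectory_model("brownian", D = 1,
                                          frame_interval = 0.004,
                                          n_frames = 50, seed = 8), 200)
  frac_simple <- mean(classify_set(br) == "simple-brownian")
  se <- sqrt(0.95 * 0.05 / 200)
  expect_lt(abs(frac_simple - 0.95), 3 * se)

  cf <- gen_trajectories(trajectory_model("confined", D = 1,
                                          frame_interval = 0.004, n_frames = 50,
                                          confinement_radius = 50, seed = 9), 100)
  expect_gt(mean(classify_set(cf) == "suppressed"), 0.5)

  dr <- gen_trajectories(trajectory_model("brownian", D = 1,
                                          frame_interval = 0.004,
                                          n_frames = 50, seed = 10), 100)
  dr$tracks$x <- dr$tracks$x + (dr$tracks$frame - 1) * 200  # strong drift
  expect_gt(mean(classify_set(dr) == "directed"), 0.5)

  short <- gen_trajectories(trajectory_model("brownian", D = 1, n_frames = 20,
                                             seed = 11), 1)
  expect_error(classify_motion(track_split(short)[[1]], cal), "shorter")
})
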