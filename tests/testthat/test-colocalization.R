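test_that("DoC parameters are validated and carry the documented defaults", {
  p <- doc_params()
  expect_equal(p$r_max, 500)
  expect_equal(p$dr, 50)
  expect_equal(p$min_total_localizations, 100L)  # (r_max / dr) * 10
  expect_equal(p$radii, seq(50, 500, 50))
  expect_error(doc_params(r_max = 480, dr = 50), "multiple")
})

test_that("the clipped-disk area primitive agrees with a Monte Carlo oracle", {
  rect <- roi(0, 0, 2000, 2000)
  cases <- list(c(1000, 1000, 400), c(100, 100, 500), c(1990, 1000, 300),
                c(10, 1990, 450), c(-100, 500, 400))
  for (cs in cases) {
    an <- smlmdomains:::disk_rect_area(cs[1], cs[2], cs[3], rect)
    mc <- mc_disk_rect_area(cs[1], cs[2], cs[3], rect, n = 4e5,
                            seed = round(sum(cs)))
    expect_lt(abs(an - mc), 4 * sqrt(mc * (roi_area(rect) - mc) / 4e5) + 1e-6)
  }
  # interior disks reduce to pi r^2
  expect_equal(smlmdomains:::disk_rect_area(1000, 1000, 400, rect),
               pi * 400^2, tolerance = 1e-12)
})

test_that("density gradients are normalized to 1 at r_max and flat on uniform input", {
  r <- roi(0, 0, 6000, 6000)
  A <- gen_csr(4000, r, seed = 1)
  B <- gen_csr(4000, r, seed = 2)
  g <- density_gradients(A, B, focal = 1:400, roi = r)
  ok <- !g$undefined
  expect_true(any(ok))
  nb <- length(g$radii)
  expect_true(all(g$d_self[ok, nb] == 1))
  expect_true(all(g$d_other[ok, nb] == 1))
  expect_true(all(g$d_self[ok, ] >= 0))
  # uniform expectation: binwise mean D(r) = 1 within 3 SE
  for (j in seq_len(nb - 1)) {
    v <- g$d_other[ok, j]
    expect_lt(abs(mean(v) - 1), 3 * stats::sd(v) / sqrt(length(v)))
  }
})

test_that("a focal point with no other-channel neighbours is excluded as undefined", {
  r <- roi(0, 0, 4000, 4000)
  A <- loc_table(x = c(500, 520, 480, 510, 530), y = c(500, 510, 490, 530, 470))
  B <- loc_table(x = 3500, y = 3500)  # farther than r_max from all of A
  res <- doc_scores(A, B, doc_params(min_total_localizations = 1), roi = r)
  a_rows <- res$scores[res$scores$channel == "A", ]
  expect_true(all(!a_rows$scored))
  expect_true(all(a_rows$reason == "undefined_gradient"))
})

test_that("an identical copy of a channel scores +1 exactly everywhere it is scored", {
  r <- roi(0, 0, 2000, 2000)
  A <- gen_csr(500, r, seed = 11)
  res <- doc_scores(A, A, doc_params(), roi = r)
  sc <- res$scores
  expect_gt(sum(sc$scored), 50)
  expect_true(all(sc$E[sc$scored] == 0))
  expect_true(all(sc$S[sc$scored] == 1))
  expect_true(all(sc$C[sc$scored] == 1))
  idx <- coloc_index(res)
  expect_equal(idx$index[idx$channel == "pooled"], 1)
})

test_that("the both-channels-below-minimum exclusion rule is enforced at the boundary", {
  r <- roi(0, 0, 10000, 10000)
  ring <- function(n, cx, cy, radii_nm, seed) {
    withr::with_seed(seed, {
      ang <- stats::runif(n, 0, 2 * pi)
      rr <- sample(radii_nm, n, replace = TRUE) + stats::runif(n, -20, 20)
      loc_table(cx + rr * cos(ang), cy + rr * sin(ang))
    })
  }
  focal <- loc_table(5000, 5000)
  # own channel: focal + 99 points within r_max (self excluded from counts)
  own <- rbind(focal, ring(99, 5000, 5000, c(150, 250, 350, 450), seed = 1))
  other_low <- ring(99, 5000, 5000, c(100, 200, 300, 400), seed = 2)
  other_high <- ring(150, 5000, 5000, c(100, 200, 300, 400), seed = 3)

  res_low <- doc_scores(own, other_low, doc_params(), roi = r)
  row1 <- res_low$scores[res_low$scores$channel == "A" & res_low$scores$index == 1, ]
  expect_equal(row1$n_self, 99)
  expect_equal(row1$n_other, 99)
  expect_false(row1$scored)
  expect_equal(row1$reason, "low_counts")

  res_high <- doc_scores(own, other_high, doc_params(), roi = r)
  row1 <- res_high$scores[res_high$scores$channel == "A" & res_high$scores$index == 1, ]
  expect_equal(row1$n_self, 99)
  expect_equal(row1$n_other, 150)
  expect_true(row1$scored)
})

test_that("DoC scores are symmetric in the channel arguments and bounded", {
  r <- roi(0, 0, 5000, 5000)
  A <- gen_csr(2500, r, seed = 21)
  B <- gen_csr(2500, r, seed = 22)
  p <- doc_params(min_total_localizations = 30)
  ab <- doc_scores(A, B, p, roi = r)
  ba <- doc_scores(B, A, p, roi = r)
  a_in_ab <- ab$scores[ab$scores$channel == "A", ]
  a_in_ba <- ba$scores[ba$scores$channel == "B", ]
  expect_equal(a_in_ab$C, a_in_ba$C)
  expect_equal(a_in_ab$scored, a_in_ba$scored)
  sc <- ab$scores
  expect_true(all(sc$S[sc$scored] >= -1 & sc$S[sc$scored] <= 1))
  expect_true(all(sc$C[sc$scored] >= -1 & sc$C[sc$scored] <= 1))
  expect_true(all(sc$E >= 0))
  expect_true(all(is.na(sc$C[!sc$scored])))
})

test_that("coupled clustered channels beat their randomized-shift control", {
  cfg <- scene_config(n_clusters = 15, cluster_radius_sd = 40,
                      locs_per_cluster = 40, background_locs = 300,
                      localization_precision_sd = 15)
  # the scene's r_max-disk counts peak near 80 inside domains; the
  # minimum-count rule is set below that so domain localizations are scored
  p <- doc_params(min_total_localizations = 30)
  wins <- 0L
  for (s in 1:5) {
    pair <- gen_paired_channels(cfg, cfg, coloc_fraction = 1, seed = s)
    A <- pair$channel_a$localizations
    B <- pair$channel_b$localizations
    orig <- coloc_index(doc_scores(A, B, p))
    ctrl <- coloc_index(doc_control(A, B, p, seed = 1000 + s))
    wins <- wins + (orig$index[3] > ctrl$index[3])
  }
  expect_gte(wins, 4L)
})

test_that("the shift control is seed-deterministic and breaks perfect colocalization", {
  r <- roi(0, 0, 2000, 2000)
  A <- gen_csr(500, r, seed = 31)
  c1 <- doc_control(A, A, doc_params(), roi = r, seed = 7)
  c2 <- doc_control(A, A, doc_params(), roi = r, seed = 7)
  expect_equal(c1$scores$C, c2$scores$C)
  expect_equal(c1$control_seed, 7)
  sc <- c1$scores
  expect_false(all(sc$C[sc$scored] == 1))
})

test_that("empty channels and empty score sets raise errors", {
  A <- gen_csr(100, seed = 41)
  expect_error(doc_scores(A, gen_csr(0)), "non-empty")
  res <- doc_scores(A, gen_csr(100, seed = 42), doc_params())  # all low_counts
  expect_error(coloc_index(res), "no scored localizations")
})
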