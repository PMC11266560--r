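test_that("four quadrant-centre points tessellate a square into equal quarters", {
  r <- roi(0, 0, 1000, 1000)
  tab <- loc_table(x = c(250, 750, 250, 750), y = c(250, 250, 750, 750))
  vm <- voronoi_densities(tab, r)
  expect_equal(vm$area, rep(250000, 4))
  expect_equal(vm$density, rep(1 / 250000, 4))
  # every side-sharing pair is adjacent (the degenerate diagonal of this
  # cocircular configuration may appear as a zero-length edge)
  pairs <- paste(vm$adjacency[, 1], vm$adjacency[, 2])
  expect_true(all(c("1 2", "1 3", "2 4", "3 4") %in% pairs))
})

test_that("clipped cell areas always sum to the roi area", {
  r <- roi(0, 0, 5000, 4000)
  for (s in 1:3) {
    vm <- voronoi_densities(gen_csr(700, r, seed = s), r)
    expect_lt(abs(sum(vm$area) - roi_area(r)) / roi_area(r), 1e-6)
    # area-weighted mean density equals the pattern intensity n / |roi|
    expect_equal(sum(vm$area * vm$density) / roi_area(r), vm$n / roi_area(r),
                 tolerance = 1e-9)
    # adjacency is a simple graph over valid cell indices
    expect_true(all(vm$adjacency >= 1 & vm$adjacency <= vm$n))
    expect_true(all(vm$adjacency[, 1] < vm$adjacency[, 2]))
  }
})

test_that("degenerate geometries are rejected", {
  r <- roi(0, 0, 1000, 1000)
  expect_error(voronoi_densities(loc_table(c(1, 2), c(1, 2)), r), "at least 3")
  expect_error(voronoi_densities(loc_table(c(100, 200, 300), c(100, 200, 300)), r),
               "collinear")
  expect_error(voronoi_densities(loc_table(c(100, 100, 300), c(100, 100, 300)), r),
               "coincident")
})

test_that("the Monte Carlo threshold is seed-deterministic and rarely fires on CSR", {
  locs <- gen_csr(600, seed = 10)
  t1 <- csr_threshold(locs, n_simulations = 10, seed = 99)
  t2 <- csr_threshold(locs, n_simulations = 10, seed = 99)
  expect_equal(as.numeric(t1), as.numeric(t2))

  # false-positive rate: fraction of CSR localizations called clustered,
  # averaged over seeds
  fr <- vapply(1:20, function(s) {
    tab <- gen_csr(600, seed = s)
    thr <- csr_threshold(tab, n_simulations = 20, seed = 1000 + s)
    vm <- voronoi_densities(tab)
    mean(vm$density >= as.numeric(thr))
  }, 0)
  expect_lte(mean(fr), 0.1)
})

test_that("a strongly clustered scene is separated from its background", {
  sc <- gen_clustered_scene(scene_config(n_clusters = 20, cluster_radius_sd = 20,
                                         locs_per_cluster = 100,
                                         background_locs = 500,
                                         localization_precision_sd = 0, seed = 1))
  locs <- sc$localizations
  thr <- csr_threshold(locs, n_simulations = 15, seed = 201)
  expect_false(attr(thr, "no_clusters"))
  vm <- voronoi_densities(locs)
  truth <- locs$cluster[vm$kept] > 0
  above <- vm$density >= as.numeric(thr)
  expect_gte(mean(above[truth]), 0.9)       # members above threshold
  expect_gte(mean(!above[!truth]), 0.9)     # background below threshold

  cl <- segment_clusters(vm, thr)
  expect_true(abs(nrow(cl) - 20) <= 2)
  memb <- attr(cl, "membership")
  expect_gte(sum(memb > 0 & truth) / sum(truth), 0.9)
})

test_that("components of five or fewer localizations are eliminated", {
  r <- roi(0, 0, 10000, 10000)
  # compact grid blobs whose cells are bounded by a guard octagon, so blob
  # cells are small (dense) while guard and sparse cells are large
  blob6 <- cbind(2000 + c(0, 10, 20, 0, 10, 20), 2000 + c(0, 0, 0, 10, 10, 10))
  blob5 <- cbind(8000 + c(0, 10, -10, 0, 0), 8000 + c(0, 0, 0, 10, -10))
  guard <- function(cx, cy) {
    ang <- 2 * pi * (1:8) / 8
    cbind(cx + 100 * cos(ang), cy + 100 * sin(ang))
  }
  sparse <- cbind(seq(500, 9500, length.out = 20),
                  rev(seq(700, 9100, length.out = 20)) + 13 * seq_len(20))
  pts <- rbind(blob6, blob5, guard(2010, 2005), guard(8000, 8000), sparse)
  # break the exact symmetry, which degenerates the tessellation
  pts <- pts + withr::with_seed(1, matrix(stats::runif(length(pts), -0.4, 0.4),
                                          ncol = 2))
  tab <- loc_table(pts[, 1], pts[, 2])
  vm <- voronoi_densities(tab, r)
  cl <- segment_clusters(vm, threshold = 1 / 2e4)  # blobs only are this dense
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_localizations, 6L)
  expect_equal(sum(attr(cl, "membership") > 0), 6L)

  empty <- segment_clusters(vm, threshold = Inf)
  expect_equal(nrow(empty), 0L)
  expect_true(all(attr(empty, "membership") == 0L))
})

test_that("raising the threshold never adds clustered localizations", {
  sc <- gen_clustered_scene(scene_config(n_clusters = 8, cluster_radius_sd = 30,
                                         locs_per_cluster = 40,
                                         background_locs = 300,
                                         localization_precision_sd = 10, seed = 2),
                            roi(0, 0, 6000, 6000))
  vm <- voronoi_densities(sc$localizations, roi(0, 0, 6000, 6000))
  thresholds <- stats::quantile(vm$density, c(0.5, 0.7, 0.9, 0.97))
  prev <- NULL
  for (th in thresholds) {
    memb <- attr(segment_clusters(vm, th), "membership")
    members <- which(memb > 0)
    expect_true(all(memb == 0 | vm$density >= th))
    if (!is.null(prev)) expect_true(all(members %in% prev))
    prev <- members
  }
})

test_that("cluster summaries follow the circle convention and median rules", {
  mk <- function(diams) {
    cl <- tibble::tibble(cluster_id = seq_along(diams),
                         n_localizations = rep(10L, length(diams)),
                         area = pi * (diams / 2)^2, diameter = diams)
    attr(cl, "membership") <- integer(0)
    class(cl) <- c("cluster_set", class(cl))
    cl
  }
  one <- cluster_summary(mk(2 * sqrt((pi * 90^2) / pi)))
  expect_equal(one$diameter_median, 180)
  expect_equal(cluster_summary(mk(c(100, 180, 300)))$diameter_median, 180)
  # even count: lower-interpolation convention
  expect_equal(cluster_summary(mk(c(100, 200)))$diameter_median, 100)

  empty <- cluster_summary(mk(numeric(0)))
  expect_equal(empty$n_clusters, 0L)
  expect_false(empty$defined)
  expect_true(is.na(empty$diameter_median))
})
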