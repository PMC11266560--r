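# Voronoi-tessellation segmentation of localization maps into nanodomains,
# with a Monte Carlo threshold against complete spatial randomness.

#' Voronoi tessellation densities of a localization map
#'
#' Tessellates the localizations inside the ROI; border cells are clipped to
#' the ROI rectangle (rather than discarded, so domains touching the field
#' edge are not lost). The local density of each localization is the
#' first-rank estimate 1/area of its clipped cell. Cell adjacency (shared
#' Voronoi edges, after clipping) is returned for connected-component
#' segmentation.
#'
#' @param table Localization table (columns `x`, `y`, nm).
#' @param roi An [roi]; localizations outside it are dropped (with a note in
#'   the returned object).
#' @return An object of class `"voronoi_map"`: list with `x`, `y`, `area`
#'   (nm^2), `density` (nm^-2), `adjacency` (2-column index matrix), `roi`,
#'   `n`, `kept` (row indices of the input table that fell inside the ROI),
#'   `n_dropped` and `tiles` (clipped cell polygons from
#'   [deldir::tile.list]).
#' @export
voronoi_densities <- function(table, roi = default_roi()) {
  r <- as_roi(roi)
  inside <- in_roi(table$x, table$y, r)
  x <- table$x[inside]; y <- table$y[inside]
  if (length(x) < 3)
    stop("voronoi_densities needs at least 3 localizations inside the roi",
         call. = FALSE)
  if (anyDuplicated(cbind(x, y)))
    stop("exactly coincident localizations cannot be tessellated; ",
         "run remove_duplicates() first", call. = FALSE)
  # collinearity check: zero area spanned
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2)
    stop("all localizations are collinear; tessellation is degenerate",
         call. = FALSE)
  dd <- deldir::deldir(x, y, rw = c(r["x_min"], r["x_max"], r["y_min"], r["y_max"]))
  area <- dd$summary$dir.area
  adj <- unique(cbind(pmin(dd$dirsgs$ind1, dd$dirsgs$ind2),
                      pmax(dd$dirsgs$ind1, dd$dirsgs$ind2)))
  structure(list(x = x, y = y, area = area, density = 1 / area,
                 adjacency = adj, roi = r, n = length(x),
                 kept = which(inside), n_dropped = sum(!inside),
                 tiles = deldir::tile.list(dd)),
            class = "voronoi_map")
}

#' @export
print.voronoi_map <- function(x, ...) {
  cat(sprintf("<voronoi_map> %d cells over %g nm^2 (mean density %.3g nm^-2)\n",
              x$n, roi_area(x$roi), mean(x$density)))
  invisible(x)
}

#' Monte Carlo density threshold against complete spatial randomness
#'
#' Determines the local density above which localizations are considered
#' clustered, by comparing the histogram of the observed Voronoi-cell areas
#' with the histograms of `n_simulations` CSR patterns of identical count
#' and ROI (clustering shows up as an excess of small cells). Scanning from
#' the CSR modal area towards smaller areas, the intersection is taken at
#' the largest-area bin in which the observed count exceeds both the mean
#' CSR count and its upper Monte Carlo envelope (the `envelope_prob`
#' quantile across simulations); the returned density threshold is the
#' reciprocal of that bin's upper area edge. Requiring the intersection to
#' lie outside the CSR noise band means a pattern that is itself random
#' rarely yields a finite threshold.
#'
#' @param table Localization table.
#' @param roi An [roi].
#' @param n_simulations Number of CSR simulations (default 100).
#' @param seed Integer seed or `NULL`.
#' @param n_bins Number of histogram bins over the shared cell-area range.
#' @param envelope_prob Quantile of the per-bin CSR counts used as the
#'   noise envelope.
#' @return Density threshold in nm^-2 (scalar). `+Inf`, with attribute
#'   `no_clusters = TRUE`, when the observed histogram never exceeds the
#'   CSR envelope below the modal area (no detectable clustering).
#'   Attributes `breaks` (areas, nm^2), `observed`, `csr_mean` carry the
#'   histograms.
#' @export
csr_threshold <- function(table, roi = default_roi(), n_simulations = 100,
                          seed = NULL, n_bins = 50, envelope_prob = 0.99) {
  n_simulations <- check_count(n_simulations, "n_simulations", min = 1)
  r <- as_roi(roi)
  vm <- voronoi_densities(table, r)
  with_seed(seed, {
    sims <- vector("list", n_simulations)
    for (s in seq_len(n_simulations)) {
      cs <- gen_csr(vm$n, r)
      sims[[s]] <- voronoi_densities(cs, r)$area
    }
    amax <- max(vm$area, vapply(sims, max, 0))
    breaks <- seq(0, amax, length.out = n_bins + 1)
    obs <- graphics::hist(vm$area, breaks = breaks, plot = FALSE)$counts
    simc <- t(vapply(sims, function(a)
      graphics::hist(pmin(a, amax), breaks = breaks, plot = FALSE)$counts,
      numeric(n_bins)))
    csr_mean <- colMeans(simc)
    env <- apply(simc, 2, stats::quantile, probs = envelope_prob, names = FALSE)
    mode_bin <- which.max(csr_mean)
    cand <- which(seq_len(n_bins) < mode_bin & obs > env & obs > csr_mean)
    if (!length(cand)) {
      thr <- structure(Inf, no_clusters = TRUE)
    } else {
      thr <- structure(1 / breaks[max(cand) + 1], no_clusters = FALSE)
    }
    attr(thr, "breaks") <- breaks
    attr(thr, "observed") <- obs
    attr(thr, "csr_mean") <- csr_mean
    thr
  })
}

#' Segment a Voronoi map into clusters
#'
#' Clusters are connected components (over shared Voronoi edges) of
#' localizations whose local density is at least `threshold`. Components
#' containing five localizations or fewer are eliminated. The cluster area
#' is the union (= sum) of its member cell areas; the equivalent diameter
#' treats the domain as a circle: `2 sqrt(area / pi)`.
#'
#' @param vmap A [voronoi_densities] map.
#' @param threshold Density threshold, nm^-2 (> 0; may be `+Inf`).
#' @param min_localizations Minimum retained component size (default 6, i.e.
#'   components with <= 5 localizations are eliminated).
#' @return A `cluster_set`: tibble with one row per cluster (`cluster_id`,
#'   `n_localizations`, `area` nm^2, `diameter` nm) and attribute
#'   `membership`, an integer vector over the map's localizations (0 =
#'   unclustered).
#' @export
segment_clusters <- function(vmap, threshold, min_localizations = 6) {
  stopifnot(inherits(vmap, "voronoi_map"))
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0)
    stop("threshold must be a single positive density", call. = FALSE)
  sel <- which(vmap$density >= threshold)
  membership <- integer(vmap$n)
  rows <- list()
  if (length(sel)) {
    insel <- logical(vmap$n); insel[sel] <- TRUE
    keep_e <- insel[vmap$adjacency[, 1]] & insel[vmap$adjacency[, 2]]
    edges <- vmap$adjacency[keep_e, , drop = FALSE]
    g <- igraph::make_empty_graph(n = 0, directed = FALSE) +
      igraph::vertices(as.character(sel))
    if (nrow(edges))
      g <- igraph::add_edges(g, as.character(t(edges)))
    comp <- igraph::components(g)
    vid <- as.integer(igraph::V(g)$name)
    cl_id <- 0L
    for (c_ in seq_len(comp$no)) {
      members <- vid[comp$membership == c_]
      if (length(members) < min_localizations) next
      cl_id <- cl_id + 1L
      membership[members] <- cl_id
      a <- sum(vmap$area[members])
      rows[[cl_id]] <- tibble::tibble(cluster_id = cl_id,
                                      n_localizations = length(members),
                                      area = a, diameter = 2 * sqrt(a / pi))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(cluster_id = integer(), n_localizations = integer(),
                   area = numeric(), diameter = numeric())
  attr(out, "membership") <- membership
  attr(out, "threshold") <- as.numeric(threshold)
  class(out) <- c("cluster_set", class(out))
  out
}

#' Summary statistics of a cluster set
#'
#' The median of the equivalent domain diameters is the domain-size
#' statistic; for an even number of clusters the lower of the two central
#' order statistics is taken (lower-interpolation convention). Quartiles use
#' the same type-1 convention.
#'
#' @param clusters A `cluster_set` from [segment_clusters()].
#' @return One-row tibble: `n_clusters`, `diameter_median`, `diameter_q25`,
#'   `diameter_q75` (nm), `area_median`, `area_total` (nm^2) and `defined`
#'   (`FALSE` when the set is empty and the medians are undefined).
#' @export
cluster_summary <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  n <- nrow(clusters)
  if (n == 0) {
    return(tibble::tibble(n_clusters = 0L, diameter_median = NA_real_,
                          diameter_q25 = NA_real_, diameter_q75 = NA_real_,
                          area_median = NA_real_, area_total = 0,
                          defined = FALSE))
  }
  q1 <- function(v, p) stats::quantile(v, p, type = 1, names = FALSE)
  tibble::tibble(
    n_clusters = n,
    diameter_median = q1(clusters$diameter, 0.5),
    diameter_q25 = q1(clusters$diameter, 0.25),
    diameter_q75 = q1(clusters$diameter, 0.75),
    area_median = q1(clusters$area, 0.5),
    area_total = sum(clusters$area),
    defined = TRUE
  )
}
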