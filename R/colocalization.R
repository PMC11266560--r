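# Degree-of-colocalization (DoC) statistic for dual-colour localization
# maps: radial density gradients around each localization, Spearman rank
# correlation between the own- and other-channel gradients, and a
# nearest-neighbour exponential weight.

#' DoC analysis parameters
#'
#' @param r_max Largest analysis radius, nm (default 500). Must be a
#'   positive multiple of `dr`.
#' @param dr Radial bin width, nm (default 50).
#' @param min_total_localizations Minimum number of localizations inside the
#'   `r_max` disk for a focal point to be scored: a point is excluded when
#'   *both* channels fall below this count. Default `(r_max / dr) * 10`.
#' @param index_range DoC score range counted by the colocalization index
#'   (default `[0.7, 1]`).
#' @param edge_correction Correct radial counts for truncation of the
#'   counting disk by the ROI boundary (exact circle-rectangle areas).
#'   With the correction, a uniform pattern has expected gradient
#'   `D(r) = 1` at every radius, including near the field edge.
#' @return A list of class `"doc_params"`.
#' @export
doc_params <- function(r_max = 500, dr = 50, min_total_localizations = NULL,
                       index_range = c(0.7, 1), edge_correction = TRUE) {
  r_max <- check_scalar(r_max, "r_max", min = 0, strict_min = TRUE)
  dr <- check_scalar(dr, "dr", min = 0, strict_min = TRUE)
  k <- r_max / dr
  if (abs(k - round(k)) > 1e-9)
    stop("r_max must be a positive multiple of dr", call. = FALSE)
  if (is.null(min_total_localizations)) min_total_localizations <- round(k) * 10
  structure(list(
    r_max = r_max, dr = dr,
    min_total_localizations = check_count(min_total_localizations,
                                          "min_total_localizations"),
    index_range = index_range,
    edge_correction = isTRUE(edge_correction),
    radii = seq(dr, r_max, by = dr)
  ), class = "doc_params")
}

# counts of `pts` within each radius of each focal point, with localizations
# at zero distance from the focal point excluded (the focal point itself in
# its own channel; an exactly coincident localization otherwise, which
# carries no gradient-shape information). Also returns the nearest-neighbour
# distance *including* zero distances.
.radial_counts <- function(focal_xy, pts_xy, radii) {
  nq <- nrow(focal_xy); np <- nrow(pts_xy)
  r_max <- max(radii)
  if (np == 0)
    return(list(counts = matrix(0L, nq, length(radii)), nnd = rep(Inf, nq)))
  k <- min(np, 256L)
  repeat {
    nn <- RANN::nn2(pts_xy, query = focal_xy, k = k,
                    searchtype = "radius", radius = r_max * (1 + 1e-12))
    within <- nn$nn.idx > 0
    if (max(rowSums(within)) < k || k == np) break
    k <- min(np, k * 2L)
  }
  d <- nn$nn.dists
  d[!within] <- Inf
  counts <- vapply(radii, function(r) rowSums(d <= r), numeric(nq))
  counts <- matrix(counts, nrow = nq)
  nzero <- rowSums(d < 1e-9)
  counts <- counts - nzero
  nnd <- RANN::nn2(pts_xy, query = focal_xy, k = 1)$nn.dists[, 1]
  list(counts = counts, nnd = nnd)
}

# normalized, area-corrected density gradients; counts: nq x nbins matrix
.gradient <- function(counts, focal_xy, radii, roi, edge_correction) {
  nb <- length(radii)
  n_rmax <- counts[, nb]
  if (edge_correction) {
    areas <- vapply(radii, function(r)
      disk_rect_area(focal_xy[, 1], focal_xy[, 2], r, roi), numeric(nrow(focal_xy)))
    areas <- matrix(areas, nrow = nrow(focal_xy))
    ratio <- areas[, nb] / areas
  } else {
    ratio <- matrix(rep(max(radii)^2 / radii^2, each = nrow(counts)),
                    nrow = nrow(counts))
  }
  counts / n_rmax * ratio
}

#' Radial density gradients around focal localizations
#'
#' For each focal localization `Ai` of channel A, counts the localizations
#' of channel A and of channel B within closed disks of radius
#' `dr, 2 dr, ..., r_max`, and normalizes to the density gradient
#' `D(r) = [N(r) / N(r_max)] * [r_max^2 / r^2]` (with the disk areas
#' replaced by exact clipped areas near the ROI edge when
#' `edge_correction` is on). A uniform pattern has expected `D(r) = 1` at
#' every radius, and `D(r_max) = 1` holds exactly whenever
#' `N(r_max) > 0`.
#'
#' @param A,B Localization tables sharing one coordinate frame.
#' @param focal Integer indices into `A` of the focal localizations
#'   (default: all).
#' @param params A [doc_params].
#' @param roi An [roi]; defaults to the joint bounding box of both channels.
#' @return A list of class `"radial_density_gradient"`: `radii`, count
#'   matrices `n_self`, `n_other`, gradient matrices `d_self`, `d_other`
#'   (rows = focal points), and `undefined` (logical; `TRUE` when either
#'   channel has no localization within `r_max`, in which case the gradient
#'   rows are `NA`).
#' @export
density_gradients <- function(A, B, focal = seq_len(nrow(A)),
                              params = doc_params(), roi = NULL) {
  stopifnot(inherits(params, "doc_params"))
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("both channels must be non-empty", call. = FALSE)
  if (any(focal < 1 | focal > nrow(A)))
    stop("focal indices out of range", call. = FALSE)
  r <- if (is.null(roi)) {
    roi(min(A$x, B$x), min(A$y, B$y), max(A$x, B$x), max(A$y, B$y))
  } else as_roi(roi)
  fxy <- cbind(A$x[focal], A$y[focal])
  cs <- .radial_counts(fxy, cbind(A$x, A$y), params$radii)
  co <- .radial_counts(fxy, cbind(B$x, B$y), params$radii)
  nb <- length(params$radii)
  undefined <- cs$counts[, nb] == 0 | co$counts[, nb] == 0
  d_self <- .gradient(cs$counts, fxy, params$radii, r, params$edge_correction)
  d_other <- .gradient(co$counts, fxy, params$radii, r, params$edge_correction)
  d_self[undefined, ] <- NA_real_
  d_other[undefined, ] <- NA_real_
  structure(list(radii = params$radii, focal = focal,
                 n_self = cs$counts, n_other = co$counts,
                 d_self = d_self, d_other = d_other,
                 nn_dist = co$nnd, undefined = undefined,
                 params = params, roi = r),
            class = "radial_density_gradient")
}

# Spearman rank correlation between the rows of two matrices (average ranks
# for ties); NA where either row has zero rank variance.
.row_spearman <- function(da, db) {
  n <- nrow(da)
  s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ra <- rank(da[i, ]); rb <- rank(db[i, ])
    va <- stats::var(ra); vb <- stats::var(rb)
    if (va > 0 && vb > 0)
      s[i] <- stats::cov(ra, rb) / sqrt(va * vb)
  }
  s
}

.score_one_channel <- function(F_tab, S_tab, O_tab, params, r) {
  fxy <- cbind(F_tab$x, F_tab$y)
  cs <- .radial_counts(fxy, cbind(S_tab$x, S_tab$y), params$radii)
  co <- .radial_counts(fxy, cbind(O_tab$x, O_tab$y), params$radii)
  d_self <- .gradient(cs$counts, fxy, params$radii, r, params$edge_correction)
  d_other <- .gradient(co$counts, fxy, params$radii, r, params$edge_correction)
  nb <- length(params$radii)
  n_self <- cs$counts[, nb]
  n_other <- co$counts[, nb]
  undefined <- n_self == 0 | n_other == 0
  low <- n_self < params$min_total_localizations &
    n_other < params$min_total_localizations
  S <- rep(NA_real_, nrow(F_tab))
  ok <- !undefined & !low
  if (any(ok))
    S[ok] <- .row_spearman(d_self[ok, , drop = FALSE],
                           d_other[ok, , drop = FALSE])
  degenerate <- ok & is.na(S)
  E <- co$nnd
  C <- S * exp(-E / params$r_max)
  reason <- rep(NA_character_, nrow(F_tab))
  reason[low] <- "low_counts"
  reason[undefined] <- "undefined_gradient"
  reason[degenerate] <- "degenerate_gradient"
  tibble::tibble(index = seq_len(nrow(F_tab)), n_self = n_self,
                 n_other = n_other, S = S, E = E, C = C,
                 scored = ok & !degenerate, reason = reason)
}

#' Per-localization degree-of-colocalization scores
#'
#' Computes, for every localization of channel A and symmetrically of
#' channel B, the Spearman rank correlation `S` between its own-channel and
#' other-channel radial density gradients, the distance `E` to the nearest
#' localization of the other channel, and the DoC score
#' `C = S * exp(-E / r_max)`. `C` ranges from -1 (segregated) through 0 (no
#' colocalization) to +1 (totally colocalized). A focal point is excluded
#' (carries no score) when both channels have fewer than
#' `min_total_localizations` within `r_max`, when either channel has none
#' (undefined gradient), or when a gradient vector is constant so its ranks
#' are degenerate.
#'
#' @param A,B Localization tables (non-empty, common coordinate frame).
#' @param params A [doc_params].
#' @param roi An [roi]; defaults to the joint bounding box.
#' @return An object of class `"doc_result"`: list with `scores` (tibble
#'   with columns `channel`, `index`, `n_self`, `n_other`, `S`, `E`, `C`,
#'   `scored`, `reason`), `histogram` (per-channel counts of C over bins of
#'   width 0.1 spanning [-1, 1]), `params`, `roi`.
#' @export
doc_scores <- function(A, B, params = doc_params(), roi = NULL) {
  stopifnot(inherits(params, "doc_params"))
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("both channels must be non-empty; the nearest-neighbour distance ",
         "is undefined otherwise", call. = FALSE)
  r <- if (is.null(roi)) {
    roi(min(A$x, B$x), min(A$y, B$y), max(A$x, B$x), max(A$y, B$y))
  } else as_roi(roi)
  sa <- .score_one_channel(A, A, B, params, r)
  sb <- .score_one_channel(B, B, A, params, r)
  scores <- rbind(cbind(tibble::tibble(channel = "A"), sa),
                  cbind(tibble::tibble(channel = "B"), sb))
  breaks <- seq(-1, 1, by = 0.1)
  histo <- lapply(split(scores$C[scores$scored], scores$channel[scores$scored]),
                  function(v) graphics::hist(v, breaks = breaks, plot = FALSE)$counts)
  structure(list(scores = scores, histogram = histo, breaks = breaks,
                 params = params, roi = r),
            class = "doc_result")
}

#' @export
print.doc_result <- function(x, ...) {
  n <- nrow(x$scores); ns <- sum(x$scores$scored)
  cat(sprintf("<doc_result> %d localizations, %d scored (%.1f%%), mean C = %.3f\n",
              n, ns, 100 * ns / n, mean(x$scores$C[x$scores$scored])))
  invisible(x)
}

#' Colocalization index of a DoC result
#'
#' Fraction of scored localizations whose DoC score lies in the
#' high-colocalization range (0.7 to 1 by default), per channel and pooled.
#' The raw count and the summation of the scores in that range are also
#' reported.
#'
#' @param result A [doc_scores] result.
#' @return Tibble with rows `A`, `B`, `pooled`: `n_scored`, `n_high`,
#'   `index` (= n_high / n_scored), `sum_c_high`.
#' @export
coloc_index <- function(result) {
  stopifnot(inherits(result, "doc_result"))
  sc <- result$scores[result$scores$scored, ]
  if (nrow(sc) == 0)
    stop("no scored localizations; colocalization index undefined", call. = FALSE)
  rng <- result$params$index_range
  one <- function(v) {
    hi <- v >= rng[1] & v <= rng[2]
    tibble::tibble(n_scored = length(v), n_high = sum(hi),
                   index = sum(hi) / length(v), sum_c_high = sum(v[hi]))
  }
  out <- rbind(one(sc$C[sc$channel == "A"]), one(sc$C[sc$channel == "B"]),
               one(sc$C))
  cbind(tibble::tibble(channel = c("A", "B", "pooled")), out)
}

#' Randomized-shift DoC control
#'
#' Recomputes the DoC scores after replacing channel B by
#' pseudo-localization coordinates generated by shifting every B
#' localization in a random direction by a random distance
#' (see [random_shift()]). This is the null against which an observed
#' colocalization index is compared.
#'
#' @inheritParams doc_scores
#' @param seed Integer seed for the shift (recorded in the result).
#' @param max_shift Maximum shift distance, nm (default `2 * r_max`).
#' @return A `"doc_result"` with the extra element `control_seed`.
#' @export
doc_control <- function(A, B, params = doc_params(), roi = NULL, seed = NULL,
                        max_shift = NULL) {
  r <- if (is.null(roi)) {
    roi(min(A$x, B$x), min(A$y, B$y), max(A$x, B$x), max(A$y, B$y))
  } else as_roi(roi)
  if (is.null(max_shift)) max_shift <- 2 * params$r_max
  out <- doc_scores(A, random_shift(B, max_shift = max_shift, roi = r, seed = seed),
                    params = params, roi = r)
  out$control_seed <- seed
  out
}
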