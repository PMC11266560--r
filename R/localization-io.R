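# Reading/writing localization tables and the post-processing filters
# applied to them before spatial analysis.

# header mapping between the ThunderSTORM CSV dialect and canonical names
.ts_headers <- c(frame = "frame", x = "x [nm]", y = "y [nm]",
                 uncertainty = "uncertainty [nm]", intensity = "intensity [photon]")

.canonical_name <- function(h) {
  m <- match(h, .ts_headers)
  ifelse(!is.na(m), names(.ts_headers)[m], sub("\\s*\\[.*\\]$", "", h))
}

#' Read a localization table
#'
#' Reads a per-channel localization CSV. Two header dialects are accepted:
#' the ThunderSTORM style (`"x [nm]"`, `"y [nm]"`, `"uncertainty [nm]"`,
#' `"intensity [photon]"`) and bare names (`x`, `y`, ...). Columns `frame`,
#' `x` and `y` are mandatory; unknown columns are preserved unchanged.
#'
#' @param path Path to a CSV file.
#' @param dialect `"auto"` (default), `"thunderstorm"` or `"bare"`. With
#'   `"auto"` the dialect is inferred from the header.
#' @return A localization tibble with canonical column names; coordinates
#'   in nm, frames 1-based integers.
#' @seealso [write_localizations()]
#' @export
read_localizations <- function(path, dialect = c("auto", "thunderstorm", "bare")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- .canonical_name(names(raw))
  if (dialect == "thunderstorm" && !all(c("x [nm]", "y [nm]") %in% names(raw)))
    stop("file does not use the ThunderSTORM header dialect", call. = FALSE)
  names(raw) <- nm
  for (col in c("frame", "x", "y")) {
    if (!col %in% nm)
      stop(sprintf("missing mandatory column '%s' in %s", col, path), call. = FALSE)
  }
  for (col in intersect(c("frame", "x", "y", "uncertainty", "intensity"), nm)) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d of %s",
                   col, bad[1], path), call. = FALSE)
    raw[[col]] <- num
  }
  if (anyNA(raw$x) || anyNA(raw$y) || anyNA(raw$frame))
    stop("NA values in frame/x/y are not allowed", call. = FALSE)
  raw$frame <- as.integer(raw$frame)
  tibble::as_tibble(raw)
}

#' Write a localization table
#'
#' Writes a localization tibble as CSV in either dialect. Coordinates (and
#' the uncertainty column) are written with 0.001 nm resolution so that a
#' write/read round trip reproduces the table exactly at that resolution.
#'
#' @param table Localization table.
#' @param path Output path.
#' @param dialect `"thunderstorm"` (default) or `"bare"`.
#' @export
write_localizations <- function(table, path, dialect = c("thunderstorm", "bare")) {
  dialect <- match.arg(dialect)
  for (col in c("frame", "x", "y")) {
    if (!col %in% names(table))
      stop(sprintf("missing mandatory column '%s'", col), call. = FALSE)
  }
  out <- as.data.frame(table)
  for (col in intersect(c("x", "y", "uncertainty"), names(out)))
    out[[col]] <- sprintf("%.3f", out[[col]])
  if (dialect == "thunderstorm") {
    m <- match(names(out), names(.ts_headers))
    names(out)[!is.na(m)] <- .ts_headers[m[!is.na(m)]]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove duplicate localizations within frames
#'
#' Reproduces the ThunderSTORM-style "remove duplicates" post-processing
#' with the distance threshold set to the localization uncertainty: within
#' each frame, any pair of localizations closer than the larger of their two
#' uncertainties is merged, keeping the higher-intensity record. The
#' operation is idempotent.
#'
#' @param table Localization table; the `uncertainty` column is required.
#' @return The filtered table (original row order preserved).
#' @export
remove_duplicates <- function(table) {
  if (!"uncertainty" %in% names(table) || anyNA(table$uncertainty))
    stop("remove_duplicates requires an uncertainty value for every localization",
         call. = FALSE)
  if (nrow(table) < 2) return(table)
  keep <- logical(nrow(table))
  intensity <- if ("intensity" %in% names(table) && !anyNA(table$intensity))
    table$intensity else rep(0, nrow(table))
  for (idx in split(seq_len(nrow(table)), table$frame)) {
    ord <- idx[order(-intensity[idx])]
    kept <- integer(0)
    for (i in ord) {
      if (length(kept)) {
        d <- sqrt((table$x[kept] - table$x[i])^2 + (table$y[kept] - table$y[i])^2)
        thr <- pmax(table$uncertainty[kept], table$uncertainty[i])
        if (any(d < thr)) next
      }
      kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  table[keep, , drop = FALSE]
}

#' Randomly subsample a localization table
#'
#' Draws exactly `min(n, nrow(table))` records uniformly without
#' replacement, preserving original row order. Used to equalize localization
#' densities across images (e.g. 15,000 localizations per image).
#'
#' @param table Localization table.
#' @param n Target number of localizations.
#' @param seed Integer seed or `NULL`.
#' @export
subsample_localizations <- function(table, n, seed = NULL) {
  n <- check_count(n, "n")
  if (n >= nrow(table)) return(table)
  with_seed(seed, {
    idx <- sort(sample.int(nrow(table), n))
    table[idx, , drop = FALSE]
  })
}

#' Expression-normalized spot-count statistic
#'
#' Difference between the number of single-molecule spots detected in cells
#' expressing the probe and in non-expressing control cells, normalized by
#' the expressed amount of probe (cytoplasmic fluorescence intensity minus
#' background intensity).
#'
#' @param n_spots_expressing,n_spots_control Spot counts (>= 0).
#' @param intensity_cytoplasm,intensity_background Fluorescence intensities
#'   (arbitrary units); `intensity_cytoplasm > intensity_background` is
#'   required.
#' @return The dimensionless normalized spot density.
#' @examples
#' normalized_spot_density(1200, 200, 150, 50)  # 10
#' @export
normalized_spot_density <- function(n_spots_expressing, n_spots_control,
                                    intensity_cytoplasm, intensity_background) {
  n_spots_expressing <- check_count(n_spots_expressing, "n_spots_expressing")
  n_spots_control <- check_count(n_spots_control, "n_spots_control")
  if (intensity_cytoplasm <= intensity_background)
    stop("intensity_cytoplasm must exceed intensity_background; ",
         "the normalization is undefined otherwise", call. = FALSE)
  (n_spots_expressing - n_spots_control) /
    (intensity_cytoplasm - intensity_background)
}

#' Read single-molecule trajectories
#'
#' Reads a trajectory CSV with columns `track_id`, `frame`, `x`, `y`
#' (coordinates in nm). Frames must be non-decreasing within a track;
#' frame gaps split a track into separate tracks (suffix `.1`, `.2`, ...)
#' rather than interpolating across the gap, since interpolated positions
#' would fabricate displacements. Tracks shorter than 2 positions after
#' splitting are dropped.
#'
#' @param path Path to a CSV file.
#' @param frame_interval Frame duration of the recording, s.
#' @return A [trajectory_set].
#' @export
read_trajectories <- function(path, frame_interval) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pieces <- list()
  dropped <- 0L
  for (id in unique(raw$track_id)) {
    tr <- raw[raw$track_id == id, , drop = FALSE]
    if (any(diff(tr$frame) <= 0))
      stop(sprintf("non-monotone frames within track '%s'", id), call. = FALSE)
    seg <- cumsum(c(0L, diff(tr$frame) > 1))
    for (s in unique(seg)) {
      part <- tr[seg == s, , drop = FALSE]
      if (nrow(part) < 2) { dropped <- dropped + 1L; next }
      part$track_id <- if (max(seg) > 0) paste0(id, ".", s + 1) else as.character(id)
      pieces[[length(pieces) + 1]] <- part
    }
  }
  if (dropped > 0)
    warning(sprintf("%d track segment(s) shorter than 2 positions were dropped",
                    dropped), call. = FALSE)
  if (!length(pieces)) stop("no usable trajectories in ", path, call. = FALSE)
  trajectory_set(do.call(rbind, pieces), frame_interval)
}

#' Write single-molecule trajectories
#'
#' @param set A [trajectory_set].
#' @param path Output path.
#' @export
write_trajectories <- function(set, path) {
  stopifnot(inherits(set, "trajectory_set"))
  out <- as.data.frame(set$tracks[, c("track_id", "frame", "x", "y")])
  out$x <- sprintf("%.3f", out$x)
  out$y <- sprintf("%.3f", out$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
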