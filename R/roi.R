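#' Rectangular region of interest
#'
#' Axis-aligned rectangle, in nanometres, delimiting the analysed field.
#' The default corresponds to a 120 x 120 pixel camera crop at 78 nm pixel
#' pitch (9360 x 9360 nm), the field size typically used for localization
#' analysis of TIRF acquisitions.
#'
#' @param x_min,y_min,x_max,y_max Rectangle corners in nm. `x_max > x_min`
#'   and `y_max > y_min` are required.
#' @return An object of class `"roi"`: a named numeric vector with elements
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @examples
#' r <- roi(0, 0, 1000, 500)
#' roi_area(r)
#' @export
roi <- function(x_min = 0, y_min = 0, x_max = 9360, y_max = 9360) {
  vals <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
            x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("roi corners must be finite numbers", call. = FALSE)
  if (vals["x_max"] <= vals["x_min"] || vals["y_max"] <= vals["y_min"])
    stop("roi must satisfy x_max > x_min and y_max > y_min", call. = FALSE)
  structure(vals, class = "roi")
}

#' @rdname roi
#' @param r An `roi` object.
#' @export
roi_area <- function(r) {
  r <- as_roi(r)
  unname((r["x_max"] - r["x_min"]) * (r["y_max"] - r["y_min"]))
}

#' @rdname roi
#' @export
default_roi <- function() roi(0, 0, 9360, 9360)

as_roi <- function(r) {
  if (inherits(r, "roi")) return(r)
  if (is.numeric(r) && length(r) == 4) return(roi(r[[1]], r[[2]], r[[3]], r[[4]]))
  stop("expected an roi object or a numeric vector (x_min, y_min, x_max, y_max)",
       call. = FALSE)
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> [%g, %g] x [%g, %g] nm (area %g nm^2)\n",
              x["x_min"], x["x_max"], x["y_min"], x["y_max"], roi_area(x)))
  invisible(x)
}

# TRUE for points inside the rectangle (closed boundaries)
in_roi <- function(x, y, r) {
  r <- as_roi(r)
  x >= r["x_min"] & x <= r["x_max"] & y >= r["y_min"] & y <= r["y_max"]
}
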