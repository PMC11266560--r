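# Exact area of a disk clipped by an axis-aligned rectangle.
#
# Used to correct radial neighbour counts for focal points whose counting
# disks are truncated by the ROI boundary: without the correction a uniform
# pattern has an inflated normalized density gradient near the field edge.

# antiderivative of sqrt(r^2 - x^2)
.disk_J <- function(x, r) {
  (x * sqrt(pmax(r^2 - x^2, 0)) + r^2 * asin(pmin(pmax(x / r, -1), 1))) / 2
}

# Area of the disk of radius r centred at the origin within the quarter-plane
# {x >= a, y >= b}. Vectorised over a and b.
.disk_corner_area <- function(a, b, r) {
  a <- pmin(pmax(a, -r), r)
  b <- pmin(pmax(b, -r), r)
  cc <- sqrt(pmax(r^2 - b^2, 0))
  lo <- pmax(a, -cc)
  # band |x| < c where the lower bound is the line y = b
  p1 <- ifelse(lo < cc, .disk_J(cc, r) - .disk_J(lo, r) - b * (cc - lo), 0)
  # for b < 0 the full chord contributes outside |x| < c, on either side
  hi_lo <- pmax(a, cc)
  p2 <- ifelse(b < 0 & hi_lo < r, 2 * (.disk_J(r, r) - .disk_J(hi_lo, r)), 0)
  p3 <- ifelse(b < 0 & a < -cc,
               2 * (.disk_J(-cc, r) - .disk_J(pmax(a, -r), r)), 0)
  p1 + p2 + p3
}

# Area of disk(centre (cx, cy), radius r) intersected with [x0,x1] x [y0,y1],
# by inclusion-exclusion over the four corner quarter-planes. Vectorised over
# centres; r is scalar.
disk_rect_area <- function(cx, cy, r, rect) {
  rect <- as_roi(rect)
  x0 <- rect[["x_min"]]; y0 <- rect[["y_min"]]
  x1 <- rect[["x_max"]]; y1 <- rect[["y_max"]]
  .disk_corner_area(x0 - cx, y0 - cy, r) -
    .disk_corner_area(x1 - cx, y0 - cy, r) -
    .disk_corner_area(x0 - cx, y1 - cy, r) +
    .disk_corner_area(x1 - cx, y1 - cy, r)
}
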