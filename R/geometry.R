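# Planar geometry helpers for the spatial analyses: convex hulls of ROI
# positions, point-in-polygon tests, and exact disc/annulus-polygon
# intersection areas used for edge correction of density profiles.

#' Convex hull of a point set as a counterclockwise polygon
#'
#' @param xy Two-column matrix of coordinates.
#' @return Matrix of hull vertices in counterclockwise order.
#' @export
convex_hull <- function(xy) {
  idx <- grDevices::chull(xy[, 1], xy[, 2])   # clockwise order
  xy[rev(idx), , drop = FALSE]
}

#' Signed area of a polygon (positive when counterclockwise)
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Test points against a convex polygon (counterclockwise vertices)
#'
#' @param px,py Point coordinates.
#' @param poly Counterclockwise polygon matrix.
#' @return Logical vector; boundary points count as inside.
#' @export
in_convex_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(TRUE, length(px))
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[if (e == n) 1 else e + 1, ]
    cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & (cross >= -1e-9)
  }
  inside
}

#' Area of the intersection of a disc with a convex polygon
#'
#' Exact (closed-form) area of `disc(center, r)` intersected with a
#' counterclockwise polygon, computed edge by edge as signed triangle and
#' circular-sector contributions.
#'
#' @param center Disc center (length-2 numeric).
#' @param r Disc radius (>= 0).
#' @param poly Counterclockwise polygon matrix.
#' @return Scalar area.
#' @export
disc_polygon_area <- function(center, r, poly) {
  .disc_poly_areas_cpp(matrix(center, 1, 2), r, poly)[1, 1]
}

#' Disc-polygon intersection areas for many centers and radii
#'
#' @param centers Two-column matrix of disc centers.
#' @param radii Vector of radii.
#' @param poly Counterclockwise polygon matrix.
#' @return Matrix of areas, centers x radii.
#' @export
disc_polygon_areas <- function(centers, radii, poly) {
  .disc_poly_areas_cpp(as.matrix(centers), as.numeric(radii), poly)
}

#' Area of an annulus clipped to a convex polygon
#'
#' @param center Annulus center.
#' @param r0,r1 Inner and outer radii.
#' @param poly Counterclockwise polygon matrix.
#' @return Scalar area of `annulus(center, r0, r1)` intersect polygon.
#' @export
annulus_polygon_area <- function(center, r0, r1, poly) {
  disc_polygon_area(center, r1, poly) - disc_polygon_area(center, r0, poly)
}
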