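#' Planar item set for occupancy models
#'
#' A set of items (points, or axis-aligned rectangles when widths and heights
#' are supplied) in degrees of visual angle, with the region used for density
#' computations.
#'
#' @param x,y item coordinates in degrees (for rectangles, the top-left
#'   corner).
#' @param w,h optional rectangle extents in degrees; `0` (the default) gives
#'   point items.
#' @param region either `NULL` (axis-aligned bounding box of the items),
#'   `"hull"` (convex hull of the item corners) or a numeric
#'   `c(xmin, xmax, ymin, ymax)`.
#' @return Object of class `point_set`.
#' @export
point_set <- function(x, y, w = 0, h = 0, region = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  items <- data.frame(x = x, y = y, w = rep_len(w, length(x)),
                      h = rep_len(h, length(x)))
  out <- list(items = items, region = region)
  class(out) <- "point_set"
  out
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("Point set: %d items, region area %.3f deg^2\n",
              nrow(x$items), region_area(x)))
  invisible(x)
}

#' Area of a point set's density region
#'
#' @param points a [point_set()].
#' @return Area in squared degrees.
#' @export
region_area <- function(points) {
  it <- points$items
  reg <- points$region
  if (is.numeric(reg) && length(reg) == 4)
    return((reg[2] - reg[1]) * (reg[4] - reg[3]))
  xs <- c(it$x, it$x + it$w)
  ys <- c(it$y, it$y + it$h)
  if (identical(reg, "hull")) {
    px <- c(it$x, it$x + it$w, it$x, it$x + it$w)
    py <- c(it$y, it$y, it$y + it$h, it$y + it$h)
    idx <- grDevices::chull(px, py)
    hx <- px[idx]; hy <- py[idx]
    n <- length(idx)
    # shoelace formula
    return(abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2)
  }
  (max(xs) - min(xs)) * (max(ys) - min(ys))
}

#' Item density of a point set
#'
#' @param points a [point_set()].
#' @return Items per squared degree, `n / region_area(points)`.
#' @export
density_of <- function(points) {
  a <- region_area(points)
  if (a <= 0) stop("region has zero area; density is undefined")
  nrow(points$items) / a
}

# Signed distance from grid positions (gx, gy) to the r-neighbourhood of one
# item: 0 inside the rectangle, Euclidean distance to it outside.  Point
# items are rectangles of zero extent.
.dist_to_item <- function(gx, gy, x, y, w, h) {
  dx <- pmax(0, x - gx, gx - (x + w))
  dy <- pmax(0, y - gy, gy - (y + h))
  sqrt(dx * dx + dy * dy)
}

#' Area of the union of influence spheres
#'
#' Computes the area covered by the union of disks of radius `r` centred on
#' the items (for rectangular items, the rectangle dilated by `r`: its
#' Minkowski sum with the disk).  The computation rasterises the bounding box
#' of the dilated items at `resolution` degrees per raster cell and counts
#' covered cells; [union_disk_area_mc()] is an independent Monte-Carlo
#' estimate of the same quantity.
#'
#' @param points a [point_set()] with at least one item.
#' @param r influence-sphere radius in degrees, `> 0`.
#' @param resolution raster cell side in degrees.
#' @return Union area in squared degrees.
#' @examples
#' union_disk_area(point_set(0, 0), r = 1)          # ~ pi
#' union_disk_area(point_set(c(0, 3), c(0, 0)), 1)  # two disjoint disks ~ 2*pi
#' @export
union_disk_area <- function(points, r, resolution = 0.02) {
  it <- points$items
  if (nrow(it) == 0) stop("empty point set")
  if (r <= 0) stop("r must be > 0")
  xmin <- min(it$x) - r; xmax <- max(it$x + it$w) + r
  ymin <- min(it$y) - r; ymax <- max(it$y + it$h) + r
  gx <- seq(xmin + resolution / 2, xmax, by = resolution)
  gy <- seq(ymin + resolution / 2, ymax, by = resolution)
  gridx <- rep(gx, times = length(gy))
  gridy <- rep(gy, each = length(gx))
  covered <- rep(FALSE, length(gridx))
  for (i in seq_len(nrow(it))) {
    covered <- covered |
      .dist_to_item(gridx, gridy, it$x[i], it$y[i], it$w[i], it$h[i]) <= r
  }
  sum(covered) * resolution^2
}

#' Monte-Carlo estimate of the union area
#'
#' Independent check of [union_disk_area()]: samples points uniformly over
#' the dilated bounding box and scales the covered fraction by the box area.
#'
#' @inheritParams union_disk_area
#' @param n_samples number of uniform samples.
#' @param seed RNG seed.
#' @return Estimated union area in squared degrees.
#' @export
union_disk_area_mc <- function(points, r, n_samples = 1e6, seed = 1L) {
  it <- points$items
  if (nrow(it) == 0) stop("empty point set")
  if (r <= 0) stop("r must be > 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  xmin <- min(it$x) - r; xmax <- max(it$x + it$w) + r
  ymin <- min(it$y) - r; ymax <- max(it$y + it$h) + r
  sx <- stats::runif(n_samples, xmin, xmax)
  sy <- stats::runif(n_samples, ymin, ymax)
  covered <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(it))) {
    covered <- covered |
      .dist_to_item(sx, sy, it$x[i], it$y[i], it$w[i], it$h[i]) <= r
  }
  mean(covered) * (xmax - xmin) * (ymax - ymin)
}

#' Occupancy model estimate (fixed influence-sphere size)
#'
#' The occupancy model predicts perceived numerosity by the total area
#' covered by disk-shaped influence spheres of fixed radius `r` --- the
#' model's single free parameter --- centred on the items.
#'
#' @inheritParams union_disk_area
#' @return Occupancy in squared degrees.
#' @export
occupancy_estimate <- function(points, r, resolution = 0.02) {
  union_disk_area(points, r, resolution)
}

#' Density-adaptive normalized occupancy
#'
#' The density-adaptive variant of the occupancy model: the influence-sphere
#' radius shrinks with item density, `r(d) = r0 / (1 + k d)` by default, and
#' the occupancy is normalized by the influence-sphere area so that `n`
#' items with disjoint spheres score exactly `n`.
#'
#' @inheritParams union_disk_area
#' @param r0 base influence radius in degrees at zero density.
#' @param k density-adaptation strength (squared degrees per item).
#' @param radius_fn optional monotone non-increasing function of density that
#'   overrides the default radius law.
#' @return Normalized occupancy (dimensionless; equals `n` for disjoint
#'   spheres).
#' @export
durgin_estimate <- function(points, r0, k = 0.5, radius_fn = NULL,
                            resolution = 0.02) {
  d <- density_of(points)
  r <- if (is.null(radius_fn)) r0 / (1 + k * d) else radius_fn(d)
  if (r <= 0) stop("influence radius must be positive")
  union_disk_area(points, r, resolution) / (pi * r^2)
}

#' Occupancy via spatial filtering of a stimulus frame
#'
#' The spatial-filtering route to occupancy: the luminance-defined item mask
#' (black texels) is convolved with a binary disk kernel of radius `r` and
#' the area with strictly positive response is counted.  This equals the
#' area of the item mask dilated by the disk.  On frames without black
#' texels --- every second-order frame --- the mask is empty and the result
#' is 0: a luminance-based filter cannot see contrast-defined items.
#'
#' @param frame a texel frame (integer luminance matrix).
#' @param r disk radius in degrees.
#' @param geometry the [display_geometry()] the frame was rendered under.
#' @return Area in squared degrees of the positive filter response.
#' @export
filter_occupancy <- function(frame, r, geometry = display_geometry()) {
  black <- geometry$luminance[["black"]]
  mask <- unclass(frame) == black
  if (!any(mask)) return(0)
  r_tex <- r / geometry$texel_deg
  rad <- floor(r_tex)
  ny <- nrow(mask); nx <- ncol(mask)
  resp <- matrix(FALSE, ny, nx)
  for (dy in -rad:rad) {
    for (dx in -rad:rad) {
      if (dx * dx + dy * dy > r_tex * r_tex) next
      sy <- max(1, 1 + dy):min(ny, ny + dy)
      sx <- max(1, 1 + dx):min(nx, nx + dx)
      resp[sy, sx] <- resp[sy, sx] | mask[sy - dy, sx - dx]
    }
  }
  sum(resp) * geometry$texel_deg^2
}
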