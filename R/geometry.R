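#' State-space grid
#'
#' Construct the discretized state-space \code{S}: a regular grid of square
#' pixels, optionally masked to an irregular region (e.g. water only). Pixel
#' indices run row-major from the south-west corner: pixel 1 is the
#' bottom-left pixel, indices increase eastwards then northwards. Masked
#' grids keep the full rectangular indexing internally but expose only the
#' \code{G} valid pixels; all model-facing quantities (covariates, activity
#' centers, movement kernels) are indexed by valid-pixel index \code{1..G}.
#'
#' Coordinates are assumed planar and pre-scaled; a convenient convention
#' for large marine study areas is 1 unit = 10 km, which keeps distances
#' and movement scales O(1).
#'
#' @param n_x,n_y number of pixel columns (east-west) and rows (north-south).
#' @param side pixel width (same units as coordinates).
#' @param origin numeric length-2, coordinates of the south-west corner of
#'   the grid (not of the first pixel center).
#' @param mask optional logical vector of length \code{n_x * n_y} (row-major
#'   from the south-west), \code{TRUE} for pixels belonging to the
#'   state-space. Default: all pixels valid.
#' @return An object of class \code{"scr_grid"}: a list with elements
#'   \code{origin}, \code{side}, \code{n_x}, \code{n_y}, \code{G} (number of
#'   valid pixels), \code{centers} (G x 2 matrix of valid pixel centers),
#'   \code{valid} (logical over the full rectangle), \code{full_index}
#'   (valid-pixel index -> rectangle index) and \code{grid_index}
#'   (rectangle index -> valid-pixel index, NA where masked).
#' @examples
#' g <- ss_grid(2, 2, side = 1)
#' g$centers
#' @export
ss_grid <- function(n_x, n_y, side, origin = c(0, 0), mask = NULL) {
  if (length(n_x) != 1 || length(n_y) != 1 || n_x < 1 || n_y < 1)
    stop("n_x and n_y must be positive integers")
  if (length(side) != 1 || !is.finite(side) || side <= 0)
    stop("pixel side must be a positive number")
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  ncell <- n_x * n_y
  if (is.null(mask)) mask <- rep(TRUE, ncell)
  if (length(mask) != ncell || !is.logical(mask))
    stop("mask must be a logical vector of length n_x * n_y")
  if (!any(mask)) stop("mask removes every pixel; state-space is empty")
  col <- rep(seq_len(n_x) - 1L, times = n_y)
  row <- rep(seq_len(n_y) - 1L, each = n_x)
  cx <- origin[1] + (col + 0.5) * side
  cy <- origin[2] + (row + 0.5) * side
  full_index <- which(mask)
  grid_index <- rep(NA_integer_, ncell)
  grid_index[full_index] <- seq_along(full_index)
  structure(list(
    origin = as.numeric(origin), side = as.numeric(side),
    n_x = n_x, n_y = n_y, G = length(full_index),
    centers = cbind(x = cx[full_index], y = cy[full_index]),
    valid = mask, full_index = full_index, grid_index = grid_index
  ), class = "scr_grid")
}

#' @export
print.scr_grid <- function(x, ...) {
  cat(sprintf(
    "State-space grid: %d x %d pixels of side %g, G = %d valid pixels\n",
    x$n_x, x$n_y, x$side, x$G))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$origin[1], x$origin[1] + x$n_x * x$side,
              x$origin[2], x$origin[2] + x$n_y * x$side))
  invisible(x)
}

#' Locate points on the state-space grid
#'
#' Map continuous coordinates to valid-pixel indices. Pixels are half-open
#' squares \code{[x_lo, x_lo + side) x [y_lo, y_lo + side)}, so a point
#' exactly on a shared edge belongs to the pixel with the larger coordinate
#' index; points on the grid's east/north outer boundary are assigned to the
#' last pixel so that the closed bounding box is covered.
#'
#' @param x,y numeric vectors of coordinates (recycled to common length).
#' @param grid an [ss_grid()] object.
#' @return Integer vector of valid-pixel indices.
#'   Errors if any point lies outside the grid bounding box or in a masked
#'   pixel.
#' @export
pixel_of_point <- function(x, y, grid) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  fx <- (x - grid$origin[1]) / grid$side
  fy <- (y - grid$origin[2]) / grid$side
  eps <- 1e-12
  if (any(fx < -eps | fx > grid$n_x + eps | fy < -eps | fy > grid$n_y + eps))
    stop("point outside the state-space bounding box")
  col <- pmin(floor(fx), grid$n_x - 1L)
  row <- pmin(floor(fy), grid$n_y - 1L)
  idx <- grid$grid_index[row * grid$n_x + col + 1L]
  if (anyNA(idx)) stop("point falls in a masked (invalid) pixel")
  as.integer(idx)
}

#' Distance from points to a transect segment
#'
#' Euclidean distance from one or more points to the closest point on a
#' closed line segment. This equals the perpendicular distance when the foot
#' of the perpendicular falls within the segment and the distance to the
#' nearer endpoint otherwise. Computed via the clamped projection parameter
#' u = clamp(((p-a).(b-a)) / |b-a|^2, 0, 1), which is well defined for every
#' segment orientation (including due north-south) and symmetric in the two
#' endpoints, so no westernmost-first ordering is required.
#'
#' @param px,py point coordinates (vectors, recycled).
#' @param x1,y1,x2,y2 segment endpoints (scalars).
#' @return Numeric vector of distances.
#' @examples
#' point_segment_distance(1, 0, 0, 0, 2, 0)  # 0: point on the line
#' point_segment_distance(0, 5, 1, 0, 3, 0)  # sqrt(26): nearest endpoint
#' @export
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) stop("zero-length segment: endpoints must be distinct")
  u <- ((px - x1) * dx + (py - y1) * dy) / len2
  u <- pmin(pmax(u, 0), 1)
  sqrt((px - (x1 + u * dx))^2 + (py - (y1 + u * dy))^2)
}

#' Minimum distance to a set of transect segments
#'
#' The quantity driving detection: \code{mindist}, the distance from a point
#' to the closest point on the closest transect segment surveyed on an
#' occasion, together with the index of that segment (whose platform selects
#' the detection function). Ties (a probability-zero event for continuous
#' locations) resolve to the lowest segment index.
#'
#' @param px,py point coordinates (vectors, recycled to common length).
#' @param segments a data frame or matrix with columns
#'   \code{x1, y1, x2, y2} (one row per segment; extra columns ignored).
#' @return A list with numeric \code{distance} and integer \code{segment}
#'   (argmin index), each of length \code{length(px)}.
#' @export
min_distance_to_transects <- function(px, py, segments) {
  segments <- as.data.frame(segments)
  L <- nrow(segments)
  if (is.null(L) || L < 1)
    stop("no transect segments supplied: no survey effort on this occasion")
  n <- max(length(px), length(py))
  px <- rep_len(as.numeric(px), n); py <- rep_len(as.numeric(py), n)
  d <- matrix(NA_real_, n, L)
  for (l in seq_len(L))
    d[, l] <- point_segment_distance(px, py, segments$x1[l], segments$y1[l],
                                     segments$x2[l], segments$y2[l])
  j <- max.col(-d, ties.method = "first")
  list(distance = d[cbind(seq_len(n), j)], segment = j)
}
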