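#' @name shape-geometry
#' @title Polygon geometry helpers for particle silhouettes
#' @description
#' Silhouettes are simple closed polygons with vertices in um. Internal
#' helpers compute signed area, perimeter, centroid and second area moments
#' with the standard shoelace-based formulas; the public entry point is
#' [shape_factors()].
NULL

check_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L || any(!is.finite(poly)))
    stop("a silhouette must be a finite n x 2 matrix with n >= 3",
         call. = FALSE)
  # drop an explicitly repeated closing vertex
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L) stop("degenerate polygon", call. = FALSE)
  poly
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(poly) {
  d <- poly - poly[c(2:nrow(poly), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# second area moments about the centroid; returns list(area, cx, cy,
# mu20, mu02, mu11)
polygon_moments <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(1, max(abs(poly))^2) * nrow(poly))
    stop("degenerate polygon (zero area)", call. = FALSE)
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(area = abs(a), cx = cx, cy = cy,
       mu20 = iyy / a - cx^2, mu02 = ixx / a - cy^2, mu11 = ixy / a - cx * cy)
}

extent_along <- function(poly, ux, uy) {
  pr <- poly[, 1] * ux + poly[, 2] * uy
  max(pr) - min(pr)
}

#' Shape factors of a particle silhouette
#'
#' Computes the morphometric descriptors used for milled-powder particles:
#'
#' * `esd`: equivalent spherical diameter, the diameter of the circle with
#'   the silhouette's area (um);
#' * `length` (L) and `width` (W): extents of the silhouette along and
#'   perpendicular to its principal axis (from second area moments), the
#'   convention of automated imaging instruments -- a 100 x 50 um rectangle
#'   has L = 100, W = 50;
#' * `elongation = 1 - W / L`: 0 for round or cubic particles, approaching 1
#'   for needles;
#' * `convexity`: convex-hull perimeter divided by the particle perimeter;
#'   1 for a smooth convex particle, lower for rough or branched outlines.
#'
#' All factors are invariant to rotation and translation; `esd`, `length`
#' and `width` scale linearly with the silhouette while `elongation` and
#' `convexity` are scale-free.
#'
#' @param poly An `n x 2` matrix of polygon vertices (um), `n >= 3`, simple
#'   (non self-intersecting); an explicitly closed ring is accepted.
#' @return A one-row `data.frame` with columns `esd_um`, `length_um`,
#'   `width_um`, `elongation`, `convexity`, `area_um2`, `perimeter_um`.
#' @export
#' @examples
#' rect <- cbind(c(0, 100, 100, 0), c(0, 0, 50, 50))
#' shape_factors(rect) # elongation 0.5
shape_factors <- function(poly) {
  poly <- check_polygon(poly)
  m <- polygon_moments(poly)
  per <- polygon_perimeter(poly)
  hull <- poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
  hull_per <- polygon_perimeter(hull)
  theta <- 0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02)
  e1 <- extent_along(poly, cos(theta), sin(theta))
  e2 <- extent_along(poly, -sin(theta), cos(theta))
  len <- max(e1, e2); wid <- min(e1, e2)
  data.frame(esd_um = 2 * sqrt(m$area / pi),
             length_um = len, width_um = wid,
             elongation = 1 - wid / len,
             convexity = min(1, hull_per / per),
             area_um2 = m$area, perimeter_um = per,
             row.names = NULL)
}

#' Shape factors for a set of silhouettes
#'
#' @param polys A list of polygons (see [shape_factors()]).
#' @param magnification Optional magnification tag recycled across particles
#'   (e.g. `"x10"`).
#' @return A `data.frame` with one row per particle (`particle_id`,
#'   `magnification`, plus the [shape_factors()] columns).
#' @export
shape_table <- function(polys, magnification = NA_character_) {
  if (length(polys) == 0L) stop("empty silhouette set", call. = FALSE)
  recs <- do.call(rbind, lapply(polys, shape_factors))
  recs <- cbind(particle_id = seq_along(polys),
                magnification = rep_len(magnification, length(polys)),
                recs)
  rownames(recs) <- NULL
  recs
}

#' Volume weights for 2-D shape records
#'
#' Planar imaging yields one silhouette per particle; to reconstruct a
#' volume-weighted view (matching laser-diffraction statistics) each particle
#' is weighted proportionally to `esd^3`, the volume of the sphere with the
#' silhouette's area-equivalent diameter.
#'
#' @param records A `data.frame` with an `esd_um` column.
#' @return The same `data.frame` with a `weight_pct` column summing to 100.
#' @export
volume_weights <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data.frame", call. = FALSE)
  if (is.null(records$esd_um)) stop("missing 'esd_um' column", call. = FALSE)
  w <- records$esd_um^3
  records$weight_pct <- 100 * w / sum(w)
  records
}

#' Volume-weighted histogram of a shape descriptor
#'
#' @param records Shape records (rows = particles) with `esd_um` and the
#'   chosen descriptor column; weights are recomputed from `esd_um` unless a
#'   `weight_pct` column is already present.
#' @param by Descriptor to bin: `"esd_um"` or `"elongation"`.
#' @param breaks Bin edges; defaults to 20 log-spaced bins over the esd range
#'   or 20 linear bins on `[0, 1]` for elongation.
#' @return A `data.frame` with columns `lo`, `hi`, `weight_pct` summing
#'   to 100.
#' @export
volume_weighted_distribution <- function(records,
                                         by = c("esd_um", "elongation"),
                                         breaks = NULL) {
  by <- match.arg(by)
  if (is.null(records$weight_pct)) records <- volume_weights(records)
  v <- records[[by]]
  if (is.null(breaks)) {
    breaks <- if (by == "esd_um")
      exp(seq(log(min(v) * 0.999), log(max(v) * 1.001), length.out = 21))
    else seq(0, 1, length.out = 21)
  }
  if (any(v < min(breaks) | v > max(breaks)))
    stop("'breaks' do not cover the data range", call. = FALSE)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx == length(breaks)] <- length(breaks) - 1L
  w <- vapply(seq_len(length(breaks) - 1L),
              function(k) sum(records$weight_pct[idx == k]), numeric(1))
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1], weight_pct = w)
}

#' Merge fine and coarse magnification populations 50/50
#'
#' Fine (< boundary, imaged at high magnification) and coarse (> boundary)
#' particles are acquired separately; when the boundary is set at the
#' powder's median size each side holds half the volume, so the merged
#' distribution is built by renormalizing each half to 50 %.
#'
#' @param small,large Weighted shape records (`esd_um`, `weight_pct`
#'   columns; weights computed with [volume_weights()] if absent) holding
#'   only particles below / above `boundary_um`.
#' @param boundary_um Merge boundary in um (default 20, the target median
#'   size of the ultrafine powders).
#' @return Combined records with `weight_pct` rescaled so each side sums to
#'   50 and the whole to 100; a `side` column tags the origin.
#' @export
merge_magnifications <- function(small, large, boundary_um = 20) {
  if (!is.data.frame(small) || nrow(small) == 0L ||
      !is.data.frame(large) || nrow(large) == 0L)
    stop("both magnification populations must be non-empty ",
         "(the 50/50 merge is undefined otherwise)", call. = FALSE)
  if (is.null(small$weight_pct)) small <- volume_weights(small)
  if (is.null(large$weight_pct)) large <- volume_weights(large)
  if (any(small$esd_um >= boundary_um))
    stop("'small' holds particles at or above the ", boundary_um,
         " um boundary", call. = FALSE)
  if (any(large$esd_um <= boundary_um))
    stop("'large' holds particles at or below the ", boundary_um,
         " um boundary", call. = FALSE)
  small$weight_pct <- 50 * small$weight_pct / sum(small$weight_pct)
  large$weight_pct <- 50 * large$weight_pct / sum(large$weight_pct)
  small$side <- "small"; large$side <- "large"
  out <- rbind(small, large)
  rownames(out) <- NULL
  out
}

#' Minimum-size filter for low-magnification imaging
#'
#' At x5 magnification, particles at or below 4.5 um cover too few pixels
#' for reliable shape factors and are excluded (strictly greater than the
#' cut survives).
#'
#' @param records Shape records with an `esd_um` column.
#' @param cut_um Exclusion cut in um (default 4.5).
#' @return Filtered records; the number of removed rows is attached as
#'   attribute `n_removed`.
#' @export
apply_min_size_filter <- function(records, cut_um = 4.5) {
  if (is.null(records$esd_um)) stop("missing 'esd_um' column", call. = FALSE)
  keep <- records$esd_um > cut_um
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Weighted cumulative distribution and median of a shape descriptor
#'
#' @param values Descriptor values (e.g. elongations).
#' @param weights Non-negative weights (defaults to equal); normalized
#'   internally.
#' @return A list with `curve` (a `data.frame` of `value` and cumulative
#'   `cum_pct`, non-decreasing) and `median` (the 50 % crossing of the
#'   cumulative mass, linearly interpolated between the mass midpoints of
#'   adjacent distinct values -- the usual weighted-percentile convention,
#'   exact for symmetric distributions).
#' @export
cumulative_distribution <- function(values, weights = NULL) {
  if (length(values) == 0L) stop("empty value set", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values) || any(weights < 0) ||
      sum(weights) <= 0)
    stop("'weights' must be non-negative (some positive) and match 'values'",
         call. = FALSE)
  o <- order(values)
  v <- values[o]; w <- weights[o] / sum(weights) * 100
  # collapse ties on the value axis
  grp <- cumsum(!duplicated(v))
  vv <- v[!duplicated(v)]
  ww <- as.numeric(tapply(w, grp, sum))
  cum <- cumsum(ww)
  curve <- data.frame(value = vv, cum_pct = cum)
  mid <- cum - ww / 2
  med <- if (50 <= mid[1]) vv[1]
    else if (50 >= mid[length(mid)]) vv[length(vv)]
    else stats::approx(mid, vv, xout = 50, ties = list("ordered", min))$y
  list(curve = curve, median = med)
}
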