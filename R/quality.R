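#' Normalize powder quality indicators to (0, 1]
#'
#' Builds comparable quality profiles from raw indicator values. For
#' lower-is-better indicators (span, elongation, agglomeration,
#' compressibility, cohesion) the raw value is first inverted (`1/value`);
#' higher-is-better indicators (specific surface area, process-efficiency
#' columns) are used as-is. Each transformed column is then divided by its
#' maximum across the powder set, so the best powder on each indicator scores
#' exactly 1.
#'
#' @param raw A `data.frame` in long form with columns `powder`, `indicator`,
#'   `value`, and optionally `direction` (`"lower"` or `"higher"`); when
#'   `direction` is absent it is looked up from `directions`.
#' @param directions Named character vector mapping indicator names to
#'   `"lower"` or `"higher"`; defaults cover the standard powder-quality set.
#' @return A `data.frame` with columns `powder`, `indicator`, `value`,
#'   `direction`, `score` (normalized to (0, 1]).
#' @export
#' @examples
#' raw <- data.frame(powder = c("A", "B"), indicator = "span",
#'                   value = c(2, 4))
#' normalize_indicators(raw) # scores 1 and 0.5
normalize_indicators <- function(raw, directions = default_directions()) {
  need <- c("powder", "indicator", "value")
  if (!is.data.frame(raw) || !all(need %in% names(raw)) || nrow(raw) == 0L)
    stop("'raw' must be a non-empty data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(raw$direction)) {
    unknown <- setdiff(unique(raw$indicator), names(directions))
    if (length(unknown))
      stop("no direction known for indicator(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    raw$direction <- unname(directions[raw$indicator])
  }
  if (!all(raw$direction %in% c("lower", "higher")))
    stop("'direction' must be 'lower' or 'higher'", call. = FALSE)
  bad <- raw$direction == "lower" & raw$value <= 0
  if (any(bad))
    stop("lower-is-better indicators must be positive to invert: ",
         paste(unique(raw$indicator[bad]), collapse = ", "), call. = FALSE)
  raw$score <- ifelse(raw$direction == "lower", 1 / raw$value, raw$value)
  for (ind in unique(raw$indicator)) {
    sel <- raw$indicator == ind
    raw$score[sel] <- raw$score[sel] / max(raw$score[sel])
  }
  raw
}

#' Default indicator directions for powder quality profiles
#'
#' @return Named character vector: `"lower"` for span, elongation,
#'   agglomeration, compressibility and cohesion; `"higher"` for SSA and the
#'   externally supplied process-efficiency indicators.
#' @export
default_directions <- function() {
  c(span = "lower", ssa = "higher", elongation = "lower",
    agglomeration = "lower", compressibility = "lower", cohesion = "lower",
    energy_utilization = "higher", productivity = "higher",
    surface_production_rate = "higher")
}

#' Default radar axis order
#'
#' Radar-polygon areas depend on the axis ordering, so the order is frozen:
#' span, ssa, elongation, agglomeration, compressibility, cohesion, with any
#' further (process-efficiency) indicators appended in the order supplied.
#'
#' @param extra Additional indicator names to append.
#' @return Character vector of axis names in plotting order.
#' @export
default_axis_order <- function(extra = character()) {
  c("span", "ssa", "elongation", "agglomeration", "compressibility",
    "cohesion", extra)
}

#' Area of a radar (spider) polygon
#'
#' Vertices sit at radius `r_i` on `n` equally spaced axes; the enclosed
#' area is `(1/2) sin(2 pi / n) * sum_i r_i r_(i+1)` (indices mod `n`),
#' equivalently the shoelace area of the Cartesian vertices.
#'
#' @param scores Numeric vector of normalized indicator values (radii),
#'   length >= 3, in axis order.
#' @param weights Optional per-axis weights multiplying the radii (default
#'   equal, i.e. 1).
#' @return The polygon area.
#' @export
#' @examples
#' radar_area(rep(1, 6)) # regular hexagon of unit circumradius
radar_area <- function(scores, weights = NULL) {
  n <- length(scores)
  if (n < 3L) stop("a radar polygon needs at least 3 axes", call. = FALSE)
  if (any(!is.finite(scores)) || any(scores < 0))
    stop("'scores' must be finite and non-negative", call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != n || any(weights < 0))
      stop("'weights' must be non-negative, one per axis", call. = FALSE)
    scores <- scores * weights
  }
  0.5 * sin(2 * pi / n) * sum(scores * scores[c(2:n, 1)])
}

#' Rank powders by relative radar area
#'
#' Each powder's normalized profile is drawn as a radar polygon over a common
#' axis order; the polygon area summarizes all-round quality and powders are
#' ranked by area relative to the best (best = 100 %). Ties are broken by
#' powder identifier (alphabetical).
#'
#' @param profiles Normalized indicator table as returned by
#'   [normalize_indicators()] (columns `powder`, `indicator`, `score`),
#'   with the same indicator set for every powder.
#' @param axis_order Axis ordering; defaults to [default_axis_order()]
#'   restricted/extended to the indicators present.
#' @param weights Optional named per-indicator weights (default equal).
#' @return A `data.frame` of class `radar_ranking`, one row per powder,
#'   ordered best first, with columns `powder`, `area`, `relative_area_pct`
#'   and `rank`.
#' @export
rank_powders <- function(profiles, axis_order = NULL, weights = NULL) {
  need <- c("powder", "indicator", "score")
  if (!is.data.frame(profiles) || !all(need %in% names(profiles)))
    stop("'profiles' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  powders <- sort(unique(profiles$powder))
  if (length(powders) < 2L)
    stop("ranking needs at least two powders", call. = FALSE)
  inds <- unique(profiles$indicator)
  for (p in powders) {
    have <- profiles$indicator[profiles$powder == p]
    if (!setequal(have, inds) || anyDuplicated(have))
      stop("powder '", p, "' does not carry the common indicator set",
           call. = FALSE)
  }
  if (is.null(axis_order)) {
    axis_order <- intersect(default_axis_order(), inds)
    axis_order <- c(axis_order, setdiff(inds, axis_order))
  }
  if (!setequal(axis_order, inds))
    stop("'axis_order' must be a permutation of the indicators", call. = FALSE)
  w <- if (is.null(weights)) NULL else {
    if (is.null(names(weights)) || !all(axis_order %in% names(weights)))
      stop("'weights' must be named by indicator", call. = FALSE)
    unname(weights[axis_order])
  }
  areas <- vapply(powders, function(p) {
    sub <- profiles[profiles$powder == p, ]
    radar_area(sub$score[match(axis_order, sub$indicator)], w)
  }, numeric(1))
  out <- data.frame(powder = powders, area = unname(areas),
                    relative_area_pct = 100 * unname(areas) / max(areas))
  out <- out[order(-out$area, out$powder), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("radar_ranking", "data.frame"),
            axis_order = axis_order)
}

#' Radar plot of powder quality profiles
#'
#' Draws the normalized profiles as overlaid radar polygons (base graphics).
#' Intended for interactive use or for writing a figure file via a graphics
#' device opened by the caller.
#'
#' @inheritParams rank_powders
#' @param main Plot title.
#' @return Invisibly, the matrix of scores (powders x axes) that was drawn.
#' @export
plot_radar <- function(profiles, axis_order = NULL, main = "Powder quality") {
  powders <- sort(unique(profiles$powder))
  inds <- unique(profiles$indicator)
  if (is.null(axis_order)) {
    axis_order <- intersect(default_axis_order(), inds)
    axis_order <- c(axis_order, setdiff(inds, axis_order))
  }
  n <- length(axis_order)
  ang <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  graphics::plot.new()
  graphics::plot.window(c(-1.4, 1.4), c(-1.4, 1.4), asp = 1)
  for (r in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey80")
  graphics::text(1.25 * cos(ang), 1.25 * sin(ang), axis_order, cex = 0.8)
  cols <- grDevices::hcl.colors(length(powders), "Dark 3")
  scores <- matrix(NA_real_, length(powders), n,
                   dimnames = list(powders, axis_order))
  for (i in seq_along(powders)) {
    sub <- profiles[profiles$powder == powders[i], ]
    r <- sub$score[match(axis_order, sub$indicator)]
    scores[i, ] <- r
    graphics::polygon(r * cos(ang), r * sin(ang), border = cols[i],
                      col = grDevices::adjustcolor(cols[i], 0.15), lwd = 2)
  }
  graphics::legend("topleft", legend = powders, col = cols, lwd = 2,
                   bty = "n", cex = 0.8)
  graphics::title(main)
  invisible(scores)
}
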