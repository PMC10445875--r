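#' Binned volume-weighted particle size distribution
#'
#' Constructs a `psd` object from laser-granulometer style binned data:
#' ascending bin edges in micrometres and the volume percentage held by each
#' bin. The representative diameter of a bin is the geometric mean of its
#' edges, as appropriate for the log-spaced bins these instruments export.
#'
#' @param bin_edges Numeric vector of strictly increasing bin edges (um),
#'   length `n + 1` for `n` bins.
#' @param volume_pct Numeric vector of per-bin volume percentages, length `n`,
#'   all non-negative.
#' @param label Powder identifier (e.g. `"VBM_bark"`).
#' @param treatment Dispersion treatment, one of `"dry"`, `"ND"` (not
#'   deagglomerated), `"LG"` (granulometer ultrasonic probe), `"EP"`
#'   (external ultrasonic probe).
#' @param normalize If `TRUE` (default), rescale `volume_pct` to sum to 100.
#'   If `FALSE`, the supplied values must already sum to 100 within `1e-6`.
#'
#' @return An object of class `psd`: a list with elements `bin_edges`,
#'   `volume_pct`, `diameter` (geometric-mean bin diameters, um), `label`
#'   and `treatment`.
#' @export
#' @examples
#' p <- psd(c(10, 20, 40), c(30, 70), label = "demo")
#' psd_quantiles(p, 0.5)
psd <- function(bin_edges, volume_pct, label = "", treatment = "dry",
                normalize = TRUE) {
  bin_edges <- as.numeric(bin_edges)
  volume_pct <- as.numeric(volume_pct)
  if (length(bin_edges) < 2L)
    stop("'bin_edges' must contain at least two edges", call. = FALSE)
  if (length(volume_pct) != length(bin_edges) - 1L)
    stop("'volume_pct' must have one value per bin (length(bin_edges) - 1)",
         call. = FALSE)
  if (any(!is.finite(bin_edges)) || any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be finite and strictly increasing", call. = FALSE)
  if (any(bin_edges <= 0))
    stop("'bin_edges' must be positive (sizes in um)", call. = FALSE)
  if (any(!is.finite(volume_pct)) || any(volume_pct < 0))
    stop("'volume_pct' must be finite and non-negative", call. = FALSE)
  total <- sum(volume_pct)
  if (total <= 0)
    stop("PSD holds no volume", call. = FALSE)
  if (normalize) {
    volume_pct <- volume_pct / total * 100
  } else if (abs(total - 100) > 1e-6) {
    stop("'volume_pct' must sum to 100 within 1e-6 (got ", format(total), ")",
         call. = FALSE)
  }
  treatment <- match.arg(treatment, c("dry", "ND", "LG", "EP"))
  structure(
    list(bin_edges = bin_edges,
         volume_pct = volume_pct,
         diameter = sqrt(bin_edges[-length(bin_edges)] * bin_edges[-1]),
         label = label,
         treatment = treatment),
    class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  s <- psd_summary(x)
  cat(sprintf("Particle size distribution%s [%s]\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$treatment))
  cat(sprintf("  %d bins over %.3g-%.3g um\n",
              length(x$volume_pct), min(x$bin_edges), max(x$bin_edges)))
  cat(sprintf("  d10 %.3g um | d50 %.3g um | d90 %.3g um | span %.3g\n",
              s$d10, s$d50, s$d90, s$span))
  cat(sprintf("  SSA %.4g um^-1 (%.4g m2.mm-3, particles >= %g um)\n",
              s$ssa_um_inv, s$ssa_m2_mm3, s$lower_cut_um))
  invisible(x)
}

stopifnot_psd <- function(x) {
  if (!inherits(x, "psd")) stop("expected a 'psd' object", call. = FALSE)
  invisible(x)
}

#' Volume-weighted size quantiles of a PSD
#'
#' Quantiles (e.g. d10, d50, d90) are read off the cumulative volume curve by
#' linear interpolation in log-diameter, the standard treatment for
#' laser-diffraction exports whose bins are log-spaced.
#'
#' @param x A [psd] object.
#' @param probs Quantile probabilities, each strictly inside (0, 1).
#' @return Numeric vector of diameters (um), one per probability.
#' @export
psd_quantiles <- function(x, probs) {
  stopifnot_psd(x)
  if (length(probs) == 0L || any(!is.finite(probs)) ||
      any(probs <= 0) || any(probs >= 1))
    stop("'probs' must lie strictly inside (0, 1)", call. = FALSE)
  cum <- c(0, cumsum(x$volume_pct)) / 100
  # collapse duplicated cumulative values (empty bins) keeping last edge
  logd <- log(x$bin_edges)
  exp(stats::approx(cum, logd, xout = probs, ties = list("ordered", min))$y)
}

#' Size summary of a PSD: d10/d50/d90, span and specific surface area
#'
#' @inheritParams psd_quantiles
#' @param lower_cut_um Lower size cut (um) applied before the SSA computation;
#'   see [psd_ssa()]. Default 2 um, the practical resolution limit once
#'   sub-2-um fines partially dissolve in the ethanol carrier.
#' @param renormalize Passed to [psd_ssa()].
#' @return A one-row `data.frame` with columns `label`, `treatment`, `d10`,
#'   `d50`, `d90` (um), `span`, `ssa_um_inv` (um^-1), `ssa_m2_mm3`
#'   (m2 per mm3 of particle volume) and `lower_cut_um`.
#' @export
psd_summary <- function(x, lower_cut_um = 2, renormalize = TRUE) {
  stopifnot_psd(x)
  q <- psd_quantiles(x, c(0.1, 0.5, 0.9))
  s <- psd_ssa(x, lower_cut_um = lower_cut_um, renormalize = renormalize)
  data.frame(label = x$label, treatment = x$treatment,
             d10 = q[1], d50 = q[2], d90 = q[3],
             span = size_span(q[1], q[2], q[3]),
             ssa_um_inv = s, ssa_m2_mm3 = ssa_to_m2_mm3(s),
             lower_cut_um = lower_cut_um,
             row.names = NULL)
}

#' Size span of a distribution
#'
#' The span, `(d90 - d10) / d50`, is a dimensionless width of the volume
#' distribution; narrow monodisperse powders approach 0.
#'
#' @param d10,d50,d90 Volume quantile diameters (um), `d50 > 0`.
#' @return The span (dimensionless).
#' @export
#' @examples
#' size_span(10, 20, 76) # 3.3
size_span <- function(d10, d50, d90) {
  if (any(d50 <= 0)) stop("'d50' must be positive", call. = FALSE)
  (d90 - d10) / d50
}

#' Volume-specific surface area from a binned PSD
#'
#' Assuming spherical particles, a bin of volume fraction `a_i` and
#' representative diameter `D_i` contributes surface `6 a_i / D_i` per unit
#' particle volume, i.e. `SSA = 3 * sum(2 a_i / D_i)`. Bins whose
#' representative diameter falls below `lower_cut_um` are discarded first;
#' with `renormalize = TRUE` (default) the retained fractions are rescaled to
#' sum to one so that SSA values remain comparable across dispersion
#' treatments that shift volume below the cut.
#'
#' @inheritParams psd_quantiles
#' @param lower_cut_um Lower size-resolution cut in um (default 2); use 0 to
#'   keep all bins.
#' @param renormalize Rescale retained volume fractions to sum to 1 before
#'   summation (default `TRUE`); `FALSE` uses the raw retained fractions.
#' @return SSA in um^-1 (um2 of surface per um3 of particle volume). Multiply
#'   by [ssa_to_m2_mm3()]'s factor (1e-3) for m2.mm-3.
#' @export
#' @examples
#' p <- psd(c(19, 21), 100)   # monodisperse ~20 um
#' psd_ssa(p)                 # ~ 6/20 = 0.3 um^-1
psd_ssa <- function(x, lower_cut_um = 2, renormalize = TRUE) {
  stopifnot_psd(x)
  keep <- x$diameter >= lower_cut_um
  if (!any(keep & x$volume_pct > 0))
    stop("no volume above the ", lower_cut_um, " um cut", call. = FALSE)
  alpha <- x$volume_pct[keep] / 100
  if (renormalize) alpha <- alpha / sum(alpha)
  3 * sum(2 * alpha / x$diameter[keep])
}

#' Conversion of SSA from um^-1 to m2 per mm3
#'
#' 1 um^-1 = 1 um2/um3 = 1e-3 m2/mm3.
#'
#' @param ssa_um_inv SSA in um^-1.
#' @return SSA in m2.mm-3.
#' @export
ssa_to_m2_mm3 <- function(ssa_um_inv) ssa_um_inv * 1e-3

#' Re-bin a PSD onto coarse grading classes
#'
#' Sums per-bin volume into user classes (half-open intervals `[lo, hi)`).
#' A source bin straddling a class edge is apportioned by the fraction of its
#' log-width falling in each class, consistent with log-spaced instrument
#' bins. Volume outside the class grid is not counted; a grid spanning the
#' full PSD support conserves the total volume exactly.
#'
#' @inheritParams psd_quantiles
#' @param class_edges Strictly increasing class edges (um), length `m + 1`
#'   for `m` classes.
#' @return Numeric vector of per-class volume percentages, named
#'   `"[lo,hi)"`.
#' @export
#' @examples
#' p <- psd(c(6, 10, 15), c(40, 60))
#' psd_rebin(p, c(2, 5, 20, 80, 200)) # all volume in the 5-20 um class
psd_rebin <- function(x, class_edges) {
  stopifnot_psd(x)
  class_edges <- as.numeric(class_edges)
  if (length(class_edges) < 2L || any(diff(class_edges) <= 0))
    stop("'class_edges' must be strictly increasing with >= 2 edges",
         call. = FALSE)
  if (any(class_edges <= 0))
    stop("'class_edges' must be positive", call. = FALSE)
  n_class <- length(class_edges) - 1L
  lo <- log(x$bin_edges[-length(x$bin_edges)])
  hi <- log(x$bin_edges[-1])
  out <- numeric(n_class)
  for (k in seq_len(n_class)) {
    clo <- log(class_edges[k]); chi <- log(class_edges[k + 1L])
    ov <- pmax(0, pmin(hi, chi) - pmax(lo, clo)) / (hi - lo)
    out[k] <- sum(x$volume_pct * ov)
  }
  names(out) <- sprintf("[%g,%g)", class_edges[-length(class_edges)],
                        class_edges[-1])
  out
}
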