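#' Carr index from apparent and packed densities
#'
#' `Ci = 100 * (rho_p - rho_a) / rho_p`, where `rho_a` is the apparent
#' (poured) density and `rho_p` the packed (tapped) density. Powders that
#' consolidate strongly under tapping flow poorly.
#'
#' @param rho_a Apparent density, kg m-3.
#' @param rho_p Packed density, kg m-3 (`rho_p >= rho_a > 0`).
#' @return Carr index in percent.
#' @export
#' @examples
#' carr_index(380, 480) # pine bark feed powder, ~20.8 %
carr_index <- function(rho_a, rho_p) {
  if (any(rho_a <= 0) || any(rho_p <= 0))
    stop("densities must be positive", call. = FALSE)
  if (any(rho_a > rho_p))
    stop("apparent density cannot exceed packed density", call. = FALSE)
  100 * (rho_p - rho_a) / rho_p
}

#' Bed compressibility under a 15 kPa normal stress
#'
#' `Cp = 100 * (Vi - V15) / Vi`: the relative volume reduction of the powder
#' bed between its conditioned initial state and the highest normal stress of
#' the compression schedule. Only the two endpoint volumes enter the index;
#' intermediate points characterize the approach but do not change `Cp`.
#'
#' @param vi_ml Initial bed volume, mL (`> 0`).
#' @param v15_ml Bed volume at 15 kPa, mL (`0 < v15_ml <= vi_ml`).
#' @return Compressibility in percent.
#' @export
#' @examples
#' compressibility(85, 68) # 20 %
compressibility <- function(vi_ml, v15_ml) {
  if (any(vi_ml <= 0)) stop("'vi_ml' must be positive", call. = FALSE)
  if (any(v15_ml > vi_ml))
    stop("compressed volume cannot exceed the initial volume", call. = FALSE)
  if (any(v15_ml <= 0)) stop("'v15_ml' must be positive", call. = FALSE)
  100 * (vi_ml - v15_ml) / vi_ml
}

#' Compressibility from a full compression test table
#'
#' @param stress_kpa Normal stress schedule, kPa (ascending).
#' @param volume_ml Bed volume at each stress, mL (non-increasing).
#' @param vi_ml Initial (pre-stress) bed volume; defaults to the volume at
#'   the lowest stress.
#' @return Compressibility in percent, per [compressibility()], using the
#'   volume at the maximum stress as the compressed endpoint.
#' @export
compression_test_cp <- function(stress_kpa, volume_ml, vi_ml = NULL) {
  if (length(stress_kpa) != length(volume_ml) || length(stress_kpa) < 2L)
    stop("need matching stress/volume vectors with >= 2 points", call. = FALSE)
  if (any(diff(stress_kpa) <= 0))
    stop("'stress_kpa' must be strictly increasing", call. = FALSE)
  if (any(diff(volume_ml) > 1e-9))
    stop("bed volume must be non-increasing with stress", call. = FALSE)
  if (is.null(vi_ml)) vi_ml <- volume_ml[1]
  compressibility(vi_ml, volume_ml[length(volume_ml)])
}

#' Mohr-Coulomb cohesion from shear-cell failure points
#'
#' Fits the failure line `tau = Co + F * sigma` by ordinary least squares to
#' the measured (normal stress, shear stress at failure) points. The
#' intercept `Co` is the cohesion -- the shear stress needed to put the
#' unconsolidated bed into flow -- and the slope `F` the static friction
#' coefficient.
#'
#' @param sigma_kpa Normal stresses, kPa, strictly increasing.
#' @param tau_kpa Shear stresses at failure, kPa.
#' @param min_points Minimum number of points required (default 3; lower it
#'   to 2 only to exercise the closed-form two-point solution).
#' @return A list of class `cohesion_fit` with `cohesion_kpa`, `friction`,
#'   `r_squared` (`NA` when the response has zero variance) and `n`.
#' @export
#' @examples
#' s <- c(1, 1.3, 1.5, 1.7, 2)
#' cohesion_fit(s, 0.4 + 0.6 * s) # Co = 0.4, F = 0.6, r2 = 1
cohesion_fit <- function(sigma_kpa, tau_kpa, min_points = 3L) {
  if (length(sigma_kpa) != length(tau_kpa))
    stop("'sigma_kpa' and 'tau_kpa' must have the same length", call. = FALSE)
  if (length(sigma_kpa) < min_points)
    stop("need at least ", min_points, " failure points", call. = FALSE)
  if (stats::var(sigma_kpa) == 0)
    stop("zero variance in normal stress; line is undetermined", call. = FALSE)
  fit <- stats::lm(tau_kpa ~ sigma_kpa)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((tau_kpa - mean(tau_kpa))^2)
  structure(
    list(cohesion_kpa = unname(stats::coef(fit)[1]),
         friction = unname(stats::coef(fit)[2]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n = length(sigma_kpa)),
    class = "cohesion_fit")
}

#' @export
print.cohesion_fit <- function(x, ...) {
  cat(sprintf("Mohr-Coulomb fit (n = %d): Co = %.3f kPa, F = %.3f, r2 = %s\n",
              x$n, x$cohesion_kpa, x$friction,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared)))
  invisible(x)
}

#' Flowability class from the Carr index
#'
#' Maps a Carr index (in percent) onto the classical flowability bands of
#' Carr's compressibility table. The default bands follow the commonly used
#' pharmacopeial rendering, with the 21-25 % band labelled
#' `"passable (slightly poor)"`; band edges are configurable because
#' published renderings of the table differ by a few points.
#'
#' @param ci Carr index in percent, in `[0, 100]`.
#' @param bands Named numeric vector of band upper edges (inclusive), in
#'   ascending order; values above the last edge fall in the final band.
#' @return Character vector of band labels.
#' @export
#' @examples
#' flowability_class(c(10, 24.3, 27.3))
flowability_class <- function(ci,
                              bands = c("excellent" = 10,
                                        "good" = 15,
                                        "fair" = 20,
                                        "passable (slightly poor)" = 25,
                                        "poor" = 31,
                                        "very poor" = 37,
                                        "very, very poor" = 100)) {
  if (any(!is.finite(ci)) || any(ci < 0) || any(ci > 100))
    stop("'ci' must lie in [0, 100]", call. = FALSE)
  if (is.null(names(bands)) || any(diff(bands) <= 0))
    stop("'bands' must be named ascending upper edges", call. = FALSE)
  idx <- findInterval(ci, bands, left.open = TRUE) + 1L
  idx[idx > length(bands)] <- length(bands)
  names(bands)[idx]
}
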