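#' @name synthetic-data
#' @title Synthetic instrument-export generator
#' @description
#' Generates every input the pipeline consumes -- binned PSDs, dispersion
#' triplets with planted soft/hard agglomeration, particle silhouettes, and
#' rheology tables -- with known ground truth, so each downstream stage can
#' be verified in a closed loop. Generation is purely statistical: no
#' milling, ultrasound-cavitation or diffraction physics is simulated.
#' All randomness flows through explicit `seed` arguments; the global RNG
#' state is saved and restored around every draw.
NULL

# run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Default laser-granulometer bin grid
#'
#' 100 log-spaced bins over 0.1-2000 um, mimicking the decade-spanning
#' export grid of laser-diffraction instruments.
#'
#' @param n_bins Number of bins (default 100).
#' @param lo,hi Grid limits in um.
#' @return Vector of `n_bins + 1` bin edges.
#' @export
default_bin_grid <- function(n_bins = 100, lo = 0.1, hi = 2000) {
  exp(seq(log(lo), log(hi), length.out = n_bins + 1))
}

#' Specification of a (possibly multimodal) lognormal PSD
#'
#' @param modes A data.frame (or matrix) with columns `gm` (geometric mean,
#'   um), `gsd` (geometric standard deviation, > 1) and `weight` (mode volume
#'   fractions, summing to 1).
#' @param bin_edges Bin grid (um), default [default_bin_grid()].
#' @return An object of class `psd_spec`.
#' @export
psd_spec <- function(modes, bin_edges = default_bin_grid()) {
  modes <- as.data.frame(modes)
  if (nrow(modes) == 0L || !all(c("gm", "gsd", "weight") %in% names(modes)))
    stop("'modes' needs columns gm, gsd, weight", call. = FALSE)
  if (any(modes$gm <= 0) || any(modes$gsd <= 1) || any(modes$weight <= 0))
    stop("mode parameters must be positive (gsd > 1)", call. = FALSE)
  if (abs(sum(modes$weight) - 1) > 1e-8)
    stop("mode weights must sum to 1", call. = FALSE)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be strictly increasing", call. = FALSE)
  if (any(modes$gm < min(bin_edges)) || any(modes$gm > max(bin_edges)))
    stop("mode geometric means must lie inside the bin grid", call. = FALSE)
  structure(list(modes = modes, bin_edges = as.numeric(bin_edges)),
            class = "psd_spec")
}

#' Built-in PSD templates for the bark/straw milling study
#'
#' * `"bark_feed"`: bimodal impact-milled pine bark feed, equal-height modes
#'   centred on 40 um and 225 um;
#' * `"straw_feed"`: unimodal impact-milled wheat straw feed with a 280 um
#'   median and a small fines drag near 35 um;
#' * `"bark_fine"` / `"straw_fine"`: ultrafine ball-milled powders with a
#'   ~20 um median; the bark powder keeps a damped bimodality, the straw
#'   powder a single broad mode (wider span).
#'
#' @param name Template name.
#' @return A [psd_spec()].
#' @export
psd_template <- function(name = c("bark_feed", "straw_feed",
                                  "bark_fine", "straw_fine")) {
  name <- match.arg(name)
  modes <- switch(name,
    bark_feed = data.frame(gm = c(40, 225), gsd = c(1.8, 1.5),
                           weight = c(0.5, 0.5)),
    straw_feed = data.frame(gm = c(35, 280), gsd = c(1.6, 2.0),
                            weight = c(0.05, 0.95)),
    bark_fine = data.frame(gm = c(7, 32), gsd = c(1.9, 1.9),
                           weight = c(0.3, 0.7)),
    straw_fine = data.frame(gm = 20, gsd = 3.1, weight = 1))
  psd_spec(modes)
}

#' Generate a binned PSD from a lognormal-mixture specification
#'
#' Bin volumes are the exact mixture-CDF increments over the bin grid,
#' multiplied by seeded lognormal measurement noise and renormalized to
#' 100 %. With `noise_sd = 0` the output is fully deterministic.
#'
#' @param spec A [psd_spec()].
#' @param seed Integer seed (required; generation never touches the global
#'   RNG stream).
#' @param label,treatment Passed to [psd()].
#' @param noise_sd Standard deviation of the multiplicative log-noise per bin
#'   (default 0.05, a mild instrument-repeatability level).
#' @return A [psd] object.
#' @export
#' @examples
#' p <- generate_psd(psd_template("bark_feed"), seed = 1, label = "IM_bark")
generate_psd <- function(spec, seed, label = "", treatment = "dry",
                         noise_sd = 0.05) {
  if (!inherits(spec, "psd_spec")) stop("expected a 'psd_spec'", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  edges <- spec$bin_edges
  vol <- rep(0, length(edges) - 1L)
  for (k in seq_len(nrow(spec$modes))) {
    cdf <- stats::plnorm(edges, meanlog = log(spec$modes$gm[k]),
                         sdlog = log(spec$modes$gsd[k]))
    vol <- vol + spec$modes$weight[k] * diff(cdf)
  }
  if (noise_sd > 0)
    vol <- with_seed(seed, vol * exp(stats::rnorm(length(vol), 0, noise_sd)))
  psd(edges, vol, label = label, treatment = treatment, normalize = TRUE)
}

#' Plan for planting soft/hard agglomeration into a synthetic powder
#'
#' @param soft_fraction,hard_fraction Planted fractions (of the fully
#'   dispersed SSA) in `[0, 1)`, summing to less than 1.
#' @param donor_ranges Two-column matrix of size ranges (um) supplying fines
#'   (default 2-5 and 5-20 um).
#' @param acceptor_ranges Size ranges receiving agglomerated volume (default
#'   20-80 and 80-200 um); must not overlap the donors.
#' @return An object of class `agglomeration_plan`.
#' @export
agglomeration_plan <- function(soft_fraction, hard_fraction,
                               donor_ranges = rbind(c(2, 5), c(5, 20)),
                               acceptor_ranges = rbind(c(20, 80), c(80, 200))) {
  if (soft_fraction < 0 || hard_fraction < 0 ||
      soft_fraction + hard_fraction >= 1)
    stop("fractions must be >= 0 with soft + hard < 1", call. = FALSE)
  donor_ranges <- as.matrix(donor_ranges)
  acceptor_ranges <- as.matrix(acceptor_ranges)
  lo_d <- min(donor_ranges); hi_d <- max(donor_ranges)
  lo_a <- min(acceptor_ranges); hi_a <- max(acceptor_ranges)
  if (max(lo_d, lo_a) < min(hi_d, hi_a) && !(hi_d <= lo_a || hi_a <= lo_d))
    stop("donor and acceptor ranges must be disjoint", call. = FALSE)
  structure(list(soft_fraction = soft_fraction, hard_fraction = hard_fraction,
                 donor_ranges = donor_ranges,
                 acceptor_ranges = acceptor_ranges),
            class = "agglomeration_plan")
}

# logical index of bins lying wholly inside any of the size ranges (whole-bin
# containment keeps planted volume transfers inside the grading-class grid)
bins_in_ranges <- function(psd, ranges) {
  lo <- psd$bin_edges[-length(psd$bin_edges)]
  hi <- psd$bin_edges[-1]
  sel <- rep(FALSE, length(lo))
  for (r in seq_len(nrow(ranges)))
    sel <- sel | (lo >= ranges[r, 1] & hi <= ranges[r, 2])
  sel
}

# move a fraction `t` of the donor-bin volume into the acceptor bins
# (proportionally to the truth's acceptor profile); conserves total volume
move_volume <- function(truth, t, donors, acceptors) {
  vol <- truth$volume_pct
  moved <- t * vol[donors]
  vol[donors] <- vol[donors] - moved
  prof <- truth$volume_pct[acceptors]
  prof <- if (sum(prof) > 0) prof / sum(prof) else
    rep(1 / sum(acceptors), sum(acceptors))
  vol[acceptors] <- vol[acceptors] + sum(moved) * prof
  vol
}

#' Plant known soft/hard agglomeration into a deagglomeration triplet
#'
#' Constructs the ND/LG/EP triplet whose SSA accounting recovers the planted
#' fractions exactly. The fully dispersed state (EP) is the supplied ground
#' truth. Agglomeration is modelled purely as volume transfer: fines from the
#' donor classes are moved into coarse acceptor classes (conserving total
#' volume), lowering the SSA. The transfer amounts are solved so that
#' `SSA_LG = (1 - hard) * SSA_EP` and `SSA_ND = (1 - hard - soft) * SSA_EP`,
#' with SSA computed under the same lower-cut/renormalization options the
#' analysis uses.
#'
#' @param truth A normalized [psd] -- the fully dispersed distribution.
#' @param plan An [agglomeration_plan()].
#' @param lower_cut_um,renormalize SSA options, see [psd_ssa()].
#' @return A [deagglomeration_triplet()] whose `ep` equals `truth`.
#' @export
#' @examples
#' tr <- plant_agglomeration(
#'   generate_psd(psd_template("bark_fine"), seed = 1, label = "demo"),
#'   agglomeration_plan(0.10, 0.10))
#' soft_hard(tr) # recovers soft 0.10, hard 0.10
plant_agglomeration <- function(truth, plan, lower_cut_um = 2,
                                renormalize = TRUE) {
  stopifnot_psd(truth)
  if (!inherits(plan, "agglomeration_plan"))
    stop("expected an 'agglomeration_plan'", call. = FALSE)
  donors <- bins_in_ranges(truth, plan$donor_ranges)
  acceptors <- bins_in_ranges(truth, plan$acceptor_ranges)
  if (!any(donors & truth$volume_pct > 0))
    stop("no donor volume available in the donor size ranges", call. = FALSE)
  ssa_ep <- psd_ssa(truth, lower_cut_um, renormalize)
  solve_t <- function(target_ssa) {
    f <- function(t) {
      p <- psd(truth$bin_edges, move_volume(truth, t, donors, acceptors),
               normalize = FALSE)
      psd_ssa(p, lower_cut_um, renormalize) - target_ssa
    }
    if (f(1) > 0)
      stop("plan fractions too large to realize from the available ",
           "donor-class volume", call. = FALSE)
    if (target_ssa >= ssa_ep) return(0)
    stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  }
  t_lg <- solve_t((1 - plan$hard_fraction) * ssa_ep)
  t_nd <- solve_t((1 - plan$hard_fraction - plan$soft_fraction) * ssa_ep)
  mk <- function(t, treatment) {
    psd(truth$bin_edges, move_volume(truth, t, donors, acceptors),
        label = truth$label, treatment = treatment, normalize = FALSE)
  }
  deagglomeration_triplet(
    nd = mk(t_nd, "ND"), lg = mk(t_lg, "LG"),
    ep = psd(truth$bin_edges, truth$volume_pct, label = truth$label,
             treatment = "EP", normalize = FALSE),
    lower_cut_um = lower_cut_um, renormalize = renormalize)
}

#' Specification of a synthetic particle-shape population
#'
#' @param n_particles Number of silhouettes to draw.
#' @param diameter_meanlog,diameter_sdlog Lognormal law of the equivalent
#'   spherical diameter (um).
#' @param elongation_shape1,elongation_shape2 Beta law of the elongation on
#'   `[0, 1)`; use [elongation_beta_for_median()] to target a median.
#' @param roughness Boundary-perturbation amplitude as a fraction of the
#'   local radius, `>= 0` (0 gives smooth ellipses).
#' @param n_vertices Polygon resolution (default 96 vertices).
#' @return An object of class `shape_population_spec`.
#' @export
shape_population_spec <- function(n_particles,
                                  diameter_meanlog = log(20),
                                  diameter_sdlog = 0.5,
                                  elongation_shape1 = 2,
                                  elongation_shape2 = 3.7,
                                  roughness = 0,
                                  n_vertices = 96L) {
  if (n_particles < 1L) stop("'n_particles' must be >= 1", call. = FALSE)
  if (roughness < 0) stop("'roughness' must be >= 0", call. = FALSE)
  if (roughness >= 1) stop("'roughness' must be < 1 (radii stay positive)",
                           call. = FALSE)
  if (elongation_shape1 <= 0 || elongation_shape2 <= 0)
    stop("beta parameters must be positive", call. = FALSE)
  if (n_vertices < 8L) stop("'n_vertices' must be >= 8", call. = FALSE)
  structure(list(n_particles = as.integer(n_particles),
                 diameter_meanlog = diameter_meanlog,
                 diameter_sdlog = diameter_sdlog,
                 elongation_shape1 = elongation_shape1,
                 elongation_shape2 = elongation_shape2,
                 roughness = roughness,
                 n_vertices = as.integer(n_vertices)),
            class = "shape_population_spec")
}

#' Beta shape2 parameter matching a target median elongation
#'
#' With `shape1` fixed, solves for the `shape2` of a Beta law whose median
#' equals the target (e.g. 0.33 for bark feed particles, 0.55 for straw).
#'
#' @param median_elongation Target median in (0, 1).
#' @param shape1 Fixed first Beta parameter (default 2).
#' @return The `shape2` value.
#' @export
elongation_beta_for_median <- function(median_elongation, shape1 = 2) {
  if (median_elongation <= 0 || median_elongation >= 1)
    stop("'median_elongation' must be in (0, 1)", call. = FALSE)
  stats::uniroot(function(b) stats::qbeta(0.5, shape1, b) - median_elongation,
                 c(0.05, 200), tol = 1e-10)$root
}

# ellipse radius at polar angle phi for semi-axes a >= b
ellipse_radius <- function(phi, a, b) {
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

#' Generate synthetic particle silhouettes
#'
#' Each particle is an ellipse with axis ratio `1 - e` (so its measured
#' elongation equals the drawn `e`), scaled to the drawn equivalent
#' spherical diameter, optionally roughened by a smooth periodic radial
#' perturbation (a few random harmonics, amplitude `roughness` of the local
#' radius), randomly rotated and translated. Radial perturbation of a
#' star-shaped boundary keeps every polygon simple.
#'
#' @param spec A [shape_population_spec()].
#' @param seed Integer seed.
#' @return A list of `n_particles` polygons (`n_vertices x 2` matrices, um)
#'   with the drawn `esd` and `elongation` attached as attributes `truth`
#'   (a `data.frame`).
#' @export
generate_shapes <- function(spec, seed) {
  if (!inherits(spec, "shape_population_spec"))
    stop("expected a 'shape_population_spec'", call. = FALSE)
  with_seed(seed, {
    n <- spec$n_particles
    esd <- stats::rlnorm(n, spec$diameter_meanlog, spec$diameter_sdlog)
    elo <- stats::rbeta(n, spec$elongation_shape1, spec$elongation_shape2)
    elo <- pmin(elo, 0.98)
    rot <- stats::runif(n, 0, pi)
    phi <- seq(0, 2 * pi, length.out = spec$n_vertices + 1L)[-1L]
    polys <- vector("list", n)
    for (i in seq_len(n)) {
      ratio <- 1 - elo[i]                       # b / a
      a <- 1; b <- ratio
      r <- ellipse_radius(phi, a, b)
      if (spec$roughness > 0) {
        # mid-frequency harmonics roughen the perimeter without denting the
        # hull much; roughness 0.18 yields convexity near 0.85-0.90
        nh <- 6L
        amp <- stats::runif(nh, 0.3, 1)
        ph <- stats::runif(nh, 0, 2 * pi)
        g <- rowSums(vapply(seq_len(nh),
                            function(h) amp[h] * cos((h + 7) * phi + ph[h]),
                            numeric(length(phi))))
        g <- g / max(abs(g))
        r <- r * (1 + spec$roughness * g)
      }
      x <- r * cos(phi); y <- r * sin(phi)
      # rescale so the polygon area matches the drawn esd
      s <- (esd[i] / 2) * sqrt(pi / abs(polygon_area(cbind(x, y))))
      x <- x * s; y <- y * s
      cs <- cos(rot[i]); sn <- sin(rot[i])
      polys[[i]] <- cbind(x * cs - y * sn, x * sn + y * cs)
    }
    attr(polys, "truth") <- data.frame(esd = esd, elongation = elo)
    polys
  })
}

#' Generate a synthetic shear test with known cohesion
#'
#' `tau_i = cohesion + friction * sigma_i + eps_i`, with iid Gaussian noise
#' of standard deviation `noise_sd_kpa`.
#'
#' @param cohesion_kpa True cohesion (kPa).
#' @param friction True static friction coefficient.
#' @param noise_sd_kpa Noise standard deviation (kPa), `>= 0`.
#' @param stresses_kpa Normal stress schedule (kPa), at least 2 points
#'   (default the 1-2 kPa consolidation schedule `1, 1.3, 1.5, 1.7, 2`).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `sigma_kpa`, `tau_kpa`.
#' @export
generate_shear_test <- function(cohesion_kpa, friction, noise_sd_kpa,
                                stresses_kpa = c(1, 1.3, 1.5, 1.7, 2),
                                seed = 1) {
  if (noise_sd_kpa < 0) stop("'noise_sd_kpa' must be >= 0", call. = FALSE)
  if (length(stresses_kpa) < 2L)
    stop("need at least 2 normal stresses (a 1-point shear test cannot ",
         "determine a failure line)", call. = FALSE)
  if (any(stresses_kpa <= 0))
    stop("'stresses_kpa' must be positive", call. = FALSE)
  eps <- if (noise_sd_kpa > 0)
    with_seed(seed, stats::rnorm(length(stresses_kpa), 0, noise_sd_kpa))
  else rep(0, length(stresses_kpa))
  data.frame(sigma_kpa = stresses_kpa,
             tau_kpa = cohesion_kpa + friction * stresses_kpa + eps)
}

#' Generate a synthetic bed-compression test
#'
#' A saturating volume decline from `vi_ml` to the endpoint implied by the
#' target compressibility: `V(s) = V15 + (Vi - V15) * ((smax - s) /
#' (smax - smin))^2` over the standard 0.5-15 kPa schedule.
#'
#' @param vi_ml Initial bed volume (mL).
#' @param cp_pct Target compressibility in percent.
#' @param stresses_kpa Stress schedule (default `0.5, 1, 2, 4, 6, 8, 10, 12,
#'   15` kPa).
#' @return A `data.frame` with columns `stress_kpa`, `volume_ml`.
#' @export
generate_compression_test <- function(vi_ml, cp_pct,
                                      stresses_kpa = c(0.5, 1, 2, 4, 6, 8,
                                                       10, 12, 15)) {
  if (vi_ml <= 0) stop("'vi_ml' must be positive", call. = FALSE)
  if (cp_pct < 0 || cp_pct >= 100)
    stop("'cp_pct' must be in [0, 100)", call. = FALSE)
  v15 <- vi_ml * (1 - cp_pct / 100)
  s <- stresses_kpa
  frac <- ((max(s) - s) / (max(s) - min(s)))^2
  data.frame(stress_kpa = s, volume_ml = v15 + (vi_ml - v15) * frac)
}

#' Density pair realizing a target Carr index
#'
#' @param rho_a Apparent density (kg m-3).
#' @param ci_pct Target Carr index (percent, `< 100`).
#' @return A `data.frame` with `rho_a`, `rho_p`.
#' @export
density_pair_for_carr <- function(rho_a, ci_pct) {
  if (rho_a <= 0 || ci_pct < 0 || ci_pct >= 100)
    stop("invalid density or Carr index", call. = FALSE)
  data.frame(rho_a = rho_a, rho_p = rho_a / (1 - ci_pct / 100))
}
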