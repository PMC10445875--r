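#' Deagglomeration triplet: ND / LG / EP distributions of one powder
#'
#' Bundles the three wet-dispersion PSD measurements used to quantify
#' agglomeration: `nd` (no ultrasound), `lg` (granulometer-embedded
#' ultrasonic probe) and `ep` (more powerful external probe). The specific
#' surface areas of the three states are computed on construction; dispersing
#' agglomerates frees surface, so `SSA <= SSA_LG <= SSA_EP` is expected and
#' violations (possible with noisy data) are reported as warnings.
#'
#' @param nd,lg,ep [psd] objects sharing an identical bin grid.
#' @param lower_cut_um,renormalize SSA options, see [psd_ssa()].
#' @return An object of class `deagglomeration_triplet` with elements `nd`,
#'   `lg`, `ep`, `ssa`, `ssa_lg`, `ssa_ep`, `lower_cut_um`, `renormalize`.
#' @export
deagglomeration_triplet <- function(nd, lg, ep, lower_cut_um = 2,
                                    renormalize = TRUE) {
  for (p in list(nd, lg, ep)) stopifnot_psd(p)
  if (!isTRUE(all.equal(nd$bin_edges, lg$bin_edges)) ||
      !isTRUE(all.equal(nd$bin_edges, ep$bin_edges)))
    stop("ND, LG and EP distributions must share the same bin grid",
         call. = FALSE)
  ssa <- psd_ssa(nd, lower_cut_um, renormalize)
  ssa_lg <- psd_ssa(lg, lower_cut_um, renormalize)
  ssa_ep <- psd_ssa(ep, lower_cut_um, renormalize)
  tol <- 1e-9
  if (ssa > ssa_lg + tol || ssa_lg > ssa_ep + tol)
    warning("unexpected SSA ordering (expected SSA <= SSA_LG <= SSA_EP); ",
            "treat soft/hard values with caution", call. = FALSE)
  structure(
    list(nd = nd, lg = lg, ep = ep,
         ssa = ssa, ssa_lg = ssa_lg, ssa_ep = ssa_ep,
         lower_cut_um = lower_cut_um, renormalize = renormalize),
    class = "deagglomeration_triplet")
}

#' @export
print.deagglomeration_triplet <- function(x, ...) {
  cat(sprintf("Deagglomeration triplet '%s'\n", x$nd$label))
  cat(sprintf("  SSA    %.4g um^-1 (ND)\n  SSA_LG %.4g um^-1\n  SSA_EP %.4g um^-1\n",
              x$ssa, x$ssa_lg, x$ssa_ep))
  invisible(x)
}

#' Soft and hard agglomeration fractions from an SSA triplet
#'
#' Mild (granulometer probe) ultrasound disperses only weakly bound, "soft"
#' agglomerates; the stronger external probe also breaks "hard" ones. Both
#' fractions are expressed relative to the fully dispersed surface `SSA_EP`:
#'
#' * soft  = (SSA_LG - SSA)   / SSA_EP
#' * hard  = (SSA_EP - SSA_LG) / SSA_EP  (default reading)
#' * total = soft + hard = (SSA_EP - SSA) / SSA_EP
#'
#' With `hard_mode = "total_deficit"` the hard fraction is instead computed
#' as `(SSA_EP - SSA)/SSA_EP`, i.e. the whole deficit; under that reading
#' "soft + hard" double-counts the soft share, so the complementary default
#' is used unless you have a reason to prefer the raw deficit.
#'
#' Small negative fractions arising from measurement noise (SSA ordering
#' violations) are clamped to 0 with a warning.
#'
#' @param triplet A [deagglomeration_triplet].
#' @param hard_mode `"complement"` (default) or `"total_deficit"`, see above.
#' @return A list of class `agglomeration_result` with `soft`, `hard`,
#'   `total` (fractions of the fully dispersed surface) and the three SSA
#'   values.
#' @export
#' @examples
#' grid <- c(10, 20, 40, 80)
#' tr <- deagglomeration_triplet(
#'   psd(grid, c(20, 50, 30), treatment = "ND"),
#'   psd(grid, c(30, 45, 25), treatment = "LG"),
#'   psd(grid, c(40, 40, 20), treatment = "EP"))
#' soft_hard(tr)
soft_hard <- function(triplet, hard_mode = c("complement", "total_deficit")) {
  if (!inherits(triplet, "deagglomeration_triplet"))
    stop("expected a 'deagglomeration_triplet'", call. = FALSE)
  hard_mode <- match.arg(hard_mode)
  if (triplet$ssa_ep <= 0) stop("SSA_EP must be positive", call. = FALSE)
  soft <- (triplet$ssa_lg - triplet$ssa) / triplet$ssa_ep
  hard <- switch(hard_mode,
                 complement = (triplet$ssa_ep - triplet$ssa_lg) / triplet$ssa_ep,
                 total_deficit = (triplet$ssa_ep - triplet$ssa) / triplet$ssa_ep)
  if (soft < 0 || hard < 0) {
    warning("negative agglomeration fraction clamped to 0 ",
            "(SSA ordering violation)", call. = FALSE)
    soft <- max(0, soft); hard <- max(0, hard)
  }
  structure(
    list(label = triplet$nd$label, soft = soft, hard = hard,
         total = soft + if (hard_mode == "complement") hard else
           (hard - soft),
         hard_mode = hard_mode,
         ssa = triplet$ssa, ssa_lg = triplet$ssa_lg, ssa_ep = triplet$ssa_ep),
    class = "agglomeration_result")
}

#' @export
print.agglomeration_result <- function(x, ...) {
  cat(sprintf("Agglomeration of '%s': soft %.1f%%, hard %.1f%%, total %.1f%%\n",
              x$label, 100 * x$soft, 100 * x$hard, 100 * x$total))
  invisible(x)
}

#' Size-class shift analysis across deagglomeration treatments
#'
#' Population-balance style accounting: the volume weight of each grading
#' class (default 2-5, 5-20, 20-80 and 80-200 um) is computed for the ND, LG
#' and EP states, and pairwise differences locate which classes lose or gain
#' volume as agglomerates are dispersed. `LG - ND` is the shift released by
#' mild ultrasound (soft agglomerates), `EP - LG` the additional shift under
#' the external probe (hard agglomerates). Because dispersion only moves
#' volume between classes, each difference column sums to zero (up to the
#' volume excluded by the class grid).
#'
#' @param triplet A [deagglomeration_triplet].
#' @param class_edges Grading class edges in um; default `c(2, 5, 20, 80,
#'   200)`. Classes are half-open `[lo, hi)`; ultrafine powders carry no
#'   volume above 200 um so no open top class is added.
#' @return A `data.frame` with one row per class and columns `class`,
#'   `nd`, `lg`, `ep` (volume %), `soft_shift` (`lg - nd`), `hard_shift`
#'   (`ep - lg`) and `total_shift` (`ep - nd`).
#' @export
class_shift <- function(triplet, class_edges = c(2, 5, 20, 80, 200)) {
  if (!inherits(triplet, "deagglomeration_triplet"))
    stop("expected a 'deagglomeration_triplet'", call. = FALSE)
  support <- range(triplet$nd$bin_edges)
  if (min(class_edges) < support[1] || max(class_edges) > support[2])
    stop("class edges fall outside the PSD bin support (",
         format(support[1]), "-", format(support[2]), " um)", call. = FALSE)
  v_nd <- psd_rebin(triplet$nd, class_edges)
  v_lg <- psd_rebin(triplet$lg, class_edges)
  v_ep <- psd_rebin(triplet$ep, class_edges)
  data.frame(class = names(v_nd),
             nd = unname(v_nd), lg = unname(v_lg), ep = unname(v_ep),
             soft_shift = unname(v_lg - v_nd),
             hard_shift = unname(v_ep - v_lg),
             total_shift = unname(v_ep - v_nd),
             row.names = NULL)
}
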