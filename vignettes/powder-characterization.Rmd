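---
title: "Characterizing ball-milled biomass powders: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing ball-milled biomass powders: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powdermetrics)
```

## The problem

Ultrafine dry milling turns lignocellulosic feedstocks (pine bark, wheat
straw, and similar materials) into powders with median particle sizes around
20 µm. Whether such a powder is "good" for an application — a biocomposite
filler, a biofuel feedstock, a substrate for chemistry — depends on far more
than its median size: the width of the size distribution, the surface area
actually accessible (agglomerates hide surface), the shape of the particles,
and the powder's flow behaviour all matter, and all depend jointly on the
biomass and on the dominant mechanical force (impact vs attrition) of the
mill that produced the powder.

`powdermetrics` implements the complete measurement-analysis chain for such
powders, from raw instrument exports (laser-granulometer size distributions,
imaging-derived particle silhouettes, powder-rheometer tables) to a single
multi-criteria quality ranking. Because the raw instrument data cannot be
bundled with a package, a synthetic-data generator with known ground truth
reproduces the statistical structure of each export, so every stage of the
chain is verifiable in a closed loop.

## Size statistics

A measured PSD arrives as volume percentages on log-spaced size bins. The
representative diameter of a bin is the geometric mean of its edges
(appropriate for log-spaced grids), and quantiles (d10, d50, d90) are read
off the cumulative volume curve by linear interpolation in log-diameter.
Interpolating in log space rather than linear space is the standard
treatment for laser-diffraction data and is frozen here so that results are
bit-for-bit reproducible. The distribution width is summarized by the span,

$$\mathrm{span} = \frac{d_{90} - d_{10}}{d_{50}},$$

and the volume-specific surface area assumes spherical particles:

$$\mathrm{SSA} = 3 \sum_i \frac{2\,\alpha_i}{D_i},$$

with $\alpha_i$ the volume fraction and $D_i$ the representative diameter of
bin $i$. SSA is held in µm⁻¹ internally; the m²·mm⁻³ figure customarily
reported by granulometer software is exactly 10⁻³ times the µm⁻¹ value, and
both columns are written to output files because unit slips are the main
practical failure mode of this quantity.

**The 2 µm cut.** Sub-2-µm bark fines partially dissolve in the ethanol used
as the wet-dispersion carrier, so sizes below 2 µm are unreliable and all
SSA computations discard bins below a configurable cut (default 2 µm). After
the cut the retained fractions are renormalized to sum to one by default, so
that SSA values remain comparable across dispersion treatments that move
volume across the cut; the raw (non-renormalized) mode is available via
`renormalize = FALSE` for sensitivity analysis, since the choice is a
genuine methodological fork and published practice does not pin it down.

## Soft and hard agglomeration

Fine biomass particles agglomerate: weakly bound ("soft") clusters disperse
under mild ultrasound, strongly bound ("hard") ones only under a more
powerful external probe. Measuring the same suspension three times — not
deagglomerated (ND), after the granulometer's internal probe (LG), and after
the external probe (EP) — yields three SSAs with expected ordering
$\mathrm{SSA} \le \mathrm{SSA}_{LG} \le \mathrm{SSA}_{EP}$, and the
agglomeration fractions are defined relative to the fully dispersed surface:

$$\mathrm{soft} = \frac{\mathrm{SSA}_{LG} - \mathrm{SSA}}{\mathrm{SSA}_{EP}},
\qquad
\mathrm{hard} = \frac{\mathrm{SSA}_{EP} - \mathrm{SSA}_{LG}}{\mathrm{SSA}_{EP}}.$$

**Design choice (hard fraction).** The hard fraction is defined as the
*additional* surface released by the external probe, so that soft + hard
equals the total deficit $(\mathrm{SSA}_{EP} - \mathrm{SSA}) /
\mathrm{SSA}_{EP}$ — the only reading under which "total agglomeration
(soft + hard)" is self-consistent. The alternative convention, where the
"hard" figure is the whole deficit, is exposed as
`soft_hard(..., hard_mode = "total_deficit")`.

Noise can violate the SSA ordering and produce small negative fractions;
these are clamped to zero with a warning, because a negative agglomeration
fraction is a data-quality event, not a result.

**Size-class shifts.** A population-balance style accounting locates the
agglomerates: volume weights are summed over the grading classes 2–5, 5–20,
20–80 and 80–200 µm (half-open intervals; ultrafine powders carry no volume
above 200 µm) for each of ND/LG/EP, and the pairwise differences LG−ND
(soft shift) and EP−LG (hard shift) show which classes gain or lose volume
on dispersion. Since dispersion only moves volume between classes, each
difference vector sums to zero — a conservation invariant the test suite
checks to 10⁻⁶.

## Particle shape

Each particle silhouette is a simple polygon in µm. The descriptors are

* equivalent spherical diameter (esd): diameter of the circle with the
  silhouette's area;
* elongation $= 1 - W/L$: 0 for round or cubic particles, → 1 for needles;
* convexity: convex-hull perimeter over particle perimeter, 1 for smooth
  convex outlines.

**Design choice (L and W).** "Length" and "width" are operationally defined
here as the extents of the silhouette along and perpendicular to its
principal axis, computed from the second area moments of the polygon. This
is the convention of automated imaging instruments and it gives the expected
values on the canonical shapes — a 100 × 50 rectangle has elongation 0.5, a
square 0, a 2:1 ellipse 0.5. A maximum-Feret-based definition (L = largest
vertex distance, W = extent perpendicular to it) was considered and
rejected: it assigns a 100 × 50 rectangle an elongation of 0.2, which
contradicts both intuition and instrument output. All descriptors are
rotation- and translation-invariant (tested at 10⁻⁶) and behave correctly
under scaling.

**Volume weighting.** Imaging sees each particle once, but the reference
statistics are volume-weighted; each particle is therefore weighted
proportionally to esd³ (the sphere volume of its area-equivalent diameter).
This is the simplest defensible 2-D→3-D proxy and is stated as an
assumption: thin platelets weigh more under esd³ than their true volume
would warrant.

**Protocols.** Coarse feed powders imaged with a single low-magnification
lens keep only particles with esd > 4.5 µm (fewer pixels give unreliable
factors; the boundary value itself is excluded). Ultrafine powders are
imaged with two lenses — fine particles (< 20 µm) at high magnification,
coarse (> 20 µm) at lower magnification — and the halves are merged by
renormalizing each to 50 % of the total volume, which is exact when the
boundary sits at the powder's median size. The merge refuses empty or
overlapping halves, as the 50/50 construction is undefined there.

Medians of weighted distributions use the mass-midpoint convention
(interpolating between cumulative masses $c_i - w_i/2$), which is exact for
symmetric distributions and returns the unique value of a degenerate one.

## Rheology

Three standard indices, all computed from plain-text rheometer exports:

* Carr index $C_i = 100\,(\rho_p - \rho_a)/\rho_p$ from the apparent/packed
  density pair, mapped to the classical flowability bands (band edges
  configurable, since published renderings of the Carr table differ by a few
  points);
* compressibility $C_p = 100\,(V_i - V_{15})/V_i$ from the bed volume under
  a 0.5–15 kPa normal-stress ramp — only the endpoints enter the index, the
  intermediate points being retained as metadata;
* cohesion, the intercept of the Mohr–Coulomb failure line
  $\tau = C_o + F\sigma$ fitted by ordinary least squares to the
  shear-cell failure points over the 1–2 kPa consolidation schedule
  (1, 1.3, 1.5, 1.7, 2 kPa by default; the schedule is configurable because
  instrument protocols vary). Plain OLS is used deliberately: with five
  nearly evenly spaced stresses there is nothing to gain from weighting.

## Multi-criteria quality ranking

A "good" powder has low span, high SSA, low elongation, little
agglomeration, low compressibility and weak cohesion. Raw indicators are
made comparable by inverting the lower-is-better ones (1/value) and dividing
every transformed column by its maximum over the powder set, so the best
powder on each indicator scores exactly 1. Each powder's profile is drawn as
a radar polygon on equally spaced axes and its area,

$$A = \tfrac12 \sin\tfrac{2\pi}{n} \sum_i r_i\, r_{i+1 \bmod n},$$

summarizes all-round quality; powders are ranked by area relative to the
best (100 %). Radar areas depend on the axis ordering — a permutation test
in the suite demonstrates this — so the axis order is frozen (span, SSA,
elongation, agglomeration, compressibility, cohesion) and any externally
supplied process-efficiency indicators (energy utilization, productivity,
surface production rate) are appended after it. Per-indicator weights are
supported with equal weights as default. Ties in area are broken
alphabetically by powder identifier.

## The synthetic study

`simulate_study()` writes a complete six-powder study — three mills (rotary
RBM, stirred SBM, vibratory VBM) × two biomasses (bark, straw) — in the
exact CSV dialects the pipeline reads. Its defaults are the study
conditions, chosen once from the reference measurements shipped with the
package and from the qualitative structure of such studies:

* **PSDs**: 100 log-spaced bins over 0.1–2000 µm. Feed templates: bark
  bimodal with equal-height modes at 40 and 225 µm; straw unimodal with a
  280 µm median. Ultrafine templates: ~20 µm median, bark narrower
  (damped bimodality at 7/32 µm) than straw (single broad mode); VBM
  powders carry more fines, as attrition erodes surfaces.
* **Agglomeration**: planted per powder as volume transfer from donor fines
  classes (2–5, 5–20 µm) into coarse acceptor classes (20–80, 80–200 µm),
  conserving volume; transfer amounts are solved (by root finding on the
  SSA) so the planted soft/hard fractions are recovered exactly by the
  analysis. Planted levels: bark 14–22 % total with the VBM hard-dominated
  (> 50 % of total), straw 4–12 % with very little agglomeration in the
  SBM. The generator treats agglomeration purely as inter-class volume
  transfer; whether fines coat or cement the coarse particles is not
  modelled, as no measurement here could distinguish the two.
* **Shapes**: ellipses with Beta-distributed elongation (medians: bark
  ~0.35 at all mills; straw 0.39–0.45 fine side, 0.50–0.62 coarse side,
  highest for the VBM), lognormal esd, roughened by mid-frequency radial
  harmonics whose amplitude 0.18 yields median convexity near 0.85–0.90.
  Radial perturbation of a star-shaped boundary keeps every polygon simple
  by construction. Note a deliberate measurement realism: roughness widens
  particles perpendicular to their main axis, so measured elongation
  medians sit slightly below the drawn Beta medians, exactly as pixel-level
  roughness biases instrument elongations; closed-loop law checks therefore
  use smooth (roughness 0) populations.
* **Rheology**: density pairs, compression curves and shear tests generated
  from the per-mill reference indices, with Gaussian shear noise of
  0.01 kPa — a realistic repeatability level at which the fitted cohesion
  still recovers the truth to ~0.014 kPa (median absolute error over 200
  tests).

All randomness is seeded explicitly; the generators save and restore the
global RNG state, and a fixed seed reproduces every file byte-for-byte —
the determinism the test suite asserts on md5 sums of pipeline outputs.

What the generator does *not* emulate: optical artefacts of laser
diffraction (Mie/Fraunhofer inversion), ultrasound cavitation physics,
segmentation errors in imaging, humidity effects on rheology, and any
correlation between shape and agglomeration. Passing closed-loop tests
therefore demonstrates the correctness of the accounting and fitting
machinery, not the instruments' physics.

## Numerical choices and degenerate inputs

* Quantile interpolation: linear in log-diameter; plateaus of the
  cumulative curve resolve to their lower edge.
* Re-binning splits straddling bins by log-width fraction; a class grid
  spanning the full support conserves volume exactly.
* Root finding for planted agglomeration uses `uniroot` at tolerance
  10⁻¹²; plans that would exhaust the donor classes raise an error rather
  than truncate.
* Degenerate polygons (< 3 distinct vertices, zero area) are rejected;
  convexity is capped at 1 against floating-point overshoot.
* A flat shear response fits $F = 0$ with undefined $r^2$ (returned as
  `NA`), not an error.
* Problem sizes in the shipped tests and acceptance script: 100-bin PSDs,
  20 random agglomeration plans, 200 noisy shear fits, 6 powders with a
  few hundred silhouettes each — sizes at which every check runs in
  seconds while keeping Monte-Carlo margins comfortable.

## Known limitations

* The esd³ volume proxy over-weights platelet-like particles.
* The 50/50 magnification merge is exact only when the boundary equals the
  volume median; real powders whose median drifts from 20 µm inherit a
  bias from the instrument protocol itself.
* Agglomeration fractions are underestimated whenever sub-cut fines
  dissolve in the carrier — inherent to the 2 µm truncation, which is why
  soft/hard values are comparative rather than absolute.
* The radar-area ranking depends on the frozen axis order; rankings from
  differently ordered axes are not comparable, and the published relative
  areas of similar studies cannot be reproduced exactly without knowing
  their axis geometry.
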