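# powdermetrics

Characterization pipeline for powders produced by ultrafine dry milling of
lignocellulosic biomass (pine bark, wheat straw and similar feedstocks) in
ball mills. Given the standard instrument exports — binned volume particle
size distributions (PSD) from laser diffraction, particle silhouettes from
automated imaging, and powder-rheometer tables — the package computes, per
powder:

* **size statistics**: d10/d50/d90 by log-linear interpolation of the
  cumulative volume curve, span `(d90 − d10)/d50`, and the volume-specific
  surface area `SSA = 3 Σᵢ 2αᵢ/Dᵢ` (spherical assumption, with a 2 µm lower
  size cut and optional renormalization of the retained fractions);
* **soft/hard agglomeration** from an ultrasonic-dispersion PSD triplet
  (untreated ND, mild in-instrument ultrasound LG, powerful external probe
  EP): `soft = (SSA_LG − SSA)/SSA_EP`, `hard = (SSA_EP − SSA_LG)/SSA_EP`,
  plus a population-balance size-class shift table over the 2–5, 5–20,
  20–80 and 80–200 µm grading classes;
* **shape morphometrics** from silhouette polygons: equivalent spherical
  diameter, principal-axis length/width, elongation `1 − W/L`, convex-hull
  convexity, with esd³ volume weighting, a 4.5 µm minimum-size filter for
  low-magnification imaging and the 50/50 fine/coarse magnification merge;
* **rheology indices**: Carr index `100(ρₚ − ρₐ)/ρₚ` with flowability
  bands, 15 kPa bed compressibility `100(Vᵢ − V₁₅)/Vᵢ`, and Mohr–Coulomb
  cohesion (OLS intercept of `τ = C₀ + Fσ` over the shear-cell failure
  points);
* **multi-criteria quality ranking**: indicators normalized to (0, 1]
  (inverting lower-is-better ones, dividing by the column maximum) and
  compared by relative radar-polygon area (best powder = 100 %).

A synthetic-data generator (`simulate_study()`) emulates all instrument
exports for a six-powder study — three mills (rotary, stirred, vibratory) ×
two biomasses (bark, straw) — with known planted ground truth, so the whole
chain is testable end to end without instrument data.

## Worked example

```r
library(powdermetrics)

# a bimodal bark feed powder from the built-in template
p <- generate_psd(psd_template("bark_feed"), seed = 1, label = "IM_bark")
print(p)
#> Particle size distribution 'IM_bark' [dry]
#>   100 bins over 0.1-2e+03 um
#>   d10 24.2 um | d50 107 um | d90 318 um | span 2.75
#>   SSA 0.1046 um^-1 (0.0001046 m2.mm-3, particles >= 2 um)

# a full synthetic six-powder study, then the complete pipeline
d <- file.path(tempdir(), "study")
simulate_study(d, seed = 1)
res <- run_pipeline(d)

res$agglomeration[res$agglomeration$powder == "VBM_bark", ]
#>    powder soft hard total ssa_nd ssa_lg ssa_ep
#>  VBM_bark  0.1 0.12  0.22   0.42  0.474  0.538

res$ranking
#>     powder  area relative_area_pct rank
#>  SBM_straw 1.621            100.00    1
#>   RBM_bark 1.482             91.44    2
#>   SBM_bark 1.478             91.17    3
#>   VBM_bark 1.340             82.65    4
#>  RBM_straw 1.197             73.82    5
#>  VBM_straw 1.114             68.70    6
```

Reading the numbers: the vibratory-mill bark powder hides 22 % of its fully
dispersed surface in agglomerates (10 % dispersible by mild ultrasound,
12 % only by the external probe), and the ranking orders the six powders by
the area of their normalized quality radar (span, SSA, elongation,
agglomeration, compressibility, cohesion) relative to the best one.

The methods vignette (`vignettes/powder-characterization.Rmd`) documents the
formulas, conventions (log-space interpolation, principal-axis length/width,
the 2 µm cut, the hard-fraction reading) and the generator's study
conditions in detail.

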