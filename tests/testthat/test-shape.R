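test_that("shape factors of canonical silhouettes match closed forms", {
  circ <- shape_factors(circle_poly(d = 20))
  expect_equal(circ$elongation, 0, tolerance = 1e-3)
  expect_equal(circ$convexity, 1, tolerance = 1e-3)
  expect_equal(circ$esd_um, 20, tolerance = 20 * 1e-3)

  rect <- shape_factors(rect_poly(100, 50))
  expect_equal(rect$elongation, 0.5, tolerance = 1e-12)
  expect_equal(rect$length_um, 100, tolerance = 1e-9)
  expect_equal(rect$width_um, 50, tolerance = 1e-9)
  expect_equal(rect$convexity, 1, tolerance = 1e-12)
  expect_equal(rect$esd_um, 2 * sqrt(5000 / pi), tolerance = 1e-12)

  # a square is as round as a circle by the elongation measure
  expect_equal(shape_factors(rect_poly(50, 50))$elongation, 0,
               tolerance = 1e-9)

  ell <- shape_factors(ellipse_poly(a = 50, b = 25))
  expect_equal(ell$elongation, 0.5, tolerance = 1e-3)
})

test_that("star convexity matches the closed form and the hull oracle", {
  st <- star_poly(R = 10, r = 3)
  sf <- shape_factors(st)
  expect_lt(sf$convexity, 0.9)
  expect_equal(sf$convexity, star_convexity_closed_form(10, 3),
               tolerance = 1e-12)
  # independent monotone-chain hull oracle on irregular generated particles
  polys <- generate_shapes(shape_population_spec(10, roughness = 0.2), 21)
  for (p in polys) {
    expect_equal(shape_factors(p)$convexity,
                 oracle_hull_perimeter(p) / sum(sqrt(rowSums(
                   (p - p[c(2:nrow(p), 1), ])^2))),
                 tolerance = 1e-9)
  }
})

test_that("shape factors are rotation/translation invariant and scale right", {
  shapes <- list(rect_poly(80, 30), ellipse_poly(40, 22), star_poly(12, 5))
  for (poly in shapes) {
    ref <- shape_factors(poly)
    for (theta in c(0.3, 1.1, 2.7)) {
      rot <- shape_factors(rotate_poly(poly, theta, dx = 13, dy = -7))
      expect_equal(rot$elongation, ref$elongation, tolerance = 1e-6)
      expect_equal(rot$convexity, ref$convexity, tolerance = 1e-6)
      expect_equal(rot$esd_um, ref$esd_um, tolerance = 1e-6)
    }
    sc <- shape_factors(poly * 3)
    expect_equal(sc$esd_um, 3 * ref$esd_um, tolerance = 1e-9)
    expect_equal(sc$length_um, 3 * ref$length_um, tolerance = 1e-9)
    expect_equal(sc$width_um, 3 * ref$width_um, tolerance = 1e-9)
    expect_equal(sc$elongation, ref$elongation, tolerance = 1e-9)
    expect_equal(sc$convexity, ref$convexity, tolerance = 1e-9)
  }
})

test_that("elongation and convexity live on their defined ranges", {
  polys <- c(generate_shapes(shape_population_spec(15, roughness = 0.25), 31),
             list(rect_poly(200, 2), star_poly(9, 2)))
  recs <- shape_table(polys)
  expect_true(all(recs$elongation >= 0 & recs$elongation < 1))
  expect_true(all(recs$convexity > 0 & recs$convexity <= 1))
  expect_equal(1 - recs$elongation, recs$width_um / recs$length_um,
               tolerance = 1e-12)
})

test_that("degenerate polygons are rejected", {
  expect_error(shape_factors(cbind(c(0, 1), c(0, 1))), "n >= 3")
  expect_error(shape_factors(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("volume weights follow the esd cube law", {
  recs <- data.frame(esd_um = c(10, 20))
  w <- volume_weights(recs)$weight_pct
  expect_equal(w, 100 * c(1 / 9, 8 / 9))
  same <- volume_weights(data.frame(esd_um = rep(7, 5)))$weight_pct
  expect_equal(same, rep(20, 5))
})

test_that("volume-weighted histograms match brute-force binning", {
  polys <- generate_shapes(shape_population_spec(
    60, diameter_meanlog = log(15), diameter_sdlog = 0.4), 41)
  recs <- volume_weights(shape_table(polys))
  h <- volume_weighted_distribution(recs, "elongation",
                                    breaks = seq(0, 1, by = 0.1))
  expect_equal(sum(h$weight_pct), 100, tolerance = 1e-9)
  # brute force: direct summation per bin
  for (k in seq_len(nrow(h))) {
    sel <- recs$elongation >= h$lo[k] &
      (recs$elongation < h$hi[k] | (k == nrow(h) & recs$elongation <= h$hi[k]))
    expect_equal(h$weight_pct[k], sum(recs$weight_pct[sel]), tolerance = 1e-9)
  }
})

test_that("magnification halves are merged 50/50", {
  small <- data.frame(esd_um = c(5, 10, 15))
  large <- data.frame(esd_um = c(30, 50))
  m <- merge_magnifications(small, large)
  expect_equal(sum(m$weight_pct), 100, tolerance = 1e-12)
  expect_equal(sum(m$weight_pct[m$side == "small"]), 50, tolerance = 1e-12)
  expect_equal(sum(m$weight_pct[m$side == "large"]), 50, tolerance = 1e-12)

  expect_error(merge_magnifications(data.frame(esd_um = numeric()), large),
               "non-empty")
  expect_error(merge_magnifications(data.frame(esd_um = c(5, 25)), large),
               "boundary")
})

test_that("balanced halves put the merged median esd at the boundary", {
  set.seed(51)
  small <- data.frame(esd_um = runif(400, 8, 19.5))
  large <- data.frame(esd_um = runif(400, 20.5, 45))
  m <- merge_magnifications(small, large)
  med <- cumulative_distribution(m$esd_um, m$weight_pct)$median
  expect_equal(med, 20, tolerance = 0.1)
})

test_that("the minimum-size filter is strict at the cut", {
  recs <- data.frame(esd_um = c(2, 4.5, 5))
  out <- apply_min_size_filter(recs)
  expect_equal(out$esd_um, 5)
  expect_equal(attr(out, "n_removed"), 2L)

  all_big <- data.frame(esd_um = c(6, 9))
  expect_equal(apply_min_size_filter(all_big)$esd_um, c(6, 9))

  set.seed(61)
  fine <- data.frame(esd_um = rlnorm(500, log(5), 0.5))
  expect_equal(nrow(apply_min_size_filter(fine)), sum(fine$esd_um > 4.5))
})

test_that("cumulative curves are monotone with interpolated medians", {
  cd <- cumulative_distribution(rep(0.5, 8))
  expect_equal(cd$median, 0.5)
  expect_true(all(diff(cd$curve$cum_pct) >= 0))

  sym <- cumulative_distribution(seq(0.1, 0.7, by = 0.01))
  expect_equal(sym$median, 0.4, tolerance = 1e-9)

  expect_error(cumulative_distribution(numeric()), "empty")
})
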