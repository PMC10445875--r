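test_that("generated PSDs are normalized, seeded and template-faithful", {
  spec <- psd_spec(data.frame(gm = 40, gsd = 1.05, weight = 1))
  p <- generate_psd(spec, seed = 1)
  expect_psd_valid(p)
  expect_equal(psd_quantiles(p, 0.5), 40, tolerance = 0.02 * 40)

  # determinism: same spec and seed give identical distributions
  expect_identical(generate_psd(spec, seed = 9)$volume_pct,
                   generate_psd(spec, seed = 9)$volume_pct)
  expect_false(identical(generate_psd(spec, seed = 9)$volume_pct,
                         generate_psd(spec, seed = 10)$volume_pct))

  expect_error(psd_spec(data.frame(gm = -1, gsd = 1.2, weight = 1)),
               "positive")
  expect_error(psd_spec(data.frame(gm = c(10, 20), gsd = c(1.2, 1.2),
                                   weight = c(0.6, 0.6))), "sum to 1")
  expect_error(psd_spec(data.frame(gm = 10, gsd = 1.2, weight = 1),
                        bin_edges = numeric()), "increasing")
})

test_that("the bark feed template is bimodal around 40 and 225 um", {
  p <- generate_psd(psd_template("bark_feed"), seed = 2, noise_sd = 0)
  v <- p$volume_pct
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  peaks <- peaks[v[peaks] > 0.1 * max(v)]
  expect_length(peaks, 2)
  expect_equal(p$diameter[peaks[1]], 40, tolerance = 0.15 * 40)
  expect_equal(p$diameter[peaks[2]], 225, tolerance = 0.15 * 225)
  # the two peaks have comparable height
  expect_gt(min(v[peaks]) / max(v[peaks]), 0.6)
})

test_that("the straw feed template has a ~280 um median", {
  p <- generate_psd(psd_template("straw_feed"), seed = 3, noise_sd = 0)
  expect_equal(psd_quantiles(p, 0.5), 280, tolerance = 0.05 * 280)
})

test_that("planting zero agglomeration returns three identical PSDs", {
  truth <- generate_psd(psd_template("bark_fine"), seed = 4, label = "b")
  tr <- plant_agglomeration(truth, agglomeration_plan(0, 0))
  expect_equal(tr$nd$volume_pct, truth$volume_pct, tolerance = 1e-9)
  expect_equal(tr$lg$volume_pct, truth$volume_pct, tolerance = 1e-9)
  expect_identical(tr$ep$volume_pct, truth$volume_pct)
})

test_that("planted agglomeration conserves volume and keeps bins >= 0", {
  truth <- generate_psd(psd_template("straw_fine"), seed = 5, label = "s")
  tr <- plant_agglomeration(truth, agglomeration_plan(0.10, 0.10))
  for (p in list(tr$nd, tr$lg, tr$ep)) {
    expect_equal(sum(p$volume_pct), 100, tolerance = 1e-9)
    expect_true(all(p$volume_pct >= 0))
  }
  # recovery within the stated closed-loop tolerance
  res <- soft_hard(tr)
  expect_equal(res$soft, 0.10, tolerance = 0.02)
  expect_equal(res$hard, 0.10, tolerance = 0.02)
})

test_that("unrealizable plans and invalid fractions are rejected", {
  expect_error(agglomeration_plan(0.6, 0.5), "< 1")
  expect_error(agglomeration_plan(-0.1, 0.1), ">= 0")
  # a coarse monodisperse powder has no donor fines to agglomerate
  coarse <- psd(c(90, 110), 100, label = "coarse")
  expect_error(plant_agglomeration(coarse, agglomeration_plan(0.2, 0.2)),
               "donor")
})

test_that("generated silhouettes honour the shape laws", {
  # elongation law concentrated at 0, no roughness: circles
  circ_spec <- shape_population_spec(10, elongation_shape1 = 1,
                                     elongation_shape2 = 1e6,
                                     roughness = 0, n_vertices = 256L)
  recs <- shape_table(generate_shapes(circ_spec, 6))
  expect_true(all(recs$elongation < 1e-3))
  expect_true(all(abs(recs$convexity - 1) < 1e-3))

  # elongation concentrated at 0.5: 2:1 ellipses
  ell_spec <- shape_population_spec(10, elongation_shape1 = 5e5,
                                    elongation_shape2 = 5e5,
                                    roughness = 0, n_vertices = 256L)
  recs2 <- shape_table(generate_shapes(ell_spec, 7))
  expect_equal(median(recs2$elongation), 0.5, tolerance = 0.02)

  # roughness lowers convexity below 1
  rough <- shape_table(generate_shapes(
    shape_population_spec(30, roughness = 0.2), 8))
  expect_lt(median(rough$convexity), 1)

  # population medians track the requested laws (smooth boundaries, so the
  # measured elongation equals the drawn one)
  b2 <- elongation_beta_for_median(0.55)
  pop <- shape_table(generate_shapes(shape_population_spec(
    4000, elongation_shape2 = b2, roughness = 0, n_vertices = 32L), 9))
  expect_lt(abs(median(pop$elongation) - 0.55), 0.02)
  expect_lt(abs(median(pop$esd_um) - 20) / 20, 0.1)

  expect_identical(generate_shapes(circ_spec, 11),
                   generate_shapes(circ_spec, 11))
  expect_error(shape_population_spec(0), ">= 1")
  expect_error(shape_population_spec(5, roughness = -0.1), ">= 0")
})

test_that("synthetic shear tests follow the planted failure line", {
  tt <- generate_shear_test(0.4, 0.6, noise_sd_kpa = 0,
                            stresses_kpa = c(1, 1.3, 1.5, 1.7, 2))
  expect_equal(tt$tau_kpa, 0.4 + 0.6 * tt$sigma_kpa, tolerance = 1e-12)
  expect_identical(generate_shear_test(0.4, 0.6, 0.02, seed = 3),
                   generate_shear_test(0.4, 0.6, 0.02, seed = 3))
  expect_error(generate_shear_test(0.4, 0.6, 0.01, stresses_kpa = 1.5),
               "at least 2")
  expect_error(generate_shear_test(0.4, 0.6, -0.1), ">= 0")
})

test_that("seeded generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_psd(psd_template("bark_fine"), seed = 99))
  invisible(generate_shapes(shape_population_spec(5), 99))
  expect_identical(.Random.seed, before)
})
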