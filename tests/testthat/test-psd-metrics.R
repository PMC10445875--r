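test_that("quantiles recover the monodisperse diameter and stay monotone", {
  p <- psd(c(19, 21), 100)
  expect_equal(psd_quantiles(p, 0.5), sqrt(19 * 21), tolerance = 1e-9)

  q <- psd_quantiles(generate_psd(psd_template("bark_feed"), seed = 1),
                     c(0.1, 0.5, 0.9))
  expect_true(all(diff(q) >= 0))

  expect_error(psd_quantiles(p, 0), "inside")
  expect_error(psd_quantiles(p, 1), "inside")
})

test_that("quantiles of log-uniform volume hit the geometric midpoint", {
  edges <- exp(seq(log(10), log(100), length.out = 11))
  p <- psd(edges, rep(10, 10))
  # cumulative volume is linear in log-diameter, so d50 = sqrt(10 * 100)
  expect_equal(psd_quantiles(p, 0.5), sqrt(1000), tolerance = 1e-9)
})

test_that("quantiles agree with a dense brute-force cumulative oracle", {
  for (tpl in c("bark_feed", "straw_feed", "bark_fine", "straw_fine")) {
    p <- generate_psd(psd_template(tpl), seed = 11)
    for (pr in c(0.1, 0.5, 0.9)) {
      expect_equal(psd_quantiles(p, pr), oracle_quantile(p, pr),
                   tolerance = 5e-3)
    }
  }
})

test_that("span is (d90 - d10) / d50", {
  expect_equal(size_span(10, 20, 76), 3.3)
  expect_equal(size_span(2, 20, 98), 4.8)
  expect_equal(size_span(20, 20, 20), 0)
  expect_error(size_span(1, 0, 3), "positive")
})

test_that("SSA matches the 6/D sphere closed form and direct summation", {
  expect_equal(psd_ssa(psd(c(19, 21), 100)), 6 / sqrt(19 * 21),
               tolerance = 1e-12)
  # D = 40 um exactly: edges 20 and 80
  expect_equal(psd_ssa(psd(c(20, 80), 100)), 0.15, tolerance = 1e-12)
  # two equal classes with D = 10 and 100 um exactly
  p2 <- psd(c(5, 20, 500), c(50, 50))
  expect_equal(psd_ssa(p2), 6 * (0.5 / 10 + 0.5 / 100), tolerance = 1e-12)
})

test_that("the lower cut drops fine bins and renormalization is optional", {
  # bins with D = 1 um (below cut) and D = 10 um
  p <- psd(c(0.5, 2, 50), c(20, 80))
  expect_equal(psd_ssa(p, lower_cut_um = 2, renormalize = TRUE), 6 / 10)
  expect_equal(psd_ssa(p, lower_cut_um = 2, renormalize = FALSE),
               6 * 0.8 / 10)
  expect_equal(psd_ssa(p, lower_cut_um = 0),
               6 * (0.2 / 1 + 0.8 / 10))
  expect_error(psd_ssa(p, lower_cut_um = 100), "cut")
})

test_that("SSA scales inversely with a global size rescaling", {
  p <- generate_psd(psd_template("bark_fine"), seed = 2)
  for (k in c(0.5, 2, 10)) {
    pk <- psd(p$bin_edges * k, p$volume_pct, normalize = FALSE)
    expect_equal(psd_ssa(pk, lower_cut_um = 2 * k), psd_ssa(p) / k,
                 tolerance = 1e-9)
  }
})

test_that("rebin conserves volume and matches per-bin assignment", {
  p <- psd(c(6, 10, 15), c(40, 60))
  expect_equal(unname(psd_rebin(p, c(2, 5, 20, 80, 200))), c(0, 100, 0, 0))

  p2 <- generate_psd(psd_template("bark_fine"), seed = 3)
  w <- psd_rebin(p2, range(p2$bin_edges))
  expect_equal(sum(w), 100, tolerance = 1e-9)

  # oracle: whole-bin assignment on a class grid aligned with bin edges
  edges <- p2$bin_edges
  cls <- edges[c(1, 31, 61, 101)]
  w3 <- psd_rebin(p2, cls)
  expect_equal(unname(w3),
               c(sum(p2$volume_pct[1:30]), sum(p2$volume_pct[31:60]),
                 sum(p2$volume_pct[61:100])), tolerance = 1e-9)

  expect_error(psd_rebin(p2, c(10, 5)), "increasing")
})

test_that("PSD construction validates its inputs", {
  expect_error(psd(c(1, 2), c(1, 2)), "one value per bin")
  expect_error(psd(c(2, 1), 100), "increasing")
  expect_error(psd(c(1, 2), -5), "non-negative")
  expect_error(psd(c(1, 2), 99, normalize = FALSE), "sum to 100")
  expect_silent(psd(c(1, 2), 99))  # normalized on request
  s <- psd_summary(psd(c(19, 21), 100))
  expect_true(s$d10 <= s$d50 && s$d50 <= s$d90)
  expect_equal(s$ssa_m2_mm3, s$ssa_um_inv * 1e-3)
})
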