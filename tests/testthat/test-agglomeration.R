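# triplets with exact SSA values built from a two-bin grid whose
# representative diameters are 6 and 24 um: SSA = 0.25 + 0.75 * w1
# (w1 = volume fraction in the fine bin), so SSA in {0.8, 0.9, 1.0}
# corresponds to w1 in {73.33..., 86.66..., 100} %
two_bin_triplet <- function(w_nd, w_lg, w_ep) {
  grid <- c(3, 12, 48)
  mk <- function(w, tr) psd(grid, c(w, 100 - w), label = "t", treatment = tr)
  deagglomeration_triplet(mk(w_nd, "ND"), mk(w_lg, "LG"), mk(w_ep, "EP"))
}

test_that("soft/hard fractions follow the SSA accounting formulas", {
  tr <- two_bin_triplet(220 / 3, 260 / 3, 100)
  expect_equal(tr$ssa, 0.8, tolerance = 1e-12)
  expect_equal(tr$ssa_lg, 0.9, tolerance = 1e-12)
  expect_equal(tr$ssa_ep, 1.0, tolerance = 1e-12)
  res <- soft_hard(tr)
  expect_equal(res$soft, 0.10, tolerance = 1e-12)
  expect_equal(res$hard, 0.10, tolerance = 1e-12)
  expect_equal(res$total, 0.20, tolerance = 1e-12)

  # identical distributions: no agglomeration
  res0 <- soft_hard(two_bin_triplet(50, 50, 50))
  expect_equal(res0$soft, 0)
  expect_equal(res0$hard, 0)

  # alternative reading: hard as the whole SSA deficit
  res2 <- soft_hard(two_bin_triplet(220 / 3, 260 / 3, 100),
                    hard_mode = "total_deficit")
  expect_equal(res2$hard, 0.20, tolerance = 1e-12)
  expect_equal(res2$total, 0.20, tolerance = 1e-12)
})

test_that("total equals soft + hard by construction", {
  for (seed in 1:5) {
    tr <- plant_agglomeration(
      generate_psd(psd_template("straw_fine"), seed = seed, label = "s"),
      agglomeration_plan(0.03 * seed, 0.02 * seed))
    res <- soft_hard(tr)
    expect_equal(res$total, res$soft + res$hard, tolerance = 1e-12)
  }
})

test_that("planted soft/hard fractions are recovered in closed loop", {
  truth <- generate_psd(psd_template("bark_fine"), seed = 4, label = "b")
  res <- soft_hard(plant_agglomeration(truth, agglomeration_plan(0.05, 0.15)))
  expect_equal(res$soft, 0.05, tolerance = 0.02)
  expect_equal(res$hard, 0.15, tolerance = 0.02)
  expect_equal(res$total, 0.20, tolerance = 0.02)
})

test_that("SSA ordering violations warn and negative fractions clamp to 0", {
  expect_warning(two_bin_triplet(90, 80, 100), "ordering")
  tr <- suppressWarnings(two_bin_triplet(90, 80, 100))
  expect_warning(soft_hard(tr), "clamped")
  res <- suppressWarnings(soft_hard(tr))
  expect_gte(res$soft, 0)
  expect_gte(res$hard, 0)
})

test_that("class shift reproduces a constructed volume transfer", {
  # PSD bins aligned with the grading classes; ND holds 10 volume-%
  # agglomerated from the 5-20 um class into the 20-80 um class
  grid <- c(2, 5, 20, 80, 200)
  ep <- psd(grid, c(10, 40, 35, 15), treatment = "EP")
  lg <- psd(grid, c(10, 35, 40, 15), treatment = "LG")
  nd <- psd(grid, c(10, 30, 45, 15), treatment = "ND")
  tr <- deagglomeration_triplet(nd, lg, ep)
  cs <- class_shift(tr)
  expect_equal(cs$total_shift, c(0, 10, -10, 0))
  expect_equal(cs$soft_shift, c(0, 5, 5 - 10, 0))
  expect_equal(cs$nd, c(10, 30, 45, 15))

  # no agglomeration: all differences vanish
  cs0 <- class_shift(deagglomeration_triplet(ep, ep, ep))
  expect_equal(cs0$soft_shift, rep(0, 4))
  expect_equal(cs0$hard_shift, rep(0, 4))

  expect_error(class_shift(tr, class_edges = c(1, 5, 20)), "support")
})

test_that("shift columns sum to zero and fines gain on dispersion", {
  tr <- plant_agglomeration(
    generate_psd(psd_template("bark_fine"), seed = 5, label = "b"),
    agglomeration_plan(0.08, 0.10))
  cs <- class_shift(tr)
  expect_equal(sum(cs$soft_shift), 0, tolerance = 1e-6)
  expect_equal(sum(cs$hard_shift), 0, tolerance = 1e-6)
  expect_equal(sum(cs$total_shift), 0, tolerance = 1e-6)
  # dispersing agglomerates returns volume to the fine classes
  expect_true(all(cs$total_shift[1:2] > 0))
  expect_true(all(cs$total_shift[3:4] < 0))
})

test_that("increasing planted soft raises soft and leaves hard unchanged", {
  truth <- generate_psd(psd_template("bark_fine"), seed = 6, label = "b")
  softs <- c(0.02, 0.06, 0.10, 0.14)
  res <- lapply(softs, function(s)
    soft_hard(plant_agglomeration(truth, agglomeration_plan(s, 0.05))))
  soft_rec <- vapply(res, `[[`, numeric(1), "soft")
  hard_rec <- vapply(res, `[[`, numeric(1), "hard")
  expect_true(all(diff(soft_rec) > 0))
  expect_equal(hard_rec, rep(0.05, 4), tolerance = 1e-6)
})

test_that("triplets require a shared bin grid", {
  a <- psd(c(2, 20, 200), c(50, 50))
  b <- psd(c(2, 30, 200), c(50, 50))
  expect_error(deagglomeration_triplet(a, b, a), "bin grid")
})
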