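test_that("Bliss volume vanishes for Bliss-generated data", {
  hA <- std_percent_hill(1, 1.2); hB <- std_percent_hill(2, 0.8)
  des <- standard_bias_design()
  chk <- simulate_checkerboard(function(a, b) bliss_effect(hA, hB, a, b),
                               des, noise_spec())
  expect_equal(bliss_volume(chk, hA, hB), 0, tolerance = 1e-12)
})

test_that("additive sham combinations show the slope-dependent deviation", {
  # the deterministic Bliss deviation of Loewe-additive self-combinations
  # on the 10x10 two-fold grid (max 32 uM): about -10.30 percent at slope
  # 0.5, -2.87 at slope 1, +2.78 at slope 4
  des <- standard_bias_design()
  dev <- vapply(c(0.5, 1, 4), function(s) {
    h <- std_percent_hill(1, s)
    chk <- simulate_checkerboard(
      function(a, b) loewe_effect(additive_pair(h, h), a, b), des,
      noise_spec())
    bliss_volume(chk, h, h)
  }, numeric(1))
  expect_equal(dev, c(-10.30, -2.87, 2.78), tolerance = 0.01)
})

test_that("Bliss volume is linear in the measured responses", {
  h <- std_percent_hill()
  des <- small_design()
  chk <- simulate_checkerboard(function(a, b) bliss_effect(h, h, a, b),
                               des, noise_spec(3, seed = 2))
  v0 <- bliss_volume(chk, h, h)
  chk$response <- chk$response + 7
  expect_equal(bliss_volume(chk, h, h), v0 + 7)
})

test_that("viability-scale Bliss volume keeps synergy positive", {
  hv <- hill_params(1, 1, 1, 0)
  d <- dilution_series(8, 4, 2, "max")
  g <- expand.grid(dA = d, dB = d)
  pred <- bliss_survival(hv, hv, g$dA, g$dB, scale = "viability")
  # deeper killing than predicted = synergy = positive volume
  chk <- data.frame(g, response = pred - 0.1)
  expect_equal(bliss_volume(chk, hv, hv, scale = "viability"), 0.1)
})

test_that("self-vs-self calibration brackets the deterministic deviation", {
  des <- standard_bias_design()
  th <- calibrate_bliss_thresholds(list(std_percent_hill(1, 1),
                                        std_percent_hill(1, 1)),
                                   des, noise_spec(0, seed = 3), reps = 2)
  expect_equal(th$lo, th$hi, tolerance = 1e-6)
  expect_equal(th$lo, -2.87, tolerance = 0.05)
  expect_equal(length(th$values), 4)

  set.seed(4)
  th2 <- calibrate_bliss_thresholds(
    lapply(seq(0.5, 4, 0.5), function(s) std_percent_hill(1, s)),
    des, noise_spec(5), reps = 3)
  expect_equal(length(th2$values), 24)
  expect_lt(th2$lo, 0)
  expect_gt(th2$hi, 0)
  expect_lt(th2$lo, -8)   # dragged down by the low-slope deviations
})

test_that("Bliss classification respects thresholds and boundaries", {
  th <- list(lo = -5, hi = 5)
  expect_equal(classify_bliss(-12, th), "antagonistic")
  expect_equal(classify_bliss(0, th), "additive")
  expect_equal(classify_bliss(6, th), "synergistic")
  expect_equal(classify_bliss(c(-5, 5), th), c("additive", "additive"))
  expect_equal(classify_bliss(1, c(-5, 5)), "additive")
})

test_that("the seven longest diagonals have the expected geometry", {
  des <- standard_bias_design()
  h <- std_percent_hill()
  chk <- simulate_checkerboard(function(a, b) bliss_effect(h, h, a, b),
                               des, noise_spec())
  diags <- extract_diagonals(chk, 7)
  lens <- vapply(diags, nrow, integer(1))
  expect_equal(sort(lens, decreasing = TRUE), c(10, 9, 9, 8, 8, 7, 7))
  ratios <- vapply(diags, attr, numeric(1), "ratio")
  expect_equal(sort(ratios), sort(c(1, 2, 1 / 2, 4, 1 / 4, 8, 1 / 8)))
  expect_equal(attr(diags[[1]], "ratio"), 1)
  # constant ratio along each series
  for (dg in diags) expect_equal(stats::sd(dg$dA / dg$dB), 0)
})

test_that("a 4x4 grid yields the single main diagonal for the screen CI", {
  d <- dilution_series(32, 4, 4, "max")
  g <- expand.grid(dA = d, dB = d)
  chk <- data.frame(g, response = 50, replicate = 1)
  diags <- extract_diagonals(chk, 1)
  expect_length(diags, 1)
  expect_equal(nrow(diags[[1]]), 4)
  expect_error(extract_diagonals(chk, 2), "odd")
  uneven <- data.frame(dA = rep(c(1, 2), 2), dB = rep(c(1, 2, 4), length.out = 4),
                       response = 0, replicate = 1)
  expect_error(extract_diagonals(uneven, 1), "square")
})

test_that("sham combinations have CI = 1 at every ratio and level", {
  h <- std_percent_hill(1, 1.5)
  des <- standard_bias_design()
  spec <- additive_pair(h, h)
  chk <- simulate_checkerboard(function(a, b) loewe_effect(spec, a, b),
                               des, noise_spec())
  sa <- simulate_single_agents(h, h, des, noise_spec())
  fA <- fit_hill_ls(sa$A, fix_bounds = c(0, 100))
  fB <- fit_hill_ls(sa$B, fix_bounds = c(0, 100))
  for (dg in extract_diagonals(chk, 7)) {
    fd <- fit_hill_ls(dose_response_data(dg$total, dg$response),
                      fix_bounds = c(0, 100))
    for (lev in c(50, 99)) {
      expect_equal(combination_index(fA, fB, fd, lev, attr(dg, "ratio")),
                   1, tolerance = 1e-3)
    }
  }
})

test_that("a uniformly more potent diagonal halves the CI", {
  h <- std_percent_hill(1, 1)
  # diagonal curve reaching each level at half the expected total dose
  diag_fit <- hill_params(0.5, 1, 0, 100)
  # sham expectation: expected total IC50 = 1 split 1:1 over ICs of 1
  expect_equal(combination_index(h, h, diag_fit, 50, 1), 0.5)
})

test_that("CI classification uses the 0.5 / 2 cutoffs", {
  expect_equal(classify_ci(2.01), "antagonistic")
  expect_equal(classify_ci(1.0), "additive")
  expect_equal(classify_ci(0.49), "synergistic")
  expect_equal(classify_ci(c(0.5, 2)), c("additive", "additive"))
  expect_true(is.na(classify_ci(NA_real_)))
})

test_that("CI is undefined when a curve cannot reach the level", {
  capped <- hill_params(1, 1, 0, 80)
  h <- std_percent_hill()
  expect_true(is.na(combination_index(capped, h, h, 90, 1)))
})

test_that("Hill product and potency index follow their definitions", {
  expect_equal(hill_product(std_percent_hill(1, 1), std_percent_hill(1, 1)), 1)
  expect_equal(hill_product(std_percent_hill(1, 0.5), std_percent_hill(1, 4)), 2)
  # IC50 at max/100 gives potency 100
  expect_equal(potency_index(std_percent_hill(0.32, 1), 32), 100)
  # IC50 at the top of the range gives the floor
  expect_equal(potency_index(std_percent_hill(32, 1), 32), 1)
  # level never reached in range: floor of 1
  weak <- hill_params(1, 1, 0, 40)   # never reaches 50% effect
  expect_equal(potency_index(weak, 32), 1)
  far <- std_percent_hill(100, 1)    # IC50 beyond the tested range
  expect_equal(potency_index(far, 32), 1)
})
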