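test_that("BRAID axis marginals are the exact Hill curves", {
  bp <- braid_params(1, 2, 1.3, 2.1, 1.5, 0, 100, 70)
  d <- c(0, 0.05, 0.4, 1, 6, 40)
  expect_equal(braid_effect(bp, d, 0),
               hill_effect(hill_params(1, 1.3, 0, 100), d))
  expect_equal(braid_effect(bp, 0, d),
               hill_effect(hill_params(2, 2.1, 0, 70), d))
})

test_that("kappa = 0 BRAID is an additive sham combination", {
  bp <- braid_params(1, 1, 2, 2, 0, 0, 100, 100)
  d <- c(0.1, 0.5, 1, 4, 16)
  expect_equal(braid_effect(bp, d / 2, d / 2),
               hill_effect(std_percent_hill(1, 2), d), tolerance = 1e-12)
})

test_that("kappa = 0 equals the asymptotic-additive reference surface", {
  # bridging property (equal Hill slopes, unequal maximal effects)
  spec <- additive_pair(hill_params(1, 1.5, 0, 100),
                        hill_params(2, 1.5, 0, 60))
  bp <- braid_params(1, 2, 1.5, 1.5, 0, 0, 100, 60)
  g <- expand.grid(a = dilution_series(16, 6, 2, "max"),
                   b = dilution_series(16, 6, 2, "max"))
  expect_equal(braid_effect(bp, g$a, g$b),
               asymptotic_additive_effect(spec, g$a, g$b),
               tolerance = 1e-6)
})

test_that("positive kappa raises the interior of the surface", {
  b0 <- braid_params(1, 1, 1, 1, 0, 0, 100, 100)
  b5 <- braid_params(1, 1, 1, 1, 5, 0, 100, 100)
  expect_gt(braid_effect(b5, 1, 1), braid_effect(b0, 1, 1))
  # and effects remain monotone in dose for kappa >= 0
  d <- sort(runif(8, 0.01, 10))
  expect_true(all(diff(braid_effect(b5, d, 1)) > 0))
})

test_that("kappa below -2 is rejected", {
  expect_error(braid_params(1, 1, 1, 1, kappa = -2.5), "kappa")
})

test_that("all 8 parameters are recovered from noise-free data", {
  bp <- braid_params(1, 2, 1.5, 2.5, 2, 0, 100, 80)
  dat <- braid_fixture(bp)
  fit <- fit_braid(dat, n_boot = 0)
  est <- unlist(fit$params)
  truth <- unlist(unclass(bp))
  rel <- abs(est - truth) / pmax(abs(truth), 1)
  expect_true(all(rel < 0.01))
  expect_lt(abs(fit$params$kappa - 2), 0.05)
})

test_that("bootstrap kappa interval is seed-deterministic", {
  bp <- braid_params(1, 1, 1, 1, 0, 0, 100, 100)
  set.seed(5)
  dat <- braid_fixture(bp, small_design(2), noise_spec(5))
  f1 <- fit_braid(dat, n_boot = 50, seed = 99)
  f2 <- fit_braid(dat, n_boot = 50, seed = 99)
  expect_identical(f1$kappa_ci, f2$kappa_ci)
  expect_true(f1$kappa_ci[1] <= f1$params$kappa &&
              f1$params$kappa <= f1$kappa_ci[2])
})

test_that("interaction calls follow the kappa-interval rule", {
  mk <- function(ci) structure(list(kappa_ci = ci), class = "braid_fit")
  expect_equal(classify_braid(mk(c(0.4, 2.1))), "synergistic")
  expect_equal(classify_braid(mk(c(-1.0, 0.3))), "additive")
  expect_equal(classify_braid(mk(c(-1.5, -0.2))), "antagonistic")
  expect_equal(classify_braid(mk(c(NA, NA))), "additive")
})

test_that("near-flat data are flagged low-information", {
  d <- dilution_series(8, 4, 2, "max")
  g <- expand.grid(dA = d, dB = d)
  dat <- rbind(data.frame(dA = g$dA, dB = g$dB, response = 0),
               data.frame(dA = d, dB = 0, response = 0),
               data.frame(dA = 0, dB = d, response = 0))
  fit <- fit_braid(dat, n_boot = 0)
  expect_true(fit$low_information)
})

test_that("IAE respects its floor, threshold monotonicity and synergy", {
  inert <- braid_params(1e4, 1e4, 1, 1, 0, 0, 100, 100)
  expect_equal(compute_iae(inert, c(10, 10), 50)$iae, 1)

  bp <- braid_params(1, 1, 2, 2, 0, 0, 100, 100)
  i50 <- compute_iae(bp, c(10, 10), 50)$iae
  i90 <- compute_iae(bp, c(10, 10), 90)$iae
  expect_lte(i90, i50)
  expect_gte(i50, 1)

  syn <- braid_params(1, 1, 2, 2, 5, 0, 100, 100)
  expect_gte(compute_iae(syn, c(10, 10), 50)$iae, i50)
})

test_that("IAE is invariant to rescaling doses and limits together", {
  bp <- braid_params(1, 2, 1.5, 1, 1, 0, 100, 100)
  a <- compute_iae(bp, c(8, 16), 50)
  bp2 <- braid_params(1000, 2000, 1.5, 1, 1, 0, 100, 100)
  b <- compute_iae(bp2, c(8000, 16000), 50)
  expect_equal(a$iae, b$iae)
  expect_equal(a$log10_iae, log10(a$iae))
})

test_that("Poisson clonogenic fit recovers the plating-efficiency surface", {
  set.seed(31)
  # log plating-efficiency surface: controls ~20% PE, combination kills
  bp <- braid_params(1, 1, 1.5, 1.5, 1, log(0.2), log(0.2) - 4,
                     log(0.2) - 4)
  d <- c(0, dilution_series(8, 5, 2, "max"))
  g <- expand.grid(dA = d, dB = d)
  mu <- 250 * exp(braid_effect(bp, g$dA, g$dB))
  counts <- data.frame(dA = g$dA, dB = g$dB,
                       colonies = rpois(nrow(g), mu))
  fit <- fit_braid_poisson(counts, 250, n_boot = 40, seed = 3)
  expect_true(fit$kappa_ci[1] <= 1 && 1 <= fit$kappa_ci[2])
  # zero-dose wells anchor e0 at the log control plating efficiency
  ctrl <- counts$colonies[counts$dA == 0 & counts$dB == 0]
  expect_equal(fit$params$e0, log(mean(ctrl) / 250), tolerance = 0.2)
})

test_that("seeding density enters the Poisson model only as exposure", {
  set.seed(32)
  bp <- braid_params(1, 1, 1, 1, 0, log(0.25), log(0.25) - 5,
                     log(0.25) - 5)
  d <- c(0, dilution_series(8, 5, 2, "max"))
  g <- expand.grid(dA = d, dB = d)
  eta <- braid_effect(bp, g$dA, g$dB)
  counts <- data.frame(dA = g$dA, dB = g$dB,
                       colonies = rpois(nrow(g), 250 * exp(eta)))
  # likelihood factorisation: refitting the same counts at doubled
  # density shifts the log-efficiency parameters by exactly -log(2) and
  # leaves doses, slopes and kappa unchanged
  f1 <- fit_braid_poisson(counts, 250, n_boot = 0)
  f2 <- fit_braid_poisson(counts, 500, n_boot = 0)
  expect_equal(f2$params$e0, f1$params$e0 - log(2), tolerance = 1e-3)
  expect_equal(f2$params$efA, f1$params$efA - log(2), tolerance = 0.05)
  expect_equal(log(f2$params$idmA), log(f1$params$idmA), tolerance = 0.01)
  expect_equal(f2$params$kappa, f1$params$kappa, tolerance = 0.05)
  # all-zero counts are flagged
  zero <- data.frame(dA = g$dA, dB = g$dB, colonies = 0L)
  expect_true(fit_braid_poisson(zero, 250, n_boot = 0)$low_information)
})

test_that("BRAID fits serialise to JSON and colony grids load from CSV", {
  bp <- braid_params(1, 1, 1, 1, 0.5, 0, 100, 100)
  dat <- braid_fixture(bp, small_design())
  fit <- fit_braid(dat, n_boot = 10, seed = 1)
  js <- jsonlite::fromJSON(braid_fit_json(fit))
  expect_equal(js$params$kappa, fit$params$kappa)
  expect_equal(js$call, fit$call_type)

  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(concA_uM = c(0, 1), concB_uM = c(0, 2),
                              colonies = c(55L, 3L)), path,
                   row.names = FALSE)
  cc <- read_colony_csv(path)
  expect_equal(cc$dA, c(0, 1))
  expect_equal(cc$colonies, c(55L, 3L))
})
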