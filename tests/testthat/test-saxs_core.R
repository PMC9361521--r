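test_that("guinier_fit is exact on a Guinier-law curve", {
  g <- guinier_fit(guinier_curve(16.8, i0 = 1))
  expect_equal(g$rg, 16.8, tolerance = 1e-6)
  expect_equal(g$i0, 1, tolerance = 1e-6)
  expect_gte(g$n_points, 3)
  expect_lte(g$qrg_max, 1.3 * 1.001)
})

test_that("guinier_fit recovers the analytic sphere Rg from a Debye curve", {
  beads <- sphere_beads(1000, 20)
  q <- seq(0.004, 0.25, length.out = 100)
  cv <- debye_scattering(beads, q)
  g <- guinier_fit(cv)
  expect_equal(g$rg, sqrt(3 / 5) * 20, tolerance = 0.02)
  # and matches the exact coordinate Rg of the bead cloud even closer
  expect_equal(g$rg, bead_rg(beads), tolerance = 0.02)
})

test_that("guinier_fit rejects curves without a Guinier region", {
  q <- seq(0.01, 0.2, by = 0.01)
  rising <- saxs_curve(q, exp(q^2 * 50), rep(1e-3, length(q)))
  expect_error(guinier_fit(rising), "no Guinier region")
})

test_that("the dimensionless Kratky peak of a Guinier curve is (sqrt(3), 3/e)", {
  cv <- guinier_curve(16.8)
  k <- dimensionless_kratky(cv, list(rg = 16.8, i0 = 1))
  pk <- kratky_peak(k)
  expect_equal(pk$x, sqrt(3), tolerance = 1e-4)
  expect_equal(pk$y, 3 / exp(1), tolerance = 1e-4)
  expect_equal(round(pk$y, 3), 1.104)
})

test_that("a flat curve transforms to a strictly increasing parabola", {
  q <- seq(0.01, 0.3, by = 0.01)
  cv <- saxs_curve(q, rep(2, length(q)), rep(0.1, length(q)))
  k <- dimensionless_kratky(cv, list(rg = 10, i0 = 2))
  expect_equal(k$y, k$x^2)
  expect_false(kratky_peak(k)$interior)
})

test_that("extended dumbbells peak at higher Kratky coordinates than globules", {
  q <- seq(0.006, 0.35, length.out = 120)
  pe <- make_two_lobe_conformers(4, compact = FALSE, seed = 21)
  pc <- make_two_lobe_conformers(4, compact = TRUE, seed = 22)
  peak_of <- function(pool) {
    cv <- simulate_saxs(pool, q, noise_scale = 0)
    kratky_peak(dimensionless_kratky(cv, guinier_fit(cv)))
  }
  ke <- peak_of(pe)
  kc <- peak_of(pc)
  expect_gt(ke$x, kc$x)
  expect_gt(ke$y, kc$y)
})

test_that("ift_pr recovers the analytic sphere p(r) and Rg", {
  beads <- sphere_beads(1000, 20)
  q <- seq(0.005, 0.35, length.out = 80)
  cv <- debye_scattering(beads, q)
  f <- ift_pr(cv, dmax = 40)
  expect_equal(f$rg_real, sqrt(3 / 5) * 20, tolerance = 0.02)
  pan <- sphere_pr(f$r, 40)
  expect_gt(cor(f$p, pan), 0.995)
  expect_equal(f$p[1], 0)
  expect_equal(f$p[length(f$p)], 0)
})

test_that("the IFT forward transform refits noisy data with chi2 near 1", {
  beads <- sphere_beads(1000, 20)
  q <- seq(0.005, 0.35, length.out = 80)
  cv <- simulate_saxs(beads, q, noise_scale = 0.01, seed = 5)
  f <- ift_pr(cv, dmax = 40)
  expect_gt(f$chi2_red, 0.5)
  expect_lt(f$chi2_red, 2)
})

test_that("guinier and real-space Rg agree on noiseless globular data", {
  beads <- sphere_beads(600, 15, seed = 9)
  q <- seq(0.006, 0.4, length.out = 90)
  cv <- debye_scattering(beads, q)
  g <- guinier_fit(cv)
  f <- ift_pr(cv, dmax = 31)
  expect_equal(f$rg_real, g$rg, tolerance = 0.05)
})

test_that("estimate_dmax finds the sphere diameter within a grid step", {
  beads <- sphere_beads(1000, 20)
  q <- seq(0.005, 0.35, length.out = 80)
  grid <- seq(25, 60, by = 2.5)
  for (ns in c(0, 0.01)) {
    cv <- simulate_saxs(beads, q, noise_scale = ns, seed = 5)
    ed <- suppressWarnings(estimate_dmax(cv, grid))
    expect_lte(abs(ed$dmax - 40), 2.5)
    # under-sized Dmax must misfit systematically
    prof <- ed$profile
    expect_gt(prof$chi2_red[prof$dmax == 30], 10 * prof$chi2_red[prof$dmax == 40])
  }
})

test_that("compact pools yield smaller Dmax than extended pools", {
  q <- seq(0.008, 0.35, length.out = 70)
  ce <- simulate_saxs(make_two_lobe_conformers(4, FALSE, seed = 11), q,
    noise_scale = 0.01, seed = 3
  )
  cc <- simulate_saxs(make_two_lobe_conformers(4, TRUE, seed = 12), q,
    noise_scale = 0.01, seed = 4
  )
  de <- suppressWarnings(estimate_dmax(ce, seq(40, 90, by = 5)))
  dc <- suppressWarnings(estimate_dmax(cc, seq(30, 70, by = 5)))
  expect_lt(dc$dmax, de$dmax)
})

test_that("debye_scattering obeys its closed forms", {
  one <- debye_scattering(matrix(0, 1, 3), c(0, 0.1, 0.5), weights = 2)
  expect_equal(one$I, rep(4, 3))
  d <- 10
  two <- debye_scattering(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE),
    qgrid = c(0, 0.05, 0.2, 0.6)
  )
  expect_equal(two$I / two$I[1], (1 + sinc(c(0, 0.05, 0.2, 0.6) * d)) / 2)
  # I(0) = (sum of form factors)^2
  beads <- sphere_beads(100, 10)
  expect_equal(debye_scattering(beads, 0)$I, 100^2)
})

test_that("histogram acceleration matches the exact double sum to 0.1%", {
  beads <- sphere_beads(500, 18, seed = 4)
  q <- seq(0.01, 0.4, length.out = 60)
  ex <- debye_scattering(beads, q, method = "exact")
  hi <- debye_scattering(beads, q, method = "histogram")
  expect_lt(max(abs(hi$I - ex$I) / ex$I), 1e-3)
})

test_that("Guinier expansion of the Debye output matches the coordinate Rg", {
  beads <- sphere_beads(400, 14, seed = 7)
  rg <- bead_rg(beads)
  q <- seq(0.001, 0.5 / rg, length.out = 40) # qRg < 0.5
  cv <- debye_scattering(beads, q)
  slope <- coef(lm(log(cv$I) ~ I(q^2)))[[2]]
  expect_equal(sqrt(-3 * slope), rg, tolerance = 0.01)
})

test_that("reduced_chi2 is zero for scaled copies and scale-invariant", {
  beads <- sphere_beads(200, 12, seed = 3)
  q <- seq(0.01, 0.3, length.out = 50)
  model <- debye_scattering(beads, q)
  data <- saxs_curve(q, 7.3 * model$I, 0.01 * model$I)
  expect_lt(reduced_chi2(model, data)$chi2_red, 1e-18)
  scaled <- saxs_curve(q, 1e4 * model$I, rep(1, length(q)))
  f1 <- reduced_chi2(model, data)
  f2 <- reduced_chi2(scaled, data)
  expect_equal(f1$chi2_red, f2$chi2_red, tolerance = 1e-9)
})

test_that("reduced_chi2 averages 1 over noise replicates", {
  beads <- sphere_beads(200, 12, seed = 3)
  q <- seq(0.01, 0.3, length.out = 60)
  model <- debye_scattering(beads, q)
  sig <- 0.01 * sqrt(model$I * model$I[1])
  chis <- withr::with_seed(42, {
    vapply(1:100, function(i) {
      data <- saxs_curve(q, model$I + rnorm(length(q), 0, sig), sig)
      reduced_chi2(model, data)$chi2_red
    }, numeric(1))
  })
  expect_equal(mean(chis), 1.0, tolerance = 0.15)
})

test_that("offset fitting removes a constant background", {
  q <- seq(0.01, 0.3, length.out = 40)
  model <- saxs_curve(q, exp(-q^2 * 60), rep(1, length(q)))
  data <- saxs_curve(q, 2 * exp(-q^2 * 60) + 0.5, rep(0.01, length(q)))
  expect_gt(reduced_chi2(model, data)$chi2_red, 1)
  withoff <- reduced_chi2(model, data, fit_offset = TRUE)
  expect_lt(withoff$chi2_red, 1e-18)
  expect_equal(withoff$offset, 0.5, tolerance = 1e-6)
})
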