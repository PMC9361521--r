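test_that("conformer generation is a pure function of its seed", {
  p1 <- make_two_lobe_conformers(3, compact = FALSE, seed = 5)
  p2 <- make_two_lobe_conformers(3, compact = FALSE, seed = 5)
  expect_identical(p1$conformers, p2$conformers)
  p3 <- make_two_lobe_conformers(3, compact = FALSE, seed = 6)
  expect_false(identical(p1$conformers, p3$conformers))
})

test_that("compact pools are always smaller than extended pools", {
  for (s in c(1, 17, 203)) {
    re <- pool_rg(make_two_lobe_conformers(4, compact = FALSE, seed = s))$rg
    rc <- pool_rg(make_two_lobe_conformers(4, compact = TRUE, seed = s))$rg
    expect_gt(min(re), max(rc))
  }
})

test_that("default geometry hits the dumbbell/globule Rg scale", {
  # extended mean Rg in [21, 24] A and compact in [16, 18] A, the scale of
  # the dumbbell-to-globule collapse (exact coordinate Rg as oracle)
  re <- pool_rg(make_two_lobe_conformers(12, compact = FALSE, seed = 11))$rg
  rc <- pool_rg(make_two_lobe_conformers(12, compact = TRUE, seed = 11))$rg
  expect_gt(mean(re), 21)
  expect_lt(mean(re), 24)
  expect_gt(mean(rc), 16)
  expect_lt(mean(rc), 18)
})

test_that("simulated SAXS is the exact Debye curve at zero noise", {
  beads <- sphere_beads(80, 12)
  q <- seq(0.01, 0.3, length.out = 40)
  cv <- simulate_saxs(beads, q, noise_scale = 0)
  expect_equal(cv$I, debye_scattering(beads, q)$I)
})

test_that("pool scattering mixes linearly in the weights", {
  pool <- make_two_lobe_conformers(2, compact = TRUE, seed = 3)
  q <- seq(0.01, 0.3, length.out = 30)
  mixed <- simulate_saxs(pool, q, noise_scale = 0, weights = c(0.5, 0.5))
  i1 <- debye_scattering(pool$conformers[[1]], q)$I
  i2 <- debye_scattering(pool$conformers[[2]], q)$I
  expect_equal(mixed$I, (i1 + i2) / 2)
})

test_that("Guinier refit of a noiseless simulated curve recovers the exact Rg", {
  pool <- make_two_lobe_conformers(1, compact = TRUE, seed = 8)
  rg_true <- bead_rg(pool$conformers[[1]])
  q <- seq(0.004, 0.2, length.out = 120)
  cv <- simulate_saxs(pool$conformers[[1]], q, noise_scale = 0)
  expect_equal(guinier_fit(cv)$rg, rg_true, tolerance = 0.02)
})

test_that("relaxation decays follow the closed form and TRACT ordering", {
  d <- simulate_relaxation(delays = c(0, 0.1), rate = 10, noise_sd = 0)
  expect_equal(d$signal[2] / d$signal[1], exp(-1))
  # R_beta > R_alpha over the whole tau_c range of interest
  for (tc in seq(1, 20, by = 2)) {
    tr <- simulate_relaxation(
      delays = c(0.01, 0.1), tau_c = tc, field = 600, noise_sd = 0
    )
    gt <- attr(tr, "ground_truth")$rates
    expect_gt(gt[["beta"]], gt[["alpha"]])
  }
  s1 <- simulate_relaxation(delays = c(0, 0.05, 0.1), rate = 8, noise_sd = 1, seed = 4)
  s2 <- simulate_relaxation(delays = c(0, 0.05, 0.1), rate = 8, noise_sd = 1, seed = 4)
  expect_identical(s1, s2)
  expect_error(simulate_relaxation(delays = 0.1, rate = 5), "2 delays")
})

test_that("HDX generator respects its kinetic limits", {
  peps <- cam_demo_peptides()[1:3, ]
  # infinite protection: no uptake at any time
  pf_inf <- rep(1e12, nchar(cam_sequence()))
  ds <- simulate_hdx(pf_inf, pf_inf,
    peptides = peps, times = c(10, 7200),
    replicates = 1, noise_sd = 0
  )
  expect_true(all(abs(ds$uptake) < 1e-6))
  # no protection, long time: saturation at max_exchangeable * d_fraction
  pf_one <- rep(1, nchar(cam_sequence()))
  ds2 <- simulate_hdx(pf_one, pf_one,
    peptides = peps, times = 1e9,
    replicates = 1, noise_sd = 0, d_fraction = 0.8
  )
  sat <- ds2$uptake[ds2$state == "free"]
  expect_equal(sat, 0.8 * max_exchangeable(peps$sequence), tolerance = 1e-8)
  expect_error(
    simulate_hdx(pf_one, pf_one,
      peptides = tibble::tibble(start = 1, end = 999)
    ),
    "outside protein"
  )
})

test_that("ITC generator inverts exactly through the one-site fit", {
  tit <- simulate_itc(kd = 1e-6, n = 1.0, dh = -1e4, noise_sd = 0)
  fit <- one_site_fit(tit)
  expect_equal(fit$kd, 1e-6, tolerance = 1e-6)
  expect_equal(fit$n, 1.0, tolerance = 1e-6)
  expect_equal(fit$dh, -1e4, tolerance = 1e-6)
  # dH = 0: every heat equals the dilution offset
  t0 <- simulate_itc(kd = 1e-6, n = 1, dh = 0, dilution_offset = 0.7, noise_sd = 0)
  expect_equal(t0$heats, rep(0.7, length(t0$heats)))
})

test_that("generator outputs pass the corresponding readers unmodified", {
  ds <- simulate_hdx(
    protection_profile(factor = 1), protection_profile(),
    peptides = cam_demo_peptides()[1:4, ], times = c(10, 60), seed = 2
  )
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ds, p)
  expect_no_error(read_uptake_table(p))

  cv <- simulate_saxs(sphere_beads(50, 10), seq(0.01, 0.3, length.out = 30),
    noise_scale = 0.01, seed = 3
  )
  pd <- withr::local_tempfile(fileext = ".dat")
  write_saxs_dat(cv, pd)
  back <- read_saxs_dat(pd)
  expect_equal(back$I, cv$I, tolerance = 1e-7)
})
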