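test_that("fit_decay reproduces exact rates", {
  t6 <- c(0.001, 0.01, 0.03, 0.06, 0.1, 0.2)
  f <- fit_decay(t6, 100 * exp(-10 * t6), noise_sd = 0)
  expect_equal(f$rate, 10, tolerance = 1e-8)
  expect_equal(f$amplitude, 100, tolerance = 1e-6)
  # two-point closed form
  f2 <- fit_decay(c(0, 0.1), c(100, 100 * exp(-1)), noise_sd = 0)
  expect_equal(f2$rate, 10, tolerance = 1e-6)
})

test_that("Monte Carlo rate errors scale linearly with the noise SD", {
  t6 <- c(0.001, 0.01, 0.03, 0.06, 0.1, 0.2)
  y <- 100 * exp(-10 * t6)
  e1 <- fit_decay(t6, y, noise_sd = 0.3, n_mc = 400, seed = 2)$err
  e2 <- fit_decay(t6, y, noise_sd = 3, n_mc = 400, seed = 2)$err
  expect_equal(e2 / e1, 10, tolerance = 0.15)
  # and vanish as noise goes to zero
  expect_equal(fit_decay(t6, y, noise_sd = 0)$err, 0)
})

test_that("non-decaying data are flagged", {
  t4 <- c(0.01, 0.05, 0.1, 0.2)
  expect_warning(f <- fit_decay(t4, 10 * exp(2 * t4), noise_sd = 0), "decay")
  expect_false(f$decaying)
})

test_that("TRACT round trip is the identity on tau_c in [1, 20] ns", {
  for (tc in c(1, 2.5, 4.5, 5.2, 8, 12, 20)) {
    eta <- tract_eta_xy(tc, 600)
    fit <- tract_tauc(25 - eta, 25 + eta, field = 600, n_mc = 0)
    expect_equal(fit$tau_c, tc, tolerance = 1e-3)
  }
})

test_that("the TRACT rate difference increases with tau_c", {
  etas <- tract_eta_xy(seq(1, 20, by = 0.5), 600)
  expect_true(all(diff(etas) > 0))
})

test_that("tau_c recovery works through the full decay-fit route", {
  delays <- c(0.001, 0.005, 0.01, 0.02, 0.04, 0.08, 0.12, 0.16, 0.22, 0.3)
  dec <- simulate_relaxation(delays, tau_c = 5.2, field = 600, noise_sd = 0)
  fits <- lapply(split(dec, dec$component), function(d) {
    fit_decay(d$delay, d$signal, noise_sd = 0)
  })
  fit <- tract_tauc(fits$alpha, fits$beta, field = 600, n_mc = 0)
  expect_equal(fit$tau_c, 5.2, tolerance = 1e-3)
})

test_that("Monte Carlo confidence interval brackets the estimate", {
  eta <- tract_eta_xy(5.2, 600)
  fit <- tract_tauc(25 - eta, 25 + eta,
    field = 600,
    r_alpha_err = 0.3, r_beta_err = 0.3, n_mc = 400, seed = 3
  )
  expect_lt(fit$ci[1], fit$tau_c)
  expect_gt(fit$ci[2], fit$tau_c)
})

test_that("the SED prediction matches the compact holo-CaM scale", {
  # M = 16706 g/mol, vbar = 0.73 cm^3/g, 37 C water: ~5.2 ns
  tc <- sed_tauc(16706, 0.73, 310.15, eta = 0.6913, hydration = 2.8)
  expect_equal(tc, 5.2, tolerance = 0.05 * 5.2)
  # bracketed over the plausible hydration range
  tcs <- vapply(seq(2.8, 3.2, by = 0.1), function(h) {
    sed_tauc(16706, 0.73, 310.15, eta = 0.6913, hydration = h)
  }, numeric(1))
  expect_true(all(tcs > 4.9 & tcs < 5.5))
})

test_that("SED obeys its scaling laws", {
  base <- sed_tauc(16706, 0.73, 298.15, eta = 0.89, hydration = 2.8)
  expect_equal(
    sed_tauc(16706, 0.73, 298.15, eta = 1.78, hydration = 2.8) / base, 2,
    tolerance = 1e-9
  )
  # hydration 0: r ~ M^(1/3), so 8x mass doubles r and scales tau_c by 8
  t1 <- sed_tauc(1e4, 0.73, 298.15, eta = 0.89, hydration = 0)
  t8 <- sed_tauc(8e4, 0.73, 298.15, eta = 0.89, hydration = 0)
  expect_equal(t8 / t1, 8, tolerance = 1e-9)
})

test_that("viscosity correction behaves like the embedded tables", {
  pure <- solvent_model(298.15, d2o = 0, dmso = 0)
  expect_equal(viscosity_correct(5, pure), 5)
  d2o <- solvent_model(298.15, d2o = 1)
  expect_equal(d2o$eta / d2o$eta_h2o, 1.23, tolerance = 0.01)
  # monotone in the D2O fraction
  taus <- vapply(seq(0, 1, by = 0.25), function(f) {
    viscosity_correct(5, solvent_model(298.15, d2o = f))
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_error(solvent_model(350, d2o = 0.1), "outside")
})

test_that("csp implements the weighted-shift formula", {
  mk <- function(dh, dn) {
    tibble::tibble(residue = seq_along(dh), d_h = 8 + dh, d_n = 118 + dn)
  }
  free <- mk(c(0, 0, 0), c(0, 0, 0))
  bound <- mk(c(0, 0, 0.06), c(0, 1, 0.5))
  out <- csp(free, bound)
  expect_equal(out$csp[1], 0)
  expect_equal(out$csp[2], 0.159)
  expect_equal(out$csp[3], sqrt(0.0795^2 + 0.06^2), tolerance = 1e-9)
  expect_equal(round(out$csp[3], 4), 0.0996)
})

test_that("csp depends only on difference magnitudes (swap symmetry)", {
  withr::with_seed(5, {
    free <- tibble::tibble(residue = 1:20, d_h = rnorm(20, 8), d_n = rnorm(20, 118))
    bound <- tibble::tibble(
      residue = 1:20, d_h = free$d_h + rnorm(20, 0, 0.1),
      d_n = free$d_n + rnorm(20, 0, 0.5)
    )
  })
  expect_equal(csp(free, bound)$csp, csp(bound, free)$csp)
})

test_that("unmatched residues are carried as missing, duplicates rejected", {
  free <- tibble::tibble(residue = 1:3, d_h = c(8, 8, 8), d_n = c(118, 118, 118))
  bound <- tibble::tibble(residue = c(1, 3, 4), d_h = 8.1, d_n = 118.4)
  out <- csp(free, bound)
  expect_equal(nrow(out), 4)
  expect_true(out$missing[out$residue == 2])
  expect_true(out$missing[out$residue == 4])
  expect_error(csp(rbind(free, free[1, ]), bound), "duplicate")
})

test_that("csp classification uses inclusive thresholds", {
  rec <- tibble::tibble(
    residue = 1:5, csp = c(0.14, 0.07, 0.0699, 0.2, 0.01),
    missing = FALSE
  )
  out <- classify_csp(rec)
  expect_equal(
    as.character(out$category),
    c("very_strong", "strong", "none", "very_strong", "none")
  )
  counts <- attr(out, "counts")
  expect_equal(as.integer(counts[c("none", "strong", "very_strong")]), c(2L, 1L, 2L))
  empty <- classify_csp(rec[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("nOe banding reproduces the legend thresholds and its gap", {
  mk <- function(ratios) {
    tibble::tibble(residue = seq_along(ratios), sat = 100 * ratios, unsat = 100)
  }
  free <- mk(rep(0.5, 4))
  bound <- mk(0.5 + c(0.18, 0.10, 0.17, 0.05))
  out <- noe_analysis(free, bound, noise_sd = 0.01)
  expect_equal(
    as.character(out$band),
    c("very_high", "high", "unclassified", "none")
  )
  # identity ratio
  same <- noe_analysis(mk(1), mk(1), noise_sd = 0.01)
  expect_equal(same$free_noe, 1)
  # reference intensity within noise of zero is unusable
  weak <- noe_analysis(
    tibble::tibble(residue = 1, sat = 1, unsat = 2),
    tibble::tibble(residue = 1, sat = 1, unsat = 2),
    noise_sd = 1
  )
  expect_false(weak$usable)
})

test_that("propagated nOe errors match Monte Carlo at decent SNR", {
  sat <- 70
  unsat <- 100
  noise <- 2 # SNR 35-50
  out <- noe_analysis(
    tibble::tibble(residue = 1, sat = sat, unsat = unsat),
    tibble::tibble(residue = 1, sat = sat, unsat = unsat),
    noise_sd = noise
  )
  mc <- withr::with_seed(8, {
    vapply(1:4000, function(i) {
      (sat + rnorm(1, 0, noise)) / (unsat + rnorm(1, 0, noise))
    }, numeric(1))
  })
  expect_equal(out$free_err, sd(mc), tolerance = 0.1)
})

test_that("the unassigned-residue partition splits 8/5/18 over the lobes", {
  unassigned <- c(
    8, 12, 14, 16, 38, 51, 52, 72, 75:79, 82, 83, 88, 92, 106, 107,
    112, 114, 124, 126, 127, 129, 130, 139, 143:146
  )
  expect_equal(length(unassigned), 31)
  part <- partition_regions(unassigned)
  counts <- table(part$region)
  expect_equal(unname(counts[["N-lobe"]]), 8)
  expect_equal(unname(counts[["linker"]]), 5)
  expect_equal(unname(counts[["C-lobe"]]), 18)
})
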