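test_that("deuterium bookkeeping reproduces the labeling and quench mixes", {
  labeling <- deuterium_fraction(
    data.frame(volume = c(30, 120), fraction = c(0, 0.9998))
  )
  expect_equal(labeling, 0.79984, tolerance = 1e-6)
  expect_equal(round(labeling, 2), 0.80)
  quench <- deuterium_fraction(
    data.frame(volume = c(20, 40), fraction = c(labeling, 0))
  )
  expect_equal(round(quench, 2), 0.27)
  expect_equal(
    deuterium_fraction(data.frame(volume = c(10, 20), fraction = c(0, 0))), 0
  )
  expect_error(deuterium_fraction(data.frame(volume = numeric(), fraction = numeric())))
})

test_that("max_exchangeable follows the N-1-proline convention", {
  expect_equal(max_exchangeable("AAAAAAAAAA"), 9L)
  expect_equal(max_exchangeable("APLG"), 2L)
  expect_equal(max_exchangeable("P"), 0L)
  expect_equal(max_exchangeable(c("AG", "PPA")), c(1L, 1L))
  expect_error(max_exchangeable("AXZ"), "unknown residue")
})

test_that("fractional uptake is the scaled ratio and scale-consistent", {
  expect_equal(fractional_uptake(2.0, 5, 0.8), 50)
  expect_equal(fractional_uptake(0, 5, 0.8), 0)
  expect_equal(fractional_uptake(4 * 0.8, 4, 0.8), 100)
  # doubling uptake and capacity together leaves RFU unchanged
  expect_equal(fractional_uptake(2, 5, 0.8), fractional_uptake(4, 10, 0.8))
  expect_error(fractional_uptake(1, 0, 0.8), "max_d")
})

test_that("delta_uptake is antisymmetric and zero on identical states", {
  pf <- protection_profile(factor = 1)
  ds <- simulate_hdx(pf, pf,
    peptides = cam_demo_peptides()[1:5, ],
    times = c(10, 600), noise_sd = 0, seed = 1
  )
  du <- delta_uptake(ds)
  expect_true(all(abs(du$summary$avg_delta) < 1e-9))

  pf2 <- protection_profile(factor = 10)
  ds2 <- simulate_hdx(pf, pf2,
    peptides = cam_demo_peptides()[1:5, ],
    times = c(10, 600), noise_sd = 0.02, seed = 2
  )
  ab <- delta_uptake(ds2, "free", "bound")$summary$avg_delta
  ba <- delta_uptake(ds2, "bound", "free")$summary$avg_delta
  expect_equal(ab, -ba)
})

test_that("hand-built deltas average as stated", {
  ds <- tidyr::crossing(
    tibble::tibble(peptide = 1L, start = 1L, end = 11L, sequence = "AAAAAAAAAAA"),
    state = c("free", "bound"), time = c(10, 100), replicate = 1:2
  )
  # bound is 10% lower at t=10 and 20% lower at t=100 (max_d = 10, dfrac = 1)
  ds$uptake <- with(ds, ifelse(state == "free", 5,
    ifelse(time == 10, 5 - 1, 5 - 2)
  ))
  du <- delta_uptake(ds, d_fraction = 1)
  expect_equal(du$per_time$delta_pct, c(-10, -20))
  expect_equal(du$summary$avg_delta, -15)
})

test_that("peptides in one state only are excluded with a warning", {
  pf <- protection_profile(factor = 1)
  ds <- simulate_hdx(pf, pf,
    peptides = cam_demo_peptides()[1:3, ],
    times = c(10, 60), seed = 1
  )
  ds_broken <- dplyr::filter(ds, !(.data$peptide == 2 & .data$state == "bound"))
  expect_warning(du <- delta_uptake(ds_broken), "only one state")
  expect_false(2 %in% du$summary$peptide)
})

test_that("protection planted in lobe segments shows up there and not in the linker", {
  ds <- simulate_hdx(
    protection_profile(factor = 1), protection_profile(factor = 20),
    seed = 3
  )
  st <- wald_fdr(ds)
  protected_peps <- st$start >= 21 & st$end <= 45 | st$start >= 84 & st$end <= 113
  expect_true(all(st$avg_delta[protected_peps] < -10))
  expect_true(all(st$significant[protected_peps]))
  linker <- dplyr::filter(st, .data$start == 73, .data$end == 83)
  expect_lt(abs(linker$avg_delta), 5)
  expect_false(linker$significant)
})

test_that("a strong planted magnitude shift gives a tiny Wald p", {
  ds <- simulate_hdx(
    protection_profile(factor = 1), protection_profile(factor = 20),
    seed = 4
  )
  st <- wald_fdr(ds)
  target <- dplyr::filter(st, .data$start == 21, .data$end == 32)
  expect_lt(target$p_magnitude, 1e-4)
})

test_that("BH reduces to the raw p-value for a single peptide", {
  pf <- protection_profile(factor = 1)
  ds <- simulate_hdx(pf, pf * 2,
    peptides = cam_demo_peptides()[3, ],
    times = c(10, 60, 600), seed = 5
  )
  st <- wald_fdr(ds)
  expect_equal(st$p_magnitude_adj, st$p_magnitude)
  expect_equal(st$p_kinetics_adj, st$p_kinetics)
})

test_that("degenerate zero-variance data yield flagged NA p-values", {
  ds <- tidyr::crossing(
    tibble::tibble(peptide = 1L, start = 1L, end = 6L, sequence = "AAAAAA"),
    state = c("free", "bound"), time = c(10, 100), replicate = 1:3
  )
  ds$uptake <- 2 # exact ties everywhere
  st <- wald_fdr(ds)
  expect_true(st$degenerate)
  expect_true(is.na(st$p_magnitude))
  expect_false(st$significant)
})

test_that("residue painting assigns the shortest covering peptide", {
  summ <- tibble::tibble(
    peptide = 1:2, start = c(1L, 3L), end = c(10L, 5L),
    avg_delta = c(-20, -5)
  )
  map <- residue_map(summ, 12)
  expect_equal(map$value[2], -20)
  expect_equal(map$value[4], -5) # covered by the shorter peptide
  expect_true(is.na(map$value[12]))
})
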