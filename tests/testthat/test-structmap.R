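test_that("hand-written PDB files round-trip exactly", {
  m <- toy_structure()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, p)
  back <- read_structure(p)
  expect_equal(nrow(back), nrow(m))
  expect_equal(back$x, m$x, tolerance = 1e-9)
  expect_equal(back$resno, m$resno)
  expect_equal(back$b, m$b, tolerance = 0.005)
})

test_that("the altloc policy keeps only blank/'A' locations", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.50 10.00           C",
    "ATOM      2  CA BALA A   1       0.500   0.000   0.000  0.50 10.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00 12.00           C",
    "END"
  ), p)
  m <- read_structure(p)
  expect_equal(nrow(m), 2)
  expect_true(all(m$altloc %in% c("", "A")))
})

test_that("kabsch_rmsd is zero for identical and rigidly moved copies", {
  withr::with_seed(1, {
    P <- matrix(rnorm(30, sd = 5), 10, 3)
  })
  expect_equal(as.numeric(kabsch_rmsd(P, P)), 0, tolerance = 1e-12)
  moved <- rotate_z(P, 0.7, shift = 12)
  expect_lt(kabsch_rmsd(P, moved), 1e-9)
})

test_that("kabsch_rmsd is symmetric and rigid-transform invariant", {
  withr::with_seed(2, {
    P <- matrix(rnorm(45, sd = 5), 15, 3)
    Q <- P + matrix(rnorm(45, sd = 0.8), 15, 3)
  })
  r1 <- kabsch_rmsd(P, Q)
  expect_equal(r1, kabsch_rmsd(Q, P), tolerance = 1e-9)
  expect_equal(r1, kabsch_rmsd(rotate_z(P, 1.1, 4), Q), tolerance = 1e-9)
  expect_equal(r1, kabsch_rmsd(P, rotate_z(Q, -2.3, -7)), tolerance = 1e-9)
})

test_that("kabsch_rmsd agrees with an independent superposition routine", {
  withr::with_seed(3, {
    P <- matrix(rnorm(60, sd = 6), 20, 3)
    Q <- rotate_z(P + matrix(rnorm(60, sd = 1), 20, 3), 0.9, 5)
  })
  ours <- as.numeric(kabsch_rmsd(P, Q))
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(P)), mobile = as.vector(t(Q)))
  )
  theirs <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - P)^2)))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("atom matching goes through chain/residue/name keys", {
  m <- toy_structure()
  m2 <- m
  m2$x <- m$x + 0.5 # uniform shift: superposition removes it
  expect_lt(as.numeric(kabsch_rmsd(m, m2, selection = list(name = c("CA", "CB")))), 1e-9)
  expect_error(
    kabsch_rmsd(m, m2, selection = list(name = "OXT")),
    "fewer than 3"
  )
})

test_that("ligand contacts respect the cutoff and are monotone in it", {
  m <- toy_structure()
  ct <- ligand_contacts(m, "LIG", cutoff = 3.9)
  expect_true(all(ct$min_dist <= 3.9))
  # residue 3 sits 25 A away: never a contact
  expect_false(3 %in% ct$resno)
  ct_wide <- ligand_contacts(m, "LIG", cutoff = 8)
  expect_true(all(ct$resno %in% ct_wide$resno))
  expect_error(ligand_contacts(m, "XYZ"), "absent")
})

test_that("a 3.8 A pair is a contact at the default cutoff, a 4.0 A pair is not", {
  mk <- function(d) {
    m <- tibble::tibble(
      serial = 1:2, name = c("CA", "C1"), element = "C",
      resname = c("ALA", "LIG"), chain = "A", resno = c(1L, 9L),
      altloc = "", occupancy = 1, b = 0,
      x = c(0, d), y = 0, z = 0, record = c("ATOM", "HETATM")
    )
    class(m) <- c("structure_model", class(m))
    m
  }
  expect_equal(ligand_contacts(mk(3.8), "LIG")$resno, 1)
  expect_equal(nrow(ligand_contacts(mk(4.0), "LIG")), 0)
})

test_that("painting replaces B-factors residue-wise and round-trips", {
  m <- toy_structure()
  painted <- paint_residue_values(
    m, tibble::tibble(residue = c(1, 2), value = c(-12.34, 5.67)),
    missing_value = -1
  )
  expect_equal(painted$b[painted$resno == 1], c(-12.34, -12.34))
  expect_equal(painted$b[painted$resno == 3], -1)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(painted, p)
  back <- read_structure(p)
  expect_equal(back$b, painted$b, tolerance = 0.005) # PDB column precision
  # constant painting hits every atom
  const <- paint_residue_values(
    m, tibble::tibble(residue = unique(m$resno), value = 1)
  )
  expect_true(all(const$b == 1))
  expect_error(paint_residue_values(m, tibble::tibble(residue = integer(), value = numeric())), "empty")
})
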