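# Shared fixtures, built in code at test time.

# beads filling a solid sphere of the given radius (uniform density)
sphere_beads <- function(n, radius, seed = 2) {
  withr::with_seed(seed, {
    pts <- matrix(runif(3 * n * 3, -radius, radius), ncol = 3)
    pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
    while (nrow(pts) < n) {
      more <- matrix(runif(3 * n * 3, -radius, radius), ncol = 3)
      pts <- rbind(pts, more[rowSums(more^2) <= radius^2, , drop = FALSE])
    }
    pts[seq_len(n), ]
  })
}

# exact Guinier-law curve
guinier_curve <- function(rg, i0 = 1, q = seq(0.001, 0.3, by = 5e-4),
                          sigma = 1e-4) {
  saxs_curve(q, i0 * exp(-q^2 * rg^2 / 3), rep(sigma, length(q)))
}

# analytic p(r) of a solid sphere of diameter D (arbitrary scale)
sphere_pr <- function(r, D) {
  x <- r / D
  p <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  p[x > 1] <- 0
  p
}

# small hand-written protein + ligand structure model
toy_structure <- function() {
  m <- tibble::tibble(
    serial = 1:6,
    name = c("CA", "CB", "CA", "CA", "C1", "CL1"),
    element = c("C", "C", "C", "C", "C", "CL"),
    resname = c("ALA", "ALA", "GLY", "SER", "LIG", "LIG"),
    chain = "A",
    resno = c(1L, 1L, 2L, 3L, 50L, 50L),
    altloc = "",
    occupancy = 1,
    b = c(10, 20, 30, 40, 0, 0),
    x = c(0, 1.4, 3.8, 30, 5.0, 7.0),
    y = c(0, 0.5, 0, 0, 0.8, 0.8),
    z = 0,
    record = c("ATOM", "ATOM", "ATOM", "ATOM", "HETATM", "HETATM")
  )
  class(m) <- c("structure_model", class(m))
  m
}

rotate_z <- function(coords, angle, shift = 0) {
  R <- matrix(
    c(cos(angle), -sin(angle), 0, sin(angle), cos(angle), 0, 0, 0, 1),
    3, 3
  )
  coords %*% R + shift
}
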