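# Synthetic two-lobe bead conformers: a coarse-grained stand-in for a
# full-atom conformer pool. Each lobe is a random close packing of beads
# inside a sphere; in extended mode the lobes are joined by a self-avoiding
# persistent linker walk, in compact mode they are placed in contact as a
# single globular cluster.

#' Default two-lobe bead geometry
#'
#' Beads per lobe, lobe radius, linker length/step and excluded-volume
#' radius sized so that the default extended pool has a mean Rg of 21-24 A
#' and the compact pool 16-18 A, the scale of calmodulin's dumbbell-to-
#' globule transition.
#'
#' @return A named list of geometry parameters (Angstrom units).
#' @export
lobe_geometry <- function() {
  list(
    beads_per_lobe = 60,
    lobe_radius = 12,
    linker_beads = 6,
    step = 3.8,
    excl_radius = 1.9,
    compact_separation = 27.5
  )
}

#' Generate a pool of two-lobe bead conformers
#'
#' Extended mode joins two rigid bead lobes by a self-avoiding random linker
#' walk with modest directional persistence, producing dumbbell-like models
#' of varying inter-lobe separation. Compact mode places the lobes at a
#' fixed near-contact separation with a collapsed linker, producing a single
#' globular cluster. Output is a pure function of `(n, compact, geometry,
#' seed)`.
#'
#' @param n Number of conformers (>= 1).
#' @param compact Logical; compact globule instead of extended dumbbell.
#' @param geometry Named list as from [lobe_geometry()].
#' @param seed Integer seed.
#' @param max_retry Bounded retries for the self-avoiding walk before
#'   raising an error.
#' @return A `conformer_pool`: list with elements `conformers` (list of
#'   n x 3 coordinate matrices), `labels`, `geometry`, `seed`.
#' @export
#' @examples
#' pool <- make_two_lobe_conformers(2, compact = TRUE, seed = 1)
#' length(pool$conformers)
make_two_lobe_conformers <- function(n, compact = FALSE,
                                     geometry = lobe_geometry(), seed = 1,
                                     max_retry = 200) {
  stopifnot(n >= 1)
  geometry <- utils::modifyList(lobe_geometry(), geometry)
  if (any(unlist(geometry) <= 0)) abort("geometry parameters must be positive")
  conformers <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      one_conformer(compact, geometry, max_retry)
    })
  })
  structure(
    list(
      conformers = conformers,
      labels = rep(if (compact) "compact" else "extended", n),
      geometry = geometry,
      seed = seed
    ),
    class = "conformer_pool"
  )
}

#' @export
print.conformer_pool <- function(x, ...) {
  rg <- vapply(x$conformers, bead_rg, numeric(1))
  cat(sprintf(
    "<conformer_pool> %d %s conformers, %d beads each, Rg %.1f-%.1f A\n",
    length(x$conformers), x$labels[1], nrow(x$conformers[[1]]),
    min(rg), max(rg)
  ))
  invisible(x)
}

#' Radii of gyration of a conformer pool
#'
#' Exact second-moment Rg about the centroid for each bead model.
#'
#' @param pool A `conformer_pool`.
#' @return A tibble with `conformer`, `label`, `rg`.
#' @export
pool_rg <- function(pool) {
  tibble(
    conformer = seq_along(pool$conformers),
    label = pool$labels,
    rg = vapply(pool$conformers, bead_rg, numeric(1))
  )
}

one_conformer <- function(compact, g, max_retry) {
  excl_d <- 2 * g$excl_radius
  lobe_a <- pack_sphere(g$beads_per_lobe, g$lobe_radius, excl_d, max_retry)
  lobe_b <- pack_sphere(g$beads_per_lobe, g$lobe_radius, excl_d, max_retry)
  if (compact) {
    sep <- g$compact_separation
    linker <- collapsed_linker(g, sep)
    coords <- rbind(
      sweep(lobe_a, 2, c(-sep / 2, 0, 0), "+"),
      linker,
      sweep(lobe_b, 2, c(sep / 2, 0, 0), "+")
    )
  } else {
    walk <- linker_walk(g, excl_d, lobe_a, max_retry)
    # attach lobe B at the linker end, continuing the exit direction
    end_dir <- walk$dir
    b_center <- walk$path[nrow(walk$path), ] + end_dir * g$lobe_radius
    coords <- rbind(lobe_a, walk$path, sweep(lobe_b, 2, b_center, "+"))
  }
  coords
}

# random sequential packing of n beads inside a sphere with a minimum
# inter-bead distance
pack_sphere <- function(n, radius, min_dist, max_retry) {
  pts <- matrix(NA_real_, n, 3)
  placed <- 0
  tries <- 0
  while (placed < n) {
    cand <- runif(3, -radius, radius)
    if (sum(cand^2) > radius^2) next
    ok <- placed == 0 ||
      min(colSums((t(pts[seq_len(placed), , drop = FALSE]) - cand)^2)) >= min_dist^2
    if (ok) {
      placed <- placed + 1
      pts[placed, ] <- cand
      tries <- 0
    } else {
      tries <- tries + 1
      if (tries > max_retry * 50) abort("bead packing infeasible for this geometry")
    }
  }
  pts
}

# persistent self-avoiding walk leaving lobe A along +x
linker_walk <- function(g, excl_d, lobe, max_retry) {
  for (attempt in seq_len(max_retry)) {
    start <- c(g$lobe_radius + g$excl_radius, 0, 0)
    dir <- c(1, 0, 0)
    path <- matrix(NA_real_, g$linker_beads, 3)
    pos <- start
    path[1, ] <- pos
    ok <- TRUE
    for (i in seq_len(g$linker_beads - 1)) {
      step_ok <- FALSE
      for (k in seq_len(20)) {
        cand_dir <- jitter_direction(dir, max_angle = 40 * pi / 180)
        cand <- pos + cand_dir * g$step
        prev <- rbind(lobe, path[seq_len(i), , drop = FALSE])
        if (min(colSums((t(prev) - cand)^2)) >= (0.9 * excl_d)^2) {
          pos <- cand
          dir <- cand_dir
          path[i + 1, ] <- pos
          step_ok <- TRUE
          break
        }
      }
      if (!step_ok) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      return(list(path = path, dir = dir))
    }
  }
  abort("self-avoiding linker walk infeasible after bounded retries")
}

# short collapsed linker strung between the lobes of a compact conformer
collapsed_linker <- function(g, sep) {
  t <- seq(-0.5, 0.5, length.out = g$linker_beads)
  cbind(
    t * (sep - 2 * g$lobe_radius + 2 * g$step),
    g$lobe_radius * 0.6 + runif(g$linker_beads, -1, 1),
    runif(g$linker_beads, -1, 1)
  )
}

# unit vector within max_angle of dir
jitter_direction <- function(dir, max_angle) {
  repeat {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2))
    cand <- dir + v * tan(runif(1, 0, max_angle))
    cand <- cand / sqrt(sum(cand^2))
    if (sum(cand * dir) > cos(max_angle)) {
      return(cand)
    }
  }
}
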