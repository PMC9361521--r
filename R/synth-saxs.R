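#' Simulate a noisy SAXS curve from a bead model or weighted pool
#'
#' Computes the Debye intensity of a single conformer, or the weighted
#' average over a pool, then adds Gaussian noise with
#' `sigma(q) = noise_scale * sqrt(I(q) * I(0))` (floor-clipped), the usual
#' counting-statistics-like envelope that decays with intensity.
#'
#' @param model An n x 3 coordinate matrix, a data frame with `x`,`y`,`z`,
#'   or a `conformer_pool`.
#' @param qgrid Momentum transfer grid (1/Angstrom).
#' @param noise_scale Relative noise amplitude (>= 0; 0 gives the exact
#'   Debye curve).
#' @param seed Integer seed.
#' @param weights For a pool: mixing weights (default uniform); normalized
#'   to sum to 1.
#' @return A [saxs_curve()] with ground-truth parameters in its metadata.
#' @export
simulate_saxs <- function(model, qgrid, noise_scale = 0.005, seed = 1,
                          weights = NULL) {
  if (noise_scale < 0) abort("noise_scale must be >= 0")
  if (inherits(model, "conformer_pool")) {
    curves <- lapply(model$conformers, debye_scattering, qgrid = qgrid)
    w <- weights %||% rep(1, length(curves))
    if (length(w) != length(curves)) abort("one weight per conformer required")
    w <- w / sum(w)
    I <- Reduce(`+`, purrr::map2(curves, w, function(cv, wi) wi * cv$I))
    truth <- sprintf(
      "ground truth: pool of %d %s conformers, weights %s",
      length(curves), model$labels[1], paste(signif(w, 4), collapse = ",")
    )
  } else {
    I <- debye_scattering(model, qgrid)$I
    truth <- sprintf("ground truth: single conformer, Rg %.3f A",
                     bead_rg(coords_matrix(model)))
  }
  I0 <- I[1]
  sig <- pmax(noise_scale * sqrt(pmax(I * I0, 0)), 1e-9 * I0)
  I_obs <- if (noise_scale > 0) {
    withr::with_seed(seed, I + rnorm(length(I), 0, sig))
  } else {
    I
  }
  saxs_curve(
    qgrid, I_obs, sig,
    metadata = c(truth, sprintf("noise_scale %.4g, seed %d", noise_scale, seed))
  )
}
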