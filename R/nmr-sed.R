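# Stokes-Einstein-Debye prediction and solvent-viscosity extrapolation.

#' Stokes-Einstein-Debye rotational correlation time
#'
#' Predicts the isotropic tumbling time of a compact hydrated sphere:
#' the dry radius follows from the molecular mass and partial specific
#' volume, `r_dry = (3 M vbar / (4 pi N_A))^(1/3)`, a hydration shell is
#' added, and `tau_c = 4 pi eta r^3 / (3 k_B T)`.
#'
#' @param mass Molecular mass (g/mol).
#' @param v_bar Partial specific volume (cm^3/g).
#' @param temperature Temperature (K).
#' @param eta Solvent viscosity (mPa s).
#' @param hydration Hydration-shell thickness (Angstrom).
#' @return tau_c in ns.
#' @export
#' @examples
#' sed_tauc(16706, 0.73, 310.15, 0.6913, 2.8) # ~5.2 ns for holo-CaM at 37 C
sed_tauc <- function(mass, v_bar = 0.73, temperature = 298.15, eta,
                     hydration = 2.8) {
  stopifnot(mass > 0, v_bar > 0, temperature > 0, eta > 0, hydration >= 0)
  r_dry_cm <- (3 * mass * v_bar / (4 * pi * .const$NA_avogadro))^(1 / 3)
  r_m <- r_dry_cm * 1e-2 + hydration * 1e-10
  tau_s <- 4 * pi * (eta * 1e-3) * r_m^3 / (3 * .const$kB * temperature)
  tau_s * 1e9
}

# embedded viscosity tables, mPa s, 0-60 C in 5 C steps
.visc_temps <- seq(0, 60, by = 5)
.visc_h2o <- c(
  1.7918, 1.5192, 1.3069, 1.1382, 1.0016, 0.8900, 0.7972,
  0.7190, 0.6527, 0.5958, 0.5465, 0.5036, 0.4660
)
# D2O/H2O viscosity ratio decreases from ~1.31 (0 C) to ~1.16 (60 C)
.visc_d2o <- .visc_h2o * c(
  1.31, 1.30, 1.28, 1.27, 1.25, 1.23, 1.22, 1.21, 1.19,
  1.18, 1.17, 1.17, 1.16
)
.visc_dmso <- c(
  3.70, 3.20, 2.80, 2.45, 2.14, 1.99, 1.79, 1.63, 1.48,
  1.36, 1.25, 1.16, 1.08
)

visc_lookup <- function(table, t_c) {
  if (t_c < min(.visc_temps) || t_c > max(.visc_temps)) {
    abort(sprintf("temperature %.1f C outside the viscosity table (0-60 C)", t_c))
  }
  approx(.visc_temps, table, xout = t_c)$y
}

#' Solvent model for viscosity extrapolation
#'
#' @param temperature Temperature (K).
#' @param d2o,dmso Volume fractions of D2O and DMSO (remainder H2O).
#' @return A `solvent_model` list with mixture and pure-water viscosities
#'   (mPa s) at the given temperature.
#' @export
solvent_model <- function(temperature, d2o = 0, dmso = 0) {
  if (d2o < 0 || dmso < 0 || d2o > 1 || dmso > 1 || d2o + dmso > 1) {
    abort("volume fractions must lie in [0,1] and sum to at most 1")
  }
  t_c <- temperature - 273.15
  eta_h2o <- visc_lookup(.visc_h2o, t_c)
  eta <- (1 - d2o - dmso) * eta_h2o +
    d2o * visc_lookup(.visc_d2o, t_c) +
    dmso * visc_lookup(.visc_dmso, t_c)
  structure(
    list(
      temperature = temperature, fractions = c(d2o = d2o, dmso = dmso),
      eta = eta, eta_h2o = eta_h2o
    ),
    class = "solvent_model"
  )
}

#' Extrapolate a correlation time to pure water
#'
#' Correlation times measured in D2O/DMSO-containing buffers are rescaled
#' to 100% H2O with the viscosity ratio:
#' `tau_c(H2O) = tau_c(measured) * eta_H2O(T) / eta_mix(T)`. The mixture
#' viscosity is a volume-fraction-linear combination of the embedded
#' component tables (first-order model).
#'
#' @param tau_c_measured Measured tau_c (ns).
#' @param solvent A [solvent_model()].
#' @return tau_c in ns referred to pure water.
#' @export
viscosity_correct <- function(tau_c_measured, solvent) {
  stopifnot(inherits(solvent, "solvent_model"))
  tau_c_measured * solvent$eta_h2o / solvent$eta
}
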