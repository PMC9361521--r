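#' Simulate exponential relaxation decays
#'
#' Generates `I(t) = I0 exp(-R t) + eps` decay tables. In TRACT mode
#' (`tau_c` given instead of `rate`) a pair of decays is emitted at the
#' slow/fast doublet rates `R_alpha = r2_base - eta_xy(tau_c)` and
#' `R_beta = r2_base + eta_xy(tau_c)`, emulating the relaxation of the two
#' 15N doublet components of a rigid tumbler at the stated field.
#'
#' @param delays Relaxation delays in seconds (>= 2 values).
#' @param rate Decay rate in 1/s (single-decay mode).
#' @param tau_c Rotational correlation time in ns (TRACT mode).
#' @param field 1H Larmor frequency in MHz (TRACT mode).
#' @param r2_base Baseline transverse rate (1/s) to which the
#'   cross-correlated rate is added/subtracted in TRACT mode.
#' @param amplitude Signal at zero delay.
#' @param noise_sd Gaussian noise SD in signal units (0 = noiseless).
#' @param seed Integer seed.
#' @param constants TRACT constants, see [tract_constants()].
#' @return A tibble with columns `component` (`"single"` or
#'   `"alpha"`/`"beta"`), `delay`, `signal`, `noise_sd`; ground truth in the
#'   `"ground_truth"` attribute.
#' @export
simulate_relaxation <- function(delays, rate = NULL, tau_c = NULL, field = 600,
                                r2_base = 25, amplitude = 100, noise_sd = 0,
                                seed = 1, constants = tract_constants()) {
  if (length(delays) < 2) abort("at least 2 delays required")
  if (any(delays < 0)) abort("delays must be >= 0")
  if (is.null(rate) == is.null(tau_c)) {
    abort("give exactly one of rate (single decay) or tau_c (TRACT pair)")
  }
  if (!is.null(tau_c)) {
    if (tau_c <= 0) abort("tau_c must be > 0")
    eta <- tract_eta_xy(tau_c, field, constants)
    if (eta >= r2_base) abort("r2_base too small: R_alpha would be negative")
    rates <- c(alpha = r2_base - eta, beta = r2_base + eta)
  } else {
    rates <- c(single = rate)
  }
  out <- withr::with_seed(seed, {
    purrr::imap_dfr(rates, function(R, nm) {
      clean <- amplitude * exp(-R * delays)
      tibble(
        component = nm,
        delay = delays,
        signal = clean + if (noise_sd > 0) rnorm(length(delays), 0, noise_sd) else 0,
        noise_sd = noise_sd
      )
    })
  })
  attr(out, "ground_truth") <- list(
    rates = rates, tau_c = tau_c, field = field, r2_base = r2_base,
    amplitude = amplitude, noise_sd = noise_sd, seed = seed
  )
  out
}
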