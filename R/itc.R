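# One-site ITC binding analysis: Wiseman isotherm forward model with
# displaced-volume bookkeeping, nonlinear least-squares fitting, and a
# synthetic titration generator.

#' Construct an ITC titration
#'
#' @param cell_conc Macromolecule concentration in the cell (M).
#' @param syringe_conc Ligand concentration in the syringe (M).
#' @param injections Injection volumes (microliters).
#' @param cell_volume Cell volume (mL).
#' @param heats Optional measured heats (microcalories per injection).
#' @param temperature Temperature (K).
#' @param max_fill Error if cumulative injected volume exceeds this fraction
#'   of the cell volume.
#' @return A `titration` object (list).
#' @export
itc_titration <- function(cell_conc, syringe_conc, injections,
                          cell_volume = 1.4, heats = NULL,
                          temperature = 298.15, max_fill = 0.35) {
  stopifnot(cell_conc > 0, syringe_conc > 0, cell_volume > 0)
  if (length(injections) == 0) abort("no injections")
  if (any(injections <= 0)) abort("injection volumes must be positive")
  if (!is.null(heats)) {
    if (length(heats) != length(injections)) {
      abort("injections and heats must have the same length")
    }
    if (any(!is.finite(heats))) abort("heats must be finite")
  }
  if (sum(injections) * 1e-3 > max_fill * cell_volume) {
    abort(sprintf(
      "cumulative injected volume exceeds %.0f%% of the cell volume", 100 * max_fill
    ))
  }
  structure(
    list(
      cell_conc = cell_conc, syringe_conc = syringe_conc,
      injections = as.numeric(injections), cell_volume = cell_volume,
      heats = heats, temperature = temperature
    ),
    class = "titration"
  )
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf(
    "<titration> %d injections, cell %.3g M (%.2f mL), syringe %.3g M, %.1f K\n",
    length(x$injections), x$cell_conc, x$cell_volume, x$syringe_conc,
    x$temperature
  ))
  invisible(x)
}

#' One-site binding isotherm: per-injection heats
#'
#' Computes cumulative binding heats `Q_i = n Theta_i [M]_i dH V0` from the
#' one-site quadratic for the bound fraction Theta, with the standard
#' perfusion-cell bookkeeping for concentrations diluted by the injected
#' volume, and returns per-injection heats
#' `dQ_i = Q_i - Q_(i-1) + (dV_i/V0) (Q_i + Q_(i-1))/2 + offset`.
#'
#' @param params Named list or vector with `kd` (M), `n` (sites), `dh`
#'   (cal/mol) and optionally `offset` (microcal/injection dilution heat).
#' @param titration A [itc_titration()].
#' @return Numeric vector of per-injection heats (microcalories).
#' @export
one_site_heats <- function(params, titration) {
  p <- as.list(params)
  kd <- p$kd
  n <- p$n
  dh <- p$dh
  offset <- p$offset %||% 0
  stopifnot(kd > 0)
  V0 <- titration$cell_volume * 1e-3 # L
  dV <- titration$injections * 1e-6 # L
  cumV <- cumsum(dV)
  # perfusion-corrected total concentrations after injection i
  Mt <- titration$cell_conc * (1 - cumV / (2 * V0)) / (1 + cumV / (2 * V0))
  Xt <- titration$syringe_conc * (cumV / V0) * (1 - cumV / (2 * V0))
  r <- Xt / (n * Mt)
  k <- kd / (n * Mt)
  disc <- (1 + r + k)^2 - 4 * r
  if (any(disc < 0)) abort("unphysical bound fraction (negative discriminant)")
  theta <- (1 + r + k - sqrt(disc)) / 2
  if (any(theta < -1e-9 | theta > 1 + 1e-9)) {
    abort("unphysical bound fraction outside [0, 1]")
  }
  Q <- n * theta * Mt * dh * V0 # cal
  Qprev <- c(0, head(Q, -1))
  dQ <- Q - Qprev + (dV / V0) * (Q + Qprev) / 2
  dQ * 1e6 + offset # microcal
}

#' Fit a one-site binding model to an ITC titration
#'
#' Nonlinear least squares on [one_site_heats()] with `log10(KD)`
#' parameterization; parameter errors from the fit covariance. The Wiseman
#' c-value `n [M] / KD` is reported, with a reliability warning outside
#' [1, 1000]. If a blank (titrant-into-buffer) titration is supplied its
#' heats are subtracted point-wise and the dilution offset is fixed at
#' zero; otherwise a constant offset is fitted.
#'
#' @param titration A [itc_titration()] with `heats`.
#' @param blank Optional blank titration (same injection schedule).
#' @param exclude_first Drop the first injection from the fit.
#' @param start Optional named list of starting values (`kd`, `n`, `dh`).
#' @return A `binding_fit` with `kd`, `n`, `dh`, `dilution_offset`, `errs`,
#'   `converged`, `c_value`, `residuals`.
#' @export
one_site_fit <- function(titration, blank = NULL, exclude_first = FALSE,
                         start = NULL) {
  if (is.null(titration$heats)) abort("titration carries no measured heats")
  heats <- titration$heats
  fit_offset <- TRUE
  if (!is.null(blank)) {
    if (length(blank$heats) != length(heats)) {
      abort("blank must have the same injection schedule")
    }
    heats <- heats - blank$heats
    fit_offset <- FALSE
  }
  keep <- seq_along(heats)
  if (exclude_first) keep <- keep[-1]
  if (length(keep) < 6) abort("at least 6 informative injections required")

  mol_inj <- titration$syringe_conc * titration$injections * 1e-6
  dh0 <- (start$dh %||% (sum(heats[keep]) * 1e-6 /
    min(sum(mol_inj), titration$cell_conc * titration$cell_volume * 1e-3)))
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1e4
  kd0 <- start$kd %||% (titration$cell_conc / 2)
  n0 <- start$n %||% 1

  model_fun <- function(lkd, n, dh, offset) {
    one_site_heats(
      list(kd = 10^lkd, n = n, dh = dh, offset = offset),
      titration
    )[keep]
  }
  df <- data.frame(y = heats[keep])
  fml <- if (fit_offset) {
    y ~ model_fun(lkd, n, dh, offset)
  } else {
    y ~ model_fun(lkd, n, dh, 0)
  }
  starts <- list(lkd = log10(kd0), n = n0, dh = dh0)
  if (fit_offset) starts$offset <- 0

  fit <- tryCatch(
    minpack.lm::nlsLM(
      fml,
      data = df, start = starts,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$convInfo$isConv

  if (is.null(fit)) {
    warn("one-site fit failed to converge; returning starting values")
    est <- unlist(starts)
    se <- rep(NA_real_, length(est))
    resid <- rep(NA_real_, length(keep))
  } else {
    est <- coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
      error = function(e) rep(NA_real_, length(est))
    )
    resid <- stats::residuals(fit)
  }
  kd <- 10^est[["lkd"]]
  gse <- function(i) if (length(se) >= i && is.finite(se[[i]])) se[[i]] else NA_real_
  kd_err <- if (is.finite(gse(1))) kd * log(10) * gse(1) else NA_real_
  offset <- if (fit_offset) est[["offset"]] else 0
  offset_err <- if (fit_offset && length(se) >= 4) se[[4]] else 0
  c_value <- est[["n"]] * titration$cell_conc / kd
  if (is.finite(c_value) && (c_value < 1 || c_value > 1000)) {
    warn(sprintf(
      "Wiseman c-value %.3g outside [1, 1000]: fitted parameters may be unreliable",
      c_value
    ))
  }
  structure(
    list(
      kd = kd, n = est[["n"]], dh = est[["dh"]], dilution_offset = offset,
      errs = c(kd = kd_err, n = gse(2), dh = gse(3), offset = offset_err),
      converged = converged, c_value = c_value,
      residuals = tibble(injection = keep, residual = resid),
      titration = titration
    ),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "<binding_fit> KD = %.3g +/- %.2g M, n = %.3g +/- %.2g, dH = %.4g cal/mol (c = %.3g)%s\n",
    x$kd, x$errs[["kd"]], x$n, x$errs[["n"]], x$dh, x$c_value,
    if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

#' @rdname one_site_fit
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(
    term = c("kd", "n", "dh", "dilution_offset"),
    estimate = c(x$kd, x$n, x$dh, x$dilution_offset),
    std.error = unname(x$errs)
  )
}

#' @rdname one_site_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(
    kd = x$kd, n = x$n, dh = x$dh, c_value = x$c_value,
    converged = x$converged
  )
}

#' @rdname one_site_fit
#' @param object A `binding_fit`.
#' @export
autoplot.binding_fit <- function(object, ...) {
  t <- object$titration
  obs <- tibble(
    injection = seq_along(t$injections),
    heat = t$heats,
    fitted = one_site_heats(
      list(kd = object$kd, n = object$n, dh = object$dh,
           offset = object$dilution_offset), t
    )
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$injection)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "injection", y = "heat (µcal)")
}

#' Simulate a one-site ITC titration
#'
#' Forward heats from [one_site_heats()] plus Gaussian noise and an
#' optional constant dilution heat.
#'
#' @param kd Dissociation constant (M).
#' @param n Stoichiometry.
#' @param dh Binding enthalpy (cal/mol).
#' @param cell_conc,syringe_conc Concentrations (M).
#' @param injections Injection volumes (microliters).
#' @param cell_volume Cell volume (mL).
#' @param dilution_offset Constant per-injection dilution heat (microcal).
#' @param noise_sd Gaussian heat noise SD (microcal).
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @return A [itc_titration()] with simulated `heats` and the ground truth
#'   in its `"ground_truth"` attribute.
#' @export
simulate_itc <- function(kd, n, dh, cell_conc = 8e-6, syringe_conc = 200e-6,
                         injections = rep(10, 28), cell_volume = 1.4,
                         dilution_offset = 0, noise_sd = 0, seed = 1,
                         temperature = 298.15) {
  t <- itc_titration(cell_conc, syringe_conc, injections, cell_volume,
    temperature = temperature
  )
  clean <- one_site_heats(
    list(kd = kd, n = n, dh = dh, offset = dilution_offset), t
  )
  t$heats <- if (noise_sd > 0) {
    withr::with_seed(seed, clean + rnorm(length(clean), 0, noise_sd))
  } else {
    clean
  }
  attr(t, "ground_truth") <- list(
    kd = kd, n = n, dh = dh, dilution_offset = dilution_offset,
    noise_sd = noise_sd, seed = seed
  )
  t
}
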