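#' Construct a SAXS scattering curve
#'
#' A scattering curve is a tibble with columns `q` (momentum transfer,
#' 1/Angstrom), `I` (intensity, absolute or arbitrary units) and `sigma`
#' (1-SD intensity uncertainty, same units as `I`). Free-text provenance is
#' kept in the `"metadata"` attribute.
#'
#' @param q Strictly increasing, non-negative momentum transfer (1/Angstrom).
#' @param I Intensities.
#' @param sigma Positive 1-SD uncertainties; must be > 0 wherever `I` is
#'   finite.
#' @param metadata Character vector of provenance lines.
#' @return A tibble of class `saxs_curve`.
#' @export
#' @examples
#' saxs_curve(q = c(0.01, 0.02), I = c(10, 9), sigma = c(1, 1))
saxs_curve <- function(q, I, sigma, metadata = character()) {
  x <- tibble(q = as.numeric(q), I = as.numeric(I), sigma = as.numeric(sigma))
  attr(x, "metadata") <- as.character(metadata)
  class(x) <- c("saxs_curve", class(x))
  validate_saxs_curve(x)
}

#' Validate a scattering curve's invariants
#'
#' Rejects (never repairs) violations: unequal column lengths, non-monotone
#' or negative `q`, or non-positive `sigma` at finite intensities.
#'
#' @param x A data frame with columns `q`, `I`, `sigma`.
#' @return `x`, invisibly classed as `saxs_curve`.
#' @export
validate_saxs_curve <- function(x) {
  if (!all(c("q", "I", "sigma") %in% names(x))) {
    abort("a scattering curve needs columns q, I, sigma")
  }
  if (nrow(x) == 0) abort("empty scattering curve")
  if (any(!is.finite(x$q)) || any(x$q < 0)) abort("q must be finite and >= 0")
  if (any(diff(x$q) <= 0)) abort("q must be strictly increasing")
  fin <- is.finite(x$I)
  if (any(!is.finite(x$sigma[fin]) | x$sigma[fin] <= 0)) {
    abort("sigma must be > 0 wherever I is finite")
  }
  if (!inherits(x, "saxs_curve")) class(x) <- c("saxs_curve", class(x))
  x
}

#' Coerce a data frame to a scattering curve
#'
#' @param x Data frame with columns `q`, `I` and optionally `sigma`.
#' @param fill_sigma If `TRUE` and `sigma` is missing, fill with 1
#'   (unit weights); otherwise a missing `sigma` is an error.
#' @return A `saxs_curve` tibble.
#' @export
as_saxs_curve <- function(x, fill_sigma = FALSE) {
  if (inherits(x, "saxs_curve")) {
    return(validate_saxs_curve(x))
  }
  if (!"sigma" %in% names(x)) {
    if (!fill_sigma) abort("no sigma column (set fill_sigma = TRUE for unit weights)")
    x$sigma <- 1
  }
  saxs_curve(x$q, x$I, x$sigma, metadata = attr(x, "metadata") %||% character())
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf(
    "<saxs_curve> %d points, q in [%.4g, %.4g] 1/A\n",
    nrow(x), min(x$q), max(x$q)
  ))
  NextMethod()
}

#' @rdname saxs_curve
#' @param object,x A `saxs_curve`.
#' @param ... Unused.
#' @export
autoplot.saxs_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$I - .data$sigma, ymax = .data$I + .data$sigma),
      size = 0.1
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (1/Å)", y = "I(q)")
}

# linear interpolation of a model curve onto a data q-grid (overlap only)
interp_curve <- function(model, q_target) {
  keep <- q_target >= min(model$q) & q_target <= max(model$q)
  list(
    q = q_target[keep],
    I = approx(model$q, model$I, xout = q_target[keep])$y,
    keep = keep
  )
}
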