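#' Guinier analysis of a scattering curve
#'
#' Weighted linear fit of `ln I` versus `q^2` over a self-consistently
#' chosen low-q range: starting from the smallest usable q, the range is
#' iterated until `q_max * Rg <= qRg_limit` (default 1.3, the standard
#' globular bound). `Rg = sqrt(-3 slope)` and `I0 = exp(intercept)`;
#' 1-SD uncertainties follow from the fit covariance by the delta method.
#'
#' @param curve A [saxs_curve()] (or data frame coercible to one).
#' @param qRg_limit Upper bound on `q * Rg` in the fitted range.
#' @param q_min Optional lower q cutoff (e.g. to skip beamstop points).
#' @return A `guinier_fit` object with fields `rg`, `i0`, `rg_err`,
#'   `i0_err`, `fit_range`, `n_points`, `qrg_max`.
#' @export
#' @examples
#' q <- seq(0.005, 0.2, by = 0.002)
#' curve <- saxs_curve(q, exp(-q^2 * 16.8^2 / 3), rep(1e-3, length(q)))
#' guinier_fit(curve)$rg
guinier_fit <- function(curve, qRg_limit = 1.3, q_min = NULL) {
  curve <- as_saxs_curve(curve)
  d <- dplyr::filter(curve, is.finite(.data$I), .data$I > 0)
  if (!is.null(q_min)) d <- dplyr::filter(d, .data$q >= q_min)
  if (nrow(d) < 3) abort("fewer than 3 usable points")

  fit_range <- function(dd) {
    w <- (dd$I / dd$sigma)^2 # var(ln I) ~ (sigma/I)^2
    fit <- lm(log(I) ~ I(q^2), data = dd, weights = w)
    slope <- coef(fit)[[2]]
    list(fit = fit, slope = slope)
  }

  # start from a generous low-q window, then iterate the qRg bound
  idx <- seq_len(min(nrow(d), max(10, ceiling(nrow(d) / 4))))
  last_n <- -1
  for (iter in 1:50) {
    dd <- d[idx, ]
    if (nrow(dd) < 3) abort("no convergent Guinier range (fewer than 3 points)")
    fr <- fit_range(dd)
    if (fr$slope >= 0) abort("no Guinier region (non-negative slope)")
    rg <- sqrt(-3 * fr$slope)
    q_max_allowed <- qRg_limit / rg
    idx_new <- which(d$q <= q_max_allowed)
    if (length(idx_new) < 3) idx_new <- seq_len(3)
    if (identical(idx_new, idx) || length(idx_new) == last_n) break
    last_n <- length(idx)
    idx <- idx_new
  }
  dd <- d[idx, ]
  fr <- fit_range(dd)
  if (fr$slope >= 0) abort("no Guinier region (non-negative slope)")
  sm <- summary(fr$fit)$coefficients
  rg <- sqrt(-3 * fr$slope)
  i0 <- exp(coef(fr$fit)[[1]])
  rg_err <- 3 / (2 * rg) * sm[2, 2]
  i0_err <- i0 * sm[1, 2]
  if (max(dd$q) * rg > qRg_limit * 1.05) {
    warn(sprintf("Guinier range ends at qRg = %.2f (limit %.2f)", max(dd$q) * rg, qRg_limit))
  }
  structure(
    list(
      rg = rg, i0 = i0, rg_err = rg_err, i0_err = i0_err,
      fit_range = range(dd$q), n_points = nrow(dd),
      qrg_max = max(dd$q) * rg, curve = curve
    ),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> Rg = %.3f +/- %.3f A, I(0) = %.4g +/- %.2g (%d pts, qRg <= %.2f)\n",
    x$rg, x$rg_err, x$i0, x$i0_err, x$n_points, x$qrg_max
  ))
  invisible(x)
}

#' @rdname guinier_fit
#' @param x A `guinier_fit`.
#' @param ... Unused.
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble(
    term = c("rg", "i0"),
    estimate = c(x$rg, x$i0),
    std.error = c(x$rg_err, x$i0_err)
  )
}

#' @rdname guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble(
    rg = x$rg, i0 = x$i0, n_points = x$n_points,
    q_min = x$fit_range[1], q_max = x$fit_range[2], qrg_max = x$qrg_max
  )
}

#' @rdname guinier_fit
#' @param object A `guinier_fit`.
#' @export
autoplot.guinier_fit <- function(object, ...) {
  d <- dplyr::filter(object$curve, .data$I > 0)
  d$in_range <- d$q >= object$fit_range[1] & d$q <= object$fit_range[2]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q^2, y = log(.data$I))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_range), size = 0.8) +
    ggplot2::geom_abline(
      intercept = log(object$i0), slope = -object$rg^2 / 3,
      linetype = 2
    ) +
    ggplot2::labs(x = expression(q^2), y = "ln I(q)", colour = "fitted")
}
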