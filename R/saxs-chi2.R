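#' Reduced chi-squared agreement between a model and data curve
#'
#' Interpolates the model onto the data q-grid within the overlap region
#' and evaluates
#' `chi2_red = 1/(N - k) * sum(((I_data - c I_model - b)/sigma)^2)` with the
#' analytically optimal scale `c` (and offset `b` when `fit_offset = TRUE`);
#' `k` counts the fitted nuisance parameters. The statistic is invariant
#' under any common rescaling of the model intensities.
#'
#' @param model Model curve (a [saxs_curve()]; `sigma` ignored).
#' @param data Data curve with uncertainties.
#' @param fit_offset Also fit a constant background offset.
#' @return A `fit_quality` list with `chi2_red`, `scale`, `offset`, `n`,
#'   and a `residuals` tibble of sigma-normalized signed residuals.
#' @export
reduced_chi2 <- function(model, data, fit_offset = FALSE) {
  model <- as_saxs_curve(model)
  data <- as_saxs_curve(data)
  ip <- interp_curve(model, data$q)
  if (sum(ip$keep) < 2) abort("fewer than 2 overlapping points")
  Id <- data$I[ip$keep]
  sig <- data$sigma[ip$keep]
  Im <- ip$I
  w <- 1 / sig^2
  if (fit_offset) {
    X <- cbind(Im, 1)
    beta <- solve(crossprod(X * sqrt(w)), crossprod(X, w * Id))
    sc <- beta[1]
    b <- beta[2]
    k <- 2
  } else {
    sc <- sum(w * Id * Im) / sum(w * Im^2)
    b <- 0
    k <- 1
  }
  res <- (Id - sc * Im - b) / sig
  n <- length(res)
  structure(
    list(
      chi2_red = sum(res^2) / (n - k),
      scale = sc, offset = b, n = n, k = k,
      residuals = tibble(q = ip$q, residual = res)
    ),
    class = "fit_quality"
  )
}

#' @export
print.fit_quality <- function(x, ...) {
  cat(sprintf(
    "<fit_quality> chi2_red = %.4g over %d points (scale %.4g, offset %.4g)\n",
    x$chi2_red, x$n, x$scale, x$offset
  ))
  invisible(x)
}
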