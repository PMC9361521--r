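#' Fit a single-exponential decay with Monte Carlo errors
#'
#' Least-squares fit of `A exp(-R t)` to a decay series. The 1-SD error on
#' the rate comes from Monte Carlo: the fitted curve is perturbed `n_mc`
#' times with Gaussian noise of the stated SD and refit; the SD of the
#' refitted rates is reported.
#'
#' @param delays Relaxation delays in seconds (>= 2 distinct values).
#' @param signals Signal values.
#' @param noise_sd Noise SD in signal units (> 0 required for Monte Carlo;
#'   0 skips it).
#' @param n_mc Monte Carlo replicates (default 1000).
#' @param seed Integer seed for the Monte Carlo draw.
#' @return A `rate_estimate`: `rate` (1/s), `amplitude`, `err`, `n_mc`,
#'   `decaying` flag.
#' @export
#' @examples
#' t <- c(0, 0.02, 0.05, 0.1, 0.2, 0.4)
#' fit_decay(t, 100 * exp(-10 * t), noise_sd = 0)$rate
fit_decay <- function(delays, signals, noise_sd, n_mc = 1000, seed = 1) {
  if (length(delays) != length(signals)) abort("delays and signals differ in length")
  if (length(unique(delays)) < 2) abort("at least 2 distinct delays required")

  fit_once <- function(y) {
    pos <- y > 0
    if (sum(pos) >= 2) {
      lf <- lm(log(y[pos]) ~ delays[pos])
      A0 <- exp(coef(lf)[[1]])
      R0 <- -coef(lf)[[2]]
    } else {
      A0 <- max(abs(y))
      R0 <- 1
    }
    if (length(y) == 2) {
      # exact two-point solution
      R <- log(y[1] / y[2]) / (delays[2] - delays[1])
      return(c(A = y[1] * exp(R * delays[1]), R = R))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-R * t),
        data = data.frame(y = y, t = delays),
        start = list(A = A0, R = max(R0, 1e-6)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(c(A = A0, R = R0))
    }
    coef(fit)[c("A", "R")]
  }

  est <- fit_once(signals)
  decaying <- est[["R"]] > 0
  if (!decaying) warn("fitted rate is non-positive: data do not decay")

  err <- 0
  if (noise_sd > 0 && n_mc > 0) {
    clean <- est[["A"]] * exp(-est[["R"]] * delays)
    rates <- withr::with_seed(seed, {
      vapply(seq_len(n_mc), function(i) {
        fit_once(clean + rnorm(length(delays), 0, noise_sd))[["R"]]
      }, numeric(1))
    })
    err <- sd(rates)
  }

  structure(
    list(
      rate = est[["R"]], amplitude = est[["A"]], err = err,
      n_mc = if (noise_sd > 0) n_mc else 0, decaying = decaying
    ),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> R = %.4g +/- %.2g /s (A = %.4g, %d MC)\n",
    x$rate, x$err, x$amplitude, x$n_mc
  ))
  invisible(x)
}

#' @rdname fit_decay
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble(
    term = c("rate", "amplitude"),
    estimate = c(x$rate, x$amplitude),
    std.error = c(x$err, NA)
  )
}
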