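# Genetic-algorithm ensemble selection: choose a small multiset of pool
# conformers whose weight-averaged scattering best fits the data, in the
# spirit of ensemble-optimization analysis of flexible proteins.

#' Select an ensemble of conformers fitting a scattering curve
#'
#' Chromosomes are multisets of conformer indices of fixed size; fitness is
#' the reduced chi-squared of the (optimally scaled) average curve against
#' the data. Evolution uses tournament selection, uniform crossover,
#' per-gene mutation and elitism, repeated over several independent runs;
#' the run-wise best ensemble is returned together with the distribution of
#' selected-conformer radii of gyration across runs.
#'
#' @param pool_curves Either a numeric matrix (rows = data q-grid points,
#'   columns = pool members) of model intensities, or a list of
#'   [saxs_curve()]s on the data q-grid.
#' @param data A [saxs_curve()] with uncertainties.
#' @param ensemble_size Multiset size (>= 1).
#' @param ga Named list of GA settings: `population`, `generations`,
#'   `mutation_rate` (per gene), `elitism`, `runs`.
#' @param seed Integer seed.
#' @param pool_rg Optional per-conformer Rg values (for the selected-Rg
#'   distribution).
#' @return An `ensemble_fit`: `member_indices` (sorted), `weights`
#'   (multiset fractions), `chi2`, `scale`, `generations`, `rg_selected`,
#'   `run_best` (per-run chi2).
#' @export
ensemble_select <- function(pool_curves, data,
                            ensemble_size = 2,
                            ga = list(),
                            seed = 1, pool_rg = NULL) {
  ga <- utils::modifyList(
    list(population = 100, generations = 200, mutation_rate = 0.1,
         elitism = 2, runs = 10),
    ga
  )
  data <- as_saxs_curve(data)
  M <- pool_curve_matrix(pool_curves, data)
  npool <- ncol(M)
  if (npool < ensemble_size) abort("pool smaller than the ensemble size")
  Id <- data$I
  w <- 1 / data$sigma^2

  fitness <- function(idx) {
    Im <- if (length(idx) == 1) M[, idx] else rowMeans(M[, idx, drop = FALSE])
    sc <- sum(w * Id * Im) / sum(w * Im^2)
    sum(w * (Id - sc * Im)^2) / (length(Id) - 1)
  }
  scale_of <- function(idx) {
    Im <- if (length(idx) == 1) M[, idx] else rowMeans(M[, idx, drop = FALSE])
    sum(w * Id * Im) / sum(w * Im^2)
  }

  runs <- withr::with_seed(seed, {
    lapply(seq_len(ga$runs), function(run) ga_run(npool, ensemble_size, ga, fitness))
  })
  chis <- vapply(runs, function(r) r$best_fit, numeric(1))
  best <- runs[[which.min(chis)]]

  baseline <- stats::median(vapply(seq_len(min(50, npool)), function(i) {
    fitness(sample.int(npool, ensemble_size, replace = TRUE))
  }, numeric(1)))
  if (best$best_fit > baseline) {
    warn("GA failed to improve over a random baseline; returning best found")
  }

  idx <- sort(best$best)
  counts <- table(idx)
  rg_sel <- if (!is.null(pool_rg)) {
    unlist(lapply(runs, function(r) pool_rg[r$best]))
  } else {
    numeric(0)
  }
  structure(
    list(
      member_indices = as.integer(names(counts)),
      weights = as.numeric(counts) / ensemble_size,
      chi2 = best$best_fit, scale = scale_of(idx),
      generations = ga$generations, runs = ga$runs,
      run_best = chis, rg_selected = rg_sel
    ),
    class = "ensemble_fit"
  )
}

ga_run <- function(npool, m, ga, fitness) {
  pop <- matrix(sample.int(npool, ga$population * m, replace = TRUE),
    nrow = ga$population
  )
  fit <- apply(pop, 1, fitness)
  for (gen in seq_len(ga$generations)) {
    ord <- order(fit)
    elite <- pop[ord[seq_len(ga$elitism)], , drop = FALSE]
    # tournament selection (size 2)
    pick <- function() {
      a <- sample.int(ga$population, 1)
      b <- sample.int(ga$population, 1)
      if (fit[a] <= fit[b]) pop[a, ] else pop[b, ]
    }
    n_child <- ga$population - ga$elitism
    children <- matrix(0L, n_child, m)
    for (i in seq_len(n_child)) {
      p1 <- pick()
      p2 <- pick()
      mask <- runif(m) < 0.5
      child <- ifelse(mask, p1, p2)
      mut <- runif(m) < ga$mutation_rate
      if (any(mut)) child[mut] <- sample.int(npool, sum(mut), replace = TRUE)
      children[i, ] <- child
    }
    pop <- rbind(elite, children)
    fit <- apply(pop, 1, fitness)
  }
  i <- which.min(fit)
  list(best = pop[i, ], best_fit = fit[i])
}

pool_curve_matrix <- function(pool_curves, data) {
  if (is.matrix(pool_curves)) {
    if (nrow(pool_curves) != nrow(data)) {
      abort("pool curve matrix rows must match the data q-grid")
    }
    return(pool_curves)
  }
  M <- vapply(pool_curves, function(cv) {
    cv <- as_saxs_curve(cv)
    if (nrow(cv) != nrow(data) || max(abs(cv$q - data$q)) > 1e-9) {
      abort("all pool curves must be on the data q-grid")
    }
    cv$I
  }, numeric(nrow(data)))
  M
}

#' Exhaustive ensemble search (small instances)
#'
#' Enumerates every multiset of the given size and returns the chi-squared
#' optimum. Intended as an exact reference for [ensemble_select()] on
#' instances small enough to enumerate.
#'
#' @inheritParams ensemble_select
#' @return A list with `member_indices`, `chi2`.
#' @export
ensemble_exhaustive <- function(pool_curves, data, ensemble_size = 2) {
  data <- as_saxs_curve(data)
  M <- pool_curve_matrix(pool_curves, data)
  npool <- ncol(M)
  Id <- data$I
  w <- 1 / data$sigma^2
  combos <- utils::combn(npool + ensemble_size - 1, ensemble_size)
  # multisets via stars-and-bars de-offset
  combos <- combos - (seq_len(ensemble_size) - 1)
  best <- NULL
  best_fit <- Inf
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    Im <- if (length(idx) == 1) M[, idx] else rowMeans(M[, idx, drop = FALSE])
    sc <- sum(w * Id * Im) / sum(w * Im^2)
    f <- sum(w * (Id - sc * Im)^2) / (length(Id) - 1)
    if (f < best_fit) {
      best_fit <- f
      best <- idx
    }
  }
  list(member_indices = sort(best), chi2 = best_fit)
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf(
    "<ensemble_fit> members {%s}, weights {%s}, chi2_red = %.4g (%d runs)\n",
    paste(x$member_indices, collapse = ","),
    paste(signif(x$weights, 3), collapse = ","),
    x$chi2, x$runs
  ))
  invisible(x)
}

#' @rdname ensemble_select
#' @param x An `ensemble_fit`.
#' @param ... Unused.
#' @export
tidy.ensemble_fit <- function(x, ...) {
  tibble(member = x$member_indices, weight = x$weights)
}

#' @rdname ensemble_select
#' @export
glance.ensemble_fit <- function(x, ...) {
  tibble(chi2 = x$chi2, scale = x$scale, runs = x$runs,
         generations = x$generations)
}
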