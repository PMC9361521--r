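# Differential HDX-MS processing: deuterium-fraction bookkeeping,
# exchangeable-amide counting, relative fractional uptake, state
# differences, and per-peptide Wald significance testing with FDR control.

#' Deuterium fraction after sequential mixing
#'
#' Volume-weighted deuterium fraction of a liquid pool built by mixing
#' stages in order. The labeling protocol (30 uL protein + 120 uL
#' deuterated buffer) gives ~0.80; the quench step (20 uL labeling mix +
#' 40 uL protiated quench) gives ~0.27.
#'
#' @param stages A data frame with columns `volume` (uL) and `fraction`
#'   (D fraction of the added liquid), or a list of `c(volume, fraction)`
#'   pairs; stages are mixed in row order.
#' @return The final deuterium fraction (unitless).
#' @export
#' @examples
#' deuterium_fraction(data.frame(volume = c(30, 120), fraction = c(0, 0.9998)))
deuterium_fraction <- function(stages) {
  if (is.list(stages) && !is.data.frame(stages)) {
    stages <- do.call(rbind, lapply(stages, function(s) {
      data.frame(volume = s[[1]], fraction = s[[2]])
    }))
  }
  check_columns(stages, c("volume", "fraction"), "mixing stage")
  if (nrow(stages) == 0) abort("empty stage list")
  if (any(stages$volume <= 0)) abort("stage volumes must be positive")
  if (any(stages$fraction < 0 | stages$fraction > 1)) {
    abort("stage fractions must lie in [0, 1]")
  }
  vol <- stages$volume[1]
  d <- stages$fraction[1]
  for (i in seq_len(nrow(stages))[-1]) {
    d <- (d * vol + stages$volume[i] * stages$fraction[i]) / (vol + stages$volume[i])
    vol <- vol + stages$volume[i]
  }
  d
}

#' Maximum exchangeable backbone amides of a peptide
#'
#' Counts `N - 1 - (prolines at positions 2..N)`: the N-terminal residue of
#' each peptide is excluded (it back-exchanges during analysis) and
#' prolines carry no backbone amide proton.
#'
#' @param sequence One-letter peptide string(s).
#' @return Integer count(s).
#' @export
#' @examples
#' max_exchangeable("APLG") # 2
max_exchangeable <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(aa, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    if (length(bad) > 0) {
      abort(paste0("unknown residue code(s): ", paste(unique(bad), collapse = ", ")))
    }
    n <- length(aa)
    if (n <= 1) {
      return(0L)
    }
    as.integer(n - 1 - sum(aa[-1] == "P"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Relative fractional uptake
#'
#' `RFU = 100 * uptake / (max_d * d_fraction)` in percent: measured uptake
#' normalized by the theoretical maximum corrected for the deuterium excess
#' of the labeling mixture. No back-exchange adjustment is applied.
#'
#' @param uptake Measured uptake (Da).
#' @param max_d Maximum exchangeable amides (>= 1).
#' @param d_fraction Deuterium fraction of the labeling mix, in (0, 1].
#' @return RFU in percent.
#' @export
fractional_uptake <- function(uptake, max_d, d_fraction) {
  if (any(max_d < 1)) abort("max_d must be >= 1")
  if (any(d_fraction <= 0 | d_fraction > 1)) abort("d_fraction must be in (0, 1]")
  100 * uptake / (max_d * d_fraction)
}

#' Per-peptide uptake differences between two states
#'
#' Replicate-mean fractional uptake difference per peptide and time
#' (`state_b - state_a`), plus the time-averaged difference `avg_delta`
#' used for structure mapping. Peptides present in only one state are
#' excluded with a warning.
#'
#' @param dataset Uptake table in the layout of [read_uptake_table()].
#' @param state_a,state_b State labels (difference is b - a).
#' @param d_fraction Deuterium fraction of the labeling mix (default: the
#'   dataset's `"d_fraction"` attribute, else 0.8).
#' @return A list with `per_time` (peptide x time deltas, Da and %) and
#'   `summary` (per-peptide `avg_delta`, %).
#' @export
delta_uptake <- function(dataset, state_a = "free", state_b = "bound",
                         d_fraction = NULL) {
  d_fraction <- d_fraction %||% attr(dataset, "d_fraction") %||% 0.8
  check_columns(
    dataset,
    c("peptide", "start", "end", "sequence", "state", "time", "uptake"), "uptake"
  )
  if (!all(c(state_a, state_b) %in% dataset$state)) {
    abort("both states must be present in the dataset")
  }
  means <- dataset |>
    dplyr::filter(.data$state %in% c(state_a, state_b)) |>
    dplyr::group_by(
      .data$peptide, .data$start, .data$end, .data$sequence,
      .data$state, .data$time
    ) |>
    dplyr::summarise(uptake = mean(.data$uptake), .groups = "drop")

  wide <- tidyr::pivot_wider(
    means,
    names_from = "state", values_from = "uptake"
  )
  orphan <- unique(wide$peptide[is.na(wide[[state_a]]) | is.na(wide[[state_b]])])
  if (length(orphan) > 0) {
    warn(sprintf(
      "peptide(s) %s present in only one state: excluded",
      paste(orphan, collapse = ", ")
    ))
    wide <- dplyr::filter(wide, !.data$peptide %in% orphan)
  }
  per_time <- wide |>
    dplyr::mutate(
      max_d = max_exchangeable(.data$sequence),
      delta_da = .data[[state_b]] - .data[[state_a]],
      delta_pct = fractional_uptake(.data$delta_da, .data$max_d, d_fraction)
    ) |>
    dplyr::select(
      "peptide", "start", "end", "sequence", "time", "max_d",
      "delta_da", "delta_pct"
    )
  summary <- per_time |>
    dplyr::group_by(.data$peptide, .data$start, .data$end, .data$sequence) |>
    dplyr::summarise(avg_delta = mean(.data$delta_pct), .groups = "drop")
  list(per_time = per_time, summary = summary)
}

#' Per-peptide Wald tests with FDR control
#'
#' Fits, per peptide, the fixed-effects linear model
#' `rfu ~ state + time + state:time` (time categorical, sum-to-zero
#' contrasts) on replicate-level fractional uptake, and computes two Wald
#' p-values: on the state main effect (a time-averaged "magnitude" shift)
#' and on the state-by-time interaction block (a change of exchange
#' "kinetics"). Benjamini-Hochberg correction is applied across peptides
#' separately per test family; a peptide is significant if either adjusted
#' p-value passes the FDR.
#'
#' @param dataset Uptake table ([read_uptake_table()] layout) with >= 2
#'   replicates per state and time.
#' @param fdr False discovery rate (default 0.05).
#' @param d_fraction Deuterium fraction (default: dataset attribute, else
#'   0.8).
#' @param state_a,state_b State labels.
#' @return A tibble with one row per peptide: `avg_delta` (%),
#'   `p_magnitude`, `p_kinetics`, adjusted values, `significant` and
#'   `degenerate` (zero residual variance; p reported as `NA`).
#' @export
wald_fdr <- function(dataset, fdr = 0.05, d_fraction = NULL,
                     state_a = "free", state_b = "bound") {
  d_fraction <- d_fraction %||% attr(dataset, "d_fraction") %||% 0.8
  check_columns(
    dataset,
    c("peptide", "sequence", "state", "time", "replicate", "uptake"), "uptake"
  )
  reps <- dataset |>
    dplyr::count(.data$peptide, .data$state, .data$time)
  if (any(reps$n < 2)) abort("at least 2 replicates per state x time required")

  dd <- dataset |>
    dplyr::filter(.data$state %in% c(state_a, state_b)) |>
    dplyr::mutate(
      rfu = fractional_uptake(
        .data$uptake, max_exchangeable(.data$sequence), d_fraction
      ),
      state_f = factor(.data$state, levels = c(state_a, state_b)),
      time_f = factor(.data$time)
    )

  deltas <- delta_uptake(dataset, state_a, state_b, d_fraction)$summary

  tests <- dd |>
    dplyr::group_by(.data$peptide) |>
    dplyr::group_modify(function(g, key) {
      fit <- lm(
        rfu ~ state_f * time_f,
        data = g,
        contrasts = list(state_f = "contr.sum", time_f = "contr.sum")
      )
      cf <- coef(fit)
      V <- suppressWarnings(vcov(fit))
      sigma2 <- suppressWarnings(summary(fit))$sigma^2
      if (!is.finite(sigma2) || sigma2 < 1e-12) {
        return(tibble(
          p_magnitude = NA_real_, p_kinetics = NA_real_, degenerate = TRUE
        ))
      }
      i_mag <- which(names(cf) == "state_f1")
      w_mag <- cf[i_mag]^2 / V[i_mag, i_mag]
      p_mag <- pchisq(w_mag, df = 1, lower.tail = FALSE)
      i_int <- grep("^state_f1:time_f", names(cf))
      b <- cf[i_int]
      Vb <- V[i_int, i_int, drop = FALSE]
      w_int <- drop(t(b) %*% solve(Vb, b))
      p_int <- pchisq(w_int, df = length(i_int), lower.tail = FALSE)
      tibble(p_magnitude = p_mag, p_kinetics = p_int, degenerate = FALSE)
    }) |>
    dplyr::ungroup()

  out <- dplyr::left_join(deltas, tests, by = "peptide") |>
    dplyr::mutate(
      p_magnitude_adj = p.adjust(.data$p_magnitude, method = "BH"),
      p_kinetics_adj = p.adjust(.data$p_kinetics, method = "BH"),
      significant = dplyr::coalesce(.data$p_magnitude_adj < fdr, FALSE) |
        dplyr::coalesce(.data$p_kinetics_adj < fdr, FALSE)
    )
  attr(out, "fdr") <- fdr
  out
}

#' Paint peptide-level differences onto residues
#'
#' Assigns each residue the `avg_delta` of its shortest covering peptide
#' (peptide-level values are not consolidated to residue resolution).
#'
#' @param summary Per-peptide summary from [delta_uptake()] or
#'   [wald_fdr()] (needs `start`, `end`, `avg_delta`).
#' @param n_res Protein length.
#' @return A tibble with `residue`, `value` (`NA` where uncovered).
#' @export
residue_map <- function(summary, n_res) {
  value <- rep(NA_real_, n_res)
  len <- rep(Inf, n_res)
  for (i in seq_len(nrow(summary))) {
    rng <- summary$start[i]:summary$end[i]
    li <- summary$end[i] - summary$start[i] + 1
    take <- rng[li < len[rng]]
    value[take] <- summary$avg_delta[i]
    len[take] <- li
  }
  tibble(residue = seq_len(n_res), value = value)
}
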