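#' Chemical shift perturbations between free and bound states
#'
#' Combines amide 1H and 15N shift differences per residue into
#' `CSP = sqrt((0.159 * ddN)^2 + ddHN^2)` (ppm), the 15N difference being
#' down-weighted by the standard factor accounting for the nitrogen shift
#' range. Residues present in only one table are carried through as
#' explicit missing records, never dropped.
#'
#' @param free,bound Shift tables with columns `residue`, `d_h`, `d_n`
#'   (ppm), e.g. from [read_shift_table()].
#' @param n_weight Weight on the 15N difference (default 0.159).
#' @return A tibble with `residue`, `d_dh`, `d_dn`, `csp`, `missing`.
#' @export
#' @examples
#' free <- tibble::tibble(residue = 1:2, d_h = c(8.1, 8.3), d_n = c(118, 120))
#' bound <- tibble::tibble(residue = 1:2, d_h = c(8.1, 8.36), d_n = c(118, 120.5))
#' csp(free, bound)
csp <- function(free, bound, n_weight = 0.159) {
  for (tbl in list(free, bound)) {
    check_columns(tbl, c("residue", "d_h", "d_n"), "shift")
    if (anyDuplicated(tbl$residue)) abort("duplicate residue indices")
  }
  dplyr::full_join(
    dplyr::rename(free, d_h_free = "d_h", d_n_free = "d_n"),
    dplyr::rename(bound, d_h_bound = "d_h", d_n_bound = "d_n"),
    by = "residue"
  ) |>
    dplyr::mutate(
      d_dh = .data$d_h_bound - .data$d_h_free,
      d_dn = .data$d_n_bound - .data$d_n_free,
      csp = sqrt((n_weight * .data$d_dn)^2 + .data$d_dh^2),
      missing = is.na(.data$csp)
    ) |>
    dplyr::select("residue", "d_dh", "d_dn", "csp", "missing") |>
    dplyr::arrange(.data$residue)
}

#' Classify chemical shift perturbations
#'
#' Applies the two-threshold scheme used for perturbation maps: `csp >=`
#' upper threshold is `"very_strong"`, values in `[lower, upper)` are
#' `"strong"`, the rest `"none"`. Missing records keep `NA`.
#'
#' @param records Output of [csp()] (needs a `csp` column).
#' @param thresholds Increasing pair `c(strong, very_strong)` in ppm
#'   (default `c(0.07, 0.14)`).
#' @return `records` with a `category` factor column; per-category counts
#'   in the `"counts"` attribute.
#' @export
classify_csp <- function(records, thresholds = c(0.07, 0.14)) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0) {
    abort("thresholds must be two increasing values")
  }
  out <- dplyr::mutate(
    records,
    category = factor(
      dplyr::case_when(
        is.na(.data$csp) ~ NA_character_,
        .data$csp >= thresholds[2] ~ "very_strong",
        .data$csp >= thresholds[1] ~ "strong",
        TRUE ~ "none"
      ),
      levels = c("none", "strong", "very_strong")
    )
  )
  attr(out, "counts") <- table(out$category, useNA = "ifany")
  out
}

#' Heteronuclear nOe ratios and state differences
#'
#' Computes per-residue steady-state nOe ratios `I_sat / I_unsat` with
#' first-order error propagation of the spectral noise, the bound-minus-
#' free difference, and the banding used for structure maps: differences
#' `>= 0.18` are `"very_high"`, `[0.10, 0.16]` `"high"`; values in the
#' legend gap `(0.16, 0.18)` are reported as `"unclassified"` rather than
#' guessed. Records whose reference intensity is within noise of zero are
#' flagged unusable.
#'
#' @param free,bound Tibbles with columns `residue`, `sat`, `unsat`
#'   (peak intensities with and without proton saturation).
#' @param noise_sd Spectral noise SD (intensity units).
#' @param bands Thresholds `c(high_low, high_up, very_high)`.
#' @return A tibble with per-state nOes, propagated errors, `delta_noe`
#'   (bound - free), `band` and `usable`.
#' @export
noe_analysis <- function(free, bound, noise_sd,
                         bands = c(0.10, 0.16, 0.18)) {
  ratio <- function(tbl, suffix) {
    check_columns(tbl, c("residue", "sat", "unsat"), "nOe intensity")
    tbl |>
      dplyr::mutate(
        noe = .data$sat / .data$unsat,
        err = abs(.data$noe) *
          sqrt((noise_sd / .data$sat)^2 + (noise_sd / .data$unsat)^2),
        usable = abs(.data$unsat) > 3 * noise_sd
      ) |>
      dplyr::select(
        "residue",
        "{suffix}_noe" := "noe", "{suffix}_err" := "err",
        "{suffix}_usable" := "usable"
      )
  }
  dplyr::inner_join(ratio(free, "free"), ratio(bound, "bound"), by = "residue") |>
    dplyr::mutate(
      delta_noe = .data$bound_noe - .data$free_noe,
      delta_err = sqrt(.data$free_err^2 + .data$bound_err^2),
      usable = .data$free_usable & .data$bound_usable,
      band = factor(
        dplyr::case_when(
          !.data$usable ~ NA_character_,
          .data$delta_noe >= bands[3] - 1e-9 ~ "very_high",
          .data$delta_noe > bands[2] + 1e-9 ~ "unclassified",
          .data$delta_noe >= bands[1] - 1e-9 ~ "high",
          TRUE ~ "none"
        ),
        levels = c("none", "high", "unclassified", "very_high")
      )
    ) |>
    dplyr::select(
      "residue", "free_noe", "free_err", "bound_noe", "bound_err",
      "delta_noe", "delta_err", "band", "usable"
    )
}
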