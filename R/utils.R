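# Shared small helpers and reference constants.

# Physical constants (SI)
.const <- list(
  kB = 1.380649e-23,          # J/K
  NA_avogadro = 6.02214076e23, # /mol
  hbar = 1.054571817e-34,     # J s
  mu0 = 4 * pi * 1e-7,        # T m / A
  gamma_h = 2.6752218744e8,   # rad /s /T
  gamma_n = -2.7126189e7      # rad /s /T  (15N, negative)
)

#' Mature human calmodulin sequence
#'
#' One-letter sequence of mature human calmodulin (148 residues, initiator
#' methionine removed). Used as the default protein for the synthetic HDX
#' generator and for residue bookkeeping.
#'
#' @return A single string of 148 one-letter residue codes.
#' @export
#' @examples
#' nchar(cam_sequence())
cam_sequence <- function() {
  paste0(
    "ADQLTEEQIAEFKEAFSLFDKDGDGTITTKELGTVMRSLGQNPTEAELQDMINEVDADGNGTIDF",
    "PEFLTMMARKMKDTDSEEEIREAFRVFDKDGNGYISAAELRHVMTNLGEKLTDEEVDEMIREADI",
    "DGDGQVNYEEFVQMMTAK"
  )
}

#' Molar extinction coefficient at 280 nm
#'
#' Predicts the molar extinction coefficient of an unfolded/native protein at
#' 280 nm from its composition with the standard per-residue increments
#' (Tyr 1490, Trp 5500, cystine 125 M^-1 cm^-1). Calmodulin (2 Tyr, no Trp,
#' no Cys) gives 2980 M^-1 cm^-1.
#'
#' @param sequence One-letter amino-acid string. Cystines are assumed absent
#'   unless `n_cystine` is given.
#' @param n_cystine Number of disulfide bonds (default 0).
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
#' @examples
#' extinction_coefficient(cam_sequence())
extinction_coefficient <- function(sequence, n_cystine = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad) > 0) {
    abort(paste0("unknown residue code(s): ", paste(unique(bad), collapse = ", ")))
  }
  1490 * sum(aa == "Y") + 5500 * sum(aa == "W") + 125 * n_cystine
}

#' Partition residue indices into N-lobe, linker and C-lobe
#'
#' Calmodulin's two lobes are joined by a flexible linker; regional summaries
#' (e.g. of unassigned NMR resonances or HDX protection) use a three-way
#' partition. The default linker window 75-81 covers the dynamic segment and
#' its immediate neighbours.
#'
#' @param residues Integer vector of residue indices (1-based).
#' @param linker Length-2 integer vector, first and last linker residue.
#' @return A tibble with columns `residue` and `region`
#'   (factor: `"N-lobe"`, `"linker"`, `"C-lobe"`).
#' @export
#' @examples
#' partition_regions(c(10, 77, 120))
partition_regions <- function(residues, linker = c(75, 81)) {
  stopifnot(length(linker) == 2, linker[1] <= linker[2])
  region <- dplyr::case_when(
    residues < linker[1] ~ "N-lobe",
    residues > linker[2] ~ "C-lobe",
    TRUE ~ "linker"
  )
  tibble(
    residue = as.integer(residues),
    region = factor(region, levels = c("N-lobe", "linker", "C-lobe"))
  )
}

#' Derive a reproducible child seed
#'
#' Fans a single pipeline seed out to per-generator seeds so that stages can
#' be re-run independently yet deterministically.
#'
#' @param seed Parent integer seed.
#' @param tag Character tag naming the consumer.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) + 97 * h) %% (2^31 - 1))
}

# radius of gyration of a set of point scatterers (equal weights)
bead_rg <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

# sin(x)/x with the x -> 0 limit
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > .Machine$double.eps
  out[nz] <- sin(x[nz]) / x[nz]
  out
}
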