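#' Read a three-column SAXS .dat file
#'
#' Parses the beamline/SASBDB dialect of whitespace-separated `q I sigma`
#' text files. Leading comment or text header lines (including `#` lines)
#' are retained in the curve's `"metadata"` attribute. `q` is expected in
#' 1/Angstrom; files recorded in 1/nm can be converted on input.
#'
#' @param path Path to the text file.
#' @param fill_sigma If the file has only two numeric columns, fill
#'   `sigma = 1` instead of raising an error.
#' @param q_unit `"A"` (default, 1/Angstrom) or `"nm"` (1/nm; divided by 10
#'   on input).
#' @return A [saxs_curve()].
#' @export
read_saxs_dat <- function(path, fill_sigma = FALSE, q_unit = c("A", "nm")) {
  q_unit <- match.arg(q_unit)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty file")

  toks <- strsplit(trimws(lines), "[,;[:space:]]+")
  nums <- lapply(toks, function(x) suppressWarnings(as.numeric(x)))
  is_data <- vapply(nums, function(x) length(x) >= 2 && !anyNA(x[1:2]), logical(1))

  header <- lines[!is_data]
  rows <- nums[is_data]
  if (length(rows) == 0) abort("no numeric data rows found")

  ncol_min <- min(vapply(rows, length, integer(1)))
  if (ncol_min < 3 && !fill_sigma) {
    abort("missing sigma column (set fill_sigma = TRUE for unit weights)")
  }
  q <- vapply(rows, `[`, numeric(1), 1)
  I <- vapply(rows, `[`, numeric(1), 2)
  sigma <- if (ncol_min >= 3) vapply(rows, `[`, numeric(1), 3) else rep(1, length(q))
  if (anyNA(sigma)) abort("sigma column contains non-numeric entries")

  if (q_unit == "nm") q <- q / 10
  saxs_curve(q, I, sigma, metadata = header)
}

#' Write a scattering curve as a three-column .dat file
#'
#' @param curve A [saxs_curve()].
#' @param path Output path. Metadata lines are written as `#` comments.
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(curve, path) {
  curve <- as_saxs_curve(curve)
  meta <- attr(curve, "metadata")
  hdr <- if (length(meta) > 0) paste0("# ", sub("^#\\s*", "", meta)) else character()
  body <- sprintf("%.8e %.8e %.8e", curve$q, curve$I, curve$sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}
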