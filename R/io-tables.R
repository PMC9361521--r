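# Delimited-table readers with named-column contracts. Comma or tab
# delimiters are auto-sniffed; decimal points only.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

read_delim_sniffed <- function(path) {
  readr::read_delim(
    path,
    delim = sniff_delim(path), show_col_types = FALSE,
    trim_ws = TRUE, progress = FALSE
  )
}

check_columns <- function(tbl, required, what) {
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(
      what, " table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  invisible(tbl)
}

#' Read an amide chemical-shift table
#'
#' Expected columns: `residue` (1-based index), `d_h` (amide 1H shift, ppm),
#' `d_n` (15N shift, ppm).
#'
#' @param path Delimited text file (comma or tab, auto-sniffed).
#' @return A typed tibble.
#' @export
read_shift_table <- function(path) {
  tbl <- read_delim_sniffed(path)
  check_columns(tbl, c("residue", "d_h", "d_n"), "shift")
  if (anyDuplicated(tbl$residue)) abort("duplicate residue indices in shift table")
  dplyr::mutate(
    tbl,
    residue = as.integer(.data$residue),
    d_h = as.numeric(.data$d_h),
    d_n = as.numeric(.data$d_n)
  )
}

#' Read a relaxation decay table
#'
#' Expected columns: `delay` (relaxation delay), `signal`, and optionally
#' `noise_sd`. Delays recorded in milliseconds are converted to seconds when
#' `delay_unit = "ms"`.
#'
#' @param path Delimited text file.
#' @param delay_unit `"s"` (default) or `"ms"`.
#' @return A typed tibble with delays in seconds.
#' @export
read_decay_table <- function(path, delay_unit = c("s", "ms")) {
  delay_unit <- match.arg(delay_unit)
  tbl <- read_delim_sniffed(path)
  check_columns(tbl, c("delay", "signal"), "decay")
  tbl <- dplyr::mutate(
    tbl,
    delay = as.numeric(.data$delay) * if (delay_unit == "ms") 1e-3 else 1,
    signal = as.numeric(.data$signal)
  )
  if (any(tbl$delay < 0)) abort("negative delays")
  tbl
}

#' Read a peptide-level deuterium uptake table
#'
#' Expected columns: `peptide` (1-based id), `start`, `end`, `sequence`,
#' `state`, `time` (s), `replicate`, `uptake` (Da, centroid mass shift).
#' Duplicate `(peptide, state, time, replicate)` keys are an error;
#' incomplete replicate blocks are flagged with a warning.
#'
#' @param path Delimited text file.
#' @return A typed tibble.
#' @export
read_uptake_table <- function(path) {
  tbl <- read_delim_sniffed(path)
  check_columns(
    tbl,
    c("peptide", "start", "end", "sequence", "state", "time", "replicate", "uptake"),
    "uptake"
  )
  tbl <- dplyr::mutate(
    tbl,
    peptide = as.integer(.data$peptide),
    start = as.integer(.data$start),
    end = as.integer(.data$end),
    sequence = as.character(.data$sequence),
    state = as.character(.data$state),
    time = as.numeric(.data$time),
    replicate = as.integer(.data$replicate),
    uptake = as.numeric(.data$uptake)
  )
  if (any(tbl$time < 0)) abort("negative labeling times")
  key <- paste(tbl$peptide, tbl$state, tbl$time, tbl$replicate)
  if (anyDuplicated(key)) abort("duplicate (peptide, state, time, replicate) keys")
  counts <- dplyr::count(tbl, .data$peptide, .data$state, .data$time)
  if (length(unique(counts$n)) > 1) {
    warn("incomplete replicate blocks: unequal replicate counts across state x time")
  }
  tbl
}

#' Read an ITC injection-heat table
#'
#' Expected columns: `injection` (index), `volume` (microliters), `heat`
#' (microcalories).
#'
#' @param path Delimited text file.
#' @return A typed tibble.
#' @export
read_itc_table <- function(path) {
  tbl <- read_delim_sniffed(path)
  check_columns(tbl, c("injection", "volume", "heat"), "ITC")
  tbl <- dplyr::mutate(
    tbl,
    injection = as.integer(.data$injection),
    volume = as.numeric(.data$volume),
    heat = as.numeric(.data$heat)
  )
  if (any(tbl$volume < 0)) abort("negative injection volumes")
  tbl
}

#' Write a stage report (key-value header plus CSV table)
#'
#' Serializes a result as `# key: value` header lines followed by a CSV
#' body, so that numeric content round-trips through [read_report()].
#' Scalars are taken from non-data-frame elements of `results` (or, for
#' fitted objects, from their `glance()` row); the table from the first
#' data-frame element (or `tidy()` output).
#'
#' @param results A named list of scalars and/or data frames, or a fitted
#'   object with `tidy()`/`glance()` methods.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (!is.list(results) || inherits(results, "data.frame")) {
    results <- list(table = as_tibble(results))
  }
  if (inherits(results, c("guinier_fit", "tract_fit", "binding_fit"))) {
    results <- list(
      glance = as.list(glance(results)),
      table = tidy(results)
    )
    results <- c(results$glance, list(table = results$table))
  }
  is_df <- vapply(results, inherits, logical(1), "data.frame")
  scalars <- results[!is_df]
  tables <- results[is_df]
  hdr <- purrr::imap_chr(scalars, function(v, k) {
    sprintf("# %s: %s", k, paste(format(v, digits = 10), collapse = " "))
  })
  tbl <- if (length(tables) > 0) tables[[1]] else tibble()
  body <- sub("\n$", "", readr::format_csv(tbl))
  writeLines(c(hdr, strsplit(body, "\n")[[1]]), path)
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report file.
#' @return A list with `meta` (named list; numeric where possible) and
#'   `table` (tibble; zero rows if the report carried no table).
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(strsplit(m[3], "\\s+")[[1]]))
      meta[[trimws(m[2])]] <- if (anyNA(val)) m[3] else val
    }
  }
  body <- lines[!is_meta]
  tbl <- if (length(body) > 1 || (length(body) == 1 && nzchar(body))) {
    readr::read_csv(I(paste(body, collapse = "\n")),
      show_col_types = FALSE, progress = FALSE
    )
  } else {
    tibble()
  }
  list(meta = meta, table = tbl)
}
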