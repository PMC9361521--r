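# Structure-level computations: PDB in/out, Kabsch superposition and RMSD,
# ligand contact detection, and painting per-residue values into the
# B-factor column.

#' Read a PDB structure into an atom table
#'
#' Parses ATOM/HETATM records (via the bio3d parser) into a tibble. By
#' default only blank or `"A"` alternate locations are kept (deterministic
#' altloc policy) and waters are separable through `keep_waters`.
#'
#' @param path PDB file.
#' @param altloc Alternate-location codes to retain (besides blank).
#' @param keep_waters Keep HOH/WAT residues.
#' @return A tibble of class `structure_model` with columns `serial`,
#'   `name`, `element`, `resname`, `chain`, `resno`, `altloc`, `occupancy`,
#'   `b`, `x`, `y`, `z`, `record`.
#' @export
read_structure <- function(path, altloc = "A", keep_waters = FALSE) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse PDB file: ", conditionMessage(e)))
  )
  a <- pdb$atom
  if (nrow(a) == 0) abort("empty model")
  out <- tibble(
    serial = as.integer(a$eleno),
    name = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
      toupper(substr(trimws(a$elety), 1, 1)), trimws(a$elesy)
    ),
    resname = a$resid,
    chain = a$chain,
    resno = as.integer(a$resno),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    occupancy = as.numeric(a$o),
    b = as.numeric(a$b),
    x = a$x, y = a$y, z = a$z,
    record = a$type
  )
  out <- dplyr::filter(out, .data$altloc %in% c("", altloc))
  if (!keep_waters) out <- dplyr::filter(out, !.data$resname %in% c("HOH", "WAT"))
  if (any(!is.finite(out$x + out$y + out$z))) abort("non-finite coordinates")
  class(out) <- c("structure_model", class(out))
  out
}

#' Write an atom table as a PDB file
#'
#' Fixed-width v3.3 ATOM/HETATM records with TER/END. B-factors are
#' clamped to the format's field range.
#'
#' @param model A `structure_model` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  check_columns(model, c("name", "resname", "chain", "resno", "x", "y", "z"), "atom")
  n <- nrow(model)
  serial <- model$serial %||% seq_len(n)
  occ <- model$occupancy %||% rep(1, n)
  b <- pmin(pmax(model$b %||% rep(0, n), -99.99), 999.99)
  rec <- model$record %||% rep("ATOM", n)
  elem <- model$element %||% toupper(substr(trimws(model$name), 1, 1))
  atom_name <- vapply(model$name, function(nm) {
    nm <- trimws(nm)
    if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
  }, character(1))
  lines <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, serial, atom_name, "", model$resname, model$chain, model$resno, "",
    model$x, model$y, model$z, occ, b, elem
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# optimal proper rotation superposing moving onto fixed (both centered)
kabsch_rotation <- function(fixed, moving) {
  H <- crossprod(moving, fixed)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  s$u %*% D %*% t(s$v)
}

#' RMSD after optimal (Kabsch) superposition
#'
#' Matches atoms between two structures by `(chain, resno, name)`
#' intersection under the given selection, superposes them by the
#' closed-form least-squares rotation (proper rotations only) and returns
#' the post-fit RMSD.
#'
#' @param a,b `structure_model` tibbles (or coordinate matrices, matched
#'   row-wise).
#' @param selection Named list: `name` (atom name, default `"CA"`),
#'   optional `resno` (indices to keep), `chain`.
#' @return RMSD in Angstrom, with the matched atom count as attribute
#'   `"n_atoms"`.
#' @export
kabsch_rmsd <- function(a, b, selection = list(name = "CA")) {
  if (is.matrix(a) && is.matrix(b)) {
    if (nrow(a) != nrow(b)) abort("coordinate matrices must match row-wise")
    P <- a
    Q <- b
  } else {
    sel <- function(m) {
      if (!is.null(selection$name)) m <- dplyr::filter(m, .data$name %in% selection$name)
      if (!is.null(selection$resno)) m <- dplyr::filter(m, .data$resno %in% selection$resno)
      if (!is.null(selection$chain)) m <- dplyr::filter(m, .data$chain %in% selection$chain)
      m
    }
    am <- sel(a)
    bm <- sel(b)
    key <- c("chain", "resno", "name")
    j <- dplyr::inner_join(am, bm, by = key, suffix = c("_a", "_b"))
    if (nrow(j) < 3) abort("fewer than 3 matched atoms")
    P <- cbind(j$x_a, j$y_a, j$z_a)
    Q <- cbind(j$x_b, j$y_b, j$z_b)
  }
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  R <- kabsch_rotation(P0, Q0)
  diffs <- Q0 %*% R - P0
  out <- sqrt(mean(rowSums(diffs^2)))
  attr(out, "n_atoms") <- nrow(P)
  out
}

#' Protein residues in contact with a ligand
#'
#' Lists protein residues with any heavy-atom pair within `cutoff` of any
#' heavy atom of the named ligand residue, with per-residue minimal
#' distances. Hydrogens are excluded; the default cutoff is the
#' conventional 3.9 Angstrom non-bonded contact limit.
#'
#' @param model A `structure_model`.
#' @param ligand_resname Ligand residue name (e.g. `"CDZ"`).
#' @param cutoff Contact distance cutoff (Angstrom).
#' @return A `contact_set` tibble with `chain`, `resno`, `resname`,
#'   `min_dist`; cutoff kept as attribute.
#' @export
ligand_contacts <- function(model, ligand_resname, cutoff = 3.9) {
  heavy <- dplyr::filter(model, .data$element != "H")
  lig <- dplyr::filter(heavy, .data$resname == ligand_resname)
  if (nrow(lig) == 0) abort(sprintf("ligand residue '%s' absent", ligand_resname))
  prot <- dplyr::filter(
    heavy,
    .data$resname != ligand_resname, .data$record == "ATOM"
  )
  if (nrow(prot) == 0) abort("no protein atoms")
  lx <- as.matrix(lig[, c("x", "y", "z")])
  px <- as.matrix(prot[, c("x", "y", "z")])
  d2 <- outer(rowSums(px^2), rowSums(lx^2), "+") - 2 * px %*% t(lx)
  prot$min_dist <- sqrt(pmax(apply(d2, 1, min), 0))
  out <- prot |>
    dplyr::group_by(.data$chain, .data$resno, .data$resname) |>
    dplyr::summarise(min_dist = min(.data$min_dist), .groups = "drop") |>
    dplyr::filter(.data$min_dist <= cutoff) |>
    dplyr::arrange(.data$chain, .data$resno)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_set", class(out))
  out
}

#' Paint per-residue values into the B-factor column
#'
#' Replaces the B-factor of every atom of each residue by the mapped value
#' (e.g. average uptake difference or CSP); residues without a value get
#' the sentinel. Values outside the PDB field range are clamped on write.
#'
#' @param model A `structure_model`.
#' @param values Tibble with `residue` and `value` columns (e.g. from
#'   [residue_map()]).
#' @param missing_value Sentinel for unmapped residues.
#' @return The model with an updated `b` column.
#' @export
paint_residue_values <- function(model, values, missing_value = -1) {
  check_columns(values, c("residue", "value"), "residue value")
  if (nrow(values) == 0) abort("empty value table")
  lut <- setNames(values$value, values$residue)
  v <- unname(lut[as.character(model$resno)])
  v[is.na(v)] <- missing_value
  model$b <- v
  model
}
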