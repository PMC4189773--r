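#' @title Macromolecular structure container
#'
#' @description A `carb_structure` is a light hierarchical atom container:
#' one data frame of atom records ordered by (chain, residue number,
#' insertion code, file order), plus free-text provenance. Residues are
#' the groups of rows sharing `(chain, resno, ins)`; metal ions and
#' waters are recognised by element / residue name.
#'
#' Columns of `$atoms`: `chain`, `resno` (author numbering), `ins`,
#' `resname`, `atom` (label, e.g. `"OG1"`, `"B6"`), `element`, `altloc`,
#' `x`, `y`, `z` (Angstrom), `occ` (occupancy in \[0,1\]), `adp`
#' (isotropic-equivalent displacement parameter, Angstrom^2), `het`
#' (HETATM flag).
#'
#' @param atoms data frame with the columns listed above.
#' @param source_id free-text provenance (e.g. an accession or file name).
#' @return A `carb_structure` object.
#' @export
new_structure <- function(atoms, source_id = "") {
  req <- c("chain", "resno", "ins", "resname", "atom", "element",
           "altloc", "x", "y", "z", "occ", "adp", "het")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, req]
  atoms$resno <- as.integer(atoms$resno)
  for (col in c("chain", "ins", "resname", "atom", "element", "altloc")) {
    atoms[[col]] <- as.character(atoms[[col]])
    atoms[[col]][is.na(atoms[[col]])] <- ""
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atoms table")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE)) {
    stop("occupancies must lie in [0, 1]")
  }
  if (any(!nzchar(atoms$element))) {
    stop("every atom needs an element symbol")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id),
            class = "carb_structure")
}

#' @export
print.carb_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<carb_structure> %s\n", x$source_id))
  cat(sprintf("  %d atoms, %d residues, %d waters, %d metal ions\n",
              nrow(a), length(unique(residue_key(a))),
              sum(a$resname == "HOH" & a$atom == "O" |
                    a$resname == "HOH" & a$element == "O"),
              sum(is_metal_row(a))))
  invisible(x)
}

#' @export
as.data.frame.carb_structure <- function(x, ...) x$atoms

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
}

METAL_ELEMENTS <- c("ZN", "MG", "MN", "FE", "CU", "NI", "CO", "CA", "NA", "K",
                    "HG", "CD")

# Metal flag: metallic element in a single-atom residue.
is_metal_row <- function(atoms) {
  key <- residue_key(atoms)
  n_per <- table(key)
  toupper(atoms$element) %in% METAL_ELEMENTS & as.vector(n_per[key]) == 1L
}

is_water_row <- function(atoms) {
  atoms$resname %in% c("HOH", "WAT", "DOD")
}

#' Residue identifier
#'
#' Convenience constructor for the `(chain, number, insertion code)` key
#' used throughout the package to address one residue.
#'
#' @param chain chain label.
#' @param resno author residue number.
#' @param ins insertion code, usually `""`.
#' @return A `carb_resid` list.
#' @export
residue_id <- function(chain, resno, ins = "") {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 ins = as.character(ins)), class = "carb_resid")
}

resid_key <- function(rid) paste(rid$chain, rid$resno, rid$ins, sep = "|")

#' Declarative atom selection
#'
#' Builds a filter over atoms; all supplied clauses must match
#' (conjunction). Residue numbers are author numbers; pass inclusive
#' ranges as plain integer vectors (e.g. `4:261`). Applying a selection
#' twice equals applying it once.
#'
#' @param chain chain labels to keep, or `NULL` for all.
#' @param resno integer vector of residue numbers to keep, or `NULL`.
#' @param resname residue names to keep, or `NULL`.
#' @param atom atom labels to keep (e.g. `"CA"`), or `NULL`.
#' @param element element symbols to keep, or `NULL`.
#' @param altloc `"best"` (default) keeps, per atom, the alternate
#'   location with highest occupancy (ties broken alphabetically);
#'   `"all"` retains every altloc record.
#' @return A `carb_selection` object.
#' @export
atom_selection <- function(chain = NULL, resno = NULL, resname = NULL,
                           atom = NULL, element = NULL,
                           altloc = c("best", "all")) {
  altloc <- match.arg(altloc)
  structure(list(chain = chain, resno = if (is.null(resno)) NULL else as.integer(resno),
                 resname = resname, atom = atom, element = element,
                 altloc = altloc),
            class = "carb_selection")
}

# Altloc policy "best": per (chain,resno,ins,atom name) keep the record
# with highest occupancy; ties go to the alphabetically first tag.
apply_altloc_best <- function(atoms) {
  if (nrow(atoms) == 0L || all(atoms$altloc == "")) return(atoms)
  key <- paste(residue_key(atoms), atoms$atom, sep = "|")
  ord <- order(key, -atoms$occ, atoms$altloc)
  keep <- !duplicated(key[ord])
  atoms[sort(ord[keep]), , drop = FALSE]
}

#' Select atoms from a structure
#'
#' Returns the atom records matching every clause of the selection, in
#' deterministic order (chain, residue number, insertion code, file
#' order within the residue).
#'
#' @param s a `carb_structure` (or an atom data frame).
#' @param sel a [atom_selection()] object; the default selects all atoms
#'   under the `"best"` altloc policy.
#' @return An atom data frame (possibly empty).
#' @export
select_atoms <- function(s, sel = atom_selection()) {
  atoms <- if (inherits(s, "carb_structure")) s$atoms else as.data.frame(s)
  if (!inherits(sel, "carb_selection")) stop("sel must be an atom_selection()")
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(sel$chain)) {
    if (!any(atoms$chain %in% sel$chain)) {
      warning("selection names chain(s) absent from the structure: ",
              paste(setdiff(sel$chain, atoms$chain), collapse = ", "))
    }
    keep <- keep & atoms$chain %in% sel$chain
  }
  if (!is.null(sel$resno)) keep <- keep & atoms$resno %in% sel$resno
  if (!is.null(sel$resname)) keep <- keep & atoms$resname %in% sel$resname
  if (!is.null(sel$atom)) keep <- keep & atoms$atom %in% sel$atom
  if (!is.null(sel$element)) {
    keep <- keep & toupper(atoms$element) %in% toupper(sel$element)
  }
  out <- atoms[keep, , drop = FALSE]
  if (sel$altloc == "best") out <- apply_altloc_best(out)
  ord <- order(out$chain, out$resno, out$ins, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1L]
  s$atoms$y <- xyz[, 2L]
  s$atoms$z <- xyz[, 3L]
  s
}

#' Summary statistics of a structure
#'
#' Atom, residue and water counts plus the unweighted arithmetic mean of
#' the isotropic-equivalent displacement parameter over the selected
#' atoms.
#'
#' @param s a `carb_structure`.
#' @param sel an [atom_selection()]; default: all atoms, best altloc.
#' @return A list with `n_atoms`, `n_residues`, `n_waters`, `mean_adp`.
#' @export
structure_stats <- function(s, sel = atom_selection()) {
  a <- select_atoms(s, sel)
  if (nrow(a) == 0L) stop("empty selection: no atoms to summarise")
  waters <- a[is_water_row(a), , drop = FALSE]
  list(n_atoms = nrow(a),
       n_residues = length(unique(residue_key(a))),
       n_waters = length(unique(residue_key(waters))),
       mean_adp = mean(a$adp))
}

# Atoms of one residue (by residue_id); best-altloc not applied.
residue_atoms <- function(s, rid) {
  a <- s$atoms
  a[a$chain == rid$chain & a$resno == rid$resno & a$ins == rid$ins, ,
    drop = FALSE]
}

# Unique residues as a data frame (chain, resno, ins, resname).
residue_table <- function(s) {
  a <- if (inherits(s, "carb_structure")) s$atoms else s
  key <- residue_key(a)
  first <- !duplicated(key)
  out <- a[first, c("chain", "resno", "ins", "resname"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Replace the atoms of one residue with a new block, keeping overall
# residue order stable.
replace_residue <- function(s, rid, new_block) {
  a <- s$atoms
  idx <- which(a$chain == rid$chain & a$resno == rid$resno & a$ins == rid$ins)
  if (length(idx) == 0L) stop("residue not found: ", resid_key(rid))
  before <- a[seq_len(min(idx) - 1L), , drop = FALSE]
  after <- a[setdiff(seq_len(nrow(a)), c(seq_len(min(idx) - 1L), idx)), ,
             drop = FALSE]
  s$atoms <- rbind(before, new_block, after)
  rownames(s$atoms) <- NULL
  s
}
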