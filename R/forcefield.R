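#' Load the nonbonded force field
#'
#' The energy model is a fixed-charge Coulomb + Lennard-Jones surrogate:
#' per van der Waals type a well depth `epsilon` (kcal/mol) and size
#' `sigma` (Angstrom), per (residue template, atom name) a partial
#' charge (elementary units) and type key. Nonpolar hydrogens on carbon
#' carry zero charge and zero well depth; their sterics are folded into
#' the parent carbon's sigma. Solvent screening uses a
#' distance-dependent dielectric `eps(r) = k * r` (default `k = 4`);
#' a constant dielectric is available for closed-form checks.
#'
#' @param path optional path to an alternative type-parameter TSV with
#'   columns `type`, `epsilon`, `sigma`.
#' @param dielectric `"distance"` (eps = k*r) or `"constant"`.
#' @param dielectric_k screening constant `k` (distance model) or the
#'   fixed relative permittivity (constant model).
#' @return A `carb_forcefield` object.
#' @export
load_forcefield <- function(path = NULL,
                            dielectric = c("distance", "constant"),
                            dielectric_k = 4) {
  dielectric <- match.arg(dielectric)
  types <- read.delim(if (is.null(path)) carb_extdata("ff_atom_types.tsv")
                      else path, stringsAsFactors = FALSE,
                      na.strings = character())
  if (any(types$epsilon < 0) || any(types$sigma <= 0)) {
    stop("force-field types need epsilon >= 0 and sigma > 0")
  }
  residues <- read.delim(carb_extdata("ff_residues.tsv"),
                         stringsAsFactors = FALSE, na.strings = character())
  lig <- load_ligand_template()$atoms
  params <- rbind(residues[, c("res", "atom", "element", "type", "charge")],
                  lig[, c("res", "atom", "element", "type", "charge")])
  unknown <- setdiff(params$type, types$type)
  if (length(unknown) > 0L) {
    stop("types without parameters: ", paste(unknown, collapse = ", "))
  }
  structure(list(types = types, params = params,
                 dielectric = dielectric, dielectric_k = dielectric_k,
                 coulomb = 332.0637),
            class = "carb_forcefield")
}

#' Assign nonbonded parameters to a structure
#'
#' Joins every atom with its template record, attaching `charge`,
#' `vdw_type`, `eps` and `sigma` columns. Hydrogens must already be
#' present (see [add_hydrogens()]); every unparameterised atom is
#' enumerated in the error.
#'
#' @param s a `carb_structure`.
#' @param ff a [load_forcefield()] object.
#' @return The structure with parameter columns added to `$atoms`.
#' @export
assign_parameters <- function(s, ff = load_forcefield()) {
  a <- s$atoms
  key <- paste(a$resname, a$atom, sep = "|")
  pkey <- paste(ff$params$res, ff$params$atom, sep = "|")
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    bad <- a[is.na(idx), , drop = FALSE]
    stop("unparameterised atoms: ",
         paste(sprintf("%s %s%d %s", bad$resname, bad$chain, bad$resno,
                       bad$atom), collapse = "; "))
  }
  a$charge <- ff$params$charge[idx]
  a$vdw_type <- ff$params$type[idx]
  tidx <- match(a$vdw_type, ff$types$type)
  a$eps <- ff$types$epsilon[tidx]
  a$sigma <- ff$types$sigma[tidx]
  s$atoms <- a
  s
}

is_parameterized <- function(s) {
  all(c("charge", "eps", "sigma") %in% names(s$atoms))
}
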