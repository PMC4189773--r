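#' Load a bundled ligand template
#'
#' A ligand template carries the topology and nonbonded parameters of a
#' ligand: atom names (heavy atoms and hydrogens), elements, bonds
#' (including the icosahedral cage adjacency for carboranes), partial
#' charges, van der Waals type keys, a deposited-name alias table, and
#' an idealised 3-D geometry for the heavy atoms.
#'
#' `"compound1"` is 1-methylenesulfamide-1,2-dicarba-closo-dodecaborane:
#' a 12-vertex ortho-carborane cage (vertices C1, C2, B3..B12, each
#' vertex bearing one exo hydrogen) with a methylene linker C3 to the
#' sulfamide group N1-S(O1)(O2)-N2. 18 heavy atoms, formal charge 0.
#'
#' @param name template identifier; currently `"compound1"`.
#' @return A `carb_ligand_template` list with elements `name`, `resname`,
#'   `atoms` (data frame: atom, element, type, charge, hyb, parent,
#'   alias), `bonds` (data frame a1, a2), `cage_atoms`, `coords`
#'   (idealised heavy-atom coordinates).
#' @export
load_ligand_template <- function(name = "compound1") {
  if (!identical(name, "compound1")) {
    stop("unknown ligand template: '", name, "'")
  }
  cached <- .carb_env$compound1
  if (!is.null(cached)) return(cached)
  atoms <- read.delim(carb_extdata("compound1_atoms.tsv"),
                      stringsAsFactors = FALSE, na.strings = character())
  bonds <- read.delim(carb_extdata("compound1_bonds.tsv"),
                      stringsAsFactors = FALSE)
  xyz <- read.delim(carb_extdata("compound1_coords.tsv"),
                    stringsAsFactors = FALSE)
  coords <- as.matrix(xyz[, c("x", "y", "z")])
  rownames(coords) <- xyz$atom
  cage <- atoms$atom[atoms$hyb == "cage"]
  tpl <- structure(list(name = name, resname = "CB1", atoms = atoms,
                        bonds = bonds, cage_atoms = cage, coords = coords),
                   class = "carb_ligand_template")
  validate_ligand_template(tpl)
  .carb_env$compound1 <- tpl
  tpl
}

validate_ligand_template <- function(tpl) {
  a <- tpl$atoms
  heavy <- a$atom[a$element != "H"]
  cage <- tpl$cage_atoms
  if (length(cage) != 12L) stop("cage must have 12 vertices")
  if (sum(a$element[a$atom %in% cage] == "C") != 2L) {
    stop("cage must contain exactly two carbon vertices")
  }
  cb <- tpl$bonds[tpl$bonds$a1 %in% cage & tpl$bonds$a2 %in% cage, ]
  deg <- table(c(cb$a1, cb$a2))
  if (!all(names(deg) %in% cage) || !all(deg == 5L)) {
    stop("cage sub-graph must be 5-regular (icosahedron)")
  }
  if (abs(sum(a$charge)) > 1e-9) stop("ligand charges must sum to 0")
  alias <- a$alias[a$element != "H"]
  if (anyDuplicated(alias) || length(alias) != length(heavy)) {
    stop("alias table must be a bijection on the heavy atoms")
  }
  invisible(tpl)
}

#' Canonicalise deposited ligand atom names
#'
#' Maps deposited atom labels to the template's canonical names through
#' the alias table.
#'
#' @param names character vector of deposited atom labels.
#' @param template a [load_ligand_template()] object.
#' @return Character vector of canonical names (`NA` where unknown).
#' @export
canonical_ligand_names <- function(names, template = load_ligand_template()) {
  a <- template$atoms
  a$atom[match(names, a$alias)]
}

#' Build ligand coordinates from the template
#'
#' Returns a `carb_structure` holding the ligand's heavy atoms at the
#' idealised template geometry (cage centred at the origin), optionally
#' rigidly transformed.
#'
#' @param template a [load_ligand_template()] object.
#' @param chain chain label for the ligand residue.
#' @param resno residue number for the ligand residue.
#' @param transform optional `carb_transform` applied to the coordinates.
#' @return A `carb_structure` with one ligand residue.
#' @export
build_ligand <- function(template = load_ligand_template(), chain = "A",
                         resno = 301L, transform = NULL) {
  heavy <- template$atoms[template$atoms$element != "H", ]
  xyz <- template$coords[heavy$atom, , drop = FALSE]
  if (!is.null(transform)) xyz <- apply_transform(xyz, transform)
  atoms <- data.frame(chain = chain, resno = as.integer(resno), ins = "",
                      resname = template$resname, atom = heavy$atom,
                      element = heavy$element, altloc = "",
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      occ = 1, adp = 0, het = TRUE,
                      stringsAsFactors = FALSE)
  new_structure(atoms, source_id = paste0("template:", template$name))
}
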