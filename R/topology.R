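# Residue templates (atoms, charges, hydrogens, bonds) and idealised
# residue geometry. Geometry is approximate textbook stereochemistry:
# it seeds synthetic fixtures and hydrogen placement; covalent geometry
# during relaxation is restrained to the *input* values, so small
# template imperfections are harmless.

residue_templates <- function() {
  cached <- .carb_env$templates
  if (!is.null(cached)) return(cached)
  atoms <- read.delim(carb_extdata("ff_residues.tsv"),
                      stringsAsFactors = FALSE, na.strings = character())
  bonds <- read.delim(carb_extdata("ff_bonds.tsv"),
                      stringsAsFactors = FALSE)
  tpl <- list(atoms = atoms, bonds = bonds)
  .carb_env$templates <- tpl
  tpl
}

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# Side-chain z-matrices: atom placed from (a1, a2, a3) with bond length,
# angle and torsion. Backbone N/CA/C/O handled separately.
SIDECHAIN_ZMAT <- list(
  ALA = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122)),
  VAL = list(c("CB", "CA", "N", "C", 1.54, 110.5, -122),
             c("CG1", "CB", "CA", "N", 1.53, 110.5, 180),
             c("CG2", "CB", "CA", "N", 1.53, 110.5, -60)),
  LEU = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.53, 114, 180),
             c("CD1", "CG", "CB", "CA", 1.53, 110.5, 60),
             c("CD2", "CG", "CB", "CA", 1.53, 110.5, 180)),
  ILE = list(c("CB", "CA", "N", "C", 1.54, 110.5, -122),
             c("CG1", "CB", "CA", "N", 1.53, 110.5, 180),
             c("CG2", "CB", "CA", "N", 1.53, 110.5, -60),
             c("CD1", "CG1", "CB", "CA", 1.53, 113, 180)),
  SER = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("OG", "CB", "CA", "N", 1.42, 110.5, 180)),
  THR = list(c("CB", "CA", "N", "C", 1.54, 110.5, -122),
             c("OG1", "CB", "CA", "N", 1.43, 109.5, 180),
             c("CG2", "CB", "CA", "N", 1.53, 110.5, -60)),
  CYS = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("SG", "CB", "CA", "N", 1.81, 113, 180)),
  MET = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.53, 114, 180),
             c("SD", "CG", "CB", "CA", 1.81, 112.7, 180),
             c("CE", "SD", "CG", "CB", 1.79, 100.2, 180)),
  PHE = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.50, 114, 180),
             c("CD1", "CG", "CB", "CA", 1.39, 120, 90),
             c("CD2", "CG", "CB", "CD1", 1.39, 120, 180),
             c("CE1", "CD1", "CG", "CB", 1.39, 120, 180),
             c("CE2", "CD2", "CG", "CB", 1.39, 120, 180),
             c("CZ", "CE1", "CD1", "CG", 1.39, 120, 0)),
  TYR = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.50, 114, 180),
             c("CD1", "CG", "CB", "CA", 1.39, 120, 90),
             c("CD2", "CG", "CB", "CD1", 1.39, 120, 180),
             c("CE1", "CD1", "CG", "CB", 1.39, 120, 180),
             c("CE2", "CD2", "CG", "CB", 1.39, 120, 180),
             c("CZ", "CE1", "CD1", "CG", 1.39, 120, 0),
             c("OH", "CZ", "CE1", "CD1", 1.38, 120, 180)),
  TRP = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.50, 114, 180),
             c("CD1", "CG", "CB", "CA", 1.37, 127, 90),
             c("CD2", "CG", "CB", "CD1", 1.43, 126, 180),
             c("NE1", "CD1", "CG", "CD2", 1.38, 110, 0),
             c("CE2", "CD2", "CG", "CD1", 1.41, 107, 0),
             c("CE3", "CD2", "CG", "CD1", 1.40, 133, 180),
             c("CZ2", "CE2", "CD2", "CE3", 1.40, 122, 180),
             c("CZ3", "CE3", "CD2", "CE2", 1.39, 118, 0),
             c("CH2", "CZ2", "CE2", "CD2", 1.37, 117, 0)),
  ASN = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.52, 113, 180),
             c("OD1", "CG", "CB", "CA", 1.23, 121, -60),
             c("ND2", "CG", "CB", "OD1", 1.33, 117, 180)),
  GLN = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.53, 114, 180),
             c("CD", "CG", "CB", "CA", 1.52, 113, 180),
             c("OE1", "CD", "CG", "CB", 1.23, 121, -60),
             c("NE2", "CD", "CG", "OE1", 1.33, 117, 180)),
  ASP = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.52, 113, 180),
             c("OD1", "CG", "CB", "CA", 1.25, 118.5, -60),
             c("OD2", "CG", "CB", "OD1", 1.25, 118.5, 180)),
  GLU = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.53, 114, 180),
             c("CD", "CG", "CB", "CA", 1.52, 113, 180),
             c("OE1", "CD", "CG", "CB", 1.25, 118.5, -60),
             c("OE2", "CD", "CG", "OE1", 1.25, 118.5, 180)),
  LYS = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.53, 114, 180),
             c("CD", "CG", "CB", "CA", 1.53, 111.3, 180),
             c("CE", "CD", "CG", "CB", 1.53, 111.3, 180),
             c("NZ", "CE", "CD", "CG", 1.49, 112, 180)),
  ARG = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.53, 114, 180),
             c("CD", "CG", "CB", "CA", 1.53, 111.3, 180),
             c("NE", "CD", "CG", "CB", 1.46, 112, 180),
             c("CZ", "NE", "CD", "CG", 1.33, 124.2, 180),
             c("NH1", "CZ", "NE", "CD", 1.33, 120, 0),
             c("NH2", "CZ", "NE", "NH1", 1.33, 120, 180)),
  HIS = list(c("CB", "CA", "N", "C", 1.53, 110.5, -122),
             c("CG", "CB", "CA", "N", 1.50, 114, 180),
             c("ND1", "CG", "CB", "CA", 1.38, 122, 90),
             c("CD2", "CG", "CB", "ND1", 1.36, 131, 180),
             c("CE1", "ND1", "CG", "CD2", 1.32, 109, 0),
             c("NE2", "CD2", "CG", "ND1", 1.37, 107, 0)),
  PRO = list(c("CB", "CA", "N", "C", 1.53, 103, -120),
             c("CG", "CB", "CA", "N", 1.52, 104, 30),
             c("CD", "CG", "CB", "CA", 1.52, 104, -35)),
  GLY = list()
)

#' Build one residue at idealised geometry
#'
#' Places backbone and side-chain heavy atoms from internal-coordinate
#' templates, with the backbone N at the origin and CA along +x. The
#' geometry is approximate (ideal bond lengths/angles, standard
#' rotamer-free torsions, planar rings); it is intended for synthetic
#' fixtures, not for refinement.
#'
#' @param resname three-letter amino-acid code (or `"HOH"`, `"ZN"`).
#' @param chain,resno,ins residue identity for the emitted records.
#' @return A `carb_structure` with one residue.
#' @export
ideal_residue <- function(resname, chain = "A", resno = 1L, ins = "") {
  resname <- toupper(resname)
  if (resname == "HOH") {
    atoms <- data.frame(chain = chain, resno = as.integer(resno), ins = ins,
                        resname = "HOH", atom = "O", element = "O",
                        altloc = "", x = 0, y = 0, z = 0, occ = 1, adp = 0,
                        het = TRUE, stringsAsFactors = FALSE)
    return(new_structure(atoms, source_id = "ideal:HOH"))
  }
  if (resname == "ZN") {
    atoms <- data.frame(chain = chain, resno = as.integer(resno), ins = ins,
                        resname = "ZN", atom = "ZN", element = "Zn",
                        altloc = "", x = 0, y = 0, z = 0, occ = 1, adp = 0,
                        het = TRUE, stringsAsFactors = FALSE)
    return(new_structure(atoms, source_id = "ideal:ZN"))
  }
  if (!resname %in% AMINO_ACIDS) stop("no template for residue ", resname)
  pos <- list()
  pos[["N"]] <- c(0, 0, 0)
  pos[["CA"]] <- c(1.458, 0, 0)
  pos[["C"]] <- pos[["CA"]] +
    1.525 * c(cos(deg2rad(180 - 111)), sin(deg2rad(180 - 111)), 0)
  pos[["O"]] <- place_atom(pos[["C"]], pos[["CA"]], pos[["N"]],
                           1.231, 120.5, 135)
  for (row in SIDECHAIN_ZMAT[[resname]]) {
    nm <- row[1L]
    pos[[nm]] <- place_atom(pos[[row[2L]]], pos[[row[3L]]], pos[[row[4L]]],
                            as.numeric(row[5L]), as.numeric(row[6L]),
                            as.numeric(row[7L]))
  }
  tpl <- residue_templates()$atoms
  order_names <- tpl$atom[tpl$res == resname & tpl$element != "H"]
  xyz <- do.call(rbind, pos[order_names])
  atoms <- data.frame(chain = chain, resno = as.integer(resno), ins = ins,
                      resname = resname, atom = order_names,
                      element = tpl$element[tpl$res == resname][
                        match(order_names,
                              tpl$atom[tpl$res == resname])],
                      altloc = "",
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      occ = 1, adp = 0, het = FALSE,
                      stringsAsFactors = FALSE)
  new_structure(atoms, source_id = paste0("ideal:", resname))
}

# Bond list for a whole structure as an integer pair matrix over atom row
# indices: template bonds (residues + ligand), X-H bonds by H-parenthood,
# and peptide C(i)-N(i+1) links detected by distance (< 1.8 A).
structure_bonds <- function(s) {
  a <- s$atoms
  tpl <- residue_templates()
  lig <- load_ligand_template()
  xyz <- coords_matrix(a)
  key <- residue_key(a)
  bonds <- NULL
  for (rk in unique(key)) {
    idx <- which(key == rk)
    rn <- a$resname[idx[1L]]
    btab <- if (rn == lig$resname) lig$bonds
            else {
              bt <- tpl$bonds[tpl$bonds$res == rn, c("a1", "a2")]
              if (rn == "HOH" || rn == "ZN" || nrow(bt) == 0L) NULL else bt
            }
    if (!is.null(btab)) {
      i1 <- idx[match(btab$a1, a$atom[idx])]
      i2 <- idx[match(btab$a2, a$atom[idx])]
      keep <- !is.na(i1) & !is.na(i2)
      if (any(keep)) bonds <- rbind(bonds, cbind(i1[keep], i2[keep]))
    }
    # hydrogens: bond to template parent
    hs <- idx[toupper(a$element[idx]) == "H"]
    if (length(hs) > 0L) {
      ptab <- if (rn == lig$resname) lig$atoms
              else tpl$atoms[tpl$atoms$res == rn, ]
      par <- ptab$parent[match(a$atom[hs], ptab$atom)]
      pi_ <- idx[match(par, a$atom[idx])]
      keep <- !is.na(pi_)
      if (any(keep)) bonds <- rbind(bonds, cbind(hs[keep], pi_[keep]))
    }
  }
  # peptide links: C of residue i to N of residue j, distance < 1.8
  cidx <- which(a$atom == "C" & a$resname %in% AMINO_ACIDS)
  nidx <- which(a$atom == "N" & a$resname %in% AMINO_ACIDS)
  for (i in cidx) {
    if (length(nidx) == 0L) break
    d <- sqrt(colSums((t(xyz[nidx, , drop = FALSE]) - xyz[i, ])^2))
    j <- nidx[d < 1.8 & key[nidx] != key[i]]
    if (length(j) > 0L) bonds <- rbind(bonds, cbind(i, j))
  }
  if (is.null(bonds)) return(matrix(integer(), 0L, 2L))
  # canonical order, unique
  bonds <- cbind(pmin(bonds[, 1L], bonds[, 2L]),
                 pmax(bonds[, 1L], bonds[, 2L]))
  bonds[!duplicated(paste(bonds[, 1L], bonds[, 2L])), , drop = FALSE]
}

# 1-3 pairs (atoms bonded to a common atom) from a bond matrix.
angle_pairs <- function(bonds, n_atoms) {
  if (nrow(bonds) == 0L) return(matrix(integer(), 0L, 2L))
  nb <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1L]; j <- bonds[r, 2L]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  out <- NULL
  for (k in seq_len(n_atoms)) {
    nbs <- nb[[k]]
    if (length(nbs) >= 2L) {
      cmb <- utils::combn(sort(nbs), 2L)
      out <- rbind(out, t(cmb))
    }
  }
  if (is.null(out)) return(matrix(integer(), 0L, 2L))
  out <- cbind(pmin(out[, 1L], out[, 2L]), pmax(out[, 1L], out[, 2L]))
  # drop 1-3 pairs that are also bonds (rings)
  bkey <- paste(bonds[, 1L], bonds[, 2L])
  out <- out[!paste(out[, 1L], out[, 2L]) %in% bkey, , drop = FALSE]
  out[!duplicated(paste(out[, 1L], out[, 2L])), , drop = FALSE]
}
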