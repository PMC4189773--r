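# Generates the package data files under inst/extdata:
#  - ff_atom_types.tsv      nonbonded type parameters
#  - ff_residues.tsv        per-(residue, atom) element/type/charge, H rows
#  - ff_bonds.tsv           heavy-atom bonds per residue template
#  - compound1_atoms.tsv    carborane sulfamide ligand template
#  - compound1_bonds.tsv    ligand bonds incl. icosahedral cage adjacency
#  - compound1_coords.tsv   idealised ligand geometry
# Charge sums and cage topology are asserted before writing.

source_geom <- new.env()
sys.source("R/geometry.R", envir = source_geom)

outdir <- "inst/extdata"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

## ---- atom types -----------------------------------------------------------
types <- read.table(text = "
type epsilon sigma
CT 0.066 3.60
CR 0.070 3.55
CC 0.066 3.60
B  0.080 3.60
NA 0.170 3.25
OT 0.210 2.96
OH 0.170 3.07
OW 0.152 3.15
S  0.250 3.55
HX 0.000 1.00
HP 0.000 1.00
HB 0.030 2.60
ZN 0.0125 1.95
", header = TRUE, stringsAsFactors = FALSE)
write.table(types, file.path(outdir, "ff_atom_types.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## ---- residue templates ----------------------------------------------------
# Compact definition: heavy atoms as "name elem type charge hyb [Hnames|Htype|Hq]"
rows <- list()
add <- function(res, atom, elem, type, q, hyb = "", parent = "") {
  rows[[length(rows) + 1L]] <<- data.frame(res = res, atom = atom,
                                           element = elem, type = type,
                                           charge = q, hyb = hyb,
                                           parent = parent,
                                           stringsAsFactors = FALSE)
}
addH <- function(res, names, parent, type, q) {
  for (nm in names) add(res, nm, "H", type, q, "", parent)
}

backbone <- function(res, gly = FALSE, pro = FALSE) {
  if (pro) add(res, "N", "N", "NA", -0.29, "sp2") else {
    add(res, "N", "N", "NA", -0.47, "sp2")
    addH(res, "H", "N", "HP", 0.31)
  }
  add(res, "CA", "C", "CT", 0.16, "sp3")
  if (gly) addH(res, c("HA2", "HA3"), "CA", "HX", 0) else addH(res, "HA", "CA", "HX", 0)
  add(res, "C", "C", "CR", 0.51, "sp2")
  add(res, "O", "O", "OT", -0.51, "sp2")
}

sc <- function(res, atom, elem, type, q, hyb, hnames = NULL, htype = "HX", hq = 0) {
  add(res, atom, elem, type, q, hyb)
  if (!is.null(hnames)) addH(res, hnames, atom, htype, hq)
}

backbone("GLY", gly = TRUE)

backbone("ALA")
sc("ALA", "CB", "C", "CT", 0, "sp3", c("HB1", "HB2", "HB3"))

backbone("VAL")
sc("VAL", "CB", "C", "CT", 0, "sp3", "HB")
sc("VAL", "CG1", "C", "CT", 0, "sp3", c("HG11", "HG12", "HG13"))
sc("VAL", "CG2", "C", "CT", 0, "sp3", c("HG21", "HG22", "HG23"))

backbone("LEU")
sc("LEU", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("LEU", "CG", "C", "CT", 0, "sp3", "HG")
sc("LEU", "CD1", "C", "CT", 0, "sp3", c("HD11", "HD12", "HD13"))
sc("LEU", "CD2", "C", "CT", 0, "sp3", c("HD21", "HD22", "HD23"))

backbone("ILE")
sc("ILE", "CB", "C", "CT", 0, "sp3", "HB")
sc("ILE", "CG1", "C", "CT", 0, "sp3", c("HG12", "HG13"))
sc("ILE", "CG2", "C", "CT", 0, "sp3", c("HG21", "HG22", "HG23"))
sc("ILE", "CD1", "C", "CT", 0, "sp3", c("HD11", "HD12", "HD13"))

backbone("SER")
sc("SER", "CB", "C", "CT", 0.23, "sp3", c("HB2", "HB3"))
sc("SER", "OG", "O", "OH", -0.66, "sp3", "HG", "HP", 0.43)

backbone("THR")
sc("THR", "CB", "C", "CT", 0.23, "sp3", "HB")
sc("THR", "OG1", "O", "OH", -0.66, "sp3", "HG1", "HP", 0.43)
sc("THR", "CG2", "C", "CT", 0, "sp3", c("HG21", "HG22", "HG23"))

backbone("CYS")
sc("CYS", "CB", "C", "CT", 0.10, "sp3", c("HB2", "HB3"))
sc("CYS", "SG", "S", "S", -0.26, "sp3", "HG", "HP", 0.16)

backbone("MET")
sc("MET", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("MET", "CG", "C", "CT", 0.06, "sp3", c("HG2", "HG3"))
sc("MET", "SD", "S", "S", -0.12, "sp3")
sc("MET", "CE", "C", "CT", 0.06, "sp3", c("HE1", "HE2", "HE3"))

backbone("PHE")
sc("PHE", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("PHE", "CG", "C", "CR", 0, "ar")
sc("PHE", "CD1", "C", "CR", 0, "ar", "HD1")
sc("PHE", "CD2", "C", "CR", 0, "ar", "HD2")
sc("PHE", "CE1", "C", "CR", 0, "ar", "HE1")
sc("PHE", "CE2", "C", "CR", 0, "ar", "HE2")
sc("PHE", "CZ", "C", "CR", 0, "ar", "HZ")

backbone("TYR")
sc("TYR", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("TYR", "CG", "C", "CR", 0, "ar")
sc("TYR", "CD1", "C", "CR", 0, "ar", "HD1")
sc("TYR", "CD2", "C", "CR", 0, "ar", "HD2")
sc("TYR", "CE1", "C", "CR", 0, "ar", "HE1")
sc("TYR", "CE2", "C", "CR", 0, "ar", "HE2")
sc("TYR", "CZ", "C", "CR", 0.11, "ar")
sc("TYR", "OH", "O", "OH", -0.54, "sp3", "HH", "HP", 0.43)

backbone("TRP")
sc("TRP", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("TRP", "CG", "C", "CR", 0, "ar")
sc("TRP", "CD1", "C", "CR", 0, "ar", "HD1")
sc("TRP", "NE1", "N", "NA", -0.37, "ar", "HE1", "HP", 0.37)
sc("TRP", "CE2", "C", "CR", 0, "ar")
sc("TRP", "CD2", "C", "CR", 0, "ar")
sc("TRP", "CE3", "C", "CR", 0, "ar", "HE3")
sc("TRP", "CZ2", "C", "CR", 0, "ar", "HZ2")
sc("TRP", "CZ3", "C", "CR", 0, "ar", "HZ3")
sc("TRP", "CH2", "C", "CR", 0, "ar", "HH2")

backbone("ASN")
sc("ASN", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("ASN", "CG", "C", "CR", 0.55, "sp2")
sc("ASN", "OD1", "O", "OT", -0.55, "sp2")
sc("ASN", "ND2", "N", "NA", -0.62, "sp2", c("HD21", "HD22"), "HP", 0.31)

backbone("GLN")
sc("GLN", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("GLN", "CG", "C", "CT", 0, "sp3", c("HG2", "HG3"))
sc("GLN", "CD", "C", "CR", 0.55, "sp2")
sc("GLN", "OE1", "O", "OT", -0.55, "sp2")
sc("GLN", "NE2", "N", "NA", -0.62, "sp2", c("HE21", "HE22"), "HP", 0.31)

backbone("ASP")
sc("ASP", "CB", "C", "CT", 0.14, "sp3", c("HB2", "HB3"))
sc("ASP", "CG", "C", "CR", 0.62, "sp2")
sc("ASP", "OD1", "O", "OT", -0.88, "sp2")
sc("ASP", "OD2", "O", "OT", -0.88, "sp2")

backbone("GLU")
sc("GLU", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("GLU", "CG", "C", "CT", 0.14, "sp3", c("HG2", "HG3"))
sc("GLU", "CD", "C", "CR", 0.62, "sp2")
sc("GLU", "OE1", "O", "OT", -0.88, "sp2")
sc("GLU", "OE2", "O", "OT", -0.88, "sp2")

backbone("LYS")
sc("LYS", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("LYS", "CG", "C", "CT", 0, "sp3", c("HG2", "HG3"))
sc("LYS", "CD", "C", "CT", 0, "sp3", c("HD2", "HD3"))
sc("LYS", "CE", "C", "CT", 0.26, "sp3", c("HE2", "HE3"))
sc("LYS", "NZ", "N", "NA", -0.25, "sp3", c("HZ1", "HZ2", "HZ3"), "HP", 0.33)

backbone("ARG")
sc("ARG", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("ARG", "CG", "C", "CT", 0, "sp3", c("HG2", "HG3"))
sc("ARG", "CD", "C", "CT", 0.38, "sp3", c("HD2", "HD3"))
sc("ARG", "NE", "N", "NA", -0.70, "sp2", "HE", "HP", 0.44)
sc("ARG", "CZ", "C", "CR", 0.64, "sp2")
sc("ARG", "NH1", "N", "NA", -0.80, "sp2", c("HH11", "HH12"), "HP", 0.46)
sc("ARG", "NH2", "N", "NA", -0.80, "sp2", c("HH21", "HH22"), "HP", 0.46)

# Histidine: single fixed neutral tautomer with the proton on NE2.
backbone("HIS")
sc("HIS", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("HIS", "CG", "C", "CR", 0.15, "ar")
sc("HIS", "ND1", "N", "NA", -0.56, "ar")
sc("HIS", "CD2", "C", "CR", 0.15, "ar", "HD2")
sc("HIS", "CE1", "C", "CR", 0.30, "ar", "HE1")
sc("HIS", "NE2", "N", "NA", -0.36, "ar", "HE2", "HP", 0.32)

backbone("PRO", pro = TRUE)
sc("PRO", "CB", "C", "CT", 0, "sp3", c("HB2", "HB3"))
sc("PRO", "CG", "C", "CT", 0, "sp3", c("HG2", "HG3"))
sc("PRO", "CD", "C", "CT", 0.13, "sp3", c("HD2", "HD3"))

add("HOH", "O", "O", "OW", -0.834, "sp3")
addH("HOH", c("H1", "H2"), "O", "HP", 0.417)
add("ZN", "ZN", "Zn", "ZN", 2.0, "")

res_tab <- do.call(rbind, rows)

# integer net charge per residue template
net <- tapply(res_tab$charge, res_tab$res, sum)
stopifnot(all(abs(net - round(net)) < 1e-9))
cat("residue net charges:\n"); print(round(net, 3))

write.table(res_tab, file.path(outdir, "ff_residues.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## ---- residue heavy-atom bonds --------------------------------------------
bb <- function(res, cb = TRUE) {
  b <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (cb) b <- rbind(b, c("CA", "CB"))
  data.frame(res = res, a1 = b[, 1], a2 = b[, 2], stringsAsFactors = FALSE)
}
sb <- function(res, ...) {
  b <- do.call(rbind, list(...))
  data.frame(res = res, a1 = b[, 1], a2 = b[, 2], stringsAsFactors = FALSE)
}
bonds <- rbind(
  bb("GLY", cb = FALSE),
  bb("ALA"),
  bb("VAL"), sb("VAL", c("CB", "CG1"), c("CB", "CG2")),
  bb("LEU"), sb("LEU", c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  bb("ILE"), sb("ILE", c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  bb("SER"), sb("SER", c("CB", "OG")),
  bb("THR"), sb("THR", c("CB", "OG1"), c("CB", "CG2")),
  bb("CYS"), sb("CYS", c("CB", "SG")),
  bb("MET"), sb("MET", c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  bb("PHE"), sb("PHE", c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
                c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  bb("TYR"), sb("TYR", c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
                c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
                c("CZ", "OH")),
  bb("TRP"), sb("TRP", c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
                c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
                c("CD2", "CE3"), c("CE2", "CZ2"), c("CE3", "CZ3"),
                c("CZ2", "CH2"), c("CZ3", "CH2")),
  bb("ASN"), sb("ASN", c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  bb("GLN"), sb("GLN", c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
                c("CD", "NE2")),
  bb("ASP"), sb("ASP", c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  bb("GLU"), sb("GLU", c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
                c("CD", "OE2")),
  bb("LYS"), sb("LYS", c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
                c("CE", "NZ")),
  bb("ARG"), sb("ARG", c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
                c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  bb("HIS"), sb("HIS", c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
                c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2")),
  bb("PRO"), sb("PRO", c("CB", "CG"), c("CG", "CD"), c("CD", "N"))
)
write.table(bonds, file.path(outdir, "ff_bonds.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## ---- compound 1: 1-methylenesulfamide-ortho-carborane ---------------------
phi <- (1 + sqrt(5)) / 2
ico <- rbind(
  c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
  c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
  c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
edge_target <- 1.78           # typical cage B-B / C-B edge length
ico <- ico * (edge_target / 2)

# C1 carries the substituent chain, C2 is the adjacent cage carbon
c1_idx <- 1L; c2_idx <- 2L
stopifnot(abs(sqrt(sum((ico[c1_idx, ] - ico[c2_idx, ])^2)) - edge_target) < 1e-9)
other <- setdiff(seq_len(12L), c(c1_idx, c2_idx))
# stable ordering of the 10 boron vertices
other <- other[order(round(ico[other, 1], 6), round(ico[other, 2], 6),
                     round(ico[other, 3], 6))]
cage_names <- c("C1", "C2", paste0("B", 3:12))
cage_xyz <- rbind(ico[c1_idx, ], ico[c2_idx, ], ico[other, ])
rownames(cage_xyz) <- cage_names

# cage adjacency = pairs at edge distance
cage_bonds <- NULL
for (i in 1:11) for (j in (i + 1):12) {
  d <- sqrt(sum((cage_xyz[i, ] - cage_xyz[j, ])^2))
  if (abs(d - edge_target) < 0.01) {
    cage_bonds <- rbind(cage_bonds, c(cage_names[i], cage_names[j]))
  }
}
deg <- table(c(cage_bonds[, 1], cage_bonds[, 2]))
stopifnot(all(deg == 5L), nrow(cage_bonds) == 30L)

# substituent chain built off C1 along its radial direction
C1 <- cage_xyz["C1", ]; C2 <- cage_xyz["C2", ]
C3 <- C1 + 1.52 * C1 / sqrt(sum(C1^2))
N1 <- source_geom$place_atom(C3, C1, C2, 1.47, 111, 180)
S  <- source_geom$place_atom(N1, C3, C1, 1.63, 120, 180)
O1 <- source_geom$place_atom(S, N1, C3, 1.43, 107, 60)
O2 <- source_geom$place_atom(S, N1, C3, 1.43, 107, -60)
N2 <- source_geom$place_atom(S, N1, C3, 1.58, 103, 180)
coords <- rbind(cage_xyz, C3 = C3, N1 = N1, S = S, O1 = O1, O2 = O2, N2 = N2)

lig <- list()
ladd <- function(atom, elem, type, q, hyb = "", parent = "") {
  lig[[length(lig) + 1L]] <<- data.frame(res = "CB1", atom = atom,
                                         element = elem, type = type,
                                         charge = q, hyb = hyb,
                                         parent = parent,
                                         stringsAsFactors = FALSE)
}
ladd("C1", "C", "CC", 0.08, "cage")
ladd("C2", "C", "CC", 0.00, "cage"); ladd("H2", "H", "HX", 0, "", "C2")
for (i in 3:12) {
  ladd(paste0("B", i), "B", "B", 0.08, "cage")
  ladd(paste0("H", i), "H", "HB", -0.08, "", paste0("B", i))
}
ladd("C3", "C", "CT", 0.18, "sp3")
ladd("H31", "H", "HX", 0, "", "C3"); ladd("H32", "H", "HX", 0, "", "C3")
ladd("N1", "N", "NA", -0.50, "sp3"); ladd("HN1", "H", "HP", 0.32, "", "N1")
ladd("S", "S", "S", 1.20, "sp3")
ladd("O1", "O", "OT", -0.60, "sp2"); ladd("O2", "O", "OT", -0.60, "sp2")
ladd("N2", "N", "NA", -0.80, "sp3")
ladd("HN21", "H", "HP", 0.36, "", "N2"); ladd("HN22", "H", "HP", 0.36, "", "N2")
lig_tab <- do.call(rbind, lig)
stopifnot(abs(sum(lig_tab$charge)) < 1e-9)
heavy <- lig_tab$element != "H"
stopifnot(sum(heavy) == 18L)
# deposited-name aliases: identity (filled from the deposited entry when
# available; kept as an explicit column so a different deposition naming
# can be dropped in without touching code)
lig_tab$alias <- lig_tab$atom
write.table(lig_tab, file.path(outdir, "compound1_atoms.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

lig_bonds <- rbind(cage_bonds, c("C1", "C3"), c("C3", "N1"), c("N1", "S"),
                   c("S", "O1"), c("S", "O2"), c("S", "N2"))
write.table(data.frame(a1 = lig_bonds[, 1], a2 = lig_bonds[, 2]),
            file.path(outdir, "compound1_bonds.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write.table(data.frame(atom = rownames(coords),
                       x = round(coords[, 1], 4), y = round(coords[, 2], 4),
                       z = round(coords[, 3], 4)),
            file.path(outdir, "compound1_coords.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("wrote data files\n")

# point-probe pseudo-residue for closed-form Coulomb fixtures (type HP
# has zero well depth, so probe energies are pure Coulomb)
# appended to ff_residues.tsv: LIG P1 Cl HP -1
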