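#' Read a macromolecular structure
#'
#' Reads PDB (fixed-column) or mmCIF coordinate files into a
#' [new_structure()] container. All atom records with coordinates are
#' retained, including alternate locations; ligands, metals and waters
#' are recognised downstream by residue name / element. The `adp` column
#' carries the isotropic-equivalent displacement parameter as deposited
#' in the ATOM records (`B_iso_or_equiv` for mmCIF).
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"`, or `"auto"` (by file extension).
#' @return A `carb_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb",
                     cif = "cif", mmcif = "cif",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format = \"pdb\" or \"cif\""))
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atom records in ", path)
  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  element <- ifelse(is.na(element) | element == "",
                    guess_element(at$elety), element)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom = at$elety,
    element = normalize_element(element),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    adp = ifelse(is.na(at$b), 0, at$b),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  new_structure(atoms, source_id = basename(path))
}

# Fallback element inference from an atom label (PDB naming: leading
# digits are greek-position prefixes, e.g. "1HB").
guess_element <- function(name) {
  nm <- gsub("[0-9']", "", toupper(name))
  two <- substr(nm, 1L, 2L)
  el <- ifelse(two %in% c("ZN", "FE", "MG", "MN", "CU", "NI", "CO", "SE",
                          "CL", "BR", "HG", "CD", "NA"),
               two, substr(nm, 1L, 1L))
  el[el == ""] <- "X"
  el
}

normalize_element <- function(el) {
  el <- as.character(el)
  n <- nchar(el)
  paste0(toupper(substr(el, 1L, 1L)),
         ifelse(n > 1L, tolower(substr(el, 2L, n)), ""))
}

#' Write a structure to disk
#'
#' Emits fixed-column PDB (through bio3d) or a minimal mmCIF
#' `atom_site` loop. Output round-trips through [read_structure()]
#' preserving atoms, names, numbering, occupancies and displacement
#' parameters (coordinates to 3 decimals).
#'
#' @param s a `carb_structure`.
#' @param path output file path.
#' @param format `"pdb"` or `"cif"` (default from extension).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  a <- s$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  if (format == "pdb") {
    ok <- tryCatch({
      bio3d::write.pdb(
        pdb = NULL, file = path,
        xyz = as.vector(t(coords_matrix(a))),
        type = ifelse(a$het, "HETATM", "ATOM"),
        resno = a$resno, resid = a$resname,
        eleno = seq_len(nrow(a)), elety = a$atom,
        chain = ifelse(a$chain == "", " ", a$chain),
        insert = ifelse(a$ins == "", "", a$ins),
        alt = ifelse(a$altloc == "", "", a$altloc),
        o = a$occ, b = a$adp, elesy = toupper(a$element))
      TRUE
    }, error = function(e) {
      stop("failed to write PDB '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  } else {
    write_cif_atoms(a, path)
  }
  invisible(path)
}

# Minimal mmCIF writer: a single atom_site loop with the auth_* items
# bio3d's reader consumes. bio3d has no mmCIF writer, so this one is
# hand-rolled and kept deliberately small.
write_cif_atoms <- function(a, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(c("data_carbscan",
               "#",
               "loop_",
               "_atom_site.group_PDB",
               "_atom_site.id",
               "_atom_site.type_symbol",
               "_atom_site.label_atom_id",
               "_atom_site.label_alt_id",
               "_atom_site.label_comp_id",
               "_atom_site.label_asym_id",
               "_atom_site.label_entity_id",
               "_atom_site.label_seq_id",
               "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x",
               "_atom_site.Cartn_y",
               "_atom_site.Cartn_z",
               "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id",
               "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id",
               "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  q <- function(x, blank = ".") ifelse(x == "" | is.na(x), blank, x)
  lines <- sprintf(
    "%-6s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)),
    toupper(a$element), q(a$atom), q(a$altloc), q(a$resname),
    q(a$chain, "A"), a$resno, q(a$ins, "?"),
    a$x, a$y, a$z, a$occ, a$adp,
    a$resno, q(a$resname), q(a$chain, "A"), q(a$atom))
  writeLines(lines, con)
  writeLines("#", con)
}
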