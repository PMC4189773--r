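#' Contact analysis and glycine scan of a solved complex
#'
#' End-to-end analysis of one protein-ligand complex: contact
#' enumeration and classification, dihydrogen-bond detection (after
#' hydrogen placement), and a rigid-mode virtual glycine scan over the
#' contacting residues. Tables are written as TSV (plus a JSON run
#' manifest) when `out_dir` is given.
#'
#' @param structure a `carb_structure` or a coordinate file path.
#' @param ligand_resname ligand residue name (default `"CB1"`).
#' @param cutoff contact cutoff, Angstrom.
#' @param scan_residues list of [residue_id()]s to scan; `NULL` scans
#'   every amino acid with a contact at the cutoff.
#' @param ff a [load_forcefield()] object.
#' @param out_dir optional output directory.
#' @return List: `contacts`, `dihydrogen_bonds`, `scan`, `structure`
#'   (protonated, parameterised), `files` (written paths).
#' @export
run_caii_analysis <- function(structure, ligand_resname = "CB1",
                              cutoff = 4.0, scan_residues = NULL,
                              ff = load_forcefield(), out_dir = NULL) {
  s <- if (is.character(structure)) read_structure(structure) else structure
  lig_sel <- atom_selection(resname = ligand_resname)
  contacts <- classify_contacts(
    enumerate_contacts(s, lig_sel, cutoff = cutoff))
  sp <- suppressWarnings(add_hydrogens(s))
  dhb <- tryCatch(detect_dihydrogen_bonds(sp, lig_sel),
                  error = function(e) NULL)
  spp <- assign_parameters(sp, ff)
  if (is.null(scan_residues)) {
    ct_res <- unique(contacts[contacts$resname %in% AMINO_ACIDS,
                              c("chain", "resno", "ins")])
    scan_residues <- lapply(seq_len(nrow(ct_res)), function(i)
      residue_id(ct_res$chain[i], ct_res$resno[i], ct_res$ins[i]))
  }
  scan <- if (length(scan_residues) > 0L) {
    suppressMessages(glycine_scan(spp, scan_residues, lig_sel, ff))
  } else NULL
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "contacts.tsv")
    write_contact_table(contacts, f1)
    files <- f1
    if (!is.null(scan)) {
      f2 <- file.path(out_dir, "glycine_scan.tsv")
      write.table(as.data.frame(scan), f2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, f2)
    }
    if (!is.null(dhb) && nrow(dhb) > 0L) {
      f3 <- file.path(out_dir, "dihydrogen_bonds.tsv")
      write.table(dhb, f3, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f3)
    }
    manifest <- list(source = s$source_id, ligand = ligand_resname,
                     cutoff = cutoff,
                     n_contacts = nrow(contacts),
                     polar_rows = sum(contacts$contact_class %in%
                                        c("polar", "metal_coordination")),
                     energy_model = paste0("coulomb-lj/", ff$dielectric,
                                           "-dielectric"))
    fm <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, fm, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, fm)
  }
  list(contacts = contacts, dihydrogen_bonds = dhb, scan = scan,
       structure = spp, files = files)
}

#' Model and analyse a ligand complex of a homologous protein
#'
#' The full template-based modeling workflow: graft the ligand (plus
#' bridging water) from a solved template complex into the homolog,
#' protonate and parameterise, relax the movable residues and ligand
#' with FIRE, then report the model's contact table, the binding-site
#' substitution list, glycine scans of both complexes side by side, and
#' the ligand displacement between the grafted and relaxed poses
#' (overall and at the cage atom B12).
#'
#' @param template `carb_structure`: solved complex (protein + ligand +
#'   metal + waters).
#' @param target `carb_structure`: apo homolog receiving the ligand.
#' @param fit_sel superposition selection (default all shared C-alpha).
#' @param ligand_resname ligand residue name.
#' @param keep_waters template water residue numbers to transfer.
#' @param movable_residues list of [residue_id()]s relaxed with the
#'   ligand; `NULL` relaxes every residue with a contact at 4 Angstrom.
#' @param site_sel selection defining the compared binding site
#'   (default: the movable residues).
#' @param ff force field; `settings` FIRE settings.
#' @param relax logical; skip relaxation if `FALSE`.
#' @param out_dir optional output directory for TSV reports.
#' @return List: `model` (relaxed complex), `grafted` (pre-relaxation),
#'   `contacts`, `substitutions`, `scan_template`, `scan_model`,
#'   `scan_table` (side-by-side ddG), `displacement` (list: `b12`,
#'   `ligand_rmsd`), `anchor` (metal-N2 distance before/after), `files`.
#' @export
run_caix_pipeline <- function(template, target,
                              fit_sel = atom_selection(atom = "CA"),
                              ligand_resname = "CB1",
                              keep_waters = integer(),
                              movable_residues = NULL, site_sel = NULL,
                              ff = load_forcefield(),
                              settings = minimizer_settings(max_iter = 800L),
                              relax = TRUE, out_dir = NULL) {
  lig_sel <- atom_selection(resname = ligand_resname)
  grafted <- suppressWarnings(
    graft_ligand(template, target, fit_sel, ligand_resname,
                 keep_waters = keep_waters))
  gp <- assign_parameters(suppressWarnings(add_hydrogens(grafted)), ff)
  if (is.null(movable_residues)) {
    ct <- enumerate_contacts(gp, lig_sel)
    ct_res <- unique(ct[ct$resname %in% AMINO_ACIDS,
                        c("chain", "resno", "ins")])
    movable_residues <- lapply(seq_len(nrow(ct_res)), function(i)
      residue_id(ct_res$chain[i], ct_res$resno[i], ct_res$ins[i]))
  }
  model <- if (relax) {
    relax_binding_site(gp, movable_residues, lig_sel, ff, settings)
  } else gp
  # displacement of the grafted ligand during relaxation
  lig0 <- select_atoms(gp, lig_sel)
  lig1 <- select_atoms(model, lig_sel)
  stopifnot(identical(lig0$atom, lig1$atom))
  disp <- sqrt(rowSums((coords_matrix(lig1) - coords_matrix(lig0))^2))
  b12 <- if ("B12" %in% lig0$atom) disp[match("B12", lig0$atom)] else NA_real_
  anchor <- metal_anchor_distance(model, ligand_resname)
  anchor0 <- metal_anchor_distance(gp, ligand_resname)
  contacts <- classify_contacts(enumerate_contacts(model, lig_sel))
  if (is.null(site_sel)) {
    # binding-site shell: every template residue with a heavy atom
    # within 7.5 A of the ligand
    tl <- select_atoms(template, lig_sel)
    ta <- template$atoms[toupper(template$atoms$element) != "H", ]
    lm <- coords_matrix(tl); tm <- coords_matrix(ta)
    d2 <- outer(rowSums(tm^2), rowSums(lm^2), "+") - 2 * tm %*% t(lm)
    near <- apply(d2, 1L, min) <= 7.5^2
    site_sel <- atom_selection(
      resno = unique(ta$resno[near & ta$resname %in% AMINO_ACIDS]))
  }
  template_p <- assign_parameters(suppressWarnings(add_hydrogens(template)),
                                  ff)
  subs <- binding_site_substitutions(template_p, target, site_sel, fit_sel)
  scan_res_t <- amino_residue_ids(template_p, site_sel)
  scan_res_m <- amino_residue_ids(model, site_sel)
  scan_template <- suppressMessages(
    glycine_scan(template_p, scan_res_t, lig_sel, ff))
  scan_model <- suppressMessages(
    glycine_scan(model, scan_res_m, lig_sel, ff))
  scan_table <- merge(
    as.data.frame(scan_template)[, c("resno", "resname", "ddg")],
    as.data.frame(scan_model)[, c("resno", "resname", "ddg")],
    by = "resno", all = TRUE, suffixes = c("_template", "_model"))
  top_model <- scan_table[order(-scan_table$ddg_model), , drop = FALSE]
  message("largest model-side scan contributors: ",
          paste(head(sprintf("%s%d (%.2f)", top_model$resname_model,
                             top_model$resno, top_model$ddg_model), 3L),
                collapse = ", "))
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "model_contacts.tsv")
    write_contact_table(contacts, f1)
    f2 <- file.path(out_dir, "substitutions.tsv")
    write.table(subs, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    f3 <- file.path(out_dir, "glycine_scan_side_by_side.tsv")
    write.table(scan_table, f3, sep = "\t", quote = FALSE,
                row.names = FALSE)
    f4 <- file.path(out_dir, "model.pdb")
    write_structure(strip_parameters(model), f4)
    files <- c(f1, f2, f3, f4)
  }
  list(model = model, grafted = gp, contacts = contacts,
       substitutions = subs, scan_template = scan_template,
       scan_model = scan_model, scan_table = scan_table,
       displacement = list(b12 = b12, ligand_rmsd = rmsd(
         coords_matrix(lig1), coords_matrix(lig0))),
       anchor = list(before = anchor0, after = anchor),
       files = files)
}

metal_anchor_distance <- function(s, ligand_resname, anchor_atom = "N2") {
  a <- s$atoms
  zn <- a[is_metal_row(a), , drop = FALSE]
  n2 <- a[a$resname == ligand_resname & a$atom == anchor_atom, ,
          drop = FALSE]
  if (nrow(zn) == 0L || nrow(n2) == 0L) return(NA_real_)
  min(sqrt((zn$x - n2$x[1L])^2 + (zn$y - n2$y[1L])^2 +
             (zn$z - n2$z[1L])^2))
}

amino_residue_ids <- function(s, sel) {
  rt <- residue_table(select_atoms(s, sel))
  rt <- rt[rt$resname %in% AMINO_ACIDS, , drop = FALSE]
  lapply(seq_len(nrow(rt)), function(i)
    residue_id(rt$chain[i], rt$resno[i], rt$ins[i]))
}

strip_parameters <- function(s) {
  s$atoms <- s$atoms[, c("chain", "resno", "ins", "resname", "atom",
                         "element", "altloc", "x", "y", "z", "occ",
                         "adp", "het")]
  s
}
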