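#' Enumerate protein-ligand contacts
#'
#' Lists every (protein-or-metal heavy atom, ligand heavy atom) pair
#' with Euclidean distance at or below the cutoff. Hydrogens are
#' excluded; waters are excluded by default. Rows are sorted with metal
#' ions first, then by residue number and distance. Distances are
#' reported to 2 decimals (column `distance`), with the unrounded value
#' kept in `distance_exact`.
#'
#' @param s a `carb_structure`.
#' @param ligand_sel an [atom_selection()] picking the ligand atoms
#'   (e.g. `atom_selection(resname = "CB1")`).
#' @param cutoff contact distance cutoff in Angstrom (inclusive).
#' @param exclude_waters drop water residues from the protein side.
#' @return A `carb_contacts` data frame: chain, resno, ins, resname,
#'   protein_atom, protein_element, ligand_atom, ligand_element,
#'   distance, distance_exact, is_metal, contact_class (`NA` until
#'   [classify_contacts()]).
#' @export
enumerate_contacts <- function(s, ligand_sel, cutoff = 4.0,
                               exclude_waters = TRUE) {
  lig <- select_atoms(s, ligand_sel)
  lig <- lig[toupper(lig$element) != "H", , drop = FALSE]
  if (nrow(lig) == 0L) stop("ligand selection matches no heavy atoms")
  env <- select_atoms(s)                    # best-altloc positions
  lkey <- paste(residue_key(lig), lig$atom, sep = "|")
  ekey <- paste(residue_key(env), env$atom, sep = "|")
  env <- env[!(ekey %in% lkey), , drop = FALSE]
  env <- env[toupper(env$element) != "H", , drop = FALSE]
  if (exclude_waters) env <- env[!is_water_row(env), , drop = FALSE]
  if (nrow(env) == 0L) stop("no environment atoms to test against")
  em <- coords_matrix(env)
  lm <- coords_matrix(lig)
  d2 <- outer(rowSums(em^2), rowSums(lm^2), "+") - 2 * em %*% t(lm)
  d2[d2 < 0] <- 0
  hits <- which(sqrt(d2) <= cutoff + 1e-9, arr.ind = TRUE)
  metal <- is_metal_row(env)
  out <- data.frame(
    chain = env$chain[hits[, 1L]],
    resno = env$resno[hits[, 1L]],
    ins = env$ins[hits[, 1L]],
    resname = env$resname[hits[, 1L]],
    protein_atom = env$atom[hits[, 1L]],
    protein_element = env$element[hits[, 1L]],
    ligand_atom = lig$atom[hits[, 2L]],
    ligand_element = lig$element[hits[, 2L]],
    distance_exact = sqrt(d2[hits]),
    is_metal = metal[hits[, 1L]],
    stringsAsFactors = FALSE)
  out$distance <- round(out$distance_exact, 2L)
  out$contact_class <- rep(NA_character_, nrow(out))
  out <- out[order(!out$is_metal, out$chain, out$resno, out$ins,
                   out$distance_exact), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("carb_contacts", "data.frame")
  out
}

#' Classify contacts
#'
#' Pure function of element pair, distance and metal flag:
#' `metal_coordination` if the protein-side atom is a metal ion within
#' the coordination cutoff; `polar` if both atoms are N/O/S within the
#' polar cutoff; `vdw` otherwise. Cutoffs follow the distance pattern of
#' crystallographic contact tables for this system: 2.5 Angstrom keeps
#' the zinc-sulfamide coordination bond and rejects longer zinc
#' approaches; 3.1 Angstrom separates hydrogen-bond-range N/O/S pairs
#' from van der Waals ones.
#'
#' @param contacts a `carb_contacts` table from [enumerate_contacts()]
#'   (or any data frame with `protein_element`, `ligand_element`,
#'   `distance`, `is_metal`).
#' @param polar_cutoff heavy-atom polar cutoff, Angstrom.
#' @param metal_cutoff metal-coordination cutoff, Angstrom.
#' @return The table with `contact_class` filled.
#' @export
classify_contacts <- function(contacts, polar_cutoff = 3.1,
                              metal_cutoff = 2.5) {
  polar_el <- c("N", "O", "S")
  pe <- toupper(contacts$protein_element)
  le <- toupper(contacts$ligand_element)
  d <- contacts$distance
  cls <- rep("vdw", nrow(contacts))
  cls[pe %in% polar_el & le %in% polar_el & d <= polar_cutoff + 1e-9] <- "polar"
  cls[contacts$is_metal & d <= metal_cutoff + 1e-9] <- "metal_coordination"
  contacts$contact_class <- cls
  contacts
}

#' Detect dihydrogen bonds
#'
#' A dihydrogen bond pairs a protic hydrogen (bound to N, O, S, or an
#' aromatic carbon) with a hydridic hydrogen on boron. Criteria: H...H
#' distance at or below `hh_cutoff` and both X-H...H angles at or above
#' `min_angle`. Hydrogens must be present (see [add_hydrogens()]); each
#' hydrogen is bonded to its nearest heavy atom within 1.6 Angstrom.
#'
#' @param s a `carb_structure` with hydrogens.
#' @param ligand_sel selection of the ligand residue (the boron side).
#' @param hh_cutoff H...H distance cutoff, Angstrom.
#' @param min_angle minimum donor and acceptor angle, degrees.
#' @return Data frame sorted by distance: protic residue/atom, hydridic
#'   atom, `hh_distance`, `donor_angle`, `acceptor_angle`.
#' @export
detect_dihydrogen_bonds <- function(s, ligand_sel, hh_cutoff = 2.4,
                                    min_angle = 90) {
  a <- select_atoms(s)
  lig <- select_atoms(s, ligand_sel)
  lkey <- paste(residue_key(lig), lig$atom, sep = "|")
  akey <- paste(residue_key(a), a$atom, sep = "|")
  in_lig <- akey %in% lkey
  hyd <- toupper(a$element) == "H"
  if (!any(hyd & in_lig)) {
    stop("no hydrogens on the ligand: run add_hydrogens() first")
  }
  if (!any(hyd & !in_lig)) {
    stop("no hydrogens on the environment: run add_hydrogens() first")
  }
  xyz <- coords_matrix(a)
  heavy_idx <- which(!hyd)
  h_idx <- which(hyd)
  # bond each H to its nearest heavy atom in the same residue
  parent <- integer(length(h_idx))
  for (k in seq_along(h_idx)) {
    i <- h_idx[k]
    same <- heavy_idx[residue_key(a)[heavy_idx] == residue_key(a)[i]]
    d <- sqrt(colSums((t(xyz[same, , drop = FALSE]) - xyz[i, ])^2))
    j <- same[which.min(d)]
    parent[k] <- if (min(d) <= 1.6) j else NA_integer_
  }
  ok <- !is.na(parent)
  h_idx <- h_idx[ok]; parent <- parent[ok]
  pel <- toupper(a$element[parent])
  aromatic_parent <- is_aromatic_atom(a$resname[parent], a$atom[parent])
  protic <- (pel %in% c("N", "O", "S") | (pel == "C" & aromatic_parent)) &
    !in_lig[h_idx]
  hydridic <- pel == "B" & in_lig[h_idx]
  if (!any(hydridic)) {
    stop("ligand has no B-H hydrogens: run add_hydrogens() first")
  }
  res <- NULL
  for (i in which(protic)) {
    for (j in which(hydridic)) {
      hp <- h_idx[i]; hb <- h_idx[j]
      dd <- sqrt(sum((xyz[hp, ] - xyz[hb, ])^2))
      if (dd > hh_cutoff + 1e-9) next
      ang_d <- angle3(xyz[parent[i], ], xyz[hp, ], xyz[hb, ])
      ang_a <- angle3(xyz[parent[j], ], xyz[hb, ], xyz[hp, ])
      if (ang_d < min_angle || ang_a < min_angle) next
      res <- rbind(res, data.frame(
        chain = a$chain[hp], resno = a$resno[hp], ins = a$ins[hp],
        resname = a$resname[hp],
        donor_atom = a$atom[parent[i]], protic_H = a$atom[hp],
        acceptor_atom = a$atom[parent[j]], hydridic_H = a$atom[hb],
        hh_distance = dd, donor_angle = ang_d, acceptor_angle = ang_a,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(res)) {
    res <- data.frame(chain = character(), resno = integer(),
                      ins = character(), resname = character(),
                      donor_atom = character(), protic_H = character(),
                      acceptor_atom = character(), hydridic_H = character(),
                      hh_distance = numeric(), donor_angle = numeric(),
                      acceptor_angle = numeric(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$hh_distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Aromaticity lookup from the residue templates (hyb == "ar").
is_aromatic_atom <- function(resname, atom) {
  tab <- residue_templates()$atoms
  key <- paste(tab$res, tab$atom, sep = "|")
  hyb <- tab$hyb[match(paste(resname, atom, sep = "|"), key)]
  !is.na(hyb) & hyb == "ar"
}

#' Compare contacting residue sets across complexes
#'
#' Builds the union of contacting residues over several complexes; each
#' cell records `""` (absent), `"x"` (contact) or `"P"` (at least one
#' polar or metal-coordination contact), mirroring the bold convention
#' of published residue-comparison tables.
#'
#' @param complexes named list; each element a list with `structure`
#'   (a `carb_structure`) and `ligand_sel` (an [atom_selection()]).
#' @param cutoff contact cutoff, Angstrom.
#' @return Data frame with residue rows and one column per complex.
#' @export
contact_residue_sets <- function(complexes, cutoff = 4.0) {
  if (length(complexes) < 1L) stop("need at least one complex")
  if (is.null(names(complexes)) || any(!nzchar(names(complexes)))) {
    stop("complexes must be a named list")
  }
  per <- lapply(complexes, function(cx) {
    ct <- classify_contacts(
      enumerate_contacts(cx$structure, cx$ligand_sel, cutoff = cutoff))
    lab <- ifelse(ct$is_metal, paste0(ct$resname),
                  paste0(ct$resname, ct$resno))
    polar <- ct$contact_class %in% c("polar", "metal_coordination")
    resno <- ifelse(ct$is_metal, 0L, ct$resno)
    data.frame(label = lab, resno = resno, polar = polar,
               stringsAsFactors = FALSE)
  })
  all_rows <- unique(do.call(rbind, lapply(per, function(p)
    p[!duplicated(p$label), c("label", "resno")])))
  all_rows <- all_rows[!duplicated(all_rows$label), , drop = FALSE]
  all_rows <- all_rows[order(all_rows$resno, all_rows$label), , drop = FALSE]
  out <- data.frame(residue = all_rows$label, stringsAsFactors = FALSE)
  for (nm in names(per)) {
    p <- per[[nm]]
    mark <- vapply(all_rows$label, function(lb) {
      sub <- p[p$label == lb, , drop = FALSE]
      if (nrow(sub) == 0L) "" else if (any(sub$polar)) "P" else "x"
    }, character(1L))
    out[[nm]] <- unname(mark)
  }
  rownames(out) <- NULL
  out
}

#' Write a classified contact table as TSV
#'
#' Columns: resno, resname, protein_atom, ligand_atom, distance (2
#' decimals), contact_class; stable row order as produced by
#' [enumerate_contacts()].
#'
#' @param contacts a classified `carb_contacts` table.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_contact_table <- function(contacts, path) {
  cols <- c("resno", "resname", "protein_atom", "ligand_atom",
            "distance", "contact_class")
  tab <- as.data.frame(contacts)[, cols, drop = FALSE]
  tab$distance <- sprintf("%.2f", tab$distance)
  ok <- tryCatch({
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write contact table to '", path,
                              "': ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a contact table written by [write_contact_table()]
#'
#' @param path TSV path.
#' @return Data frame with the written columns (`distance` numeric).
#' @export
read_contact_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$distance <- as.numeric(tab$distance)
  tab
}

#' Reported contact tables bundled with the package
#'
#' Returns the published crystal-contact table for the carbonic
#' anhydrase II complex of the carborane sulfamide ligand
#' (`which = "caii"`, 39 rows including 3 zinc rows) or the published
#' model-contact table for the isoenzyme IX complex
#' (`which = "caix_model"`). `polar` marks the rows highlighted as polar
#' interactions in the publication. These tables are inputs (printed
#' data), not outputs of this package.
#'
#' @param which `"caii"` or `"caix_model"`.
#' @return Data frame: resno (NA for zinc), resname, protein_atom,
#'   ligand_atom, distance, polar.
#' @export
reported_contacts <- function(which = c("caii", "caix_model")) {
  which <- match.arg(which)
  f <- if (which == "caii") "caii_compound1_contacts_reported.tsv"
       else "caix_compound1_model_contacts_reported.tsv"
  read.delim(carb_extdata(f), stringsAsFactors = FALSE)
}
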