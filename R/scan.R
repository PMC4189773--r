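#' Virtual glycine scan
#'
#' Quantifies each side chain's contribution to ligand binding by
#' computational mutagenesis: every scanned residue is truncated to
#' glycine ([truncate_to_glycine()]), the ligand-environment interaction
#' energy is recomputed, and the change is reported as
#' `ddG = G_int(glycine mutant) - G_int(wild type)` in kcal/mol, so a
#' positive value means the side chain favours binding. The wild-type
#' complex is restored between mutations; mutations are independent, so
#' the result does not depend on scan order. In `"rigid"` mode (the
#' default) no re-relaxation is performed and the scan over n residues
#' costs n + 1 energy evaluations; `"relaxed"` mode re-relaxes the
#' movable set for the wild type and for every mutant.
#'
#' @param s a protonated, parameterised `carb_structure` complex.
#' @param residues list of [residue_id()]s to scan.
#' @param ligand_sel an [atom_selection()] for the ligand.
#' @param ff a [load_forcefield()] object.
#' @param mode `"rigid"` or `"relaxed"`.
#' @param movable_residues residues free to move in `"relaxed"` mode
#'   (defaults to the scanned residues).
#' @param settings [minimizer_settings()] for `"relaxed"` mode.
#' @return A `carb_scan` data frame: chain, resno, ins, resname, ddg,
#'   already_glycine, in_contact; attributes `mode`, `wt_total`.
#' @export
glycine_scan <- function(s, residues, ligand_sel,
                         ff = load_forcefield(),
                         mode = c("rigid", "relaxed"),
                         movable_residues = residues,
                         settings = minimizer_settings()) {
  mode <- match.arg(mode)
  if (!is_parameterized(s)) {
    stop("structure is not parameterised: run assign_parameters() first")
  }
  contact_res <- tryCatch(
    unique(residue_key(classify_contacts(
      enumerate_contacts(s, ligand_sel))[,
        c("chain", "resno", "ins")])),
    error = function(e) character())
  wt <- s
  if (mode == "relaxed") {
    wt <- relax_binding_site(wt, movable_residues, ligand_sel, ff, settings)
  }
  e_wt <- energy_total(interaction_energy(wt, ligand_sel, ff))
  rows <- lapply(residues, function(rid) {
    block <- residue_atoms(s, rid)
    if (nrow(block) == 0L) stop("scan residue not found: ", resid_key(rid))
    rn <- block$resname[1L]
    in_contact <- resid_key(rid) %in% contact_res
    if (!in_contact) {
      message("scanned residue ", resid_key(rid),
              " has no contact with the ligand at 4 A")
    }
    if (rn == "GLY") {
      return(data.frame(chain = rid$chain, resno = rid$resno,
                        ins = rid$ins, resname = rn, ddg = 0,
                        already_glycine = TRUE, in_contact = in_contact,
                        stringsAsFactors = FALSE))
    }
    mut <- suppressMessages(truncate_to_glycine(s, rid))
    mut$atoms$charge <- NULL; mut$atoms$eps <- NULL
    mut$atoms$sigma <- NULL; mut$atoms$vdw_type <- NULL
    mut <- assign_parameters(mut, ff)
    if (mode == "relaxed") {
      mut <- relax_binding_site(mut, movable_residues, ligand_sel, ff,
                                settings)
    }
    e_mut <- energy_total(interaction_energy(mut, ligand_sel, ff))
    data.frame(chain = rid$chain, resno = rid$resno, ins = rid$ins,
               resname = rn, ddg = e_mut - e_wt,
               already_glycine = FALSE, in_contact = in_contact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "wt_total") <- e_wt
  attr(out, "energy_model") <- paste0("coulomb-lj/",
                                      ff$dielectric, "-dielectric")
  class(out) <- c("carb_scan", "data.frame")
  out
}
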