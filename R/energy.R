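# Nonbonded energy: E = 332.0637 q_i q_j / (eps(r) r)
#                     + 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]
# with Lorentz-Berthelot combination; eps(r) = k r (distance-dependent
# dielectric) or a constant. Units: kcal/mol, Angstrom, elementary
# charges.

COULOMB_K <- 332.0637

# Vectorised pairwise energies; r, qq, epsij, sigij are equal-length.
nb_energy_terms <- function(r, qq, epsij, sigij, ff) {
  if (any(r < 1e-9)) stop("singularity: zero interatomic distance")
  eel <- if (ff$dielectric == "distance") {
    ff$coulomb * qq / (ff$dielectric_k * r * r)
  } else {
    ff$coulomb * qq / (ff$dielectric_k * r)
  }
  sr6 <- (sigij / r)^6
  evdw <- 4 * epsij * (sr6 * sr6 - sr6)
  list(elec = eel, vdw = evdw)
}

# d(E)/d(r), same conventions.
nb_energy_deriv <- function(r, qq, epsij, sigij, ff) {
  del <- if (ff$dielectric == "distance") {
    -2 * ff$coulomb * qq / (ff$dielectric_k * r^3)
  } else {
    -ff$coulomb * qq / (ff$dielectric_k * r^2)
  }
  sr6 <- (sigij / r)^6
  dvdw <- 4 * epsij * (-12 * sr6 * sr6 + 6 * sr6) / r
  del + dvdw
}

#' Pairwise nonbonded energy between two parameterised atoms
#'
#' Coulomb term with the force field's dielectric model plus
#' Lennard-Jones 12-6 with Lorentz-Berthelot combination
#' (arithmetic-mean sigma, geometric-mean epsilon). Symmetric in its
#' arguments.
#'
#' @param i,j single parameterised atom records (1-row data frames from
#'   a structure after [assign_parameters()], or lists with `x`, `y`,
#'   `z`, `charge`, `eps`, `sigma`).
#' @param ff a [load_forcefield()] object.
#' @return A list: `elec`, `vdw`, `total` (kcal/mol).
#' @export
pair_energy <- function(i, j, ff = load_forcefield()) {
  r <- sqrt((i$x - j$x)^2 + (i$y - j$y)^2 + (i$z - j$z)^2)
  te <- nb_energy_terms(r, i$charge * j$charge,
                        sqrt(i$eps * j$eps), (i$sigma + j$sigma) / 2, ff)
  list(elec = te$elec, vdw = te$vdw, total = te$elec + te$vdw)
}

#' Ligand-environment interaction energy, decomposed per residue
#'
#' Sums pairwise nonbonded energies over every (ligand atom,
#' environment atom) pair, split into electrostatic and van der Waals
#' components and grouped by environment residue. No distance cutoff is
#' applied (active-site-scale systems). The grand total equals the sum
#' of per-residue totals by construction.
#'
#' @param s a parameterised `carb_structure` (see [assign_parameters()];
#'   hydrogens should be present).
#' @param ligand_sel an [atom_selection()] for the ligand atoms.
#' @param ff a [load_forcefield()] object.
#' @return A `carb_energy` data frame (chain, resno, ins, resname, elec,
#'   vdw, total) with attribute `total` (the grand total, kcal/mol).
#' @export
interaction_energy <- function(s, ligand_sel, ff = load_forcefield()) {
  if (!is_parameterized(s)) {
    stop("structure is not parameterised: run assign_parameters() first")
  }
  lig <- select_atoms(s, ligand_sel)
  if (nrow(lig) == 0L) stop("ligand selection is empty")
  env <- select_atoms(s)
  lkey <- paste(residue_key(lig), lig$atom, sep = "|")
  ekey <- paste(residue_key(env), env$atom, sep = "|")
  env <- env[!(ekey %in% lkey), , drop = FALSE]
  if (nrow(env) == 0L) stop("environment is empty")
  lm <- coords_matrix(lig); em <- coords_matrix(env)
  d2 <- outer(rowSums(em^2), rowSums(lm^2), "+") - 2 * em %*% t(lm)
  r <- sqrt(pmax(d2, 0))
  qq <- outer(env$charge, lig$charge)
  epsij <- sqrt(outer(env$eps, lig$eps))
  sigij <- outer(env$sigma, lig$sigma, "+") / 2
  te <- nb_energy_terms(as.vector(r), as.vector(qq), as.vector(epsij),
                        as.vector(sigij), ff)
  eel_rows <- rowSums(matrix(te$elec, nrow(env)))
  evd_rows <- rowSums(matrix(te$vdw, nrow(env)))
  key <- residue_key(env)
  first <- !duplicated(key)
  out <- env[first, c("chain", "resno", "ins", "resname")]
  out$elec <- as.numeric(tapply(eel_rows, key, sum)[key[first]])
  out$vdw <- as.numeric(tapply(evd_rows, key, sum)[key[first]])
  out$total <- out$elec + out$vdw
  out <- out[order(out$chain, out$resno, out$ins), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- sum(out$total)
  class(out) <- c("carb_energy", "data.frame")
  out
}

#' Grand-total interaction energy
#'
#' @param e a `carb_energy` table from [interaction_energy()].
#' @return The grand total, kcal/mol.
#' @export
energy_total <- function(e) attr(e, "total")
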