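#' Specification of a synthetic test complex
#'
#' Describes a self-contained active-site fixture: a rigid ligand at
#' the origin surrounded by residues placed at controlled distances,
#' with optional zinc ion and bridging water. The same seed and spec
#' always produce a bit-identical fixture.
#'
#' @param seed integer RNG seed (orientation spins draw from it).
#' @param residues data frame with columns `resname`, `resno`
#'   (author numbers), `res_atom` (the residue atom placed at the
#'   engineered distance), `lig_atom` (the ligand atom it faces) and
#'   `distance` (Angstrom). Optional column `chain` (default `"A"`).
#' @param ligand `"compound1"` (the carborane sulfamide at idealised
#'   geometry) or `"point_probe"` (a single charged probe atom; its LJ
#'   well depth is zero so energies are pure Coulomb, closed-form).
#' @param probe_charge probe charge, elementary units (point probe only).
#' @param metal place a zinc ion facing the sulfamide anchor.
#' @param metal_distance Zn-N2 distance, Angstrom.
#' @param water optional residue number for a bridging water placed near
#'   the sulfamide O1; `NULL` for none.
#' @param substitutions optional data frame (`resno`, `to`) of residue
#'   substitutions for [make_homolog_pair()].
#' @param min_separation minimum heavy-atom distance enforced between
#'   different residues during placement.
#' @return A `carb_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, residues = default_site_residues(),
                         ligand = c("compound1", "point_probe"),
                         probe_charge = -1, metal = TRUE,
                         metal_distance = 2.0, water = NULL,
                         substitutions = NULL, min_separation = 2.2) {
  ligand <- match.arg(ligand)
  residues <- as.data.frame(residues)
  if (is.null(residues$chain)) residues$chain <- "A"
  req <- c("resname", "resno", "res_atom", "lig_atom", "distance")
  if (!all(req %in% names(residues))) {
    stop("residues needs columns: ", paste(req, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), residues = residues,
                 ligand = ligand, probe_charge = probe_charge,
                 metal = metal, metal_distance = metal_distance,
                 water = water, substitutions = substitutions,
                 min_separation = min_separation),
            class = "carb_fixture_spec")
}

#' Default synthetic active-site residue layout
#'
#' A carbonic-anhydrase-II-like site: the residue identities and
#' engineered contact distances follow the published crystal-contact
#' table of the carborane sulfamide complex (shortest contact per
#' residue), with the remaining site residues of the isoenzyme
#' comparison placed just outside contact range.
#'
#' @return Data frame accepted by [fixture_spec()].
#' @export
default_site_residues <- function() {
  read.table(text = "
resname resno res_atom lig_atom distance
TRP       5      CZ2       B5     3.74
ASN      62      ND2       B9     3.80
HIS      64      NE2       B7     4.60
ASN      67      OD1      B11     4.30
ILE      91      CD1      B10     4.50
GLN      92      OE1       B6     3.47
HIS      94      CE1       O2     2.97
HIS      96      NE2       N2     3.14
HIS     119      ND1       N2     3.39
VAL     121      CG2       O2     3.82
TRP     123      CZ2       B8     4.50
PHE     131       CZ       B8     3.83
VAL     135      CG1      B12     4.20
LEU     198       CA       O1     3.09
THR     199      OG1       N2     2.74
THR     200      OG1       N1     3.02
PRO     201        O       B4     3.60
LEU     204      CD1       B3     4.30
", header = TRUE, stringsAsFactors = FALSE)
}

# Substitutions distinguishing the isoenzyme-IX-like homolog from the
# II-like site (position: II identity -> IX identity).
#' @rdname default_site_residues
#' @export
default_homolog_substitutions <- function() {
  data.frame(resno = c(67L, 91L, 123L, 131L, 135L, 204L),
             to = c("GLN", "LEU", "LEU", "VAL", "LEU", "ALA"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic active-site complex with known ground truth
#'
#' Builds the ligand at the origin, places each residue so that its
#' `res_atom` sits exactly `distance` Angstrom from the named ligand
#' atom (pointing outward), resolves residue-residue collisions by
#' deterministic outward shifts and re-spins, then recomputes exhaustive
#' ground truth from the final coordinates with plain double loops:
#' all protein-ligand heavy-atom distances, the expected contact set at
#' any cutoff, expected polar classes, and (for the point probe)
#' closed-form per-residue Coulomb energies.
#'
#' @param spec a [fixture_spec()].
#' @return List: `structure` (a `carb_structure`), `truth` (list with
#'   `distances` data frame, `contact_set(cutoff)` function,
#'   `probe_energies` data frame or `NULL`).
#' @export
make_toy_complex <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  lig <- if (spec$ligand == "compound1") {
    build_ligand()
  } else {
    atoms <- data.frame(chain = "A", resno = 301L, ins = "",
                        resname = "LIG", atom = "P1", element = "Cl",
                        altloc = "", x = 0, y = 0, z = 0, occ = 1,
                        adp = 0, het = TRUE, stringsAsFactors = FALSE)
    new_structure(atoms, source_id = "point_probe")
  }
  lig_xyz <- coords_matrix(lig$atoms)
  rownames(lig_xyz) <- lig$atoms$atom
  center <- colMeans(lig_xyz)
  placed <- list(lig$atoms)
  # clearance is checked against the *protonated* ligand, so that the
  # exo hydrogen shell (1.19 A off every cage vertex) is respected even
  # though hydrogens are only added to the emitted structure on demand
  lig_clear_ref <- tryCatch(suppressWarnings(add_hydrogens(lig)),
                            error = function(e) lig)
  placed_xyz <- coords_matrix(lig_clear_ref$atoms)
  rownames(placed_xyz) <- lig_clear_ref$atoms$atom
  lig_is_h <- toupper(lig_clear_ref$atoms$element) == "H"
  # hydridic cage hydrogens carry LJ volume of their own; polar/aliphatic
  # ligand hydrogens are sterically folded into their parent atom
  clear_xyz_tmp <- coords_matrix(lig_clear_ref$atoms)
  lig_is_cage_h <- lig_is_h & vapply(seq_len(nrow(clear_xyz_tmp)),
    function(i) {
      if (!lig_is_h[i]) return(FALSE)
      d <- sqrt(colSums((t(clear_xyz_tmp[!lig_is_h, , drop = FALSE]) -
                           clear_xyz_tmp[i, ])^2))
      toupper(lig_clear_ref$atoms$element[!lig_is_h][which.min(d)]) == "B"
    }, logical(1L))
  req_placed <- ifelse(lig_is_cage_h, 2.4, ifelse(lig_is_h, 1.8, 3.0))
  n_res <- nrow(spec$residues)
  fib <- fibonacci_sphere(max(n_res, 1L))
  for (i in order(spec$residues$distance)) {   # tight contacts first
    r <- spec$residues[i, ]
    if (!r$lig_atom %in% rownames(lig_xyz)) {
      stop("unknown ligand atom in placement: ", r$lig_atom)
    }
    anchor <- lig_xyz[r$lig_atom, ]
    radial <- anchor - center
    if (vnorm(radial) < 1e-6) radial <- fib[i, ]
    u <- unitv(0.6 * unitv(radial) + 0.4 * fib[i, ])
    block <- place_residue_block(r, u, anchor, placed_xyz, req_placed,
                                 spec$min_separation,
                                 lig_rows = which(!lig_is_h),
                                 lig_h_rows = which(lig_is_h),
                                 lig_cage_h_rows = which(lig_is_cage_h),
                                 anchor_col = match(r$lig_atom,
                                                    rownames(placed_xyz)))
    placed[[length(placed) + 1L]] <- block
    placed_xyz <- rbind(placed_xyz, coords_matrix(block))
    req_placed <- c(req_placed, rep(spec$min_separation, nrow(block)))
  }
  if (spec$metal) {
    n2 <- lig_xyz["N2", ]
    s_at <- if ("S" %in% rownames(lig_xyz)) lig_xyz["S", ] else center
    # zinc on a tetrahedral lone-pair direction of the anchor nitrogen
    # (Zn-N-S about 113 degrees), leaving the two N-H slots free
    zn_pos <- if ("O1" %in% rownames(lig_xyz)) {
      place_atom(n2, s_at, lig_xyz["O1", ], spec$metal_distance, 113, 180)
    } else n2 + spec$metal_distance * unitv(n2 - s_at)
    zn <- ideal_residue("ZN", resno = 262L)
    zn$atoms$x <- zn_pos[1L]; zn$atoms$y <- zn_pos[2L]
    zn$atoms$z <- zn_pos[3L]
    placed[[length(placed) + 1L]] <- zn$atoms
  }
  if (!is.null(spec$water) && "O1" %in% rownames(lig_xyz)) {
    # bridging water: 2.8 A from the sulfamide O1, in the direction with
    # the most clearance from everything already placed
    o1 <- lig_xyz["O1", ]
    all_placed <- do.call(rbind, lapply(placed, coords_matrix))
    dirs <- fibonacci_sphere(200L)
    best <- NULL; best_d <- -Inf
    for (k in seq_len(nrow(dirs))) {
      cand <- o1 + 2.8 * dirs[k, ]
      dmin <- min(sqrt(rowSums(sweep(all_placed, 2L, cand)^2)))
      if (dmin > best_d) { best_d <- dmin; best <- cand }
    }
    w <- ideal_residue("HOH", resno = as.integer(spec$water))
    w$atoms$x <- best[1L]; w$atoms$y <- best[2L]; w$atoms$z <- best[3L]
    placed[[length(placed) + 1L]] <- w$atoms
  }
  atoms <- do.call(rbind, placed)
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  st <- new_structure(atoms, source_id = sprintf("toy(seed=%d)", spec$seed))
  truth <- fixture_ground_truth(st, lig_resname = lig$atoms$resname[1L],
                                probe_charge = if (spec$ligand ==
                                                   "point_probe")
                                  spec$probe_charge else NULL)
  list(structure = st, truth = truth, spec = spec)
}

# Orient an ideal residue so its contact atom faces the ligand along -u
# and sits at the engineered distance. Collision handling is a seeded
# search over azimuthal spins and direction jitter (plus outward shifts
# for residues beyond contact range, whose exact distance is not an
# engineered constraint); the candidate with the largest clearance wins.
place_residue_block <- function(r, u, anchor, placed_xyz, req_placed,
                                min_sep, lig_rows, lig_h_rows,
                                lig_cage_h_rows, anchor_col) {
  base <- ideal_residue(r$resname, resno = r$resno,
                        chain = if (is.null(r$chain)) "A" else r$chain)
  ba <- base$atoms
  if (!r$res_atom %in% ba$atom) {
    stop("residue ", r$resname, " has no atom ", r$res_atom)
  }
  xyz0 <- coords_matrix(ba)
  capos <- xyz0[match(r$res_atom, ba$atom), ]
  centroid <- colMeans(xyz0)
  # orientation axis: blend of residue bulk and the contact atom's
  # bonded neighbourhood, so that both the body of the residue and the
  # atoms covalently tied to the contact atom end up on the far side of
  # the ligand
  nb <- xyz0[sqrt(rowSums(sweep(xyz0, 2L, capos)^2)) < 1.9, , drop = FALSE]
  nb_dir <- if (nrow(nb) > 1L) colMeans(nb) - capos else c(0, 0, 0)
  out_dir <- unitv(centroid - capos + 1e-6) + 1.5 * nb_dir
  if (vnorm(out_dir) < 1e-6) out_dir <- c(0, 0, 1)
  # per-placed-row requirements seen by the engineered contact atom:
  # free approach to its anchor, near-engineered distance to the rest of
  # the ligand, a reduced shell toward ligand hydrogens
  req_contact <- req_placed
  req_contact[lig_rows] <- 0.95 * min(r$distance, 3.0)
  req_contact[lig_h_rows] <- max(1.6, 0.95 * min(r$distance, 3.0) - 1.19)
  # a heavy atom must keep a real shell even from the exo hydrogen of
  # its own anchor vertex (radial approach gives distance - 1.19)
  req_contact[lig_cage_h_rows] <- min(max(r$distance - 1.25, 2.0), 2.6)
  req_contact[anchor_col] <- 1e-3
  shiftable <- r$distance > 4.0
  best <- NULL
  best_dmin <- -Inf
  contact_row <- which(ba$atom == r$res_atom)
  for (attempt in seq_len(150L)) {
    uj <- if (attempt == 1L) u else {
      unitv(u + 0.45 * stats::runif(3L, -1, 1))
    }
    rot0 <- rotation_between(unitv(out_dir), uj)
    spin <- rotation_about(uj, stats::runif(1L, 0, 2 * pi))
    shift <- if (shiftable) 0.5 * ((attempt - 1L) %/% 30L) else 0
    target <- anchor + (r$distance + shift) * uj
    rot <- spin %*% rot0
    xyz <- sweep(xyz0, 2L, capos) %*% t(rot)
    xyz <- sweep(xyz, 2L, -target)
    dmin <- placement_clearance(xyz, placed_xyz, req_placed, req_contact,
                                contact_row, min_sep)
    if (dmin > best_dmin) {
      best_dmin <- dmin
      best <- xyz
    }
    if (best_dmin >= min_sep) break
  }
  if (best_dmin < min_sep) {
    message("fixture: residue ", r$resname, r$resno,
            " placed with clearance score ", round(best_dmin, 2), " A")
  }
  ba$x <- best[, 1L]; ba$y <- best[, 2L]; ba$z <- best[, 3L]
  ba
}

# Clearance score of a candidate placement: the smallest ratio of an
# atom-pair distance to its per-pair requirement, scaled to Angstrom by
# min_sep so the acceptance threshold stays min_sep.
placement_clearance <- function(new_xyz, placed_xyz, req_placed,
                                req_contact, contact_row, min_sep) {
  worst <- Inf
  for (i in seq_len(nrow(new_xyz))) {
    d <- sqrt(colSums((t(placed_xyz) - new_xyz[i, ])^2))
    req <- if (i == contact_row) req_contact else req_placed
    worst <- min(worst, min(d / req))
  }
  worst * min_sep
}

# Exhaustive ground truth by plain double loops (no reuse of the
# package's vectorised contact path).
fixture_ground_truth <- function(st, lig_resname, probe_charge = NULL) {
  a <- st$atoms
  lig_rows <- which(a$resname == lig_resname & toupper(a$element) != "H")
  env_rows <- which(a$resname != lig_resname & toupper(a$element) != "H" &
                      !is_water_row(a))
  recs <- list()
  for (i in env_rows) {
    for (j in lig_rows) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      recs[[length(recs) + 1L]] <- data.frame(
        resno = a$resno[i], resname = a$resname[i],
        protein_atom = a$atom[i], protein_element = a$element[i],
        ligand_atom = a$atom[j], ligand_element = a$element[j],
        distance = d, is_metal = FALSE, stringsAsFactors = FALSE)
    }
  }
  dist_tab <- do.call(rbind, recs)
  metal_res <- unique(a$resno[is_metal_row(a)])
  dist_tab$is_metal <- dist_tab$resno %in% metal_res
  contact_set <- function(cutoff = 4.0) {
    sub <- dist_tab[dist_tab$distance <= cutoff + 1e-9, , drop = FALSE]
    polar_el <- c("N", "O", "S")
    cls <- rep("vdw", nrow(sub))
    cls[toupper(sub$protein_element) %in% polar_el &
          toupper(sub$ligand_element) %in% polar_el &
          round(sub$distance, 2) <= 3.1 + 1e-9] <- "polar"
    cls[sub$is_metal & round(sub$distance, 2) <= 2.5 + 1e-9] <-
      "metal_coordination"
    sub$contact_class <- cls
    sub
  }
  probe_energies <- NULL
  if (!is.null(probe_charge)) {
    ff <- load_forcefield()
    tpl <- ff$params
    rows <- list()
    for (rn in unique(dist_tab$resno)) {
      sub <- dist_tab[dist_tab$resno == rn, , drop = FALSE]
      e <- 0
      for (k in seq_len(nrow(sub))) {
        q <- tpl$charge[tpl$res == sub$resname[k] &
                          tpl$atom == sub$protein_atom[k]]
        if (length(q) != 1L) next
        e <- e + 332.0637 * q * probe_charge / (4 * sub$distance[k]^2)
      }
      rows[[length(rows) + 1L]] <- data.frame(resno = rn, elec = e,
                                              stringsAsFactors = FALSE)
    }
    probe_energies <- do.call(rbind, rows)
  }
  list(distances = dist_tab, contact_set = contact_set,
       probe_energies = probe_energies)
}

#' Generate a homologous active-site pair with engineered substitutions
#'
#' Builds a toy complex (structure A), then derives structure B by
#' substituting the listed residues (new side chains grafted onto the
#' same backbone), removing ligand and waters (apo form, zinc retained)
#' and applying a seeded random rigid transform. The applied transform
#' and the substitution list are returned for use as oracles.
#'
#' @param spec a [fixture_spec()]; `spec$substitutions` defaults to
#'   [default_homolog_substitutions()].
#' @return List: `a` (holo complex), `b` (transformed apo homolog),
#'   `substitutions`, `transform` (maps B-frame onto A-frame),
#'   `truth` (ground truth for A).
#' @export
make_homolog_pair <- function(spec = fixture_spec(
                                water = 272L,
                                substitutions = default_homolog_substitutions())) {
  subs <- spec$substitutions
  if (is.null(subs)) subs <- default_homolog_substitutions()
  toy <- make_toy_complex(spec)
  a <- toy$structure
  missing_sub <- setdiff(subs$resno, spec$residues$resno)
  if (length(missing_sub) > 0L) {
    stop("substitution at residue(s) absent from the fixture: ",
         paste(missing_sub, collapse = ", "))
  }
  b <- a
  lig_resnames <- c("CB1", "LIG")
  keep <- !(b$atoms$resname %in% lig_resnames) & !is_water_row(b$atoms)
  b$atoms <- b$atoms[keep, , drop = FALSE]
  for (i in seq_len(nrow(subs))) {
    rid <- residue_id("A", subs$resno[i])
    old <- residue_atoms(b, rid)
    new_res <- ideal_residue(subs$to[i], resno = subs$resno[i])
    bb <- c("N", "CA", "C")
    old_bb <- coords_matrix(old[match(bb, old$atom), ])
    new_bb <- coords_matrix(new_res$atoms[match(bb, new_res$atoms$atom), ])
    tr <- kabsch_fit(old_bb, new_bb)
    new_xyz <- apply_transform(coords_matrix(new_res$atoms), tr)
    new_res$atoms$x <- new_xyz[, 1L]
    new_res$atoms$y <- new_xyz[, 2L]
    new_res$atoms$z <- new_xyz[, 3L]
    b <- replace_residue(b, rid, new_res$atoms)
  }
  tr_rand <- rigid_transform(random_rotation(), stats::runif(3L, -8, 8))
  # b is stored in its own frame: apply the inverse of tr_rand, so that
  # tr_rand maps B back onto A
  inv <- rigid_transform(t(tr_rand$rotation),
                         -as.numeric(t(tr_rand$rotation) %*%
                                       tr_rand$translation))
  b <- apply_transform(b, inv)
  b$source_id <- sprintf("homolog(seed=%d)", spec$seed)
  list(a = a, b = b, substitutions = subs, transform = tr_rand,
       truth = toy$truth)
}

#' Minimisation fixtures with known optima
#'
#' @param kind `"harmonic"` (isotropic 3-D well, analytic minimum at the
#'   center), `"lj_dimer"` (one movable atom against a fixed one;
#'   analytic optimum separation `2^(1/6) * sigma`), or `"cluster"`
#'   (seeded Lennard-Jones cluster with one movable atom; the reference
#'   energy is computed at build time by 1,000 steps of fixed-step
#'   steepest descent, a deliberately weaker optimiser).
#' @param seed RNG seed for starts.
#' @param sigma,eps LJ parameters (dimer/cluster).
#' @return List with `fn`, `gr`, `start`, and the analytic `optimum`
#'   (harmonic), `opt_separation` (dimer) or `reference_energy`
#'   (cluster).
#' @export
make_minimization_fixture <- function(kind = c("harmonic", "lj_dimer",
                                               "cluster"),
                                      seed = 1L, sigma = 3.4, eps = 0.25) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "harmonic") {
    center <- stats::rnorm(3L)
    k <- 12
    return(list(
      fn = function(p) k * sum((p - center)^2),
      gr = function(p) 2 * k * (p - center),
      start = center + stats::rnorm(3L, sd = 2),
      optimum = center))
  }
  lj <- function(r) 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  dlj <- function(r) 4 * eps * (-12 * (sigma / r)^12 + 6 * (sigma / r)^6) / r
  if (kind == "lj_dimer") {
    fixed <- c(0, 0, 0)
    return(list(
      fn = function(p) lj(sqrt(sum((p - fixed)^2))),
      gr = function(p) {
        r <- sqrt(sum((p - fixed)^2))
        dlj(r) * (p - fixed) / r
      },
      start = c(sigma * 1.8, 0.3, -0.2),
      opt_separation = 2^(1 / 6) * sigma))
  }
  # cluster: 4 fixed atoms + 1 movable
  fixed <- matrix(stats::rnorm(12L, sd = 2.5), 4L, 3L)
  fixed <- sweep(fixed, 2L, colMeans(fixed))
  fixed <- fixed * (sigma / max(1, max(abs(fixed))))
  fn <- function(p) sum(apply(fixed, 1L, function(f)
    lj(max(sqrt(sum((p - f)^2)), 0.5))))
  gr <- function(p) {
    g <- numeric(3L)
    for (i in seq_len(nrow(fixed))) {
      r <- max(sqrt(sum((p - fixed[i, ])^2)), 0.5)
      g <- g + dlj(r) * (p - fixed[i, ]) / r
    }
    g
  }
  start <- c(sigma * 1.6, sigma * 1.4, sigma * 1.2)
  p <- start
  for (i in seq_len(1000L)) {           # steepest-descent reference
    g <- gr(p)
    step <- 0.01 / max(1, sqrt(sum(g * g)))
    cand <- p - step * g * max(1, sqrt(sum(g * g)))
    if (fn(cand) < fn(p)) p <- cand
  }
  list(fn = fn, gr = gr, start = start, reference_energy = fn(p),
       fixed = fixed)
}
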