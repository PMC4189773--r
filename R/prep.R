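H_BOND_LENGTH <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34, B = 1.19)

#' Add hydrogens at idealised positions
#'
#' Places missing hydrogens by ideal geometry: sp3/sp2 rules with
#' standard X-H bond lengths (C-H 1.09, N-H 1.01, O-H 0.96, S-H 1.34
#' Angstrom); carborane cage hydrogens are placed radially outward from
#' the cage centroid (B-H 1.19 Angstrom). Existing hydrogens and all
#' heavy atoms are left untouched; the operation is idempotent.
#' Histidine is protonated on NE2 (single fixed neutral tautomer).
#' Water hydrogens are oriented toward the nearest nitrogen/oxygen
#' acceptor of another residue when one lies within 3.5 Angstrom.
#' Residues with unknown or incomplete topology are skipped with a
#' warning.
#'
#' @param s a `carb_structure`.
#' @return The structure with hydrogens appended per residue.
#' @export
add_hydrogens <- function(s) {
  a <- s$atoms
  tpl <- residue_templates()$atoms
  lig <- load_ligand_template()
  key <- residue_key(a)
  out_blocks <- list()
  all_xyz <- coords_matrix(a)
  for (rk in unique(key)) {
    idx <- which(key == rk)
    block <- a[idx, , drop = FALSE]
    rn <- block$resname[1L]
    ptab <- if (rn == lig$resname) lig$atoms else tpl[tpl$res == rn, ]
    if (nrow(ptab) == 0L) {
      warning("no topology for residue ", rn, " (", rk, "): skipped")
      out_blocks[[length(out_blocks) + 1L]] <- block
      next
    }
    heavy_tpl <- ptab$atom[ptab$element != "H"]
    if (!all(heavy_tpl %in% block$atom)) {
      warning("incomplete residue ", rn, " (", rk,
              "): hydrogens not added")
      out_blocks[[length(out_blocks) + 1L]] <- block
      next
    }
    h_tpl <- ptab[ptab$element == "H", , drop = FALSE]
    h_missing <- h_tpl[!(h_tpl$atom %in% block$atom), , drop = FALSE]
    if (nrow(h_missing) == 0L) {
      out_blocks[[length(out_blocks) + 1L]] <- block
      next
    }
    new_h <- place_residue_hydrogens(block, h_missing, ptab, rn, lig,
                                     s, all_xyz)
    out_blocks[[length(out_blocks) + 1L]] <- rbind(block, new_h)
  }
  s$atoms <- do.call(rbind, out_blocks)
  rownames(s$atoms) <- NULL
  s
}

place_residue_hydrogens <- function(block, h_missing, ptab, rn, lig,
                                    s, all_xyz) {
  pos <- function(nm) {
    i <- match(nm, block$atom)
    c(block$x[i], block$y[i], block$z[i])
  }
  # intra-residue heavy bond map
  btab <- if (rn == lig$resname) lig$bonds
          else {
            tb <- residue_templates()$bonds
            tb[tb$res == rn, c("a1", "a2")]
          }
  nbrs_of <- function(nm) {
    nb <- c(btab$a2[btab$a1 == nm], btab$a1[btab$a2 == nm])
    nb[nb %in% block$atom]
  }
  cage_centroid <- if (rn == lig$resname) {
    colMeans(coords_matrix(block[block$atom %in% lig$cage_atoms, ,
                                 drop = FALSE]))
  } else NULL
  rows <- list()
  parents <- unique(h_missing$parent)
  for (p in parents) {
    hnames <- h_missing$atom[h_missing$parent == p]
    pelem <- toupper(ptab$element[match(p, ptab$atom)])
    blen <- H_BOND_LENGTH[[pelem]]
    pxyz <- pos(p)
    phyb <- ptab$hyb[match(p, ptab$atom)]
    nbn <- nbrs_of(p)
    # amide nitrogen: previous residue's carbonyl C completes the plane
    extra_nbr <- NULL
    if (p == "N" && rn %in% AMINO_ACIDS) {
      prev_c <- which(s$atoms$atom == "C" &
                        residue_key(s$atoms) != residue_key(block)[1L])
      if (length(prev_c) > 0L) {
        d <- sqrt(colSums((t(all_xyz[prev_c, , drop = FALSE]) - pxyz)^2))
        if (min(d) < 1.8) extra_nbr <- all_xyz[prev_c[which.min(d)], ]
      }
    }
    nxyz <- if (length(nbn) > 0L) {
      m <- do.call(rbind, lapply(nbn, pos))
      if (!is.null(extra_nbr)) rbind(m, extra_nbr) else m
    } else if (!is.null(extra_nbr)) rbind(extra_nbr) else NULL
    hxyz <- if (!is.null(cage_centroid) &&
                identical(phyb, "cage")) {
      # exo-cage hydrogen along the centroid-vertex axis
      rbind(pxyz + blen * unitv(pxyz - cage_centroid))
    } else if (rn == "HOH") {
      place_water_hydrogens(pxyz, s, all_xyz, residue_key(block)[1L])
    } else {
      place_generic_hydrogens(pxyz, nxyz, length(hnames), phyb, blen,
                              ref_fn = function(first_nbr) {
                                # second-shell reference for torsions
                                nn <- nbrs_of(first_nbr)
                                nn <- setdiff(nn, p)
                                if (length(nn) > 0L) pos(nn[1L]) else NULL
                              },
                              nbr_names = nbn,
                              avoid = if (pelem %in% c("N", "O", "S"))
                                metal_positions(s, all_xyz) else NULL)
    }
    if (is.null(hxyz) || nrow(hxyz) < length(hnames)) {
      warning("could not place hydrogens on ", rn, " ", p)
      next
    }
    for (k in seq_along(hnames)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = block$chain[1L], resno = block$resno[1L],
        ins = block$ins[1L], resname = rn, atom = hnames[k],
        element = "H", altloc = "", x = hxyz[k, 1L], y = hxyz[k, 2L],
        z = hxyz[k, 3L], occ = 1, adp = 0, het = block$het[1L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(block[0L, , drop = FALSE])
  do.call(rbind, rows)
}

metal_positions <- function(s, all_xyz) {
  m <- which(is_metal_row(s$atoms))
  if (length(m) == 0L) return(NULL)
  all_xyz[m, , drop = FALSE]
}

place_generic_hydrogens <- function(pxyz, nxyz, n_h, hyb, blen, ref_fn,
                                    nbr_names, avoid = NULL) {
  nn <- if (is.null(nxyz)) 0L else nrow(nxyz)
  if (nn == 0L) return(NULL)
  units <- t(apply(nxyz, 1L, function(v) unitv(v - pxyz)))
  if (n_h == 1L && nn >= 3L) {
    return(rbind(pxyz + blen * unitv(-colSums(units))))
  }
  if (n_h == 1L && nn == 2L) {
    return(rbind(pxyz + blen * unitv(-(units[1L, ] + units[2L, ]))))
  }
  if (n_h == 2L && nn == 2L) {
    # methylene-style pair perpendicular to the neighbour plane
    bis <- unitv(-(units[1L, ] + units[2L, ]))
    perp <- unitv(cross3(units[1L, ], units[2L, ]))
    half <- deg2rad(109.47 / 2)
    return(rbind(pxyz + blen * (cos(half) * bis + sin(half) * perp),
                 pxyz + blen * (cos(half) * bis - sin(half) * perp)))
  }
  if (nn == 1L) {
    u <- units[1L, ]
    ref <- if (length(nbr_names) > 0L) ref_fn(nbr_names[1L]) else NULL
    if (is.null(ref)) {
      aux <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      ref <- pxyz + (-u) + aux     # arbitrary but deterministic plane
    }
    if (identical(hyb, "sp2") && n_h <= 2L) {
      # in-plane at +-120 degrees from the single neighbour
      tors <- if (n_h == 1L) 180 else c(0, 180)
      out <- t(vapply(tors, function(tt)
        place_atom(pxyz, pxyz + u, ref, blen, 120, tt), numeric(3L)))
      return(out)
    }
    ang <- 109.47
    base_tors <- switch(as.character(n_h),
                        "1" = 180, "2" = c(60, 300), "3" = c(60, 180, 300))
    offsets <- if (is.null(avoid)) 0 else seq(0, 330, by = 30)
    best <- NULL; best_score <- -Inf
    for (off in offsets) {
      cand <- t(vapply(base_tors + off, function(tt)
        place_atom(pxyz, pxyz + u, ref, blen, ang, tt), numeric(3L)))
      score <- if (is.null(avoid)) 0 else
        min(apply(cand, 1L, function(h)
          min(sqrt(rowSums(sweep(avoid, 2L, h)^2)))))
      if (score > best_score) { best_score <- score; best <- cand }
    }
    return(best)
  }
  NULL
}

place_water_hydrogens <- function(pxyz, s, all_xyz, own_key) {
  acc <- which(toupper(s$atoms$element) %in% c("N", "O") &
                 residue_key(s$atoms) != own_key)
  dir1 <- c(1, 0, 0)
  if (length(acc) > 0L) {
    d <- sqrt(colSums((t(all_xyz[acc, , drop = FALSE]) - pxyz)^2))
    if (min(d) <= 3.5) dir1 <- unitv(all_xyz[acc[which.min(d)], ] - pxyz)
  }
  aux <- if (abs(dir1[1L]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  perp <- unitv(cross3(dir1, aux))
  ang <- deg2rad(104.5)
  h1 <- pxyz + 0.96 * dir1
  h2 <- pxyz + 0.96 * (cos(ang) * dir1 + sin(ang) * perp)
  rbind(h1, h2)
}

#' Truncate a residue to glycine
#'
#' Removes every side-chain atom beyond C-alpha, adds HA2 along the old
#' CA->CB direction at standard C-H length, renames an existing HA to
#' HA3, and renames the residue GLY. Backbone atoms (N, CA, C, O and
#' their hydrogens) are untouched; every other residue is bit-identical.
#' Truncating a glycine is a no-op.
#'
#' @param s a `carb_structure`.
#' @param rid a [residue_id()].
#' @return The mutated structure.
#' @export
truncate_to_glycine <- function(s, rid) {
  block <- residue_atoms(s, rid)
  if (nrow(block) == 0L) stop("residue not found: ", resid_key(rid))
  rn <- block$resname[1L]
  if (rn == "GLY") {
    message("residue ", resid_key(rid), " is already glycine (no-op)")
    return(s)
  }
  if (!rn %in% AMINO_ACIDS) {
    stop("cannot truncate non-amino-acid residue ", rn)
  }
  if (!"CA" %in% block$atom) stop("residue lacks CA; cannot truncate")
  keep_names <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA")
  kept <- block[block$atom %in% keep_names, , drop = FALSE]
  ca <- as.numeric(kept[kept$atom == "CA", c("x", "y", "z")])
  if ("CB" %in% block$atom) {
    cb <- as.numeric(block[block$atom == "CB", c("x", "y", "z")][1L, ])
    hpos <- ca + 1.09 * unitv(cb - ca)
    kept$atom[kept$atom == "HA"] <- "HA3"
    kept <- rbind(kept, within(kept[kept$atom == "CA", , drop = FALSE], {
      atom <- "HA2"; element <- "H"; x <- hpos[1L]; y <- hpos[2L]
      z <- hpos[3L]; adp <- 0
    }))
  }
  kept$resname <- "GLY"
  replace_residue(s, rid, kept)
}

#' Graft a ligand from a template complex into a target protein
#'
#' Superposes the template complex onto the target over `fit_sel`
#' (paired by chain/residue number/atom name), then transfers the
#' ligand residue(s) -- plus the metal ion if the target has none, and
#' any named bridging waters -- into the target frame. Transferred
#' atoms closer than `clash_cutoff` to a target heavy atom are reported
#' as a warning (relaxation resolves such clashes; the graft itself
#' never moves target atoms).
#'
#' @param template a `carb_structure`: protein + ligand (+ metal/water).
#' @param target a `carb_structure`: the receiving protein (apo in the
#'   ligand site).
#' @param fit_sel an [atom_selection()] for the superposition (e.g.
#'   C-alpha atoms).
#' @param ligand_resname residue name(s) of the ligand in the template.
#' @param keep_waters integer vector of template water residue numbers
#'   to transfer (bridging waters); default none.
#' @param clash_cutoff heavy-atom clash threshold, Angstrom.
#' @return A `carb_structure` of the modeled complex, with attributes
#'   `transform` (template -> target frame) and `fit_rmsd`.
#' @export
graft_ligand <- function(template, target, fit_sel,
                         ligand_resname = "CB1", keep_waters = integer(),
                         clash_cutoff = 1.5) {
  if (any(target$atoms$resname %in% ligand_resname)) {
    stop("target already contains a ligand residue (",
         paste(ligand_resname, collapse = ", "),
         "); remove it before grafting")
  }
  fit <- superpose_structures(target, template, fit_sel)
  ta <- template$atoms
  take <- ta$resname %in% ligand_resname
  if (!any(take)) stop("template has no residue named ",
                       paste(ligand_resname, collapse = ", "))
  if (!any(is_metal_row(target$atoms)) && any(is_metal_row(ta))) {
    take <- take | is_metal_row(ta)
  }
  if (length(keep_waters) > 0L) {
    take <- take | (is_water_row(ta) & ta$resno %in% keep_waters)
  }
  moved <- ta[take, , drop = FALSE]
  moved_xyz <- apply_transform(coords_matrix(moved), fit$transform)
  moved$x <- moved_xyz[, 1L]; moved$y <- moved_xyz[, 2L]
  moved$z <- moved_xyz[, 3L]
  # clash report against target heavy atoms
  th <- target$atoms[toupper(target$atoms$element) != "H", , drop = FALSE]
  mh <- moved[toupper(moved$element) != "H", , drop = FALSE]
  if (nrow(th) > 0L && nrow(mh) > 0L) {
    tm <- coords_matrix(th); mm <- coords_matrix(mh)
    d2 <- outer(rowSums(tm^2), rowSums(mm^2), "+") - 2 * tm %*% t(mm)
    hits <- which(d2 < clash_cutoff^2, arr.ind = TRUE)
    if (nrow(hits) > 0L) {
      warning("grafted atoms clash (< ", clash_cutoff, " A) with target: ",
              paste(sprintf("%s%d:%s-%s:%s (%.2f A)",
                            th$resname[hits[, 1L]], th$resno[hits[, 1L]],
                            th$atom[hits[, 1L]], mh$resname[hits[, 2L]],
                            mh$atom[hits[, 2L]],
                            sqrt(pmax(d2[hits], 0))),
                    collapse = "; "))
    }
  }
  out <- new_structure(rbind(target$atoms, moved),
                       source_id = paste0(target$source_id, "+graft"))
  attr(out, "transform") <- fit$transform
  attr(out, "fit_rmsd") <- fit$rmsd
  out
}

#' List binding-site substitutions between two structures
#'
#' Superposes `b` onto `a` over `fit_sel`, then pairs each site residue
#' of `a` with the spatially nearest C-alpha of `b` (within
#' `pair_cutoff`); author numbering is not used for pairing, since it
#' may differ between isoenzymes. Reports positions whose residue names
#' differ; unpairable site residues are listed with `name_b = NA` rather
#' than dropped.
#'
#' @param a,b `carb_structure` objects.
#' @param site_sel selection of site residues in `a`.
#' @param fit_sel selection for the superposition (default: all shared
#'   C-alpha atoms).
#' @param pair_cutoff C-alpha pairing radius, Angstrom.
#' @return Data frame: chain_a, resno_a, name_a, resno_b, name_b,
#'   matched (logical). Substitutions are the matched rows with
#'   differing names.
#' @export
binding_site_substitutions <- function(a, b, site_sel,
                                       fit_sel = atom_selection(atom = "CA"),
                                       pair_cutoff = 2.5) {
  fit <- superpose_structures(a, b, fit_sel)
  aca <- select_atoms(a, atom_selection(atom = "CA"))
  bca <- select_atoms(b, atom_selection(atom = "CA"))
  bxyz <- apply_transform(coords_matrix(bca), fit$transform)
  site <- select_atoms(a, site_sel)
  site_res <- residue_table(site)
  site_res <- site_res[site_res$resname %in% AMINO_ACIDS, , drop = FALSE]
  rows <- lapply(seq_len(nrow(site_res)), function(i) {
    r <- site_res[i, ]
    ai <- which(aca$chain == r$chain & aca$resno == r$resno &
                  aca$ins == r$ins)
    if (length(ai) == 0L) {
      return(data.frame(chain_a = r$chain, resno_a = r$resno,
                        name_a = r$resname, resno_b = NA_integer_,
                        name_b = NA_character_, matched = FALSE,
                        stringsAsFactors = FALSE))
    }
    apos <- as.numeric(aca[ai[1L], c("x", "y", "z")])
    d <- sqrt(colSums((t(bxyz) - apos)^2))
    j <- which.min(d)
    if (d[j] > pair_cutoff) {
      return(data.frame(chain_a = r$chain, resno_a = r$resno,
                        name_a = r$resname, resno_b = NA_integer_,
                        name_b = NA_character_, matched = FALSE,
                        stringsAsFactors = FALSE))
    }
    data.frame(chain_a = r$chain, resno_a = r$resno, name_a = r$resname,
               resno_b = bca$resno[j], name_b = bca$resname[j],
               matched = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$differs <- out$matched & out$name_a != out$name_b
  rownames(out) <- NULL
  out
}
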