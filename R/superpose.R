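#' Rigid-body transform
#'
#' A proper rotation plus translation; applying it maps moving
#' coordinates into the reference frame as `x R^T + t`.
#'
#' @param rotation 3x3 proper rotation matrix (det +1).
#' @param translation length-3 numeric vector, Angstrom.
#' @return A `carb_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "carb_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix (or a `carb_structure`).
#' @param transform a `carb_transform`.
#' @return Transformed coordinates (or structure).
#' @export
apply_transform <- function(xyz, transform) {
  if (inherits(xyz, "carb_structure")) {
    return(set_coords(xyz, apply_transform(coords_matrix(xyz$atoms),
                                           transform)))
  }
  xyz <- rbind(xyz)
  sweep(xyz %*% t(transform$rotation), 2L, -transform$translation)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the sum of
#' squared distances between paired points, via singular value
#' decomposition with determinant correction; reflections are excluded
#' by construction.
#'
#' @param ref n x 3 reference coordinates.
#' @param mov n x 3 moving coordinates (same pairing order).
#' @return A `carb_transform` mapping `mov` onto `ref`.
#' @export
kabsch_fit <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov)) {
    stop("pairing error: coordinate lists differ in length (",
         nrow(ref), " vs ", nrow(mov), ")")
  }
  if (nrow(ref) < 3L) stop("need at least 3 paired points for a fit")
  mr <- colMeans(ref); mm <- colMeans(mov)
  rc <- sweep(ref, 2L, mr); mc <- sweep(mov, 2L, mm)
  h <- crossprod(mc, rc)
  sv <- svd(h)
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-30)) {
    stop("rank-deficient geometry: points are (nearly) collinear")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(rot, as.numeric(mr - rot %*% mm))
}

#' Root-mean-square deviation of paired coordinates
#'
#' @param a,b n x 3 coordinate matrices in pairing order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    stop("pairing error: coordinate lists differ in length")
  }
  if (nrow(a) == 0L) stop("need at least one paired point")
  sqrt(mean(rowSums((a - b)^2)))
}

# Pair atoms of two structures by (chain, resno, ins, atom name) on a
# selection; residues present on only one side are dropped.
pair_atoms <- function(ref, mov, sel) {
  ra <- select_atoms(ref, sel)
  ma <- select_atoms(mov, sel)
  rkey <- paste(residue_key(ra), ra$atom, sep = "|")
  mkey <- paste(residue_key(ma), ma$atom, sep = "|")
  if (anyDuplicated(rkey) || anyDuplicated(mkey)) {
    stop("pairing error: duplicate atom keys in selection ",
         "(use altloc = \"best\")")
  }
  common <- intersect(rkey, mkey)
  n_dropped <- (length(rkey) - length(common)) + (length(mkey) - length(common))
  if (n_dropped > 0L) {
    message(n_dropped, " unpaired atom record(s) dropped from superposition")
  }
  list(ref = ra[match(common, rkey), , drop = FALSE],
       mov = ma[match(common, mkey), , drop = FALSE])
}

#' Superpose one structure onto another
#'
#' Pairs atoms of the selection by (chain, residue number, insertion
#' code, atom name), fits `mov` onto `ref` by [kabsch_fit()], and
#' reports the post-fit RMSD over the selection. The returned transform
#' can be applied to any other atoms of `mov` (e.g. a ligand) without
#' refitting.
#'
#' @param ref,mov `carb_structure` objects.
#' @param sel an [atom_selection()]; e.g. C-alpha of a residue range.
#' @return A `carb_superposition` list: `transform`, `rmsd`, `n_atoms`.
#' @export
superpose_structures <- function(ref, mov,
                                 sel = atom_selection(atom = "CA")) {
  p <- pair_atoms(ref, mov, sel)
  if (nrow(p$ref) < 3L) {
    stop("underdetermined superposition: only ", nrow(p$ref),
         " paired atoms")
  }
  tr <- kabsch_fit(coords_matrix(p$ref), coords_matrix(p$mov))
  fitted <- apply_transform(coords_matrix(p$mov), tr)
  structure(list(transform = tr,
                 rmsd = rmsd(coords_matrix(p$ref), fitted),
                 n_atoms = nrow(p$ref)),
            class = "carb_superposition")
}

#' @export
print.carb_superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d paired atoms, rmsd %.3f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Per-residue deviation after superposition
#'
#' Fits `mov` onto `ref` using `fit_sel` (typically all C-alpha), then
#' reports, per residue of `sel`, the RMS distance between paired atoms
#' in the fitted frame. Residues present in only one structure are
#' omitted with a warning.
#'
#' @param ref,mov `carb_structure` objects.
#' @param sel selection of reported atoms (default C-alpha).
#' @param fit_sel selection defining the superposition (default `sel`).
#' @return Data frame (chain, resno, ins, resname, deviation) sorted by
#'   residue, with attributes `max` and `argmax`.
#' @export
per_residue_deviation <- function(ref, mov,
                                  sel = atom_selection(atom = "CA"),
                                  fit_sel = sel) {
  fit <- superpose_structures(ref, mov, fit_sel)
  p <- pair_atoms(ref, mov, sel)
  if (nrow(p$ref) == 0L) stop("no paired atoms in reporting selection")
  fitted <- apply_transform(coords_matrix(p$mov), fit$transform)
  d2 <- rowSums((coords_matrix(p$ref) - fitted)^2)
  key <- residue_key(p$ref)
  dev <- sqrt(tapply(d2, key, mean))
  first <- !duplicated(key)
  out <- p$ref[first, c("chain", "resno", "ins", "resname")]
  out$deviation <- as.numeric(dev[key[first]])
  out <- out[order(out$chain, out$resno, out$ins), , drop = FALSE]
  rownames(out) <- NULL
  imax <- which.max(out$deviation)
  attr(out, "max") <- out$deviation[imax]
  attr(out, "argmax") <- residue_id(out$chain[imax], out$resno[imax],
                                    out$ins[imax])
  attr(out, "fit") <- fit
  out
}
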