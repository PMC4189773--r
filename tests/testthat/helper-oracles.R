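# Independent oracles and small fixture builders shared by the tests.
# Everything here is deliberately naive (plain double loops, closed
# forms) so it cannot share a defect with the vectorised package paths.

# brute-force contact enumeration by nested loops
brute_contacts <- function(s, lig_resname, cutoff = 4.0) {
  a <- select_atoms(s)                 # same altloc policy as the package
  lig <- a[a$resname == lig_resname & toupper(a$element) != "H", ]
  env <- a[a$resname != lig_resname & toupper(a$element) != "H" &
             !(a$resname %in% c("HOH", "WAT")), ]
  out <- character()
  for (i in seq_len(nrow(env))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((env$x[i] - lig$x[j])^2 + (env$y[i] - lig$y[j])^2 +
                  (env$z[i] - lig$z[j])^2)
      if (d <= cutoff + 1e-9) {
        out <- c(out, paste(env$chain[i], env$resno[i], env$atom[i],
                            lig$atom[j], sep = "|"))
      }
    }
  }
  sort(out)
}

contact_keys <- function(ct) {
  sort(paste(ct$chain, ct$resno, ct$protein_atom, ct$ligand_atom,
             sep = "|"))
}

# random loose structure: a few pseudo-residues plus a pseudo-ligand,
# all atoms at uniform random positions in a box
random_loose_structure <- function(seed, n_res = 4L, atoms_per_res = 4L,
                                   n_lig = 6L, box = 9) {
  set.seed(seed)
  elements <- c("C", "N", "O", "S", "B")
  blocks <- list()
  for (r in seq_len(n_res)) {
    blocks[[r]] <- data.frame(
      chain = "A", resno = r, ins = "", resname = "ALA",
      atom = paste0("X", seq_len(atoms_per_res)),
      element = sample(elements, atoms_per_res, replace = TRUE),
      altloc = "", x = runif(atoms_per_res, -box, box),
      y = runif(atoms_per_res, -box, box),
      z = runif(atoms_per_res, -box, box),
      occ = 1, adp = 10, het = FALSE, stringsAsFactors = FALSE)
  }
  blocks[[n_res + 1L]] <- data.frame(
    chain = "A", resno = 900L, ins = "", resname = "XLG",
    atom = paste0("L", seq_len(n_lig)),
    element = sample(elements, n_lig, replace = TRUE),
    altloc = "", x = runif(n_lig, -3, 3), y = runif(n_lig, -3, 3),
    z = runif(n_lig, -3, 3), occ = 1, adp = 10, het = TRUE,
    stringsAsFactors = FALSE)
  new_structure(do.call(rbind, blocks), source_id = sprintf("rand%d", seed))
}

# a structure holding exactly the rows given (x, y, z, element, ...)
bare_structure <- function(df) {
  defaults <- data.frame(chain = "A", resno = 1L, ins = "",
                         resname = "ALA", atom = "X1", element = "C",
                         altloc = "", x = 0, y = 0, z = 0, occ = 1,
                         adp = 0, het = FALSE, stringsAsFactors = FALSE)
  full <- defaults[rep(1L, nrow(df)), ]
  for (nm in names(df)) full[[nm]] <- df[[nm]]
  rownames(full) <- NULL
  new_structure(full, source_id = "bare")
}

# random proper rotation drawn from the current RNG stream
test_rotation <- function() {
  m <- matrix(rnorm(9L), 3L, 3L)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# tiny two-residue protein fragment at idealised geometry
tiny_protein <- function(resnames = c("THR", "TRP"), spacing = 8) {
  blocks <- lapply(seq_along(resnames), function(i) {
    r <- ideal_residue(resnames[i], resno = i)
    r$atoms$x <- r$atoms$x + (i - 1L) * spacing
    r$atoms
  })
  new_structure(do.call(rbind, blocks), source_id = "tiny")
}

# minimal energetic complex: one residue near a point probe, parameters
# attached through the normal package path
probe_complex <- function(resname = "SER", distance = 3.0, seed = 1L) {
  spec <- fixture_spec(
    seed = seed,
    residues = data.frame(resname = resname, resno = 10L,
                          res_atom = "CB", lig_atom = "P1",
                          distance = distance,
                          stringsAsFactors = FALSE),
    ligand = "point_probe", metal = FALSE)
  make_toy_complex(spec)
}
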