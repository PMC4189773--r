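test_that("fixtures are bit-identical under a repeated seed", {
  a <- suppressMessages(make_toy_complex(fixture_spec(seed = 57)))
  b <- suppressMessages(make_toy_complex(fixture_spec(seed = 57)))
  expect_identical(a$structure$atoms, b$structure$atoms)
  p1 <- file.path(tempdir(), "fx1.pdb")
  p2 <- file.path(tempdir(), "fx2.pdb")
  write_structure(a$structure, p1)
  write_structure(b$structure, p2)
  expect_identical(readLines(p1), readLines(p2))
  c_ <- suppressMessages(make_toy_complex(fixture_spec(seed = 58)))
  expect_false(identical(a$structure$atoms, c_$structure$atoms))
})

test_that("engineered contact distances are honoured exactly", {
  spec <- fixture_spec(seed = 3)
  toy <- suppressMessages(make_toy_complex(spec))
  a <- toy$structure$atoms
  lig <- a[a$resname == "CB1", ]
  for (i in seq_len(nrow(spec$residues))) {
    r <- spec$residues[i, ]
    pa <- a[a$resno == r$resno & a$atom == r$res_atom, ]
    la <- lig[lig$atom == r$lig_atom, ]
    d <- sqrt((pa$x - la$x)^2 + (pa$y - la$y)^2 + (pa$z - la$z)^2)
    if (r$distance <= 4.0) {
      # contact-range placements are exact
      expect_equal(d, r$distance, tolerance = 1e-9,
                   info = paste(r$resname, r$resno))
    } else {
      # out-of-range residues may be shifted outward to relieve crowding
      expect_gte(d, r$distance - 1e-9)
    }
  }
})

test_that("fixture ground truth agrees with brute-force recomputation", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 62)))
  truth_set <- toy$truth$contact_set(4.0)
  ct <- classify_contacts(
    enumerate_contacts(toy$structure, atom_selection(resname = "CB1")))
  key <- function(t) sort(paste(t$resno, t$protein_atom, t$ligand_atom))
  expect_identical(key(ct), key(truth_set))
  m <- match(paste(ct$resno, ct$protein_atom, ct$ligand_atom),
             paste(truth_set$resno, truth_set$protein_atom,
                   truth_set$ligand_atom))
  expect_equal(ct$distance_exact, truth_set$distance[m], tolerance = 1e-9)
  expect_identical(ct$contact_class, truth_set$contact_class[m])
})

test_that("homolog pairs return their own oracles", {
  hp <- suppressMessages(make_homolog_pair(fixture_spec(
    seed = 71, water = 272L,
    substitutions = default_homolog_substitutions())))
  expect_identical(nrow(hp$substitutions), 6L)
  # the recorded transform maps B's CA set onto A's
  aca <- select_atoms(hp$a, atom_selection(atom = "CA"))
  bca <- select_atoms(hp$b, atom_selection(atom = "CA"))
  expect_identical(aca$resno, bca$resno)
  back <- apply_transform(coords_matrix(bca), hp$transform)
  expect_lt(max(abs(back - coords_matrix(aca))), 1e-8)
  # kabsch recovers that transform independently
  fit <- kabsch_fit(coords_matrix(aca), coords_matrix(bca))
  expect_lt(max(abs(fit$rotation - hp$transform$rotation)), 1e-8)
  # no-substitution degenerate case
  same <- suppressMessages(make_homolog_pair(fixture_spec(
    seed = 72, water = 272L,
    substitutions = data.frame(resno = integer(), to = character()))))
  expect_identical(nrow(same$substitutions), 0L)
  expect_identical(sort(unique(same$b$atoms$resname)),
                   sort(unique(hp$a$atoms$resname[
                     !hp$a$atoms$resname %in% c("CB1", "HOH")])))
  # substitution at a missing residue is a spec error
  expect_error(suppressMessages(make_homolog_pair(fixture_spec(
    seed = 73, substitutions = data.frame(resno = 999L, to = "ALA")))),
    "absent")
})

test_that("minimisation fixtures expose their optima", {
  h <- make_minimization_fixture("harmonic", seed = 2L)
  expect_equal(h$gr(h$optimum), c(0, 0, 0), tolerance = 1e-12)
  d <- make_minimization_fixture("lj_dimer", seed = 2L, sigma = 3.4)
  expect_equal(d$opt_separation, 2^(1 / 6) * 3.4)
  expect_lt(d$fn(c(d$opt_separation, 0, 0)), d$fn(c(3.4, 0, 0)))
  cl <- make_minimization_fixture("cluster", seed = 7L)
  expect_lt(cl$reference_energy, cl$fn(cl$start))
})
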