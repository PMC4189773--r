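scan_fixture <- function(seed = 10L) {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = seed)))
  ff <- load_forcefield()
  list(s = assign_parameters(add_hydrogens(toy$structure), ff), ff = ff,
       sel = atom_selection(resname = "CB1"))
}

test_that("a glycine scans to exactly zero and state is isolated", {
  fx <- scan_fixture()
  s <- fx$s
  # plant a glycine by truncating first
  s0 <- truncate_to_glycine(s, residue_id("A", 121L))
  s0$atoms$charge <- NULL; s0$atoms$eps <- NULL
  s0$atoms$sigma <- NULL; s0$atoms$vdw_type <- NULL
  s0 <- assign_parameters(s0, fx$ff)
  before <- s0$atoms
  res <- suppressMessages(glycine_scan(
    s0, list(residue_id("A", 121L), residue_id("A", 94L)), fx$sel, fx$ff))
  expect_identical(res$ddg[res$resno == 121L], 0)
  expect_true(res$already_glycine[res$resno == 121L])
  expect_false(res$already_glycine[res$resno == 94L])
  expect_identical(s0$atoms, before)           # wild type restored
})

test_that("scan results are independent of residue order", {
  fx <- scan_fixture()
  ids <- lapply(c(5L, 92L, 94L, 199L, 200L), function(r)
    residue_id("A", r))
  fwd <- suppressMessages(glycine_scan(fx$s, ids, fx$sel, fx$ff))
  rev_ <- suppressMessages(glycine_scan(fx$s, rev(ids), fx$sel, fx$ff))
  m <- match(fwd$resno, rev_$resno)
  expect_identical(fwd$ddg, rev_$ddg[m])
})

test_that("a sole-contact side chain's ddG equals its pairwise energy sum", {
  # one residue near the ligand, everything else absent; backbone
  # parameters are shared between the wild type and the glycine mutant,
  # so ddG must equal minus the side-chain/ligand pair-energy sum
  toy <- suppressMessages(make_toy_complex(fixture_spec(
    seed = 41, metal = FALSE,
    residues = data.frame(resname = "GLN", resno = 92L, res_atom = "OE1",
                          lig_atom = "B6", distance = 3.47))))
  ff <- load_forcefield()
  s <- assign_parameters(add_hydrogens(toy$structure), ff)
  res <- suppressMessages(glycine_scan(s, list(residue_id("A", 92L)),
                                       atom_selection(resname = "CB1"),
                                       ff))
  backbone <- c("N", "CA", "C", "O", "H", "HA", "HA2", "HA3")
  side <- s$atoms[s$atoms$resno == 92L & !(s$atoms$atom %in% backbone), ]
  lig <- s$atoms[s$atoms$resname == "CB1", ]
  hand <- 0
  for (i in seq_len(nrow(side))) {
    for (j in seq_len(nrow(lig))) {
      r <- sqrt((side$x[i] - lig$x[j])^2 + (side$y[i] - lig$y[j])^2 +
                  (side$z[i] - lig$z[j])^2)
      sij <- (side$sigma[i] + lig$sigma[j]) / 2
      eij <- sqrt(side$eps[i] * lig$eps[j])
      hand <- hand + 332.0637 * side$charge[i] * lig$charge[j] / (4 * r^2) +
        4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  expect_equal(res$ddg, -hand, tolerance = 1e-9)
})

test_that("side chains far from the ligand contribute nothing", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(
    seed = 43, metal = FALSE,
    residues = data.frame(resname = c("THR", "LEU"), resno = c(199L, 77L),
                          res_atom = c("OG1", "CD1"),
                          lig_atom = c("N2", "B7"),
                          distance = c(2.74, 100)))))
  ff <- load_forcefield()
  s <- assign_parameters(add_hydrogens(toy$structure), ff)
  res <- suppressMessages(glycine_scan(s, list(residue_id("A", 77L)),
                                       atom_selection(resname = "CB1"),
                                       ff))
  expect_false(res$in_contact)
  expect_lt(abs(res$ddg), 1e-6)
})
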