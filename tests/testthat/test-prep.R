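test_that("hydrogen placement is complete, idempotent and never moves heavy atoms", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 6)))
  s <- toy$structure
  sp <- add_hydrogens(s)
  heavy <- sp$atoms[toupper(sp$atoms$element) != "H", ]
  expect_equal(unname(coords_matrix(heavy)),
               unname(coords_matrix(s$atoms)), tolerance = 0)
  # glycine check on a fragment
  gly <- add_hydrogens(tiny_protein("GLY"))
  expect_true(all(c("H", "HA2", "HA3") %in% gly$atoms$atom))
  # ligand: 10 B-H + 1 cage C-H + 2 methylene + 3 N-H
  lig <- add_hydrogens(build_ligand())
  expect_identical(sum(lig$atoms$element == "H"), 16L)
  # idempotence
  sp2 <- add_hydrogens(sp)
  expect_identical(nrow(sp2$atoms), nrow(sp$atoms))
  expect_identical(coords_matrix(sp2$atoms), coords_matrix(sp$atoms))
  # unknown residue skipped loudly
  odd <- bare_structure(data.frame(resname = "XXX", atom = "Q1",
                                   element = "C"))
  expect_warning(add_hydrogens(odd), "no topology")
  # incomplete residue skipped loudly
  part <- tiny_protein("THR")
  part$atoms <- part$atoms[part$atoms$atom != "OG1", ]
  expect_warning(add_hydrogens(part), "incomplete")
})

test_that("glycine truncation removes the side chain and nothing else", {
  s <- add_hydrogens(tiny_protein(c("TRP", "THR")))
  rid <- residue_id("A", 1L)
  mut <- truncate_to_glycine(s, rid)
  gly_block <- mut$atoms[mut$atoms$resno == 1L, ]
  expect_identical(gly_block$resname[1L], "GLY")
  expect_setequal(gly_block$atom, c("N", "CA", "C", "O", "H", "HA2", "HA3"))
  # backbone untouched
  for (nm in c("N", "CA", "C", "O")) {
    expect_identical(
      as.numeric(gly_block[gly_block$atom == nm, c("x", "y", "z")]),
      as.numeric(s$atoms[s$atoms$resno == 1L & s$atoms$atom == nm,
                         c("x", "y", "z")]))
  }
  # HA2 along the old CA->CB direction at C-H length
  ca <- as.numeric(gly_block[gly_block$atom == "CA", c("x", "y", "z")])
  cb <- as.numeric(s$atoms[s$atoms$resno == 1L & s$atoms$atom == "CB",
                           c("x", "y", "z")])
  ha2 <- as.numeric(gly_block[gly_block$atom == "HA2", c("x", "y", "z")])
  expect_equal(sqrt(sum((ha2 - ca)^2)), 1.09, tolerance = 1e-9)
  expect_lt(max(abs((ha2 - ca) / 1.09 - (cb - ca) / sqrt(sum((cb - ca)^2)))),
            1e-9)
  # untouched residues bit-identical (row names aside)
  other_mut <- mut$atoms[mut$atoms$resno == 2L, ]
  other_wt <- s$atoms[s$atoms$resno == 2L, ]
  rownames(other_mut) <- NULL
  rownames(other_wt) <- NULL
  expect_identical(other_mut, other_wt)
  # no-op on glycine, error on non-amino residues
  expect_message(again <- truncate_to_glycine(mut, rid), "no-op")
  expect_identical(again$atoms, mut$atoms)
  zn <- suppressMessages(make_toy_complex(fixture_spec(seed = 1)))$structure
  expect_error(truncate_to_glycine(zn, residue_id("A", 262L)),
               "non-amino")
})

test_that("sequential and batched truncation agree", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 9)))
  s <- toy$structure
  targets <- c(92L, 199L, 200L)
  seqwise <- s
  for (rn in targets) {
    seqwise <- truncate_to_glycine(seqwise, residue_id("A", rn))
  }
  reversed <- s
  for (rn in rev(targets)) {
    reversed <- truncate_to_glycine(reversed, residue_id("A", rn))
  }
  expect_identical(seqwise$atoms[order(seqwise$atoms$resno,
                                       seqwise$atoms$atom), ],
                   reversed$atoms[order(reversed$atoms$resno,
                                        reversed$atoms$atom), ])
})

test_that("grafting reproduces an engineered pose exactly", {
  hp <- suppressMessages(make_homolog_pair(fixture_spec(
    seed = 13, water = 272L,
    substitutions = default_homolog_substitutions())))
  # the fixture returns the transform mapping B onto A's frame; grafting
  # A's ligand into B must land it at the inverse image of its A pose
  g <- suppressWarnings(suppressMessages(
    graft_ligand(hp$a, hp$b, atom_selection(atom = "CA"),
                 keep_waters = 272L)))
  expect_lt(attr(g, "fit_rmsd"), 1e-9)
  lig_a <- select_atoms(hp$a, atom_selection(resname = "CB1"))
  lig_g <- select_atoms(g, atom_selection(resname = "CB1"))
  inv <- rigid_transform(t(hp$transform$rotation),
                         -as.numeric(t(hp$transform$rotation) %*%
                                       hp$transform$translation))
  expected <- apply_transform(coords_matrix(lig_a), inv)
  expect_lt(max(abs(coords_matrix(lig_g) - expected)), 1e-8)
  expect_true(any(is_water_row(g$atoms) & g$atoms$resno == 272L))
  # grafting onto a holo target is refused
  expect_error(graft_ligand(hp$a, hp$a, atom_selection(atom = "CA")),
               "already contains")
})

test_that("a self-graft is the identity on the ligand pose", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 17)))
  apo <- toy$structure
  holo <- apo
  apo$atoms <- apo$atoms[apo$atoms$resname != "CB1", ]
  g <- suppressWarnings(suppressMessages(
    graft_ligand(holo, apo, atom_selection(atom = "CA"))))
  expect_lt(attr(g, "fit_rmsd"), 1e-12)
  expect_lt(max(abs(
    coords_matrix(select_atoms(g, atom_selection(resname = "CB1"))) -
      coords_matrix(select_atoms(holo, atom_selection(resname = "CB1"))))),
    1e-10)
})

test_that("binding-site substitutions are found spatially, not by numbering", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 23)))
  s <- toy$structure
  site <- atom_selection(resno = unique(s$atoms$resno))
  none <- suppressMessages(binding_site_substitutions(s, s, site))
  expect_identical(sum(none$differs), 0L)
  hp <- suppressMessages(make_homolog_pair(fixture_spec(
    seed = 23, water = 272L,
    substitutions = default_homolog_substitutions())))
  subs <- suppressMessages(
    binding_site_substitutions(hp$a, hp$b, site))
  hits <- subs[subs$differs, ]
  expect_identical(sort(hits$resno_a), sort(hp$substitutions$resno))
  expect_identical(hits$name_b[order(hits$resno_a)],
                   hp$substitutions$to[order(hp$substitutions$resno)])
  # single engineered difference
  one <- suppressMessages(make_homolog_pair(fixture_spec(
    seed = 31, water = 272L,
    substitutions = data.frame(resno = 94L, to = "ALA"))))
  s1 <- suppressMessages(binding_site_substitutions(one$a, one$b, site))
  expect_identical(s1$resno_a[s1$differs], 94L)
})
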