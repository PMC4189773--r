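test_that("the 4 Angstrom cutoff is inclusive at the boundary", {
  near <- bare_structure(data.frame(
    resno = c(1L, 900L), resname = c("ALA", "XLG"),
    atom = c("X1", "L1"), element = c("C", "C"),
    x = c(0, 4.00), het = c(FALSE, TRUE)))
  far <- bare_structure(data.frame(
    resno = c(1L, 900L), resname = c("ALA", "XLG"),
    atom = c("X1", "L1"), element = c("C", "C"),
    x = c(0, 4.01), het = c(FALSE, TRUE)))
  sel <- atom_selection(resname = "XLG")
  expect_identical(nrow(enumerate_contacts(near, sel)), 1L)
  expect_identical(nrow(enumerate_contacts(far, sel)), 0L)
  expect_error(enumerate_contacts(near, atom_selection(resname = "ZZZ")),
               "no heavy atoms")
})

test_that("enumeration equals the brute-force all-pairs oracle on random fixtures", {
  for (seed in 1:25) {
    s <- random_loose_structure(seed)
    ct <- enumerate_contacts(s, atom_selection(resname = "XLG"))
    expect_identical(contact_keys(ct), brute_contacts(s, "XLG"),
                     info = paste("seed", seed))
  }
})

test_that("classification is a pure function of elements, distance and metal flag", {
  rec <- function(pe, le, d, metal = FALSE) {
    data.frame(protein_element = pe, ligand_element = le, distance = d,
               is_metal = metal, stringsAsFactors = FALSE)
  }
  tab <- rbind(rec("Zn", "N", 1.87, TRUE),   # coordination bond
               rec("Zn", "O", 3.05, TRUE),   # metal beyond cutoff
               rec("O", "N", 3.02, FALSE),   # polar
               rec("N", "N", 3.14, FALSE),   # just outside polar cutoff
               rec("C", "C", 3.50, FALSE),   # apolar
               rec("O", "B", 2.90, FALSE))   # boron never polar
  cls <- classify_contacts(tab)$contact_class
  expect_identical(cls, c("metal_coordination", "vdw", "polar", "vdw",
                          "vdw", "vdw"))
  # permutation invariance
  perm <- sample(nrow(tab))
  expect_identical(classify_contacts(tab[perm, ])$contact_class,
                   cls[perm])
})

test_that("the reported crystal-contact table classifies to exactly its bold rows", {
  rep_tab <- reported_contacts("caii")
  expect_identical(nrow(rep_tab), 39L)
  expect_identical(sum(is.na(rep_tab$resno)), 3L)       # three zinc rows
  el_of <- function(atom) substr(gsub("[0-9]", "", atom), 1L, 1L)
  tab <- data.frame(
    protein_element = ifelse(rep_tab$resname == "ZN", "Zn",
                             el_of(rep_tab$protein_atom)),
    ligand_element = el_of(rep_tab$ligand_atom),
    distance = rep_tab$distance,
    is_metal = rep_tab$resname == "ZN", stringsAsFactors = FALSE)
  cls <- classify_contacts(tab)$contact_class
  highlighted <- cls %in% c("polar", "metal_coordination")
  expect_identical(highlighted, rep_tab$polar)
  expect_identical(sum(highlighted), 4L)
})

test_that("dihydrogen bonds obey the distance and angle criteria", {
  # N-H ... H-B constructed near-linear at a given H...H distance
  build <- function(hh, donor_angle = 170, acceptor_angle = 170) {
    n <- c(0, 0, 0)
    h_protic <- c(1.01, 0, 0)
    h_hydridic <- h_protic + c(hh, 0, 0)
    # rotate the N off-axis to set the donor angle at the protic H
    th <- (180 - donor_angle) * pi / 180
    n <- h_protic - 1.01 * c(cos(th), sin(th), 0)
    tb <- (180 - acceptor_angle) * pi / 180
    b <- h_hydridic + 1.19 * c(cos(tb), -sin(tb), 0)
    bare_structure(data.frame(
      resno = c(1L, 1L, 900L, 900L),
      resname = c("TRP", "TRP", "CB1", "CB1"),
      atom = c("NE1", "HE1", "B3", "H3"),
      element = c("N", "H", "B", "H"),
      x = c(n[1], h_protic[1], b[1], h_hydridic[1]),
      y = c(n[2], h_protic[2], b[2], h_hydridic[2]),
      z = 0, het = c(FALSE, FALSE, TRUE, TRUE)))
  }
  sel <- atom_selection(resname = "CB1")
  hit <- detect_dihydrogen_bonds(build(2.3), sel)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$hh_distance, 2.3, tolerance = 1e-9)
  expect_gt(hit$donor_angle, 160)
  expect_identical(hit$protic_H, "HE1")
  expect_identical(hit$hydridic_H, "H3")
  expect_identical(nrow(detect_dihydrogen_bonds(build(2.5), sel)), 0L)
  expect_identical(nrow(detect_dihydrogen_bonds(
    build(2.0, donor_angle = 80), sel)), 0L)
  # missing hydrogens -> directs to add_hydrogens
  bald <- bare_structure(data.frame(
    resno = c(1L, 900L), resname = c("TRP", "CB1"),
    atom = c("NE1", "B3"), element = c("N", "B"), x = c(0, 3),
    het = c(FALSE, TRUE)))
  expect_error(detect_dihydrogen_bonds(bald, sel), "add_hydrogens")
})

test_that("residue-set comparison marks shared and polar contacts", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 2)))
  sel <- atom_selection(resname = "CB1")
  cmp <- contact_residue_sets(list(one = list(structure = toy$structure,
                                              ligand_sel = sel),
                                   two = list(structure = toy$structure,
                                              ligand_sel = sel)))
  expect_identical(cmp$one, cmp$two)            # identical complexes
  expect_true("P" %in% cmp$one)                 # anchors are polar
  expect_true(any(grepl("^ZN", cmp$residue)))
})

test_that("contact tables round-trip through TSV", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 4)))
  ct <- classify_contacts(
    enumerate_contacts(toy$structure, atom_selection(resname = "CB1")))
  p <- file.path(tempdir(), "contacts.tsv")
  write_contact_table(ct, p)
  back <- read_contact_table(p)
  expect_identical(nrow(back), nrow(ct))
  expect_equal(back$distance, ct$distance)
  expect_identical(back$contact_class, ct$contact_class)
  empty <- ct[0L, ]
  p2 <- file.path(tempdir(), "empty.tsv")
  write_contact_table(empty, p2)
  expect_identical(nrow(read_contact_table(p2)), 0L)
  expect_identical(length(readLines(p2)), 1L)   # header only
})
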