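test_that("PDB and mmCIF round-trips preserve atoms, numbering and ADPs", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 11)))
  s <- toy$structure
  for (fmt in c("pdb", "cif")) {
    path <- file.path(tempdir(), paste0("rt.", fmt))
    write_structure(s, path)
    s2 <- suppressWarnings(read_structure(path))
    expect_identical(nrow(s2$atoms), nrow(s$atoms))
    expect_identical(s2$atoms$atom, s$atoms$atom)
    expect_identical(s2$atoms$resno, s$atoms$resno)
    expect_identical(s2$atoms$resname, s$atoms$resname)
    expect_lt(max(abs(coords_matrix(s2$atoms) - coords_matrix(s$atoms))),
              5e-4 + 1e-9)
    expect_lt(max(abs(s2$atoms$occ - s$atoms$occ)), 0.005)
    expect_lt(max(abs(s2$atoms$adp - s$atoms$adp)), 0.005)
    expect_identical(toupper(s2$atoms$element), toupper(s$atoms$element))
  }
})

test_that("parse failures are explicit", {
  empty <- file.path(tempdir(), "empty.pdb")
  file.create(empty)
  expect_error(read_structure(empty))
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               "not found")
  weird <- file.path(tempdir(), "x.xyz")
  writeLines("not a structure", weird)
  expect_error(read_structure(weird), "format")
})

test_that("altloc records survive writing and the best-occupancy policy picks one", {
  lines <- c(
    "ATOM      1  N   THR A 199      10.000  10.000  10.000  1.00 10.00           N",
    "ATOM      2  CB ATHR A 199      12.000  11.400  10.000  0.60 12.00           C",
    "ATOM      3  CB BTHR A 199      12.100  11.300  10.100  0.40 12.50           C",
    "ATOM      4  OG1ATHR A 199      11.500  12.100  11.100  0.50 13.00           O",
    "ATOM      5  OG1BTHR A 199      11.600  12.000  11.200  0.50 13.50           O",
    "END")
  p <- file.path(tempdir(), "alt.pdb")
  writeLines(lines, p)
  s <- read_structure(p)
  expect_identical(nrow(s$atoms), 5L)           # all altlocs retained
  all_sel <- select_atoms(s, atom_selection(altloc = "all"))
  expect_identical(nrow(all_sel), 5L)
  best <- select_atoms(s)                       # default policy
  expect_identical(nrow(best), 3L)
  cb <- best[best$atom == "CB", ]
  expect_identical(cb$altloc, "A")              # higher occupancy wins
  og <- best[best$atom == "OG1", ]
  expect_identical(og$altloc, "A")              # tie -> alphabetic
  p2 <- file.path(tempdir(), "alt2.pdb")
  write_structure(s, p2)
  expect_identical(nrow(read_structure(p2)$atoms), 5L)
})

test_that("select_atoms is idempotent, deterministic and warns on unknown chains", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 3)))
  s <- toy$structure
  all_atoms <- select_atoms(s)
  expect_identical(select_atoms(bare_structure(all_atoms)), all_atoms)
  expect_identical(nrow(select_atoms(s, atom_selection())),
                   nrow(s$atoms))                # identity filter
  expect_warning(
    res <- select_atoms(s, atom_selection(chain = "Z")),
    "chain")
  expect_identical(nrow(res), 0L)
  none <- select_atoms(s, atom_selection(resname = c("TYR", "MET")))
  expect_identical(nrow(none), 0L)
  ca <- select_atoms(s, atom_selection(atom = "CA", resno = 90:125))
  in_range <- unique(s$atoms$resno[s$atoms$resno %in% 90:125 &
                                     s$atoms$resname %in% c(
                                       "ALA", "ARG", "ASN", "ASP", "CYS",
                                       "GLN", "GLU", "GLY", "HIS", "ILE",
                                       "LEU", "LYS", "MET", "PHE", "PRO",
                                       "SER", "THR", "TRP", "TYR", "VAL")])
  expect_identical(nrow(ca), length(in_range))   # one CA per residue
})

test_that("structure_stats reports counts and the unweighted mean ADP", {
  df <- data.frame(resno = c(1L, 1L, 2L, 3L), atom = c("X1", "X2", "O", "O"),
                   resname = c("ALA", "ALA", "HOH", "HOH"),
                   element = c("C", "C", "O", "O"),
                   adp = c(4, 6, 20, 30))
  s <- bare_structure(df)
  st <- structure_stats(s)
  expect_identical(st$n_atoms, 4L)
  expect_identical(st$n_residues, 3L)
  expect_identical(st$n_waters, 2L)
  expect_equal(st$mean_adp, 15)
  one <- structure_stats(s, atom_selection(resno = 1L, atom = "X1"))
  expect_equal(one$mean_adp, 4)
  two <- structure_stats(s, atom_selection(resno = 1L))
  expect_equal(two$mean_adp, 5)
  expect_error(structure_stats(s, atom_selection(resname = "TRP")),
               "empty")
})
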