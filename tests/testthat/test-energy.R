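test_that("pair energies match closed forms", {
  ffc <- load_forcefield(dielectric = "constant", dielectric_k = 1)
  i <- list(x = 0, y = 0, z = 0, charge = 1, eps = 0, sigma = 1)
  j <- list(x = 3.320637, y = 0, z = 0, charge = -1, eps = 0, sigma = 1)
  pe <- pair_energy(i, j, ffc)
  expect_equal(pe$elec, -100.0, tolerance = 1e-9)
  expect_equal(pe$vdw, 0)
  # LJ minimum is exactly -eps at 2^(1/6) sigma
  k <- list(x = 2^(1 / 6) * 3.4, y = 0, z = 0, charge = 0, eps = 0.25,
            sigma = 3.4)
  l <- list(x = 0, y = 0, z = 0, charge = 0, eps = 0.25, sigma = 3.4)
  expect_equal(pair_energy(k, l, ffc)$vdw, -0.25, tolerance = 1e-12)
  # symmetry and the full formula against a hand evaluation
  ffd <- load_forcefield()                     # eps(r) = 4r
  set.seed(12)
  a <- list(x = rnorm(1), y = rnorm(1), z = rnorm(1), charge = 0.31,
            eps = 0.17, sigma = 3.25)
  b <- list(x = rnorm(1) + 3, y = rnorm(1), z = rnorm(1), charge = -0.52,
            eps = 0.21, sigma = 2.96)
  r <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  sij <- (a$sigma + b$sigma) / 2
  eij <- sqrt(a$eps * b$eps)
  hand <- 332.0637 * a$charge * b$charge / (4 * r * r) +
    4 * eij * ((sij / r)^12 - (sij / r)^6)
  expect_equal(pair_energy(a, b, ffd)$total, hand, tolerance = 1e-12)
  expect_equal(pair_energy(b, a, ffd)$total, pair_energy(a, b, ffd)$total)
  expect_error(pair_energy(a, a, ffd), "singularity")
})

test_that("parameter assignment covers templates and names every offender", {
  ff <- load_forcefield()
  lig <- assign_parameters(add_hydrogens(build_ligand()), ff)
  expect_lt(abs(sum(lig$atoms$charge)), 1e-9)          # neutral compound
  expect_identical(sum(lig$atoms$vdw_type == "B"), 10L)
  wat <- assign_parameters(add_hydrogens(
    suppressMessages(ideal_residue("HOH"))), ff)
  expect_lt(abs(sum(wat$atoms$charge)), 1e-9)
  stray <- bare_structure(data.frame(resname = "ALA", atom = "QQ7",
                                     element = "C"))
  expect_error(assign_parameters(stray, ff), "QQ7")
  # residue template net charges are integral
  tab <- ff$params
  nets <- tapply(tab$charge, tab$res, sum)
  expect_true(all(abs(nets - round(nets)) < 1e-9))
})

test_that("interaction energy is additive over residues and rigid-motion invariant", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 14)))
  ff <- load_forcefield()
  s <- assign_parameters(add_hydrogens(toy$structure), ff)
  sel <- atom_selection(resname = "CB1")
  e <- interaction_energy(s, sel, ff)
  expect_equal(attr(e, "total"), sum(e$total), tolerance = 1e-9)
  expect_equal(e$total, e$elec + e$vdw, tolerance = 1e-12)
  # environment of two residues equals the sum of single-residue runs
  two <- s
  keep <- two$atoms$resno %in% c(94L, 199L) | two$atoms$resname == "CB1"
  two$atoms <- two$atoms[keep, ]
  e2 <- interaction_energy(two, sel, ff)
  for (rn in c(94L, 199L)) {
    one <- s
    one$atoms <- one$atoms[one$atoms$resno == rn |
                             one$atoms$resname == "CB1", ]
    e1 <- interaction_energy(one, sel, ff)
    expect_equal(e2$total[e2$resno == rn], e1$total, tolerance = 1e-12)
  }
  # rigid motion of the whole system changes nothing
  set.seed(3)
  tr <- rigid_transform(test_rotation(), runif(3L, -20, 20))
  e_rot <- interaction_energy(apply_transform(s, tr), sel, ff)
  expect_lt(max(abs(e_rot$total - e$total)), 1e-9)
  expect_lt(abs(attr(e_rot, "total") - attr(e, "total")), 1e-9)
})

test_that("zero-parameter ligands give exactly zero energy", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 14)))
  ff <- load_forcefield()
  s <- assign_parameters(add_hydrogens(toy$structure), ff)
  idx <- s$atoms$resname == "CB1"
  s$atoms$charge[idx] <- 0
  s$atoms$eps[idx] <- 0
  e <- interaction_energy(s, atom_selection(resname = "CB1"), ff)
  expect_identical(max(abs(e$total)), 0)
})

test_that("point-probe energies match the closed-form Coulomb ground truth", {
  for (seed in c(2L, 5L)) {
    px <- probe_complex("SER", distance = 2.74, seed = seed)
    s <- assign_parameters(px$structure, load_forcefield())
    e <- interaction_energy(s, atom_selection(resname = "LIG"))
    truth <- px$truth$probe_energies
    expect_equal(e$elec[match(truth$resno, e$resno)], truth$elec,
                 tolerance = 1e-9)
    expect_lt(max(abs(e$vdw)), 1e-12)          # probe has no well depth
  }
})

test_that("an attractive pair relaxes monotonically toward zero with distance", {
  ff <- load_forcefield()
  ds <- seq(2.5, 12, by = 0.5)
  es <- vapply(ds, function(d) {
    i <- list(x = 0, y = 0, z = 0, charge = 1, eps = 0, sigma = 1)
    j <- list(x = d, y = 0, z = 0, charge = -1, eps = 0, sigma = 1)
    pair_energy(i, j, ff)$elec
  }, numeric(1L))
  expect_true(all(diff(es) > 0))               # increasing toward 0
  expect_true(all(es < 0))
})
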