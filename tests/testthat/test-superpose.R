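test_that("kabsch_fit recovers applied rigid transforms and rejects reflections", {
  set.seed(101)
  for (rep in 1:20) {
    ref <- matrix(rnorm(30L, sd = 4), ncol = 3L)
    rot <- test_rotation()
    tr <- runif(3L, -10, 10)
    mov <- sweep(ref %*% t(rot), 2L, -tr)      # mov = R ref + t ... inverse view
    fit <- kabsch_fit(ref, mov)
    back <- apply_transform(mov, fit)
    expect_lt(max(abs(back - ref)), 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  # mirrored points cannot be fit by a proper rotation
  ref <- matrix(rnorm(24L, sd = 3), ncol = 3L)
  mir <- ref %*% diag(c(-1, 1, 1))
  fit <- kabsch_fit(ref, mir)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(rmsd(ref, apply_transform(mir, fit)), 0.1)
  # identity
  fit0 <- kabsch_fit(ref, ref)
  expect_lt(max(abs(fit0$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(fit0$translation)), 1e-10)
  # degenerate input
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_fit(line, line + 1), "collinear")
  expect_error(kabsch_fit(ref, ref[1:4, ]), "pairing")
})

test_that("kabsch fit beats random rigid placements (optimality property)", {
  set.seed(77)
  ref <- matrix(rnorm(24L, sd = 3), ncol = 3L)
  mov <- ref + matrix(rnorm(24L, sd = 0.6), ncol = 3L)
  fit_rmsd <- rmsd(ref, apply_transform(mov, kabsch_fit(ref, mov)))
  mc <- sweep(mov, 2L, colMeans(mov))
  rc_mean <- colMeans(ref)
  for (i in 1:1000) {
    r <- test_rotation()
    cand <- sweep(mc %*% t(r), 2L, -rc_mean)
    expect_gte(rmsd(ref, cand), fit_rmsd - 1e-12)
  }
})

test_that("rmsd is symmetric, rigid-motion invariant and matches hand values", {
  a <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3L, byrow = TRUE)
  b <- a + matrix(c(0, 1, 0, 0, 1, 0), ncol = 3L, byrow = TRUE)
  expect_equal(rmsd(a, b), 1.0)
  expect_identical(rmsd(a, b), rmsd(b, a))
  expect_equal(rmsd(a, a), 0)
  set.seed(5)
  x <- matrix(rnorm(30L), ncol = 3L)
  y <- matrix(rnorm(30L), ncol = 3L)
  r <- test_rotation(); t <- runif(3L)
  tr <- rigid_transform(r, t)
  expect_equal(rmsd(apply_transform(x, tr), apply_transform(y, tr)),
               rmsd(x, y), tolerance = 1e-10)
  expect_error(rmsd(x, y[1:5, ]), "pairing")
})

test_that("structure superposition is exact on itself and on rigidly moved copies", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 21)))
  s <- toy$structure
  self <- superpose_structures(s, s)
  expect_lt(self$rmsd, 1e-12)
  expect_lt(max(abs(self$transform$rotation - diag(3))), 1e-9)
  set.seed(8)
  tr <- rigid_transform(test_rotation(), runif(3L, -5, 5))
  moved <- apply_transform(s, tr)
  fit <- superpose_structures(s, moved)
  expect_lt(fit$rmsd, 1e-9)
  expect_gt(fit$n_atoms, 10L)
  tiny <- tiny_protein(c("GLY", "ALA"))
  expect_error(superpose_structures(tiny, tiny,
                                    atom_selection(atom = "CA")),
               "underdetermined")
})

test_that("per-residue deviation localises an engineered displacement", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 33)))
  ref <- toy$structure
  mov <- ref
  idx <- mov$atoms$resno == 131                 # displace one residue
  mov$atoms$x[idx] <- mov$atoms$x[idx] + 2.0
  fit_sel <- atom_selection(atom = "CA",
                            resno = setdiff(unique(ref$atoms$resno), 131L))
  dev <- suppressMessages(
    per_residue_deviation(ref, mov, sel = atom_selection(atom = "CA"),
                          fit_sel = fit_sel))
  expect_equal(attr(dev, "argmax")$resno, 131L)
  expect_equal(attr(dev, "max"), 2.0, tolerance = 1e-9)
  others <- dev$deviation[dev$resno != 131L]
  expect_lt(max(others), 1e-9)
  dev0 <- suppressMessages(per_residue_deviation(ref, ref))
  expect_lt(max(dev0$deviation), 1e-12)
})
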