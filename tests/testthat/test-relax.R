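test_that("FIRE reaches analytic minima of harmonic and LJ objectives", {
  for (seed in c(3L, 11L, 29L)) {
    fx <- make_minimization_fixture("harmonic", seed = seed)
    r <- fire_minimize(fx$start, fx$fn, fx$gr,
                       minimizer_settings(ftol = 1e-8))
    expect_true(r$converged)
    expect_lt(sqrt(sum((r$par - fx$optimum)^2)), 1e-6)
    expect_lte(r$energy, fx$fn(fx$start))
  }
  fx <- make_minimization_fixture("lj_dimer", seed = 7L)
  r <- fire_minimize(fx$start, fx$fn, fx$gr,
                     minimizer_settings(ftol = 1e-9, dt_init = 0.05))
  expect_lt(abs(sqrt(sum(r$par^2)) - fx$opt_separation), 1e-6)
  expect_equal(r$energy, -0.25, tolerance = 1e-9)
})

test_that("FIRE energy never increases and beats a steepest-descent reference", {
  fx <- make_minimization_fixture("cluster", seed = 7L)
  r <- fire_minimize(fx$start, fx$fn, fx$gr,
                     minimizer_settings(ftol = 1e-6, max_iter = 3000L))
  expect_lte(r$energy, fx$fn(fx$start))
  expect_lte(r$energy, fx$reference_energy + 1e-9)
  # non-finite start is refused with advice
  expect_error(fire_minimize(c(0, 0, 0),
                             function(p) 1 / sum(p^2),
                             function(p) -2 * p / sum(p^2)^2,
                             minimizer_settings()),
               "pre-separate")
})

test_that("binding-site relaxation lowers energy and freezes the frozen", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(seed = 19)))
  ff <- load_forcefield()
  s <- assign_parameters(add_hydrogens(toy$structure), ff)
  movable <- list(residue_id("A", 199L), residue_id("A", 200L))
  out <- relax_binding_site(s, movable, atom_selection(resname = "CB1"),
                            ff, minimizer_settings(max_iter = 300L))
  fire <- attr(out, "fire")
  expect_lte(fire$energy_final, fire$energy_initial)
  moved_res <- c(199L, 200L, 301L)
  frozen_in <- s$atoms[!(s$atoms$resno %in% moved_res), ]
  frozen_out <- out$atoms[!(out$atoms$resno %in% moved_res), ]
  expect_identical(coords_matrix(frozen_out), coords_matrix(frozen_in))
  # empty movable set is the identity
  idem <- relax_binding_site(s, list(), NULL, ff)
  expect_identical(coords_matrix(idem$atoms), coords_matrix(s$atoms))
})

test_that("relaxation resolves an engineered 1.2 Angstrom clash", {
  toy <- suppressMessages(make_toy_complex(fixture_spec(
    seed = 25,
    residues = data.frame(resname = c("VAL", "THR"), resno = c(50L, 199L),
                          res_atom = c("CG1", "OG1"),
                          lig_atom = c("B7", "N2"),
                          distance = c(1.2, 2.74)))))
  ff <- load_forcefield()
  s <- assign_parameters(add_hydrogens(toy$structure), ff)
  out <- relax_binding_site(s, list(residue_id("A", 50L)), NULL, ff,
                            minimizer_settings(max_iter = 600L))
  a <- out$atoms
  val <- a[a$resno == 50L & toupper(a$element) != "H", ]
  lig <- a[a$resname == "CB1", ]
  vm <- coords_matrix(val); lm <- coords_matrix(lig)
  dmin <- min(sqrt(outer(rowSums(vm^2), rowSums(lm^2), "+") -
                     2 * vm %*% t(lm)))
  expect_gte(dmin, 2.4)
})

test_that("FIRE matches the analytic minimiser of random quadratics", {
  set.seed(4)
  for (rep in 1:5) {
    center <- rnorm(6L, sd = 3)
    w <- runif(6L, 0.5, 4)
    fn <- function(p) sum(w * (p - center)^2)
    gr <- function(p) 2 * w * (p - center)
    r <- fire_minimize(center + rnorm(6L, sd = 2), fn, gr,
                       minimizer_settings(ftol = 1e-9))
    expect_lt(max(abs(r$par - center)), 1e-6)
  }
})
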