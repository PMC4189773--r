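#' FIRE minimiser settings
#'
#' Parameters of the Fast Inertial Relaxation Engine, following the
#' original published scheme: velocity mixing factor alpha starting at
#' 0.1 and decaying by 0.99 after each of at least 5 consecutive
#' downhill steps, time step growing by 1.1 up to `dt_max` and halved
#' (with velocity reset) on uphill steps.
#'
#' @param dt_init initial time step.
#' @param dt_max time-step cap (default 10 * dt_init).
#' @param f_inc,f_dec,alpha_start,f_alpha,n_min FIRE constants.
#' @param ftol convergence threshold on the maximum force component,
#'   kcal/mol/Angstrom.
#' @param max_iter iteration cap.
#' @param max_step largest per-coordinate displacement in one step,
#'   Angstrom (keeps early steps finite on strained starts).
#' @return A `carb_fire_settings` list.
#' @export
minimizer_settings <- function(dt_init = 0.02, dt_max = 10 * dt_init,
                               f_inc = 1.1, f_dec = 0.5,
                               alpha_start = 0.1, f_alpha = 0.99,
                               n_min = 5L, ftol = 0.05,
                               max_iter = 5000L, max_step = 0.2) {
  stopifnot(f_dec > 0, f_dec < 1, f_inc > 1, alpha_start > 0,
            alpha_start < 1, ftol > 0, dt_init > 0, dt_max >= dt_init,
            max_step > 0)
  structure(list(dt_init = dt_init, dt_max = dt_max, f_inc = f_inc,
                 f_dec = f_dec, alpha_start = alpha_start,
                 f_alpha = f_alpha, n_min = as.integer(n_min),
                 ftol = ftol, max_iter = as.integer(max_iter),
                 max_step = max_step),
            class = "carb_fire_settings")
}

#' FIRE minimisation of a differentiable objective
#'
#' Semi-implicit Euler dynamics with FIRE velocity mixing on a free
#' coordinate vector. The returned point never has higher energy than
#' the best visited configuration (the best point is tracked and
#' returned).
#'
#' @param par numeric start vector.
#' @param fn objective: `fn(par)` returns energy (kcal/mol).
#' @param gr gradient: `gr(par)` returns d(energy)/d(par).
#' @param settings a [minimizer_settings()] object.
#' @return List: `par`, `energy`, `iterations`, `converged`,
#'   `max_force` (largest force component at the returned point).
#' @export
fire_minimize <- function(par, fn, gr, settings = minimizer_settings()) {
  e0 <- fn(par)
  g <- gr(par)
  if (!all(is.finite(e0)) || !all(is.finite(g))) {
    stop("non-finite energy or gradient at the start; ",
         "pre-separate clashing atoms before minimising")
  }
  v <- numeric(length(par))
  dt <- settings$dt_init
  alpha <- settings$alpha_start
  npos <- 0L
  best_par <- par; best_e <- e0
  it <- 0L
  converged <- FALSE
  while (it < settings$max_iter) {
    it <- it + 1L
    f <- -g
    if (max(abs(f)) <= settings$ftol) { converged <- TRUE; break }
    p <- sum(f * v)
    if (p < 0) {                 # uphill: brake and reset
      npos <- 0L
      dt <- dt * settings$f_dec
      alpha <- settings$alpha_start
      v[] <- 0
    } else if (p > 0) {
      npos <- npos + 1L
      if (npos > settings$n_min) {
        dt <- min(dt * settings$f_inc, settings$dt_max)
        alpha <- alpha * settings$f_alpha
      }
    }
    v <- v + dt * f
    fn_norm <- sqrt(sum(f * f))
    vn <- sqrt(sum(v * v))
    if (fn_norm > 0) {
      v <- (1 - alpha) * v + alpha * vn * f / fn_norm
    }
    step <- dt * v
    smax <- max(abs(step))
    if (smax > settings$max_step) step <- step * (settings$max_step / smax)
    par <- par + step
    g <- gr(par)
    e <- fn(par)
    if (!all(is.finite(e)) || !all(is.finite(g))) {
      # blown-up step: restart from the best point with smaller dt
      par <- best_par; g <- gr(par); v[] <- 0
      dt <- dt * settings$f_dec
      next
    }
    if (e < best_e) { best_e <- e; best_par <- par }
  }
  f_best <- -gr(best_par)
  list(par = best_par, energy = best_e, iterations = it,
       converged = converged || max(abs(f_best)) <= settings$ftol,
       max_force = max(abs(f_best)))
}

# Build the relaxation objective for a structure: nonbonded terms over
# every pair with at least one movable atom (1-2 and 1-3 pairs
# excluded), plus harmonic restraints holding bonds (k = 300
# kcal/mol/A^2) and 1-3 distances (k = 60) at their input values.
# Returns fn/gr closures over the movable coordinates.
build_relax_objective <- function(s, movable, kb = 300, ka = 60) {
  a <- s$atoms
  n <- nrow(a)
  xyz0 <- coords_matrix(a)
  bonds <- structure_bonds(s)
  angles <- angle_pairs(bonds, n)
  excl <- rbind(bonds, angles)
  excl_key <- paste(excl[, 1L], excl[, 2L])
  mov <- which(movable)
  # nonbonded pair list: movable x all, minus exclusions, frozen-frozen
  pi_ <- rep(mov, each = n)
  pj <- rep(seq_len(n), times = length(mov))
  keep <- pi_ != pj & !(pj %in% mov & pj < pi_)  # unique unordered pairs
  pi_ <- pi_[keep]; pj <- pj[keep]
  kmin <- pmin(pi_, pj); kmax <- pmax(pi_, pj)
  nb_keep <- !(paste(kmin, kmax) %in% excl_key)
  pi_ <- pi_[nb_keep]; pj <- pj[nb_keep]
  qq <- a$charge[pi_] * a$charge[pj]
  epsij <- sqrt(a$eps[pi_] * a$eps[pj])
  sigij <- (a$sigma[pi_] + a$sigma[pj]) / 2
  # restraints involving at least one movable atom
  keep_b <- (bonds[, 1L] %in% mov) | (bonds[, 2L] %in% mov)
  rb <- bonds[keep_b, , drop = FALSE]
  rb0 <- sqrt(rowSums((xyz0[rb[, 1L], , drop = FALSE] -
                         xyz0[rb[, 2L], , drop = FALSE])^2))
  keep_a <- (angles[, 1L] %in% mov) | (angles[, 2L] %in% mov)
  ra <- angles[keep_a, , drop = FALSE]
  ra0 <- sqrt(rowSums((xyz0[ra[, 1L], , drop = FALSE] -
                         xyz0[ra[, 2L], , drop = FALSE])^2))
  ff <- attr(s, "forcefield")
  full_xyz <- xyz0
  unpack <- function(par) {
    x <- full_xyz
    x[mov, ] <- matrix(par, ncol = 3L, byrow = TRUE)
    x
  }
  pair_r <- function(x, ii, jj) {
    dx <- x[ii, , drop = FALSE] - x[jj, , drop = FALSE]
    list(dx = dx, r = sqrt(rowSums(dx^2)))
  }
  fn <- function(par) {
    x <- unpack(par)
    e <- 0
    if (length(pi_) > 0L) {
      pr <- pair_r(x, pi_, pj)
      te <- nb_energy_terms(pr$r, qq, epsij, sigij, ff)
      e <- e + sum(te$elec) + sum(te$vdw)
    }
    if (nrow(rb) > 0L) {
      pr <- pair_r(x, rb[, 1L], rb[, 2L])
      e <- e + sum(kb * (pr$r - rb0)^2)
    }
    if (nrow(ra) > 0L) {
      pr <- pair_r(x, ra[, 1L], ra[, 2L])
      e <- e + sum(ka * (pr$r - ra0)^2)
    }
    e
  }
  gr <- function(par) {
    x <- unpack(par)
    g <- matrix(0, nrow = n, ncol = 3L)
    acc <- function(ii, jj, dEdr, dx, r) {
      w <- dEdr / r
      gij <- dx * w
      for (k in 1:3) {
        g[, k] <<- g[, k] + tabulate_add(ii, gij[, k], n) -
          tabulate_add(jj, gij[, k], n)
      }
    }
    if (length(pi_) > 0L) {
      pr <- pair_r(x, pi_, pj)
      dEdr <- nb_energy_deriv(pr$r, qq, epsij, sigij, ff)
      acc(pi_, pj, dEdr, pr$dx, pr$r)
    }
    if (nrow(rb) > 0L) {
      pr <- pair_r(x, rb[, 1L], rb[, 2L])
      acc(rb[, 1L], rb[, 2L], 2 * kb * (pr$r - rb0), pr$dx, pr$r)
    }
    if (nrow(ra) > 0L) {
      pr <- pair_r(x, ra[, 1L], ra[, 2L])
      acc(ra[, 1L], ra[, 2L], 2 * ka * (pr$r - ra0), pr$dx, pr$r)
    }
    as.vector(t(g[mov, , drop = FALSE]))
  }
  list(fn = fn, gr = gr, movable_idx = mov)
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}


# Resolve hard overlaps before minimisation: movable heavy atoms closer
# than `cutoff` to any non-bonded heavy atom are pushed apart in small
# deterministic sweeps, so FIRE starts from finite forces. Covalent
# geometry disturbed here is restored by the relaxation restraints.
pre_separate <- function(s, movable, cutoff = 1.7, max_sweeps = 200L) {
  a <- s$atoms
  # every atom with its own LJ volume takes part (all heavy atoms plus
  # the hydridic cage hydrogens; polar/aliphatic H are volume-free)
  heavy <- toupper(a$element) != "H" |
    (!is.null(a$eps) & !is.na(a$eps) & a$eps > 0)
  bonds <- structure_bonds(s)
  excl <- rbind(bonds, angle_pairs(bonds, nrow(a)))
  excl_key <- paste(pmin(excl[, 1L], excl[, 2L]),
                    pmax(excl[, 1L], excl[, 2L]))
  xyz <- coords_matrix(a)
  mov_heavy <- which(movable & heavy)
  others <- which(heavy)
  for (sweep_i in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in mov_heavy) {
      d <- sqrt(colSums((t(xyz[others, , drop = FALSE]) - xyz[i, ])^2))
      close <- others[d < cutoff & others != i]
      close <- close[!(paste(pmin(close, i), pmax(close, i)) %in% excl_key)]
      for (j in close) {
        dx <- xyz[i, ] - xyz[j, ]
        dn <- sqrt(sum(dx * dx))
        push <- if (dn < 1e-6) c(cutoff, 0, 0) else dx / dn *
          (cutoff - dn)
        if (movable[j]) {
          xyz[i, ] <- xyz[i, ] + 0.5 * push
          xyz[j, ] <- xyz[j, ] - 0.5 * push
        } else {
          xyz[i, ] <- xyz[i, ] + push
        }
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  set_coords(s, xyz)
}

#' Relax a binding site with FIRE
#'
#' Minimises the nonbonded energy of the movable atoms (listed residues
#' plus the ligand) in the field of the frozen remainder, with harmonic
#' restraints holding covalent bond lengths and 1-3 distances at their
#' input values (the energy model itself is nonbonded-only). Frozen
#' atoms are bit-identical on return; the returned configuration never
#' has higher energy than the input.
#'
#' @param s a parameterised, protonated `carb_structure` (attach the
#'   force field via `attr(s, "forcefield") <- ff` or pass `ff`).
#' @param movable_residues list of [residue_id()]s free to move.
#' @param ligand_sel ligand selection; ligand atoms are movable unless
#'   `NULL`.
#' @param ff a [load_forcefield()] object.
#' @param settings a [minimizer_settings()] object.
#' @return The relaxed structure, with attribute `fire` (trajectory
#'   summary: energies, iterations, convergence flag).
#' @export
relax_binding_site <- function(s, movable_residues, ligand_sel = NULL,
                               ff = load_forcefield(),
                               settings = minimizer_settings()) {
  if (!is_parameterized(s)) {
    stop("structure is not parameterised: run assign_parameters() first")
  }
  a <- s$atoms
  movable <- rep(FALSE, nrow(a))
  key <- residue_key(a)
  for (rid in movable_residues) {
    movable[key == resid_key(rid)] <- TRUE
  }
  if (!is.null(ligand_sel)) {
    lig <- select_atoms(s, ligand_sel)
    movable[key %in% unique(residue_key(lig))] <- TRUE
  }
  if (!any(movable)) {
    attr(s, "fire") <- list(energy_initial = NA_real_,
                            energy_final = NA_real_, iterations = 0L,
                            converged = TRUE, note = "empty movable set")
    return(s)
  }
  attr(s, "forcefield") <- ff
  s <- pre_separate(s, movable)
  obj <- build_relax_objective(s, movable)
  par0 <- as.vector(t(coords_matrix(a)[obj$movable_idx, , drop = FALSE]))
  e0 <- obj$fn(par0)
  res <- fire_minimize(par0, obj$fn, obj$gr, settings)
  if (res$energy > e0) {             # never return uphill
    res$par <- par0; res$energy <- e0
  }
  xyz <- coords_matrix(a)
  xyz[obj$movable_idx, ] <- matrix(res$par, ncol = 3L, byrow = TRUE)
  out <- set_coords(s, xyz)
  attr(out, "fire") <- list(energy_initial = e0, energy_final = res$energy,
                            iterations = res$iterations,
                            converged = res$converged,
                            max_force = res$max_force)
  out
}
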