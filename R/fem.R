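# Vectorized 3x3 helpers on M x 9 column-major-per-row matrices
# (entry (r, c) of tet t lives in column (c-1)*3 + r of row t).
mat9_mul <- function(A, B) {
  C <- matrix(0, nrow(A), 9)
  for (cc in 1:3) for (r in 1:3) {
    acc <- 0
    for (k in 1:3)
      acc <- acc + A[, (k - 1) * 3 + r] * B[, (cc - 1) * 3 + k]
    C[, (cc - 1) * 3 + r] <- acc
  }
  C
}

mat9_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 8] * A[, 6]) -
    A[, 4] * (A[, 2] * A[, 9] - A[, 8] * A[, 3]) +
    A[, 7] * (A[, 2] * A[, 6] - A[, 5] * A[, 3])
}

mat9_inv <- function(A) {
  d <- mat9_det(A)
  if (any(abs(d) < 1e-300)) stop("singular 3x3 matrix in growth/reference data")
  inv <- matrix(0, nrow(A), 9)
  inv[, 1] <- (A[, 5] * A[, 9] - A[, 8] * A[, 6]) / d
  inv[, 2] <- -(A[, 2] * A[, 9] - A[, 8] * A[, 3]) / d
  inv[, 3] <- (A[, 2] * A[, 6] - A[, 5] * A[, 3]) / d
  inv[, 4] <- -(A[, 4] * A[, 9] - A[, 7] * A[, 6]) / d
  inv[, 5] <- (A[, 1] * A[, 9] - A[, 7] * A[, 3]) / d
  inv[, 6] <- -(A[, 1] * A[, 6] - A[, 4] * A[, 3]) / d
  inv[, 7] <- (A[, 4] * A[, 8] - A[, 7] * A[, 5]) / d
  inv[, 8] <- -(A[, 1] * A[, 8] - A[, 7] * A[, 2]) / d
  inv[, 9] <- (A[, 1] * A[, 5] - A[, 4] * A[, 2]) / d
  inv
}

# reference shape matrices Ahat = [x1-x0 x2-x0 x3-x0] per tet, M x 9
reference_shape_matrices <- function(mesh) {
  p0 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  out <- matrix(0, nrow(mesh$tets), 9)
  for (c in 1:3) {
    d <- mesh$nodes[mesh$tets[, c + 1], , drop = FALSE] - p0
    out[, (c - 1) * 3 + (1:3)] <- d
  }
  out
}

#' Neo-Hookean strain energy density
#'
#' \deqn{W = \frac{\mu}{2}\left[\mathrm{Tr}(F F^T) J^{-2/3} - 3\right] +
#'        \frac{K}{2} (J - 1)^2}
#' with `J = det(F)`. `W >= 0`, vanishing iff `F` is a rotation.
#'
#' @param F 3 x 3 elastic deformation gradient with `det(F) > 0`.
#' @param mu shear modulus.
#' @param K bulk modulus.
#' @return energy density (same units as `mu`).
#' @export
strain_energy_density <- function(F, mu, K) {
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("inverted element: det(F) = ", signif(J, 4))
  mu / 2 * (sum(F * F) * J^(-2 / 3) - 3) + K / 2 * (J - 1)^2
}

#' Cauchy stress of the neo-Hookean model
#'
#' \eqn{\sigma = J^{-1} (\partial W/\partial F) F^T}, which for the energy of
#' [strain_energy_density()] reduces to the closed form
#' \eqn{\sigma = \mu J^{-5/3} \mathrm{dev}(F F^T) + K (J - 1) I}
#' (verified against finite differences of `W` in the test suite).
#'
#' @inheritParams strain_energy_density
#' @return symmetric 3 x 3 Cauchy stress.
#' @export
cauchy_stress <- function(F, mu, K) {
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("inverted element: det(F) = ", signif(J, 4))
  b <- tcrossprod(F)
  mu * J^(-5 / 3) * (b - diag(3) * sum(diag(b)) / 3) + K * (J - 1) * diag(3)
}

#' Dynamic-relaxation solver configuration
#'
#' Controls the damped second-order pseudo-time integration used to find
#' elastic equilibria. The pseudo time step is
#' `dt = dt_factor * a / sqrt(K_max)` (with `a` the mean node spacing and
#' `K_max` the largest bulk modulus), the node mass is `m = a^3`, and the
#' viscous damping starts at `gamma0_factor * m` and is halved whenever the
#' energy decrease over a window stagnates, floored at
#' `gamma_floor_factor * m`. Convergence requires the elastic energy to
#' change by less than `energy_rel_tol` over `energy_window` iterations and
#' the per-step node displacement to fall below `disp_tol * a`.
#'
#' @param dt_factor pseudo-time-step factor (dimensionless).
#' @param gamma0_factor initial damping, in units of the node mass.
#' @param gamma_floor_factor damping floor, in units of the node mass.
#' @param energy_window convergence window (iterations).
#' @param energy_rel_tol relative energy tolerance over the window.
#' @param disp_tol per-step displacement tolerance, in units of `a`.
#' @param max_iterations iteration cap.
#' @param check_every bookkeeping interval (iterations).
#' @param perturbation_amplitude seeded symmetry-breaking surface
#'   perturbation, as a fraction of the sheet thickness (0 disables).
#' @param rng_seed seed for the perturbation.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(dt_factor = 0.01, gamma0_factor = 10,
                          gamma_floor_factor = 0.1,
                          energy_window = 1e5, energy_rel_tol = 0.001,
                          disp_tol = 1e-6, max_iterations = 2e6,
                          check_every = 50,
                          perturbation_amplitude = 1e-3, rng_seed = 1L) {
  stopifnot(dt_factor > 0, energy_window > 0, energy_rel_tol > 0,
            disp_tol > 0, max_iterations > 0, check_every > 0,
            perturbation_amplitude >= 0)
  structure(list(dt_factor = dt_factor, gamma0_factor = gamma0_factor,
                 gamma_floor_factor = gamma_floor_factor,
                 energy_window = as.integer(energy_window),
                 energy_rel_tol = energy_rel_tol, disp_tol = disp_tol,
                 max_iterations = as.integer(max_iterations),
                 check_every = as.integer(check_every),
                 perturbation_amplitude = perturbation_amplitude,
                 rng_seed = as.integer(rng_seed)), class = "solver_config")
}

#' Initial solver state for a mesh
#' @param mesh a `tet_mesh`.
#' @return an object of class `solver_state` at the reference configuration.
#' @export
init_state <- function(mesh) {
  structure(list(x = mesh$nodes, v = matrix(0, nrow(mesh$nodes), 3),
                 iteration = 0L, converged = FALSE, energy = NA_real_,
                 history = NULL, perturbation_applied = FALSE),
            class = "solver_state")
}

# per-node constraint codes: 0 free, 1 fixed, 2 crease line (move along C),
# 3 crease plane (zero normal displacement)
node_constraint_codes <- function(mesh, mode = c("AUTO", "SINGLE_SHEET",
                                                 "MULTI_LAYER")) {
  mode <- match.arg(mode)
  if (mode == "AUTO")
    mode <- if (any(mesh$region == "SUBSTRATE")) "MULTI_LAYER" else "SINGLE_SHEET"
  code <- integer(nrow(mesh$nodes))
  code[mesh$node_sets$CREASE] <- if (mode == "SINGLE_SHEET") 2L else 3L
  code[mesh$node_sets$PLANE_CONFINED] <- 3L  # strip end faces
  code[mesh$node_sets$FIXED_INNER] <- 1L
  code
}

#' Apply kinematic constraints to a nodal vector field
#'
#' Fixed-boundary nodes get zero vectors; in `SINGLE_SHEET` mode crease
#' nodes keep only their component along the crease direction `C`; in
#' `MULTI_LAYER` mode crease nodes lose their component along the
#' crease-plane normal (they stay in the sagittal plane).
#'
#' @param field N x 3 matrix (forces or velocities).
#' @param mesh a `tet_mesh`.
#' @param mode `"SINGLE_SHEET"`, `"MULTI_LAYER"`, or `"AUTO"` (multi-layer
#'   iff the mesh has a substrate region).
#' @return the projected field.
#' @export
apply_constraints <- function(field, mesh, mode = "AUTO") {
  code <- node_constraint_codes(mesh, mode)
  field[code == 1L, ] <- 0
  if (any(code == 2L)) {
    C <- mesh$crease_direction
    idx <- which(code == 2L)
    d <- field[idx, , drop = FALSE] %*% C
    field[idx, ] <- d %*% t(C)
  }
  if (any(code == 3L)) {
    n <- mesh$crease_plane_normal
    idx <- which(code == 3L)
    d <- field[idx, , drop = FALSE] %*% n
    field[idx, ] <- field[idx, , drop = FALSE] - d %*% t(n)
  }
  field
}

# per-tet material vectors and (G Ahat)^{-1}, det(G) V_ref
solver_arrays <- function(mesh, growth, materials) {
  reg <- mesh$region
  mu <- vapply(materials, `[[`, numeric(1), "mu")[reg]
  K <- vapply(materials, `[[`, numeric(1), "K")[reg]
  Ahat <- reference_shape_matrices(mesh)
  GA <- mat9_mul(growth$G, Ahat)
  list(mu = unname(mu), K = unname(K), Binv = mat9_inv(GA),
       volg = growth$detG * mesh$volumes)
}

#' Assemble nodal forces and total elastic energy
#'
#' For each tet the elastic deformation gradient is `F = A (G Ahat)^{-1}`;
#' the traction on each deformed face, `s_i = -sigma n_i` with `n_i` the
#' area-weighted outward face normal, is distributed equally to the three
#' face vertices. For linear tets the assembled forces equal minus the
#' gradient of the total elastic energy.
#'
#' @param state a `solver_state` (its `x` is used), or an N x 3 matrix.
#' @param mesh a `tet_mesh`.
#' @param growth an `element_growth` from [growth_field()].
#' @param materials named list of [material()] per region.
#' @return list with `forces` (N x 3), `energy` (scalar), and
#'   `inverted_tet` (`NULL`, or the index of an inverted element).
#' @export
assemble_nodal_forces <- function(state, mesh, growth, materials) {
  x <- if (inherits(state, "solver_state")) state$x else state
  arr <- solver_arrays(mesh, growth, materials)
  .forces_energy_cpp(x, mesh$tets, arr$Binv, arr$mu, arr$K, arr$volg)
}

#' Relax a grown configuration to elastic equilibrium
#'
#' Damped second-order dynamics
#' `v <- v + (f - gamma v) dt / m ; x <- x + v dt`
#' run until the energy and displacement criteria of the [solver_config()]
#' are met. On the first call for a fresh state a seeded symmetry-breaking
#' perturbation (amplitude `perturbation_amplitude * T`, anterior-surface
#' nodes) is applied before stepping; without it the discretized symmetric
#' problem can stall on an unstable flat branch.
#'
#' @param state a `solver_state` (fresh from [init_state()] or warm from a
#'   previous relaxation).
#' @param mesh a `tet_mesh`.
#' @param growth an `element_growth`.
#' @param materials named list of [material()] per region.
#' @param config a [solver_config()].
#' @param mode constraint mode, see [apply_constraints()].
#' @return the converged `solver_state` (check `$converged`).
#' @export
relax_to_steady_state <- function(state, mesh, growth, materials,
                                  config = solver_config(), mode = "AUTO") {
  stopifnot(inherits(state, "solver_state"), inherits(config, "solver_config"))
  arr <- solver_arrays(mesh, growth, materials)
  code <- node_constraint_codes(mesh, mode)
  a <- mesh$spacing_a
  mass <- a^3
  dt <- config$dt_factor * a / sqrt(max(arr$K))
  x <- state$x
  if (state$iteration == 0L && !state$perturbation_applied &&
      config$perturbation_amplitude > 0) {
    x <- x + make_perturbation(mesh, config$perturbation_amplitude,
                               config$rng_seed)
    state$perturbation_applied <- TRUE
  }
  cdir <- if (!is.null(mesh$crease_direction)) mesh$crease_direction else c(0, 1, 0)
  cnorm <- if (!is.null(mesh$crease_plane_normal)) mesh$crease_plane_normal else c(1, 0, 0)
  res <- .relax_cpp(x, state$v, mesh$tets, arr$Binv, arr$mu, arr$K, arr$volg,
                    code, cdir, cnorm, dt, mass,
                    config$gamma0_factor * mass,
                    config$gamma_floor_factor * mass,
                    config$energy_window, config$energy_rel_tol,
                    config$disp_tol * a, config$max_iterations,
                    config$check_every)
  state$x <- res$x
  state$v <- res$v
  state$iteration <- state$iteration + res$iterations
  state$converged <- res$converged
  state$energy <- res$energy
  state$max_step <- res$max_step
  state$dt_used <- res$dt_final
  state$gamma_final <- res$gamma_final
  state$history <- rbind(state$history, res$history)
  if (!res$converged)
    warning("relaxation hit max_iterations (", res$iterations,
            ") with max step ", signif(res$max_step, 3), " mm")
  state
}

#' Apply a full growth state at once and relax
#'
#' The apply-at-once driver: the growth tensors for the final targets are
#' built, the state is relaxed to equilibrium, and morphometrics are
#' computed on the converged configuration.
#'
#' @param mesh a `tet_mesh`.
#' @param targets a [growth_targets()].
#' @param materials named list of [material()] per region (single-region
#'   meshes need only `SKIN`).
#' @param config a [solver_config()].
#' @param growth_mode passed to [growth_field()] (default: `"uniform"` for
#'   single-sheet meshes, `"attenuated"` for bilayers).
#' @param direction optional uniaxial growth direction (strips).
#' @param mode constraint mode.
#' @return list with `state` (converged `solver_state`) and `report`
#'   (a [ridge_report()]).
#' @export
run_static_growth <- function(mesh, targets, materials,
                              config = solver_config(), growth_mode = NULL,
                              direction = NULL, mode = "AUTO") {
  if (is.null(growth_mode))
    growth_mode <- if (any(mesh$region == "SUBSTRATE")) "attenuated" else "uniform"
  growth <- growth_field(mesh, targets, mode = growth_mode,
                         direction = direction)
  state <- relax_to_steady_state(init_state(mesh), mesh, growth, materials,
                                 config, mode = mode)
  list(state = state,
       report = ridge_report(state, mesh, allow_unconverged = TRUE))
}

#' Quasi-static growth driver
#'
#' Grows the mesh along a [growth_schedule()]: at each normalized time the
#' growth tensors are rebuilt and the state is re-relaxed starting from the
#' previous converged configuration, mirroring the discrete-time formulation
#' in which elastic energy is minimised at each growth increment.
#'
#' @param mesh a `tet_mesh`.
#' @param schedule a [growth_schedule()].
#' @param materials named list of [material()] per region.
#' @param config a [solver_config()].
#' @param growth_mode passed to [growth_field()].
#' @param mode constraint mode.
#' @return list with `trajectory` (data frame: tau, g_surface, g_crease,
#'   ridge_count, energy, converged), `reports` (list of [ridge_report()]s),
#'   and `state` (final `solver_state`).
#' @export
run_quasi_static <- function(mesh, schedule, materials,
                             config = solver_config(), growth_mode = NULL,
                             mode = "AUTO") {
  stopifnot(inherits(schedule, "growth_schedule"))
  if (is.null(growth_mode))
    growth_mode <- if (any(mesh$region == "SUBSTRATE")) "attenuated" else "uniform"
  taus <- schedule$normalized_times
  taus <- taus[taus > 0]
  state <- init_state(mesh)
  rows <- list()
  reports <- list()
  for (i in seq_along(taus)) {
    tg <- evaluate_schedule(schedule, taus[i])
    growth <- growth_field(mesh, tg, mode = growth_mode)
    state$converged <- FALSE
    state <- relax_to_steady_state(state, mesh, growth, materials, config,
                                   mode = mode)
    rep_i <- ridge_report(state, mesh, allow_unconverged = TRUE)
    reports[[i]] <- rep_i
    rows[[i]] <- data.frame(tau = taus[i], g_surface = tg$g_surface,
                            g_crease = tg$g_crease,
                            ridge_count = rep_i$ridge_count,
                            energy = state$energy,
                            converged = state$converged)
  }
  list(trajectory = do.call(rbind, rows), reports = reports, state = state)
}
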