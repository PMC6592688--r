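test_that("strain energy density matches hand-evaluated cases", {
  expect_equal(strain_energy_density(diag(3), 1, 1), 0)
  # pure dilation: isochoric term vanishes, W = K/2 (J-1)^2
  expect_equal(strain_energy_density(diag(rep(1.1, 3)), 1, 1),
               0.5 * (1.1^3 - 1)^2)
  # simple shear: J = 1, Tr(FF^T) = 3.25, W = mu/2 * 0.25
  Fs <- diag(3); Fs[1, 2] <- 0.5
  expect_equal(strain_energy_density(Fs, 1, 1), 0.125)
  expect_error(strain_energy_density(diag(c(1, 1, -1)), 1, 1), "inverted")
})

test_that("W is nonnegative, zero only at rotations, and objective", {
  set.seed(7)
  for (i in 1:25) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.2), 3, 3)
    if (det(F) <= 0.05) next
    W <- strain_energy_density(F, 1.3, 4)
    expect_gte(W, -1e-14)
    R <- random_rotation()
    expect_equal(strain_energy_density(R %*% F, 1.3, 4), W,
                 tolerance = 1e-12)
    expect_equal(strain_energy_density(R, 1.3, 4), 0, tolerance = 1e-12)
  }
})

test_that("Cauchy stress agrees with finite differences of W", {
  expect_equal(cauchy_stress(diag(3), 1, 1), matrix(0, 3, 3))
  # pure dilation: deviatoric part exactly zero
  g <- 1.23
  s <- cauchy_stress(diag(rep(g, 3)), 2, 5)
  expect_equal(s, 5 * (g^3 - 1) * diag(3), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.15), 3, 3)
    if (det(F) <= 0.2) next
    mu <- runif(1, 0.5, 2); K <- runif(1, 2, 8)
    # P = dW/dF by central differences, sigma = P F^T / J
    h <- 1e-6
    P <- matrix(0, 3, 3)
    for (r in 1:3) for (cc in 1:3) {
      Fp <- F; Fp[r, cc] <- Fp[r, cc] + h
      Fm <- F; Fm[r, cc] <- Fm[r, cc] - h
      P[r, cc] <- (strain_energy_density(Fp, mu, K) -
                     strain_energy_density(Fm, mu, K)) / (2 * h)
    }
    sig_fd <- P %*% t(F) / det(F)
    sig <- cauchy_stress(F, mu, K)
    expect_equal(sig, sig_fd, tolerance = 1e-5)
    expect_equal(sig, t(sig), tolerance = 1e-12)
  }
})

test_that("material alpha and K follow the Poisson-ratio relation", {
  m <- material(2, 0.45)
  expect_equal(m$alpha, (2 + 2 * 0.45) / (3 - 6 * 0.45))
  expect_equal(m$K, m$alpha * 2)
  expect_equal(m$young_E, 2 * 2 * 1.45)
  expect_error(material(1, 0.5))
  r <- materials_from_ratio(100, 0.45)
  expect_equal(r$SKIN$young_E / r$SUBSTRATE$young_E, 100)
})

test_that("assembled forces vanish on the undeformed ungrown mesh and sum to zero", {
  mesh <- two_tet_mesh()
  mats <- list(SKIN = material(1, 0.45))
  gI <- manual_growth(mesh, diag(3))
  fe <- assemble_nodal_forces(mesh$nodes, mesh, gI, mats)
  expect_lt(max(abs(fe$forces)), 1e-12)
  expect_equal(fe$energy, 0, tolerance = 1e-14)
  # any deformed state: total force on the free body is zero
  set.seed(3)
  x <- mesh$nodes + matrix(rnorm(15, 0, 0.05), 5, 3)
  fe2 <- assemble_nodal_forces(x, mesh, manual_growth(mesh, diag(c(1.2, 1.1, 1))),
                               mats)
  expect_lt(max(abs(colSums(fe2$forces))), 1e-10 * max(abs(fe2$forces)))
})

test_that("forces equal minus the energy gradient on a 2-tet mesh", {
  mesh <- two_tet_mesh()
  mats <- list(SKIN = material(1.4, 0.45))
  G <- element_growth_tensor(1.2, 1.1, c(0, 0, 1), c(0, 1, 0))
  growth <- manual_growth(mesh, G)
  set.seed(5)
  x <- mesh$nodes + matrix(rnorm(15, 0, 0.05), 5, 3)
  fe <- assemble_nodal_forces(x, mesh, growth, mats)
  h <- 1e-6
  gnum <- matrix(0, 5, 3)
  for (i in 1:5) for (r in 1:3) {
    xp <- x; xp[i, r] <- xp[i, r] + h
    xm <- x; xm[i, r] <- xm[i, r] - h
    gnum[i, r] <- (assemble_nodal_forces(xp, mesh, growth, mats)$energy -
                     assemble_nodal_forces(xm, mesh, growth, mats)$energy) /
      (2 * h)
  }
  expect_lt(max(abs(fe$forces + gnum)) / max(abs(gnum)), 1e-5)
})

test_that("constraints zero, project along C, or confine to the crease plane", {
  mesh <- small_lobe(res = c(10, 6))
  f <- matrix(rnorm(3 * nrow(mesh$nodes)), ncol = 3)
  fs <- apply_constraints(f, mesh, "SINGLE_SHEET")
  expect_true(all(fs[mesh$node_sets$FIXED_INNER, ] == 0))
  cr <- mesh$node_sets$CREASE
  # single sheet: crease vectors parallel to C
  C <- mesh$crease_direction
  perp <- fs[cr, , drop = FALSE] - (fs[cr, , drop = FALSE] %*% C) %*% t(C)
  expect_lt(max(abs(perp)), 1e-12)
  # multi layer: no component along the crease-plane normal
  fm <- apply_constraints(f, mesh, "MULTI_LAYER")
  expect_lt(max(abs(fm[cr, , drop = FALSE] %*% mesh$crease_plane_normal)),
            1e-12)
  expect_error(node_constraint_codes(mesh, "BOGUS"))
})

test_that("relaxation: no growth stays put; free uniform growth is stress-free", {
  mesh <- small_semicylinder(res = c(8, 4))
  mats <- list(SKIN = material(1, 0.45))
  cfg <- fast_config(max_iterations = 60000, perturbation_amplitude = 0)
  st <- relax_to_steady_state(init_state(mesh), mesh,
                              growth_field(mesh, growth_targets(1, 1,
                                           crease_equals_surface = TRUE),
                                           mode = "uniform"), mats, cfg)
  expect_true(st$converged)
  expect_lt(max(abs(st$x - mesh$nodes)), 1e-12)
  expect_equal(st$energy, 0)

  # a single unconstrained tet under G = gI relaxes to the scaled tet
  mesh1 <- two_tet_mesh()
  mesh1$tets <- mesh1$tets[1, , drop = FALSE]
  mesh1$region <- "SKIN"
  mesh1$volumes <- mesh1$volumes[1]
  mesh1$normal_of_tet <- mesh1$normal_of_tet[1, , drop = FALSE]
  g <- 1.3
  st1 <- relax_to_steady_state(init_state(mesh1), mesh1,
                               manual_growth(mesh1, diag(rep(g, 3))),
                               list(SKIN = material(1, 0.45)),
                               fast_config(dt_factor = 0.1,
                                           energy_window = 2000,
                                           disp_tol = 1e-8,
                                           max_iterations = 1e5,
                                           perturbation_amplitude = 0))
  expect_true(st1$converged)
  expect_lt(st1$energy, 1e-8 * 1 * mesh1$volumes[1])
  expect_equal(sqrt(sum((st1$x[2, ] - st1$x[1, ])^2)), g, tolerance = 1e-4)
})

test_that("relaxation is deterministic for a fixed seed", {
  mesh <- small_semicylinder(T_over_L = 0.04, res = c(10, 5))
  mats <- list(SKIN = material(1, 0.45))
  gf <- growth_field(mesh, growth_targets(1.15, 1, crease_equals_surface = TRUE),
                     mode = "uniform")
  cfg <- fast_config(max_iterations = 50000, energy_window = 2000)
  s1 <- relax_to_steady_state(init_state(mesh), mesh, gf, mats, cfg)
  s2 <- relax_to_steady_state(init_state(mesh), mesh, gf, mats, cfg)
  expect_identical(s1$energy, s2$energy)
  expect_identical(s1$x, s2$x)
})
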