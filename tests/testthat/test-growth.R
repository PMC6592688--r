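test_that("logistic attenuation reproduces hand-evaluated values", {
  # at x = T the exponential is 1, so the denominator is 1.25
  expect_equal(logistic_attenuation(1.3, 0.047, 0.047), 1 + 0.3 / 1.25)
  # at the surface with T = 0.047 mm and sharpness 100/mm
  expect_equal(logistic_attenuation(1.3, 0, 0.047),
               1 + 0.3 / (1 + 0.25 * exp(-4.7)))
  expect_equal(logistic_attenuation(2.2, Inf, 0.047), 1)
})

test_that("attenuation is bounded and monotone nonincreasing in depth", {
  x <- seq(0, 1, length.out = 200)
  for (g in c(1, 1.1, 1.3, 2.2, 5)) {
    gi <- logistic_attenuation(g, x, T = 0.047)
    expect_true(all(gi >= 1))
    expect_true(all(gi <= g))
    expect_true(all(diff(gi) <= 1e-15))
  }
  expect_error(logistic_attenuation(0.9, 0, 0.047), "resorption")
})

test_that("growth tensor matches the tangential/crease construction", {
  expect_equal(element_growth_tensor(1, 1, c(0, 0, 1), c(0, 1, 0)), diag(3))
  Gs_only <- element_growth_tensor(1.3, 1, c(0, 0, 1), c(0, 1, 0))
  expect_equal(Gs_only, diag(c(1.3, 1.3, 1.0)))
  G <- element_growth_tensor(1.3, 2.2, c(0, 0, 1), c(0, 1, 0))
  expect_equal(G, diag(c(1.3, 2.86, 1.0)))
  expect_error(element_growth_tensor(1.3, 2.2, c(0, 0, 2), c(0, 1, 0)),
               "unit")
})

test_that("det(G) = gs^2 gc, so pure surface growth has det gs^2", {
  set.seed(1)
  for (i in 1:20) {
    gs <- runif(1, 1, 2.5); gc <- runif(1, 1, 2.5)
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    # a crease direction orthogonal to the normal, as in the mesh convention
    cr <- rnorm(3); cr <- cr - sum(cr * n) * n; cr <- cr / sqrt(sum(cr^2))
    G <- element_growth_tensor(gs, gc, n, cr)
    expect_equal(det(G), gs^2 * gc, tolerance = 1e-12)
  }
})

test_that("growth field on a mesh: identity at g = 1, uniform mode flat", {
  mesh <- small_semicylinder()
  tg1 <- growth_targets(1, 1, crease_equals_surface = TRUE)
  gf <- growth_field(mesh, tg1, mode = "uniform")
  expect_equal(max(abs(gf$G - matrix(rep(as.vector(diag(3)),
                                         each = nrow(mesh$tets)),
                                     ncol = 9))), 0)
  gf2 <- growth_field(mesh, growth_targets(1.2, 1, crease_equals_surface = TRUE),
                      mode = "uniform")
  expect_true(all(abs(gf2$detG - 1.2^2) < 1e-12))
  gf3 <- growth_field(mesh, growth_targets(1.2, 1, crease_equals_surface = TRUE),
                      mode = "isotropic")
  expect_true(all(abs(gf3$detG - 1.2^3) < 1e-12))
})

test_that("attenuated growth field confines growth to the skin of a bilayer", {
  p <- geometry_params("BILAYER_FRILL", thickness_T = 0.047,
                       boundary_length_L = 0.047 / 0.014,
                       resolution = c(16, 10), through_thickness_layers = 2,
                       substrate_layers = 4)
  mesh <- build_bilayer_frill(p)
  gf <- growth_field(mesh, growth_targets(1.3, 2.2), mode = "attenuated")
  skin <- mesh$region == "SKIN"
  # deepest skin tet centroid sits at 7T/8, where the logistic gives 1.263
  expect_true(all(gf$g_s_local[skin] > 1.26))
  # deep substrate elements barely grow
  depth <- compute_depth_fields(mesh)
  deep <- depth$x_s > 3 * mesh$thickness_T
  expect_true(all(gf$g_s_local[deep] < 1.01))
})

test_that("schedule ramps hit the printed anchors exactly", {
  sch <- growth_schedule()
  t0 <- evaluate_schedule(sch, 0)
  expect_equal(t0$g_surface, 1); expect_equal(t0$g_crease, 1)
  t1 <- evaluate_schedule(sch, 1)
  expect_equal(t1$g_surface, 1.3); expect_equal(t1$g_crease, 2.2)
  tm <- evaluate_schedule(sch, 1 / 3)
  expect_equal(tm$g_surface, 1.1)
  expect_equal(tm$g_crease, 1.5)
  # the quadratic is 1 + 1.65 tau - 0.45 tau^2
  expect_equal(unname(sch$crease_coef), c(-0.45, 1.65, 1), tolerance = 1e-12)
  expect_error(evaluate_schedule(sch, 1.01), "\\[0, 1\\]")
  # monotone nondecreasing ramps
  taus <- seq(0, 1, by = 0.05)
  gs <- vapply(taus, function(t) evaluate_schedule(sch, t)$g_surface, 1)
  gc <- vapply(taus, function(t) evaluate_schedule(sch, t)$g_crease, 1)
  expect_true(all(diff(gs) >= 0) && all(diff(gc) >= 0))
})
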