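test_that("perturbation is seeded, bounded and zero on constrained nodes", {
  mesh <- small_lobe(res = c(14, 8))
  p1 <- make_perturbation(mesh, 1e-3, seed = 42)
  p2 <- make_perturbation(mesh, 1e-3, seed = 42)
  expect_identical(p1, p2)
  p3 <- make_perturbation(mesh, 1e-3, seed = 43)
  expect_false(identical(p1, p3))
  expect_equal(max(abs(p1)), 1e-3 * mesh$thickness_T)
  expect_true(all(p1[mesh$node_sets$FIXED_INNER, ] == 0))
  expect_true(all(p1[mesh$node_sets$CREASE, ] == 0))
  expect_error(make_perturbation(mesh, 0), "stalls")
  expect_error(make_perturbation(mesh, 0.5))
})

test_that("synthetic indentation profiles are deterministic and span decades", {
  gen <- two_layer_params(11440, 220, 1, 1.5, 47)
  clean <- make_indentation_profile(gen, noise_cv = 0)
  expect_equal(clean$moduli,
               two_layer_modulus(clean$depths, 47, gen))
  n1 <- make_indentation_profile(gen, noise_cv = 0.05, seed = 9)
  n2 <- make_indentation_profile(gen, noise_cv = 0.05, seed = 9)
  expect_identical(n1$moduli, n2$moduli)
  # ratio ~52 profile spans close to two decades
  expect_gt(max(clean$moduli) / min(clean$moduli), 30)
  expect_error(make_indentation_profile(gen, noise_cv = 0.9), "noise_cv")
})

test_that("presets are complete, self-contained and correctly parameterized", {
  ps <- list_presets()
  expect_setequal(names(ps),
                  c("semicylinder_growth_sweep", "semicylinder_thickness_sweep",
                    "single_lobe", "pdms_analog", "bilayer_ratio_sweep",
                    "bilayer_quasistatic", "single_sheet_quasistatic"))
  for (p in ps) {
    expect_s3_class(p, "scenario_preset")
    # every preset builds a valid config and mesh with no external input
    cfg <- morphofrill:::preset_to_config(p)
    expect_true(is.list(cfg$geometry))
    expect_equal(p$materials$nu, 0.45)
  }
  lobe <- get_preset("single_lobe")
  expect_equal(lobe$geometry$thickness_T / lobe$geometry$boundary_length_L,
               0.014, tolerance = 1e-12)
  bi <- get_preset("bilayer_ratio_sweep")
  expect_equal(bi$growth$g_surface, 1.3)
  expect_equal(bi$growth$g_crease, 2.2)
  expect_setequal(bi$sweep$values, c(20, 65, 100, 1000, 2000))
  qs <- get_preset("single_sheet_quasistatic")
  expect_equal(qs$growth$g_surface_final, 1.28)
  pd <- get_preset("pdms_analog")
  expect_equal(pd$geometry$thickness_T / pd$geometry$boundary_length_L, 0.01)
  expect_identical(pd$growth_mode, "isotropic")
  expect_error(get_preset("nope"), "unknown preset")
})
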