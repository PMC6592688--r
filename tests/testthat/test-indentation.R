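test_that("two-layer model has exact asymptotics and monotone decay", {
  fit <- two_layer_params(E_skin = 11440, E_substrate = 220, coeff_A = 1.2,
                          coeff_B = 1.6, skin_thickness_T = 47)
  expect_equal(two_layer_modulus(0, 47, fit), 11440)
  expect_equal(two_layer_modulus(1e9, 47, fit), 220, tolerance = 1e-6)
  d <- seq(1, 500, by = 1)
  E <- two_layer_modulus(d, 47, fit)
  expect_true(all(diff(E) < 0))
  # d = T with A = B = 1: mixing exponent 1/2, geometric mean
  f2 <- two_layer_params(10000, 100, 1, 1, 47)
  expect_equal(two_layer_modulus(47, 47, f2), sqrt(10000 * 100))
  expect_error(two_layer_modulus(10, 47, two_layer_params(1, 1, -1, 1, 47)))
})

test_that("printed moduli give the quoted stiffness ratios", {
  e26 <- two_layer_params(11440, 220)
  e45 <- two_layer_params(36880, 228)
  expect_equal(stiffness_ratio(e26)$rounded, 52)
  expect_equal(stiffness_ratio(e45)$rounded, 162)
  expect_equal(stiffness_ratio(e45)$raw, 36880 / 228, tolerance = 1e-12)
  same <- two_layer_params(500, 500)
  expect_equal(stiffness_ratio(same)$raw, 1)
})

test_that("noiseless round trip recovers all four parameters within 1%", {
  gen <- two_layer_params(11440, 220, coeff_A = 1.3, coeff_B = 1.7,
                          skin_thickness_T = 47)
  prof <- make_indentation_profile(gen, noise_cv = 0)
  fit <- fit_two_layer(prof, thickness_range = 47)
  expect_equal(fit$E_skin, gen$E_skin, tolerance = 0.01)
  expect_equal(fit$E_substrate, gen$E_substrate, tolerance = 0.01)
  expect_equal(fit$coeff_A, gen$coeff_A, tolerance = 0.01)
  expect_equal(fit$coeff_B, gen$coeff_B, tolerance = 0.01)
  expect_equal(stiffness_ratio(fit)$raw, 52, tolerance = 0.01)
})

test_that("5% multiplicative noise still recovers the moduli within 10%", {
  gen <- two_layer_params(11440, 220, coeff_A = 1, coeff_B = 1.5,
                          skin_thickness_T = 47)
  errs <- vapply(1:20, function(seed) {
    prof <- make_indentation_profile(gen, noise_cv = 0.05, seed = seed)
    fit <- fit_two_layer(prof, thickness_range = 47)
    max(abs(fit$E_skin / gen$E_skin - 1),
        abs(fit$E_substrate / gen$E_substrate - 1))
  }, numeric(1))
  # the substrate modulus extrapolates beyond the deepest point, so single
  # draws may exceed the bound; the accuracy claim is distributional
  expect_lt(stats::median(errs), 0.10)
  expect_gte(mean(errs < 0.10), 0.90)
})

test_that("a constant profile yields equal layer moduli (ratio ~ 1)", {
  d <- exp(seq(log(5), log(470), length.out = 24))
  prof <- depth_profile(d, rep(300, length(d)))
  fit <- suppressWarnings(fit_two_layer(prof, thickness_range = 47))
  expect_equal(fit$E_skin, 300, tolerance = 0.02)
  expect_equal(fit$E_substrate, 300, tolerance = 0.02)
  expect_equal(stiffness_ratio(fit)$raw, 1, tolerance = 0.05)
})

test_that("fitting across the thickness range reports parameter spread", {
  gen <- two_layer_params(11440, 220, coeff_A = 1, coeff_B = 1.5,
                          skin_thickness_T = 47)
  prof <- make_indentation_profile(gen, noise_cv = 0)
  fit <- fit_two_layer(prof, thickness_range = c(27, 72))
  # E_skin, E_substrate and B are T-invariant in this model (A rescales as
  # (T/T_gen)^B), so their spread across the range stays small
  expect_lt(fit$uncertainty[["E_skin"]] / fit$E_skin, 0.05)
  expect_lt(fit$uncertainty[["E_substrate"]] / fit$E_substrate, 0.05)
  expect_gt(fit$uncertainty[["coeff_A"]], 0)
  expect_equal(nrow(fit$per_thickness), 10)
  expect_true(all(fit$mixing_exponent > 0 & fit$mixing_exponent <= 1))
})

test_that("profile validation and CSV round trip", {
  expect_error(depth_profile(c(1, 1, 2), c(1, 1, 1)), "increasing")
  expect_error(depth_profile(c(1, 2), c(1, -1)), "positive")
  prof <- depth_profile(c(5, 10, 20), c(900, 700, 400))
  path <- tempfile(fileext = ".csv")
  write_depth_profile(prof, path)
  back <- read_depth_profile(path)
  expect_equal(back$depths, prof$depths)
  expect_equal(back$moduli, prof$moduli)
  # negative modulus rejected with the line number
  writeLines(c("depth_um,modulus_pa", "5,900", "10,-3"), path)
  expect_error(read_depth_profile(path), "line 3")
})
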