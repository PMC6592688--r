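preset_def <- function(name, description, geometry, growth, materials,
                       growth_mode, expected, solver = list(), sweep = NULL) {
  structure(list(name = name, description = description, geometry = geometry,
                 growth = growth, materials = materials,
                 growth_mode = growth_mode, expected = expected,
                 solver = solver, sweep = sweep), class = "scenario_preset")
}

#' Named scenario presets
#'
#' Fully self-contained parameter sets for the package's standard
#' experiments: each preset carries its geometry, growth, material and
#' solver settings and the qualitative outcome it is expected to produce.
#' Physical parameters follow the embryonic measurements (skin thickness
#' 0.047 mm, thickness-to-boundary ratio 0.014, Poisson's ratio 0.45,
#' surface growth 1.3, crease growth 2.2); the gel-analog preset uses the
#' measured sheet (T/L = 0.01, isotropic swelling by 1.3).
#'
#' @return named list of `scenario_preset` objects.
#' @export
list_presets <- function() {
  lobe_L <- 0.047 / 0.014
  presets <- list(
    preset_def(
      "semicylinder_growth_sweep",
      "Clamped semicircular sheet, T/L = 0.02: ridge count increases with uniform tangential growth g",
      geometry = list(kind = "SEMICYLINDER", thickness_T = 0.02,
                      boundary_length_L = 1, resolution = c(79, 12),
                      through_thickness_layers = 2),
      growth = list(type = "static", g_surface = 1.2,
                    crease_equals_surface = TRUE),
      materials = list(nu = 0.45), growth_mode = "uniform",
      solver = list(dt_factor = 0.3, energy_window = 3000,
                    max_iterations = 200000, disp_tol = 1e-4,
                    check_every = 50, perturbation_amplitude = 5e-3,
                    gamma_floor_factor = 1, rng_seed = 1),
      expected = "ridge count nondecreasing over g in {1.05, 1.1, 1.2, 1.3}",
      sweep = list(parameter = "g", values = c(1.05, 1.1, 1.2, 1.3))),
    preset_def(
      "semicylinder_thickness_sweep",
      "Clamped semicircular sheet at g = 1.2: ridge count decreases with relative thickness T/L",
      geometry = list(kind = "SEMICYLINDER", thickness_T = 0.02,
                      boundary_length_L = 1, resolution = c(79, 12),
                      through_thickness_layers = 2),
      growth = list(type = "static", g_surface = 1.2,
                    crease_equals_surface = TRUE),
      materials = list(nu = 0.45), growth_mode = "uniform",
      solver = list(dt_factor = 0.3, energy_window = 3000,
                    max_iterations = 200000, disp_tol = 1e-4,
                    check_every = 50, perturbation_amplitude = 5e-3,
                    gamma_floor_factor = 1, rng_seed = 1),
      expected = "ridge count nonincreasing over T/L in {0.01, 0.02, 0.04}",
      sweep = list(parameter = "T_over_L", values = c(0.01, 0.02, 0.04))),
    preset_def(
      "single_lobe",
      "Single-lobe sheet with curved fixed inner boundary and crease, T/L = 0.014, crease grows with the surface",
      geometry = list(kind = "CURVED_LOBE", thickness_T = 0.047,
                      boundary_length_L = lobe_L, resolution = c(100, 16),
                      through_thickness_layers = 2),
      growth = list(type = "static", g_surface = 1.2,
                    crease_equals_surface = TRUE),
      materials = list(nu = 0.45), growth_mode = "uniform",
      solver = list(dt_factor = 0.3, energy_window = 3000,
                    max_iterations = 200000, disp_tol = 1e-4,
                    check_every = 50, perturbation_amplitude = 5e-3,
                    gamma_floor_factor = 1, rng_seed = 1),
      expected = "2 ridges near g = 1.10, 3 ridges at g = 1.20"),
    preset_def(
      "pdms_analog",
      "Gel-analog semicircular sheet, T/L = 0.01, isotropic swelling by 30%",
      geometry = list(kind = "SEMICYLINDER", thickness_T = 0.8462,
                      boundary_length_L = 84.62, resolution = c(100, 16),
                      through_thickness_layers = 2),
      growth = list(type = "static", g_surface = 1.3,
                    crease_equals_surface = TRUE),
      materials = list(nu = 0.45), growth_mode = "isotropic",
      solver = list(dt_factor = 0.3, energy_window = 3000,
                    max_iterations = 150000, disp_tol = 1e-4,
                    check_every = 50, perturbation_amplitude = 5e-3,
                    gamma_floor_factor = 1, rng_seed = 1),
      expected = "3 pleats, wavelength increasing toward the free edge"),
    preset_def(
      "bilayer_ratio_sweep",
      "Bilayer lobe (skin on substrate), g_s = 1.3, g_c = 2.2: ridge count inversely related to the stiffness ratio",
      geometry = list(kind = "BILAYER_FRILL", thickness_T = 0.047,
                      boundary_length_L = lobe_L, resolution = c(80, 10),
                      through_thickness_layers = 2, substrate_layers = 3,
                      substrate_depth_ratio = 10),
      growth = list(type = "static", g_surface = 1.3, g_crease = 2.2),
      materials = list(stiffness_ratio = 100, nu = 0.45),
      growth_mode = "attenuated",
      solver = list(dt_factor = 0.3, energy_window = 3000,
                    max_iterations = 200000, disp_tol = 1e-4,
                    check_every = 50, perturbation_amplitude = 5e-3,
                    gamma_floor_factor = 1, rng_seed = 1),
      expected = "3 ridges at ratio 100; count nonincreasing over {20, 65, 100, 1000, 2000}",
      sweep = list(parameter = "stiffness_ratio",
                   values = c(20, 65, 100, 1000, 2000))),
    preset_def(
      "bilayer_quasistatic",
      "Bilayer lobe at stiffness ratio 100 grown along the measured schedule (linear surface, quadratic crease)",
      geometry = list(kind = "BILAYER_FRILL", thickness_T = 0.047,
                      boundary_length_L = lobe_L, resolution = c(80, 10),
                      through_thickness_layers = 2, substrate_layers = 3,
                      substrate_depth_ratio = 10),
      growth = list(type = "schedule", g_surface_final = 1.3,
                    g_crease_final = 2.2, g_crease_mid = 1.5, n_steps = 10),
      materials = list(stiffness_ratio = 100, nu = 0.45),
      growth_mode = "attenuated",
      solver = list(dt_factor = 0.3, energy_window = 3000,
                    max_iterations = 200000, disp_tol = 1e-4,
                    check_every = 50, perturbation_amplitude = 5e-3,
                    gamma_floor_factor = 1, rng_seed = 1),
      expected = "transition from 2 to 3 ridges along the schedule"),
    preset_def(
      "single_sheet_quasistatic",
      "Single lobe grown stepwise to g = 1.28 with crease growth equal to surface growth",
      geometry = list(kind = "CURVED_LOBE", thickness_T = 0.047,
                      boundary_length_L = lobe_L, resolution = c(100, 16),
                      through_thickness_layers = 2),
      growth = list(type = "schedule", g_surface_final = 1.28,
                    crease_equals_surface = TRUE, n_steps = 14),
      materials = list(nu = 0.45), growth_mode = "uniform",
      solver = list(dt_factor = 0.3, energy_window = 3000,
                    max_iterations = 200000, disp_tol = 1e-4,
                    check_every = 50, perturbation_amplitude = 5e-3,
                    gamma_floor_factor = 1, rng_seed = 1),
      expected = "first 2 then 3 ridges"))
  stats::setNames(presets, vapply(presets, `[[`, character(1), "name"))
}

#' @rdname list_presets
#' @param name preset name.
#' @export
get_preset <- function(name) {
  p <- list_presets()
  if (!name %in% names(p))
    stop("unknown preset '", name, "'; available: ",
         paste(names(p), collapse = ", "))
  p[[name]]
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("preset", x$name, "\n  ", x$description, "\n", sep = "")
  cat("  expected:", x$expected, "\n")
  invisible(x)
}
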