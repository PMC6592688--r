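# cached heavyweight simulations shared across acceptance criteria

sheet_quasistatic_run <- function() {
  cached("sheet_qs", run_simulation("single_sheet_quasistatic"))
}

pdms_run <- function() {
  cached("pdms", run_simulation("pdms_analog", resolution = c(90, 12)))
}

bilayer_run <- function(ratio, resolution = NULL, key = NULL) {
  key <- key %||% paste0("bi", ratio)
  cached(key, {
    cfg <- morphofrill:::preset_to_config(get_preset("bilayer_ratio_sweep"))
    cfg$material$stiffness_ratio <- ratio
    if (ratio != 100) cfg$solver$max_iterations <- 160000
    suppressWarnings(run_simulation(cfg, resolution = resolution))
  })
}

# film-on-substrate strip at the study growth g = 1.3, uniaxial film growth
strip_run <- function(ratio, len_T, h) {
  cached(paste0("strip", ratio), {
    nx <- round(len_T / h)
    p <- geometry_params("BILAYER_STRIP", thickness_T = 1,
                         boundary_length_L = len_T,
                         substrate_depth_ratio = 14,
                         resolution = c(nx, 2), through_thickness_layers = 2,
                         substrate_layers = 6, strip_width = 2 * h)
    mesh <- build_bilayer_strip(p)
    mats <- materials_from_ratio(ratio, 0.45)
    gf <- growth_field(mesh, growth_targets(1.3, 1,
                                            crease_equals_surface = TRUE),
                       mode = "attenuated", direction = c(1, 0, 0))
    cfg <- solver_config(dt_factor = 0.3, energy_window = 3000,
                         max_iterations = 200000, disp_tol = 1e-4,
                         check_every = 50, rng_seed = 1,
                         perturbation_amplitude = 5e-3,
                         gamma_floor_factor = 0.1)
    st <- suppressWarnings(
      relax_to_steady_state(init_state(mesh), mesh, gf, mats, cfg))
    list(mesh = mesh, state = st, mats = mats)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
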