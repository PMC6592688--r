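# ---- run configuration ------------------------------------------------------

config_schema <- list(
  geometry = c("kind", "thickness_T", "boundary_length_L",
               "substrate_depth_ratio", "resolution",
               "through_thickness_layers", "substrate_layers",
               "arc_angle_deg", "lobe_extent", "strip_width"),
  material = c("nu", "stiffness_ratio", "mu_skin", "mu_substrate"),
  growth = c("type", "g_surface", "g_crease", "g_outer",
             "crease_equals_surface", "g_surface_final", "g_crease_final",
             "g_crease_mid", "n_steps", "mode", "sharpness"),
  solver = c("dt_factor", "gamma0_factor", "gamma_floor_factor",
             "energy_window", "energy_rel_tol", "disp_tol", "max_iterations",
             "check_every", "perturbation_amplitude", "rng_seed"))

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("run config must be a list")
  for (sec in names(cfg)) {
    if (!sec %in% names(config_schema))
      stop("unknown config section '", sec, "'")
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop("unknown key '", bad[1], "' in config section [", sec, "]")
  }
  if (is.null(cfg$geometry)) stop("config is missing the [geometry] section")
  cfg
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration has sections `geometry`, `material`, `growth` and
#' `solver`; unknown sections or keys are rejected with the offending key
#' named.
#'
#' @param path YAML file path.
#' @return the validated configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname load_run_config
#' @param config configuration list to write.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(validate_config(config), path)
  invisible(path)
}

# 31-bit djb2 hash of the serialized object; used to stamp outputs so a
# finished run can be matched to its exact configuration
hash_config <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

preset_to_config <- function(p) {
  mat <- p$materials
  validate_config(list(geometry = p$geometry, material = mat,
                       growth = c(p$growth, list(mode = p$growth_mode)),
                       solver = p$solver))
}

build_geometry_from_config <- function(g) {
  params <- do.call(geometry_params, g)
  switch(params$kind,
         SEMICYLINDER = build_semicylinder_sheet(params),
         CURVED_LOBE = build_curved_lobe_sheet(params),
         BILAYER_FRILL = build_bilayer_frill(params),
         BILAYER_STRIP = build_bilayer_strip(params))
}

build_materials_from_config <- function(m, mesh) {
  nu <- if (is.null(m$nu)) 0.45 else m$nu
  if (!is.null(m$stiffness_ratio))
    return(materials_from_ratio(m$stiffness_ratio, nu))
  mu_s <- if (is.null(m$mu_skin)) 1 else m$mu_skin
  mats <- list(SKIN = material(mu_s, nu))
  if (any(mesh$region == "SUBSTRATE")) {
    if (is.null(m$mu_substrate))
      stop("bilayer mesh needs stiffness_ratio or mu_substrate")
    mats$SUBSTRATE <- material(m$mu_substrate, nu)
  }
  mats
}

# ---- drivers ----------------------------------------------------------------

#' Run one simulation from a preset or configuration
#'
#' Executes the full pipeline (geometry, growth, relaxation or quasi-static
#' growth, morphometrics) for a named preset, a `scenario_preset`, a YAML
#' config path, or a config list. If `outdir` is given, writes the deformed
#' mesh (VTK, with per-element J and energy density), the energy history
#' (CSV), the ridge report (JSON) and a run record (JSON: config snapshot,
#' hash, seed, package version, convergence stats, file paths).
#'
#' @param config preset name, `scenario_preset`, YAML path, or config list.
#' @param g optional override of the static surface-growth factor.
#' @param resolution optional override of the lattice resolution.
#' @param solver named list of [solver_config()] overrides.
#' @param outdir optional output directory.
#' @param error_on_nonconvergence error (instead of warn) if the relaxation
#'   does not converge.
#' @return list with `mesh`, `state`, `report`, `record`, and (for a
#'   schedule run) `trajectory`.
#' @export
run_simulation <- function(config, g = NULL, resolution = NULL,
                           solver = list(), outdir = NULL,
                           error_on_nonconvergence = FALSE) {
  if (inherits(config, "scenario_preset")) config <- preset_to_config(config)
  else if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config) || grepl("\\.ya?ml$", config))
      load_run_config(config) else preset_to_config(get_preset(config))
  } else config <- validate_config(config)
  if (!is.null(g)) config$growth$g_surface <- g
  if (!is.null(resolution)) config$geometry$resolution <- resolution
  config$solver <- utils::modifyList(as.list(config$solver %||% list()), solver)

  mesh <- build_geometry_from_config(config$geometry)
  materials <- build_materials_from_config(config$material %||% list(), mesh)
  scfg <- do.call(solver_config, config$solver)
  gw <- config$growth %||% list(type = "static", g_surface = 1.2)
  gmode <- gw$mode %||% NULL
  trajectory <- NULL
  if (identical(gw$type, "schedule")) {
    sched <- growth_schedule(
      g_surface_final = gw$g_surface_final %||% 1.3,
      g_crease_final = gw$g_crease_final %||% 2.2,
      g_crease_mid = gw$g_crease_mid %||% 1.5,
      n_steps = gw$n_steps %||% 20,
      crease_equals_surface = gw$crease_equals_surface %||% FALSE)
    res <- run_quasi_static(mesh, sched, materials, scfg, growth_mode = gmode)
    state <- res$state
    report <- res$reports[[length(res$reports)]]
    trajectory <- res$trajectory
  } else {
    targets <- growth_targets(
      g_surface = gw$g_surface %||% 1.2,
      g_crease = gw$g_crease %||% 1,
      crease_equals_surface = gw$crease_equals_surface %||% FALSE)
    res <- run_static_growth(mesh, targets, materials, scfg,
                             growth_mode = gmode)
    state <- res$state
    report <- res$report
  }
  if (error_on_nonconvergence && !isTRUE(state$converged))
    stop("simulation did not converge within max_iterations")

  record <- list(config = config, config_hash = hash_config(config),
                 seed = scfg$rng_seed,
                 package_version = as.character(utils::packageVersion("morphofrill")),
                 iterations = state$iteration, converged = state$converged,
                 final_energy = state$energy, files = character(0))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(outdir, paste0("run_", record$config_hash))
    files <- c(mesh = paste0(stem, ".vtk"),
               energy = paste0(stem, "_energy.csv"),
               report = paste0(stem, "_report.json"),
               record = paste0(stem, "_record.json"))
    write_vtk(mesh, files[["mesh"]], state = state)
    utils::write.csv(state$history, files[["energy"]], row.names = FALSE)
    jsonlite::write_json(unclass(report), files[["report"]],
                         auto_unbox = TRUE, digits = NA)
    record$files <- as.list(files)
    jsonlite::write_json(record, files[["record"]], auto_unbox = TRUE,
                         digits = NA)
  }
  list(mesh = mesh, state = state, report = report, record = record,
       trajectory = trajectory)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameter sweep over growth, thickness or stiffness ratio
#'
#' Runs one simulation per grid point (and per seed), collecting the ridge
#' morphometrics into a tidy data frame; failing points are flagged rather
#' than aborting the sweep. Monotonicity of the ridge count along the grid
#' is evaluated and reported in the `monotone` attribute.
#'
#' @param preset preset name or `scenario_preset` providing the base run.
#' @param parameter one of `"g"`, `"T_over_L"`, `"stiffness_ratio"`.
#' @param values grid values (may be empty).
#' @param seeds perturbation seeds to run per grid point.
#' @param resolution optional lattice-resolution override: a length-2
#'   integer vector, or a function of the grid value returning one (so a
#'   thickness sweep can keep the spacing-to-thickness ratio fixed).
#' @param solver named list of solver overrides.
#' @param outfile optional CSV path for the tidy table.
#' @return data frame with one row per (value, seed): parameter value,
#'   ridge_count, amplitude, wavelength, realized growth, converged, failed.
#' @export
run_sweep <- function(preset, parameter = c("g", "T_over_L",
                                            "stiffness_ratio"),
                      values, seeds = 1L, resolution = NULL,
                      solver = list(), outfile = NULL) {
  parameter <- match.arg(parameter)
  base <- if (inherits(preset, "scenario_preset")) preset else get_preset(preset)
  rows <- list()
  for (val in values) for (sd in seeds) {
    cfg <- preset_to_config(base)
    if (parameter == "g") cfg$growth$g_surface <- val
    if (parameter == "T_over_L")
      cfg$geometry$thickness_T <- val * cfg$geometry$boundary_length_L
    if (parameter == "stiffness_ratio") cfg$material$stiffness_ratio <- val
    sv <- utils::modifyList(solver, list(rng_seed = sd))
    res_pt <- if (is.function(resolution)) resolution(val) else resolution
    res <- tryCatch(
      run_simulation(cfg, resolution = res_pt, solver = sv),
      error = function(e) e)
    rows[[length(rows) + 1L]] <- if (inherits(res, "error"))
      data.frame(parameter = parameter, value = val, seed = sd,
                 ridge_count = NA_integer_, amplitude_mm = NA_real_,
                 wavelength_mm = NA_real_, realized_growth = NA_real_,
                 converged = FALSE, failed = TRUE,
                 message = conditionMessage(res))
    else
      data.frame(parameter = parameter, value = val, seed = sd,
                 ridge_count = res$report$ridge_count,
                 amplitude_mm = res$report$middle_ridge_amplitude_mm,
                 wavelength_mm = res$report$mean_wavelength_mm,
                 realized_growth = res$report$realized_linear_growth,
                 converged = res$report$converged, failed = FALSE,
                 message = "")
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(parameter = character(0), value = numeric(0),
                  seed = integer(0), ridge_count = integer(0),
                  amplitude_mm = numeric(0), wavelength_mm = numeric(0),
                  realized_growth = numeric(0), converged = logical(0),
                  failed = logical(0), message = character(0))
  ok <- out[!out$failed, , drop = FALSE]
  if (nrow(ok) > 1) {
    counts <- tapply(ok$ridge_count, ok$value, function(x)
      as.integer(round(stats::median(x))))
    counts <- counts[order(as.numeric(names(counts)))]
    attr(out, "monotone") <- list(
      nondecreasing = all(diff(counts) >= 0),
      nonincreasing = all(diff(counts) <= 0))
  }
  if (!is.null(outfile)) utils::write.csv(out, outfile, row.names = FALSE)
  out
}

#' Fit the two-layer indentation model from a profile CSV
#'
#' @param path CSV with columns `depth_um`, `modulus_pa`.
#' @param thickness_range skin-thickness interval (um) for [fit_two_layer()].
#' @param out_json optional path; the fit (including the stiffness ratio and
#'   parameter uncertainties) is written as JSON.
#' @return the `two_layer_fit`.
#' @export
fit_indentation_file <- function(path, thickness_range = c(27, 72),
                                 out_json = NULL) {
  profile <- read_depth_profile(path)
  fit <- fit_two_layer(profile, thickness_range)
  if (!is.null(out_json)) {
    payload <- list(E_skin = fit$E_skin, E_substrate = fit$E_substrate,
                    coeff_A = fit$coeff_A, coeff_B = fit$coeff_B,
                    stiffness_ratio = fit$stiffness_ratio,
                    stiffness_ratio_rounded = round(fit$stiffness_ratio),
                    uncertainty = as.list(fit$uncertainty),
                    thickness_range_um = fit$thickness_range)
    jsonlite::write_json(payload, out_json, auto_unbox = TRUE, digits = NA)
  }
  fit
}
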