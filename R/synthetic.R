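# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Seeded symmetry-breaking perturbation
#'
#' Deterministic random normal-direction displacement of the anterior
#' surface nodes, with maximum magnitude `amplitude * T`, and exactly zero
#' on the fixed boundary and crease. The flat grown configuration is an
#' (unstable) equilibrium of the discretized problem; this perturbation
#' selects the buckled branch.
#'
#' @param mesh a `tet_mesh`.
#' @param amplitude perturbation amplitude as a fraction of the sheet
#'   thickness, in (0, 0.01].
#' @param seed RNG seed.
#' @return an N x 3 displacement field (mm).
#' @export
make_perturbation <- function(mesh, amplitude = 1e-3, seed = 1L) {
  if (amplitude <= 0)
    stop("amplitude must be > 0 (a zero perturbation stalls on the ",
         "symmetric branch)")
  if (amplitude > 0.01) stop("amplitude must be <= 0.01")
  n <- nrow(mesh$nodes)
  field <- matrix(0, n, 3)
  idx <- setdiff(mesh$node_sets$ANTERIOR_SURFACE,
                 c(mesh$node_sets$FIXED_INNER, mesh$node_sets$CREASE))
  r <- with_local_seed(seed, stats::runif(length(idx), -1, 1))
  field[idx, 3] <- amplitude * mesh$thickness_T * r / max(abs(r))
  field
}

#' Synthetic displaced surface with known morphometrics
#'
#' Builds a single-lobe mesh (or uses the given one) and displaces its
#' anterior region by a sinusoidal ridge pattern with a known ridge count,
#' amplitude and wavelength, for validating the morphometric estimators: on
#' every band the profile carries `n_ridges` equal peaks of peak-to-trough
#' amplitude `2 * amplitude`, spaced `wavelength` apart in arc length.
#'
#' @param n_ridges number of ridges (>= 0).
#' @param amplitude sinusoid amplitude (mm); peak-to-trough is twice this.
#' @param wavelength peak spacing in band arc length (mm); must be at least
#'   `4 * spacing_a` to be resolvable.
#' @param mesh optional `tet_mesh`; default a coarse curved lobe.
#' @return list with `mesh` and a synthetic converged `state`.
#' @export
make_fixture_surface <- function(n_ridges, amplitude = 0.02,
                                 wavelength = NULL, mesh = NULL) {
  stopifnot(n_ridges >= 0)
  if (is.null(mesh)) {
    p <- geometry_params("CURVED_LOBE", thickness_T = 0.014,
                         boundary_length_L = 1, resolution = c(60, 24),
                         through_thickness_layers = 2)
    mesh <- build_curved_lobe_sheet(p)
  }
  state <- init_state(mesh)
  if (n_ridges > 0) {
    sp <- mesh$surface_param
    surf <- which(!is.na(sp[, 1]))
    vs <- unique(sp[surf, 2])
    mid_arc <- NULL
    for (v0 in vs) {
      nodes <- surf[abs(sp[surf, 2] - v0) < 1e-12]
      nodes <- nodes[order(sp[nodes, 1])]
      ref <- mesh$nodes[nodes, , drop = FALSE]
      seg <- sqrt(rowSums((ref[-1, , drop = FALSE] -
                             ref[-nrow(ref), , drop = FALSE])^2))
      s <- c(0, cumsum(seg))
      if (abs(v0 - 0.5) < 1e-9 || is.null(mid_arc)) mid_arc <- max(s)
      lam <- if (is.null(wavelength)) max(s) / (n_ridges + 1) else wavelength
      if (lam < 4 * mesh$spacing_a)
        stop("wavelength below 4 * spacing_a is unresolvable on this mesh")
      # rows too short for the full packet carry as many ridges as fit
      n_row <- min(n_ridges, floor(max(s) / lam))
      if (n_row < 1) next
      smid <- max(s) / 2
      first <- smid - (n_row - 1) * lam / 2
      inside <- s >= first - lam / 2 & s <= first + (n_row - 1) * lam + lam / 2
      w <- ifelse(inside, amplitude * cos(2 * pi * (s - first) / lam), 0)
      state$x[nodes, 3] <- state$x[nodes, 3] + w
    }
    lam_mid <- if (is.null(wavelength)) NULL else wavelength
    if (!is.null(lam_mid) && n_ridges * lam_mid > mid_arc)
      stop("n_ridges * wavelength exceeds the mid-band arc length")
  }
  state$converged <- TRUE
  state$energy <- 0
  list(mesh = mesh, state = state)
}

#' Synthetic depth-dependent indentation profile
#'
#' Moduli generated from the two-layer model with multiplicative lognormal
#' noise of given coefficient of variation; deterministic per seed.
#' Emulates depth-dependent nanoindentation of embryonic frill tissue: a
#' thin stiff skin over a ~100x softer substrate produces a profile spanning
#' about two decades of modulus between shallow and deep indentation.
#'
#' @param fit a [two_layer_params()] (generating parameters).
#' @param depths indentation depths (um).
#' @param noise_cv coefficient of variation of the multiplicative noise,
#'   in `[0, 0.5]`.
#' @param seed RNG seed.
#' @return a [depth_profile()].
#' @export
make_indentation_profile <- function(fit, depths = NULL, noise_cv = 0.05,
                                     seed = 1L) {
  if (noise_cv < 0 || noise_cv > 0.5) stop("noise_cv must lie in [0, 0.5]")
  if (is.null(depths))
    depths <- exp(seq(log(0.1 * fit$skin_thickness_T),
                      log(10 * fit$skin_thickness_T), length.out = 30))
  E <- two_layer_modulus(depths, fit$skin_thickness_T, fit)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- with_local_seed(seed,
      stats::rlnorm(length(depths), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    E <- E * noise
  }
  depth_profile(depths, E)
}
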