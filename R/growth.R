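#' Target growth factors
#'
#' The measured relative growth factors driving the model: tangential surface
#' expansion `g_surface` (the growth of the frill skin perpendicular to its
#' surface normal), crease expansion `g_crease` (growth of the sagittal
#' central crease along its direction C), and the outer free-edge growth
#' `g_outer` (observed to be ~1 and therefore not applied as a tensor).
#' Measured end-of-period values for the frill are `g_surface = 1.3`,
#' `g_crease = 2.2`, `g_outer = 1.0`.
#'
#' @param g_surface tangential surface growth factor (>= 1, dimensionless).
#' @param g_crease crease growth factor (>= 1).
#' @param g_outer outer free-edge growth (recorded for provenance only).
#' @param crease_equals_surface if `TRUE` (single-sheet runs), the crease
#'   growth factor is slaved to the surface growth factor: the crease tensor
#'   `Gc` is applied with `g_c = g_surface`.
#' @return an object of class `growth_targets`.
#' @export
growth_targets <- function(g_surface = 1.3, g_crease = 2.2, g_outer = 1.0,
                           crease_equals_surface = FALSE) {
  if (g_surface < 1 || g_crease < 1)
    stop("growth factors must be >= 1 (resorption is not modeled)")
  structure(list(g_surface = g_surface, g_crease = g_crease,
                 g_outer = g_outer,
                 crease_equals_surface = isTRUE(crease_equals_surface)),
            class = "growth_targets")
}

#' Depth attenuation of a growth factor (generalized logistic)
#'
#' Attenuates a target growth factor with distance from the growing surface
#' (or crease):
#' \deqn{g_i = 1 + \frac{g^{(i)} - 1}{1 + 0.25\, e^{-s (T - x_i)}}}
#' where `T` is the skin thickness, `x_i` the distance to the anterior
#' surface (for surface growth) or to the crease plane (for crease growth),
#' and `s` the sharpness (1/mm, default 100 with lengths in mm). The factor
#' equals approximately the target within the skin and decays to 1 over a
#' transition of width ~1/s beyond depth T.
#'
#' @param g_target target factor (>= 1).
#' @param x_i distance(s), mm, >= 0 (may be `Inf`).
#' @param T skin thickness, mm.
#' @param sharpness transition sharpness, 1/mm.
#' @return attenuated factor(s), in `[1, g_target]`.
#' @export
logistic_attenuation <- function(g_target, x_i, T, sharpness = 100) {
  if (g_target < 1) stop("g_target must be >= 1 (resorption is not modeled)")
  stopifnot(T > 0, sharpness > 0, all(x_i >= 0))
  1 + (g_target - 1) / (1 + 0.25 * exp(-sharpness * (T - x_i)))
}

#' Per-element growth tensor
#'
#' Builds the multiplicative growth tensor `G = Gs Gc` from the attenuated
#' local factors: `Gs = gs I + (1 - gs) N N^T` expands the element by `gs` in
#' the two directions perpendicular to the reference surface normal `N`, and
#' `Gc = I + (gc - 1) C C^T` stretches it by `gc` along the crease direction
#' `C`.
#'
#' @param g_s_local,g_c_local attenuated local growth factors.
#' @param N unit reference surface normal (length-3).
#' @param C unit crease direction (length-3).
#' @return a 3 x 3 growth tensor.
#' @export
element_growth_tensor <- function(g_s_local, g_c_local, N, C = c(0, 1, 0)) {
  if (abs(sum(N^2) - 1) > 1e-9 || abs(sum(C^2) - 1) > 1e-9)
    stop("N and C must be unit vectors")
  I3 <- diag(3)
  Gs <- g_s_local * I3 + (1 - g_s_local) * tcrossprod(N)
  Gc <- I3 + (g_c_local - 1) * tcrossprod(C)
  Gs %*% Gc
}

#' Growth field for a mesh
#'
#' Evaluates the per-element growth tensors for the whole mesh. Three modes:
#' \describe{
#'   \item{`"attenuated"`}{the generalized logistic attenuates `g_surface`
#'     with distance to the anterior surface and `g_crease` with distance to
#'     the crease plane (the bilayer configuration: the skin grows, the
#'     substrate barely does).}
#'   \item{`"uniform"`}{no depth attenuation: every element grows
#'     tangentially by `g_surface` (the single-sheet configuration, where the
#'     whole sheet is growing skin). Crease growth, when distinct from the
#'     surface growth, is still attenuated with distance to the crease.}
#'   \item{`"isotropic"`}{`G = g I` everywhere (swelling, as in the gel
#'     analog experiment).}
#' }
#' For strips a unit `direction` may be given, replacing the tangential
#' expansion by uniaxial growth `I + (g - 1) d d^T`.
#'
#' @param mesh a `tet_mesh`.
#' @param targets a [growth_targets()].
#' @param mode growth mode, see Details.
#' @param sharpness logistic sharpness (1/mm).
#' @param direction optional unit vector for uniaxial growth.
#' @return an object of class `element_growth`: list with `G` (M x 9 matrix,
#'   column-major per tet), `g_s_local`, `g_c_local`, and `detG`.
#' @export
growth_field <- function(mesh, targets, mode = c("attenuated", "uniform",
                                                 "isotropic"),
                         sharpness = 100, direction = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(targets, "growth_targets"))
  mode <- match.arg(mode)
  M <- nrow(mesh$tets)
  g_crease_target <- if (targets$crease_equals_surface) targets$g_surface
                     else targets$g_crease
  has_crease <- length(mesh$node_sets$CREASE) > 0 && g_crease_target > 1
  if (mode == "isotropic") {
    g <- targets$g_surface
    G <- matrix(rep(as.vector(diag(3) * g), each = M), M, 9)
    return(structure(list(G = G, g_s_local = rep(g, M), g_c_local = rep(1, M),
                          detG = rep(g^3, M)), class = "element_growth"))
  }
  depth <- compute_depth_fields(mesh, require_crease = FALSE)
  g_s <- if (mode == "uniform") rep(targets$g_surface, M)
         else logistic_attenuation(targets$g_surface, depth$x_s,
                                   mesh$thickness_T, sharpness)
  g_c <- if (has_crease)
           logistic_attenuation(g_crease_target, depth$x_c,
                                mesh$thickness_T, sharpness)
         else rep(1, M)
  if (!is.null(direction)) {
    d <- direction / sqrt(sum(direction^2))
    ddt <- as.vector(tcrossprod(d))
    G <- matrix(rep(as.vector(diag(3)), each = M), M, 9) +
      (g_s - 1) * matrix(rep(ddt, each = M), M, 9)
    return(structure(list(G = G, g_s_local = g_s, g_c_local = rep(1, M),
                          detG = rep(1, M) + (g_s - 1)),
                     class = "element_growth"))
  }
  N <- mesh$normal_of_tet
  C <- if (!is.null(mesh$crease_direction)) mesh$crease_direction else c(0, 1, 0)
  # Gs = gs I + (1-gs) N N^T ; Gc = I + (gc-1) C C^T ; G = Gs Gc, vectorized.
  G <- matrix(0, M, 9)
  I3 <- diag(3)
  CCt <- tcrossprod(C)
  for (col in 1:3) {
    for (row in 1:3) {
      # Gs[row, k] = gs * I[row,k] + (1-gs) * N[,row] * N[,k]
      acc <- 0
      for (k in 1:3) {
        Gs_rk <- g_s * I3[row, k] + (1 - g_s) * N[, row] * N[, k]
        Gc_kc <- I3[k, col] + (g_c - 1) * CCt[k, col]
        acc <- acc + Gs_rk * Gc_kc
      }
      G[, (col - 1) * 3 + row] <- acc
    }
  }
  structure(list(G = G, g_s_local = g_s, g_c_local = g_c,
                 detG = g_s^2 * g_c), class = "element_growth")
}

#' Developmental growth schedule
#'
#' Normalized-time ramps for the quasi-static driver. The surface growth
#' follows a linear ramp from 1 at `tau = 0` to `g_surface_final` at
#' `tau = 1`; the crease growth follows the quadratic fixed by its three
#' anchors (1 at `tau = 0`, `g_crease_mid` at `tau = 1/3`, `g_crease_final`
#' at `tau = 1`). With the default anchors (1, 1.5, 2.2) the crease ramp is
#' `g_c(tau) = 1 + 1.65 tau - 0.45 tau^2`, monotone on [0, 1]; the default
#' surface ramp reaches 1.1 at `tau = 1/3`, matching the growth measured one
#' third of the way through the ridge-forming period.
#'
#' @param g_surface_final surface growth at `tau = 1`.
#' @param g_crease_final crease growth at `tau = 1`.
#' @param g_crease_mid crease growth anchor at `tau = 1/3`.
#' @param n_steps number of equal quasi-static steps on (0, 1].
#' @param crease_equals_surface single-sheet flag, see [growth_targets()].
#' @return an object of class `growth_schedule`.
#' @export
growth_schedule <- function(g_surface_final = 1.3, g_crease_final = 2.2,
                            g_crease_mid = 1.5, n_steps = 20,
                            crease_equals_surface = FALSE) {
  stopifnot(g_surface_final >= 1, g_crease_final >= 1, n_steps >= 1)
  # quadratic through (0, 1), (1/3, mid), (1, final)
  A <- rbind(c(0, 0, 1), c(1 / 9, 1 / 3, 1), c(1, 1, 1))
  cf <- solve(A, c(1, g_crease_mid, g_crease_final))
  gc_fun <- function(tau) cf[1] * tau^2 + cf[2] * tau + cf[3]
  tt <- seq(0, 1, length.out = 201)
  if (any(diff(gc_fun(tt)) < -1e-12))
    stop("crease anchors give a non-monotone quadratic ramp")
  structure(list(
    normalized_times = seq(0, 1, length.out = n_steps + 1L),
    g_surface_final = g_surface_final,
    crease_coef = cf,
    g_crease_final = g_crease_final, g_crease_mid = g_crease_mid,
    crease_equals_surface = isTRUE(crease_equals_surface),
    anchors = list(surface = cbind(tau = c(0, 1), g = c(1, g_surface_final)),
                   crease = cbind(tau = c(0, 1 / 3, 1),
                                  g = c(1, g_crease_mid, g_crease_final)))),
    class = "growth_schedule")
}

#' Evaluate a growth schedule at a normalized time
#'
#' @param schedule a [growth_schedule()].
#' @param tau normalized time in `[0, 1]` (0 = start of the ridge-forming
#'   period, 1 = end).
#' @return a [growth_targets()] at time `tau`.
#' @export
evaluate_schedule <- function(schedule, tau) {
  stopifnot(inherits(schedule, "growth_schedule"))
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  gs <- 1 + (schedule$g_surface_final - 1) * tau
  cf <- schedule$crease_coef
  gcv <- cf[1] * tau^2 + cf[2] * tau + cf[3]
  growth_targets(g_surface = gs, g_crease = max(1, gcv),
                 crease_equals_surface = schedule$crease_equals_surface)
}
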