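#' Neo-Hookean material parameters
#'
#' A nearly incompressible neo-Hookean solid parameterized by its shear
#' modulus `mu` and Poisson's ratio `nu`. The bulk modulus is `K = alpha mu`
#' with `alpha = (2 + 2 nu) / (3 - 6 nu)`, and the Young's modulus is
#' `E = 2 mu (1 + nu)`. Internally the solver works in skin-normalized
#' stress units (`mu_skin = 1`); `mu` may be given in those units or in Pa.
#'
#' @param mu shear modulus (Pa, or skin-normalized).
#' @param nu Poisson's ratio in `[0, 0.5)`; soft embryonic tissues are
#'   modeled as nearly incompressible with `nu = 0.45`.
#' @return an object of class `nh_material`.
#' @export
material <- function(mu = 1, nu = 0.45) {
  stopifnot(mu > 0, nu >= 0, nu < 0.5)
  alpha <- (2 + 2 * nu) / (3 - 6 * nu)
  structure(list(mu = mu, nu = nu, alpha = alpha, K = alpha * mu,
                 young_E = 2 * mu * (1 + nu)), class = "nh_material")
}

#' Region materials from a skin-to-substrate stiffness ratio
#'
#' Both regions share the same Poisson's ratio, so the Young's-modulus ratio
#' `E_skin / E_substrate` equals the shear-modulus ratio. The skin shear
#' modulus is normalized to 1.
#'
#' @param stiffness_ratio `E_skin / E_substrate` (> 0).
#' @param nu shared Poisson's ratio.
#' @return named list with `SKIN` and `SUBSTRATE` [material()] objects.
#' @export
materials_from_ratio <- function(stiffness_ratio = 100, nu = 0.45) {
  stopifnot(stiffness_ratio > 0)
  list(SKIN = material(mu = 1, nu = nu),
       SUBSTRATE = material(mu = 1 / stiffness_ratio, nu = nu))
}
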