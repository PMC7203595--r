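#' Physical parameters of the canalicular flow model
#'
#' Bundles the physical constants entering the hydraulic model of the
#' lacunocanalicular network (LCN): bone-fluid viscosity, canalicular and
#' cell-process radii, the annular flow cross-section, the effective
#' canalicular permeability (Brinkman value for the fiber-filled pericellular
#' annulus), the shear-stress constant, the volumetric strain rate and the
#' lacunar pore volume.
#'
#' The annular cross-section `A = (Ca.Rd^2 - CP.Rd^2) * pi` is derived from
#' the two radii unless `annulus_area` is supplied explicitly, in which case it
#' must agree with the derived value to within 2%.
#'
#' @param mu Dynamic viscosity of the interstitial bone fluid, Pa s.
#' @param canaliculus_radius Radius of the canaliculus (`Ca.Rd`), nm.
#' @param process_radius Radius of the osteocyte cell process (`CP.Rd`), nm.
#' @param k_p_eff Effective permeability of a single canaliculus, m^2.
#' @param shear_constant Shear-stress constant `K` relating mean fluid velocity
#'   to the shear stress on the cell-process membrane, 1/um.
#' @param strain_rate Volumetric strain rate applied in the deformation-driven
#'   boundary condition, 1/s. The default corresponds to peak strain rates
#'   during vigorous exercise; walking is about tenfold lower.
#' @param lacuna_volume Fluid volume attributed to an osteocyte lacuna, um^3.
#' @param annulus_area Optional override for the annular cross-section, um^2.
#'
#' @return An object of class `hydraulic_params`: a named list with fields
#'   `mu`, `canaliculus_radius`, `process_radius`, `annulus_area`, `k_p_eff`,
#'   `shear_constant`, `strain_rate`, `lacuna_volume`.
#' @examples
#' p <- hydraulic_params()
#' p$annulus_area            # ~0.061 um^2
#' edge_conductivity(1, p)   # ~8.8e-4 um^3/(Pa s) for a 1-um canaliculus
#' @export
hydraulic_params <- function(mu = 1.06e-3,
                             canaliculus_radius = 157.5,
                             process_radius = 73,
                             k_p_eff = 1.53e-17,
                             shear_constant = 465,
                             strain_rate = 0.015,
                             lacuna_volume = 350,
                             annulus_area = NULL) {
  if (process_radius >= canaliculus_radius)
    stop("process_radius must be smaller than canaliculus_radius")
  vals <- c(mu = mu, canaliculus_radius = canaliculus_radius,
            process_radius = process_radius, k_p_eff = k_p_eff,
            shear_constant = shear_constant, strain_rate = strain_rate,
            lacuna_volume = lacuna_volume)
  if (any(vals <= 0))
    stop("all physical parameters must be positive")
  # radii are given in nm; the flow cross-section is kept in um^2
  a_derived <- (1e-3 * canaliculus_radius)^2 * pi - (1e-3 * process_radius)^2 * pi
  if (!is.null(annulus_area)) {
    if (abs(annulus_area - a_derived) > 0.02 * a_derived)
      stop(sprintf("annulus_area override %.4g disagrees with value derived from radii (%.4g) by more than 2%%",
                   annulus_area, a_derived))
    a_derived <- annulus_area
  }
  structure(list(mu = mu,
                 canaliculus_radius = canaliculus_radius,
                 process_radius = process_radius,
                 annulus_area = a_derived,
                 k_p_eff = k_p_eff,
                 shear_constant = shear_constant,
                 strain_rate = strain_rate,
                 lacuna_volume = lacuna_volume),
            class = "hydraulic_params")
}

#' @export
print.hydraulic_params <- function(x, ...) {
  cat("Hydraulic parameters of the canalicular flow model\n")
  cat(sprintf("  viscosity mu           : %.3g Pa s\n", x$mu))
  cat(sprintf("  canaliculus radius     : %.4g nm\n", x$canaliculus_radius))
  cat(sprintf("  cell process radius    : %.4g nm\n", x$process_radius))
  cat(sprintf("  annulus cross-section A: %.4g um^2\n", x$annulus_area))
  cat(sprintf("  canalicular k_p,eff    : %.3g m^2\n", x$k_p_eff))
  cat(sprintf("  shear constant K       : %.4g 1/um\n", x$shear_constant))
  cat(sprintf("  strain rate            : %.3g 1/s\n", x$strain_rate))
  cat(sprintf("  lacunar volume         : %.4g um^3\n", x$lacuna_volume))
  invisible(x)
}

# k_p,eff / mu in um^2 / (Pa s); 1 m^2 = 1e12 um^2
mobility_um2 <- function(params) (params$k_p_eff * 1e12) / params$mu

#' Hydraulic conductivity of a single canaliculus
#'
#' Darcy conductivity of the annular channel between the osteocyte process and
#' the canalicular wall: `C = (k_p_eff / mu) * A / l`, returned in
#' um^3/(Pa s). Conductivities are stored positive; the direction of flow is
#' carried by the edge orientation convention, so that fluid always runs from
#' high to low pressure.
#'
#' @param length Canalicular arc length, um (positive).
#' @param params A [hydraulic_params()] object.
#' @return Conductivity in um^3/(Pa s), same shape as `length`.
#' @export
edge_conductivity <- function(length, params = hydraulic_params()) {
  if (any(!is.finite(length)) || any(length <= 0))
    stop("edge lengths must be positive and finite")
  mobility_um2(params) * params$annulus_area / length
}

#' Shear stress on the cell-process membrane
#'
#' Converts a mean canalicular fluid velocity into the wall shear stress felt
#' by the osteocyte process, `tau = mu * K * |v|`. With `v` in um/s and `K` in
#' 1/um the product is in Pa.
#'
#' @param velocity Fluid velocity, um/s (sign is ignored).
#' @param params A [hydraulic_params()] object.
#' @return Shear stress in Pa, same shape as `velocity`.
#' @examples
#' shear_stress(1)  # ~0.49 Pa
#' @export
shear_stress <- function(velocity, params = hydraulic_params()) {
  params$mu * params$shear_constant * abs(velocity)
}
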