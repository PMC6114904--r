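#' Physical environment for bond dynamics
#'
#' Bundles the thermodynamic and hydrodynamic constants the model needs:
#' temperature, thermal energy \eqn{k_B T}, and solvent viscosity. The
#' diffusivity of the reorienting protein domain follows from Stokes drag on
#' a sphere of radius `r0` (the hinge-to-interface distance of the parameter
#' set), \eqn{D = k_B T / (6 \pi \eta r_0)}.
#'
#' @param temperature Absolute temperature in kelvin.
#' @param viscosity Solvent viscosity in Pa s. The default is water at room
#'   temperature.
#' @return A `bond_environment` object: a list with fields `temperature`
#'   (K), `viscosity` (Pa s) and `thermal_energy` (pN nm).
#' @examples
#' env <- bond_environment()
#' env$thermal_energy      # ~4.12 pN nm
#' diffusivity(env, r0 = 1.7)  # nm^2/s
#' @export
bond_environment <- function(temperature = 298.15, viscosity = 8.9e-4) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0,
            is.numeric(viscosity), length(viscosity) == 1L, viscosity > 0)
  structure(
    list(
      temperature = temperature,
      viscosity = viscosity,
      # kB = 1.380649e-23 J/K; 1 J = 1e21 pN nm
      thermal_energy = 1.380649e-2 * temperature
    ),
    class = "bond_environment"
  )
}

#' @export
print.bond_environment <- function(x, ...) {
  cat("<bond_environment>\n")
  cat(sprintf("  temperature:    %.2f K\n", x$temperature))
  cat(sprintf("  thermal energy: %.4f pN nm\n", x$thermal_energy))
  cat(sprintf("  viscosity:      %.3g Pa s\n", x$viscosity))
  invisible(x)
}

#' Stokes diffusivity of the reorienting domain
#'
#' @param env A [bond_environment()].
#' @param r0 Hydrodynamic radius in nm; conventionally the hinge-to-interface
#'   distance of the parameter set.
#' @return Diffusion coefficient in nm^2/s.
#' @export
diffusivity <- function(env, r0) {
  stopifnot(inherits(env, "bond_environment"), is.numeric(r0), r0 > 0)
  # kBT in J, r0 in m -> D in m^2/s -> nm^2/s
  (env$thermal_energy * 1e-21) / (6 * pi * env$viscosity * (r0 * 1e-9)) * 1e18
}
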