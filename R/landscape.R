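#' Angle-dependent spring constant of the bond
#'
#' \eqn{k(\theta) = k_0 + k_1 (1 + \cos\theta)}: the effective stiffness of
#' the adhesive interface, which grows as the polar angle decreases (large
#' inter-domain angle), encoding the allosteric strengthening of the bond.
#'
#' @param theta Polar angle(s) in degrees, within the parameter set's
#'   `[theta_min, theta_max]`.
#' @param params A [bond_parameters()] object.
#' @return Stiffness in kBT/nm^2.
#' @export
spring_constant <- function(theta, params) {
  params <- as_bond_parameters(params)
  check_theta_range(theta, params)
  k_theta(theta * pi / 180, params)
}

#' Angular (conformational) potential
#'
#' The cusp-shaped double-basin potential \eqn{C(\theta)}: piecewise linear
#' in \eqn{\cos\theta}, zero at `theta_max` (small inter-domain angle), `H`
#' at the transition angle `theta_c`, and `G` at `theta_min` (large
#' inter-domain angle).
#'
#' @inheritParams spring_constant
#' @return Energy in kBT.
#' @export
angular_potential <- function(theta, params) {
  params <- as_bond_parameters(params)
  check_theta_range(theta, params)
  C_theta(theta * pi / 180, params)
}

check_theta_range <- function(theta, params, tol = 1e-9) {
  if (any(theta < params$theta_min - tol | theta > params$theta_max + tol)) {
    stop(sprintf("`theta` must lie within [%.6g, %.6g] degrees",
                 params$theta_min, params$theta_max), call. = FALSE)
  }
  invisible(theta)
}

#' Bond energy landscape
#'
#' Evaluates \eqn{U(r, \theta) = \tfrac12 k(\theta) (r - r_0)^2 -
#' F r \cos\theta + C(\theta)} in kBT. Vectorized over `r`, `theta` and
#' `force` (recycled to a common length). Values at `r > r0 + d` lie beyond
#' the rupture boundary and are meaningful for plotting only.
#'
#' @param r Bond extension coordinate(s), nm.
#' @param theta Polar angle(s), degrees.
#' @param force Applied force(s), pN.
#' @param params A [bond_parameters()] object.
#' @param env A [bond_environment()].
#' @return Potential energy in kBT.
#' @examples
#' p <- cca_parameters()
#' potential_energy(p$r0 + p$d, p$theta_max, 0, p)  # E0
#' @export
potential_energy <- function(r, theta, force = 0, params,
                             env = bond_environment()) {
  params <- as_bond_parameters(params)
  check_theta_range(theta, params)
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  if (any(force < 0)) stop("`force` must be non-negative", call. = FALSE)
  th <- theta * pi / 180
  0.5 * k_theta(th, params) * (r - params$r0)^2 -
    force * r * cos(th) / env$thermal_energy +
    C_theta(th, params)
}

#' Tidy grid of the energy landscape
#'
#' Evaluates the landscape on a regular (r, alpha) grid for plotting or
#' export, in the inter-domain-angle parameterization used in figures.
#'
#' @inheritParams potential_energy
#' @param n_r,n_alpha Grid resolution.
#' @param r_max Upper edge of the radial grid; defaults to just beyond the
#'   rupture boundary `r0 + d`.
#' @return A tibble with columns `r`, `alpha`, `theta`, `energy` and
#'   `ruptured` (`TRUE` beyond the rupture boundary).
#' @export
landscape_grid <- function(params, env = bond_environment(), force = 0,
                           n_r = 121, n_alpha = 181, r_max = NULL) {
  params <- as_bond_parameters(params)
  dom <- radial_domain(params)
  if (is.null(r_max)) r_max <- params$r0 + 1.05 * params$d
  grid <- tidyr::expand_grid(
    r = seq(dom[1], r_max, length.out = n_r),
    alpha = seq(params$alpha_min, params$alpha_max, length.out = n_alpha)
  )
  grid$theta <- alpha_from_theta(grid$alpha, params$phi)  # same linear map
  grid$energy <- potential_energy(grid$r, grid$theta, force, params, env)
  grid$ruptured <- grid$r > params$r0 + params$d
  grid
}

#' Equilibrium probability of the small inter-domain angle state
#'
#' Integrates the Boltzmann distribution of the landscape over the bound
#' region (`r` up to the rupture boundary) and returns the weight of the
#' small-angle basin `alpha < alpha_c` (equivalently `theta > theta_c`),
#' \eqn{p_S(F) = Z_S / (Z_S + Z_L)}. The configuration-space measure is set
#' by `measure`: `"planar"` (default) treats the hinge reorientation as
#' in-plane rotation of the domain vector (weight `r dr dtheta`),
#' `"spherical"` as free 3D reorientation (`r^2 sin(theta) dr dtheta`), and
#' `"flat"` uses the bare coordinates (`dr dtheta`).
#'
#' @param force Applied force(s) in pN; vectorized.
#' @inheritParams potential_energy
#' @param measure Configuration-space measure: `"planar"`, `"spherical"` or
#'   `"flat"`.
#' @param control A [numeric_control()].
#' @return Probability in `[0, 1]`, one value per force.
#' @examples
#' equilibrium_small_angle_probability(0, cca_parameters())
#' @export
equilibrium_small_angle_probability <- function(force, params,
                                                env = bond_environment(),
                                                measure = "planar",
                                                control = numeric_control()) {
  params <- as_bond_parameters(params)
  if (any(force < 0)) stop("`force` must be non-negative", call. = FALSE)
  vapply(force, function(f) {
    p_small_from_profile(angular_profile(f, params, env, measure, control))
  }, 0)
}

#' Reduced angular free energy
#'
#' The effective one-dimensional potential governing the conformational
#' coordinate after the bound-region radial fluctuations are integrated
#' out: \eqn{W(\theta) = -k_B T \ln \int g(r)\, e^{-U(r,\theta)/k_B T} dr}
#' (plus the angular part of the measure). This is the profile on which the
#' angular transition rates are computed, so equilibrium quantities and
#' kinetics share one code path.
#'
#' @inheritParams equilibrium_small_angle_probability
#' @param force Single force in pN.
#' @return A tibble with columns `theta` (degrees), `alpha` (degrees),
#'   `free_energy` (kBT, minimum at zero) and `basin` (`"small"`/`"large"`
#'   inter-domain angle).
#' @export
angular_free_energy <- function(force, params, env = bond_environment(),
                                measure = "planar",
                                control = numeric_control()) {
  params <- as_bond_parameters(params)
  stopifnot(length(force) == 1L, force >= 0)
  prof <- angular_profile(force, params, env, measure, control)
  tibble::tibble(
    theta = prof$theta * 180 / pi,
    alpha = alpha_from_theta(theta, params$phi),
    free_energy = prof$W - min(prof$W),
    basin = ifelse(prof$small, "small", "large")
  )
}
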