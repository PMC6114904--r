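#' Convert between the inter-domain angle and the polar angle
#'
#' The conformational coordinate of the model is the angle `alpha` between
#' the M2 and M3 helix bundles of alpha-catenin; the dynamical coordinate is
#' the polar angle `theta` between the hinge-to-interface vector and the
#' force axis. With the M2 domain offset from the force axis by `phi`, the
#' two are related by `alpha = 180 - theta - phi` (degrees).
#'
#' @param alpha,theta Angles in degrees, in (0, 180).
#' @param phi Offset angle of the M2 domain from the force axis, degrees.
#' @return The converted angle in degrees.
#' @examples
#' theta_from_alpha(48, 0)   # 132
#' alpha_from_theta(132, 0)  # 48
#' @export
theta_from_alpha <- function(alpha, phi = 0) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 180)) {
    stop("`alpha` must lie strictly between 0 and 180 degrees", call. = FALSE)
  }
  180 - alpha - phi
}

#' @rdname theta_from_alpha
#' @export
alpha_from_theta <- function(theta, phi = 0) {
  if (any(!is.finite(theta))) stop("`theta` must be finite", call. = FALSE)
  180 - theta - phi
}

#' Convert rupture-barrier energies to stiffness coefficients
#'
#' The angle-dependent spring constant is
#' \eqn{k(\theta) = k_0 + k_1 (1 + \cos\theta)}, and the zero-force rupture
#' barrier in each conformation is \eqn{k(\theta) d^2/2}. The two stiffness
#' coefficients are therefore fixed by the barrier `E0` at the small-angle
#' end (`theta_max`) and the barrier increment `E1` at the large-angle end
#' (`theta_min`):
#' \eqn{k_1 = 2 E_1 / (d^2 (\cos\theta_{min} - \cos\theta_{max}))} and
#' \eqn{k_0 = 2 E_0 / d^2 - k_1 (1 + \cos\theta_{max})}.
#'
#' @param E0 Rupture barrier at the minimum inter-domain angle, kBT.
#' @param E1 Extra rupture barrier at the maximum inter-domain angle, kBT.
#' @param d Transition-state distance, nm.
#' @param theta_min,theta_max Angular range of the polar angle, degrees.
#' @return Named numeric vector with components `k0` and `k1` (kBT/nm^2).
#' @examples
#' stiffness_from_energies(21.8, 5.8, 0.56, 11, 132)
#' @export
stiffness_from_energies <- function(E0, E1, d, theta_min, theta_max) {
  stopifnot(d > 0, E0 >= 0, E1 >= 0)
  if (theta_min >= theta_max) {
    stop("degenerate geometry: `theta_min` must be smaller than `theta_max`",
         call. = FALSE)
  }
  cmin <- cos(theta_min * pi / 180)
  cmax <- cos(theta_max * pi / 180)
  if (cmin <= cmax) {
    stop("degenerate geometry: cos(theta_min) must exceed cos(theta_max)",
         call. = FALSE)
  }
  k1 <- 2 * E1 / (d^2 * (cmin - cmax))
  k0 <- 2 * E0 / d^2 - k1 * (1 + cmax)
  if (k0 < 0) {
    stop("invalid parameters: implied k0 is negative (E1 too large relative to E0)",
         call. = FALSE)
  }
  c(k0 = unname(k0), k1 = unname(k1))
}

#' @rdname stiffness_from_energies
#' @param k0,k1 Stiffness coefficients, kBT/nm^2.
#' @return For `energies_from_stiffness()`, a named vector `E0`, `E1` (kBT).
#' @export
energies_from_stiffness <- function(k0, k1, d, theta_min, theta_max) {
  stopifnot(d > 0)
  cmin <- cos(theta_min * pi / 180)
  cmax <- cos(theta_max * pi / 180)
  c(E0 = unname((k0 + k1 * (1 + cmax)) * d^2 / 2),
    E1 = unname(k1 * (cmin - cmax) * d^2 / 2))
}

#' Landscape parameter set for the two-basin catch-bond model
#'
#' Constructs and validates the full parameterization of the bond energy
#' landscape \eqn{U(r, \theta) = \tfrac12 k(\theta)(r - r_0)^2 -
#' F r \cos\theta + C(\theta)}: interface energetics (`E0`, `E1`), the
#' angular barrier and basin offset (`H`, `G`), the geometry (`d`, `r0`,
#' angular range) and the derived stiffnesses and polar angles.
#'
#' @param E0 Free energy barrier to rupture at the minimum inter-domain
#'   angle (zero force), kBT. Must be positive.
#' @param E1 Extra rupture barrier at the maximum inter-domain angle, kBT.
#' @param H Free energy barrier for the small-to-large angle transition, kBT.
#' @param G Free energy offset between the angular basins, kBT. The reverse
#'   barrier is `H - G`, which must be non-negative.
#' @param d Transition-state distance: the bond ruptures at `r > r0 + d`, nm.
#' @param r0 Natural bond length (hinge-to-interface distance), nm.
#' @param alpha_min,alpha_c,alpha_max Minimum, transition and maximum
#'   inter-domain angles, degrees, with
#'   `0 < alpha_min < alpha_c < alpha_max < 180`.
#' @param phi Offset angle of the M2 domain from the force axis, degrees.
#' @return A `bond_parameters` object: a named list carrying the ten inputs
#'   plus the derived `k0`, `k1` (kBT/nm^2) and `theta_min`, `theta_c`,
#'   `theta_max` (degrees).
#' @examples
#' p <- bond_parameters(E0 = 21.8, E1 = 5.8, H = 25, G = 5, d = 0.56,
#'                      r0 = 1.7, alpha_min = 48, alpha_c = 53,
#'                      alpha_max = 169)
#' p$k0
#' @seealso [cca_parameters()] for the packaged cadherin-catenin-actin
#'   best-fit values, [read_bond_parameters()] for JSON files.
#' @export
bond_parameters <- function(E0, E1, H, G, d, r0,
                            alpha_min, alpha_c, alpha_max, phi = 0) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
    as.numeric(x)
  }
  E0 <- num1(E0, "E0"); E1 <- num1(E1, "E1"); H <- num1(H, "H")
  G <- num1(G, "G"); d <- num1(d, "d"); r0 <- num1(r0, "r0")
  alpha_min <- num1(alpha_min, "alpha_min"); alpha_c <- num1(alpha_c, "alpha_c")
  alpha_max <- num1(alpha_max, "alpha_max"); phi <- num1(phi, "phi")

  if (d <= 0) stop("`d` must be positive", call. = FALSE)
  if (r0 <= 0) stop("`r0` must be positive", call. = FALSE)
  if (E0 <= 0) stop("`E0` must be positive", call. = FALSE)
  if (E1 < 0) stop("`E1` must be non-negative", call. = FALSE)
  if (H < 0) stop("`H` must be non-negative", call. = FALSE)
  # H - G < 0 (a downhill large-to-small crossing) is allowed: the in-silico
  # mutation protocol lowers H at fixed G all the way to zero.
  if (!(alpha_min < alpha_c && alpha_c < alpha_max)) {
    stop("constraint violated: need alpha_min < alpha_c < alpha_max",
         call. = FALSE)
  }
  if (alpha_min <= 0 || alpha_max >= 180) {
    stop("constraint violated: angles must lie strictly within (0, 180) degrees",
         call. = FALSE)
  }
  theta_max <- theta_from_alpha(alpha_min, phi)
  theta_c <- theta_from_alpha(alpha_c, phi)
  theta_min <- theta_from_alpha(alpha_max, phi)
  if (theta_min <= 0 || theta_max >= 180) {
    stop("constraint violated: polar angle range must lie within (0, 180) degrees; adjust `phi`",
         call. = FALSE)
  }
  k <- stiffness_from_energies(E0, E1, d, theta_min, theta_max)
  structure(
    list(E0 = E0, E1 = E1, H = H, G = G, d = d, r0 = r0,
         alpha_min = alpha_min, alpha_c = alpha_c, alpha_max = alpha_max,
         phi = phi,
         k0 = unname(k["k0"]), k1 = unname(k["k1"]),
         theta_min = theta_min, theta_c = theta_c, theta_max = theta_max),
    class = "bond_parameters"
  )
}

#' @export
print.bond_parameters <- function(x, ...) {
  cat("<bond_parameters>\n")
  cat(sprintf("  E0 = %.3g kBT, E1 = %.3g kBT (rupture barriers %.3g / %.3g)\n",
              x$E0, x$E1, x$E0, x$E0 + x$E1))
  cat(sprintf("  H = %.3g kBT, G = %.3g kBT (angular barriers %.3g / %.3g)\n",
              x$H, x$G, x$H, x$H - x$G))
  cat(sprintf("  d = %.3g nm, r0 = %.3g nm\n", x$d, x$r0))
  cat(sprintf("  alpha: %.4g / %.4g / %.4g deg (phi = %.3g)\n",
              x$alpha_min, x$alpha_c, x$alpha_max, x$phi))
  cat(sprintf("  derived k0 = %.4g, k1 = %.4g kBT/nm^2\n", x$k0, x$k1))
  invisible(x)
}

#' Best-fit parameters for the cadherin-catenin-actin complex
#'
#' Loads the packaged parameter file with the published best-fit landscape
#' parameters for the cadherin/beta-catenin/alpha-catenin/F-actin bond under
#' optical-tweezer loading (E0 = 21.8 kBT, E1 = 5.8 kBT, H = 25 kBT,
#' G = 5 kBT, d = 0.56 nm, r0 = 1.7 nm, alpha angles 48/53/169 degrees,
#' phi = 0).
#'
#' @return A [bond_parameters()] object.
#' @examples
#' cca_parameters()
#' @export
cca_parameters <- function() {
  read_bond_parameters(system.file("extdata", "table1.json",
                                   package = "catchbond", mustWork = TRUE))
}

#' Coerce a list or data frame row to bond parameters
#'
#' @param x A `bond_parameters` object, a named list, or a one-row data
#'   frame with columns named as the [bond_parameters()] arguments.
#' @return A validated `bond_parameters` object.
#' @export
as_bond_parameters <- function(x) {
  if (inherits(x, "bond_parameters")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  stopifnot(is.list(x))
  nms <- c("E0", "E1", "H", "G", "d", "r0",
           "alpha_min", "alpha_c", "alpha_max")
  missing <- setdiff(nms, names(x))
  if (length(missing)) {
    stop("missing parameter fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bond_parameters(E0 = x$E0, E1 = x$E1, H = x$H, G = x$G, d = x$d, r0 = x$r0,
                  alpha_min = x$alpha_min, alpha_c = x$alpha_c,
                  alpha_max = x$alpha_max,
                  phi = if (is.null(x$phi)) 0 else x$phi)
}

#' @method tidy bond_parameters
#' @export
tidy.bond_parameters <- function(x, ...) {
  tibble::tibble(
    term = c("E0", "E1", "H", "G", "d", "r0",
             "alpha_min", "alpha_c", "alpha_max", "phi", "k0", "k1"),
    estimate = c(x$E0, x$E1, x$H, x$G, x$d, x$r0,
                 x$alpha_min, x$alpha_c, x$alpha_max, x$phi, x$k0, x$k1),
    unit = c("kBT", "kBT", "kBT", "kBT", "nm", "nm",
             "deg", "deg", "deg", "deg", "kBT/nm^2", "kBT/nm^2")
  )
}

# replace a subset of natural parameters, re-deriving k0/k1 and thetas
modify_parameters <- function(params, ...) {
  repl <- list(...)
  base <- params[c("E0", "E1", "H", "G", "d", "r0",
                   "alpha_min", "alpha_c", "alpha_max", "phi")]
  bad <- setdiff(names(repl), names(base))
  if (length(bad)) {
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  base[names(repl)] <- repl
  do.call(bond_parameters, base)
}
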