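# Internal numerical core shared by the landscape equilibrium quantities and
# the kinetic rate reconstruction. Everything here works in reduced units:
# energies in kBT, lengths in nm, angles in radians, time in seconds.

#' Resolution control for the landscape/kinetics quadratures
#'
#' The angular free-energy profile, the exact 1D mean-first-passage-time
#' double integrals and the basin averages are evaluated on fixed grids.
#' Defaults resolve the cusp region (thermal decay length ~ kBT / |C'|)
#' with tens of points for barrier heights up to ~40 kBT.
#'
#' @param n_theta Total number of angular grid points (split between the
#'   two basins, at least 200 each).
#' @param n_r Radial points for the marginal (Boltzmann-weight) integrals.
#' @param n_r_mfpt Radial points for the rupture first-passage integrals.
#' @param n_rup_nodes Angular nodes per basin at which the radial rupture
#'   rate is evaluated before spline interpolation and basin averaging.
#' @return A list of class `numeric_control`.
#' @export
numeric_control <- function(n_theta = 1200, n_r = 160, n_r_mfpt = 400,
                            n_rup_nodes = 25) {
  stopifnot(n_theta >= 200, n_r >= 40, n_r_mfpt >= 80, n_rup_nodes >= 8)
  structure(list(n_theta = as.integer(n_theta), n_r = as.integer(n_r),
                 n_r_mfpt = as.integer(n_r_mfpt),
                 n_rup_nodes = as.integer(n_rup_nodes)),
            class = "numeric_control")
}

# measure switch: exponent of the radial weight r^p and the sin(theta) flag
measure_opts <- function(measure = c("planar", "spherical", "flat")) {
  measure <- match.arg(measure)
  switch(measure,
         planar = list(rpow = 1, sin = FALSE),
         spherical = list(rpow = 2, sin = TRUE),
         flat = list(rpow = 0, sin = FALSE))
}

# piecewise-linear-in-cos(theta) angular potential, theta in radians
C_theta <- function(theta, params) {
  cmin <- cos(params$theta_min * pi / 180)
  cmax <- cos(params$theta_max * pi / 180)
  cc <- cos(params$theta_c * pi / 180)
  ct <- cos(theta)
  thc <- params$theta_c * pi / 180
  ifelse(theta >= thc,
         params$H * (ct - cmax) / (cc - cmax),
         (params$H - params$G) * (ct - cmin) / (cc - cmin) + params$G)
}

# k(theta) in kBT/nm^2, theta in radians
k_theta <- function(theta, params) {
  params$k0 + params$k1 * (1 + cos(theta))
}

# radial domain of the bound region [r_lo, r0 + d]
radial_domain <- function(params) {
  k_soft <- k_theta(params$theta_max * pi / 180, params)
  sigma <- if (k_soft > 0) 1 / sqrt(k_soft) else Inf
  r_lo <- max(1e-3, min(params$r0 - 6 * sigma, params$r0))
  c(r_lo, params$r0 + params$d)
}

# trapezoid cumulative integral from the left; same length as x, first = 0
cumtrapz_left <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(x)]) / 2)

# log of int g(r) exp(-u(r, theta)) dr over the bound radial domain,
# vectorized over theta (radians). Force in pN, kBT in pN nm.
log_radial_weight <- function(theta, force, params, kBT, rpow, n_r = 160) {
  dom <- radial_domain(params)
  r <- seq(dom[1], dom[2], length.out = n_r)
  k <- k_theta(theta, params)
  # u[i, j] = 0.5 k_i (r_j - r0)^2 - F r_j cos(theta_i) / kBT
  u <- outer(k, (r - params$r0)^2 / 2) -
    outer(force * cos(theta) / kBT, r)
  lg <- rpow * log(r / params$r0)
  lw <- sweep(-u, 2, lg, "+")
  m <- apply(lw, 1, max)
  ew <- exp(lw - m)
  # trapezoid along r
  h <- r[2] - r[1]
  ints <- h * (rowSums(ew) - 0.5 * (ew[, 1] + ew[, n_r]))
  m + log(ints)
}

# angular grid (radians) with the cusp as a shared grid point and the
# reduced free energy W(theta) = C - ln(measure) - ln(radial weight), in kBT
angular_profile <- function(force, params, env, measure = "planar",
                            control = numeric_control()) {
  mo <- measure_opts(measure)
  th_min <- params$theta_min * pi / 180
  th_c <- params$theta_c * pi / 180
  th_max <- params$theta_max * pi / 180
  n_half <- max(200L, control$n_theta %/% 2L)
  th_L <- seq(th_min, th_c, length.out = n_half)
  th_S <- seq(th_c, th_max, length.out = n_half)
  theta <- c(th_L, th_S[-1])
  W <- C_theta(theta, params) -
    log_radial_weight(theta, force, params, env$thermal_energy, mo$rpow,
                      control$n_r)
  if (mo$sin) W <- W - log(sin(theta))
  i_c <- n_half  # index of the cusp
  list(theta = theta, W = W, i_c = i_c, small = theta >= th_c)
}

# mean first passage time to an absorbing end, started from the normalized
# density exp(-W) * start_mask, reflecting at the opposite end.
# x increasing; D in x-units^2 per second.
mfpt_profile <- function(x, W, D, absorb = c("right", "left"), start_mask) {
  absorb <- match.arg(absorb)
  W <- W - min(W)
  em <- exp(-W)
  ep <- exp(W)
  if (absorb == "right") {
    Phi <- cumtrapz_left(x, em)                 # int_a^y exp(-W)
    Phim <- cumtrapz_left(x, em * start_mask)   # start mass below y
    Z <- Phim[length(x)]
    trapz(x, ep * Phi * Phim) / (D * Z)
  } else {
    n <- length(x)
    Phi <- rev(cumtrapz_left(rev(x) * -1, rev(em)))      # int_y^b exp(-W)
    Phim <- rev(cumtrapz_left(rev(x) * -1, rev(em * start_mask)))
    Z <- Phim[1]
    trapz(x, ep * Phi * Phim) / (D * Z)
  }
}

# radial rupture rate 1/<tau> at fixed theta (radians)
radial_rupture_rate <- function(theta, force, params, env, rpow,
                                n_r = 400, eval_at = c("average", "minimum")) {
  eval_at <- match.arg(eval_at)
  dom <- radial_domain(params)
  r <- seq(dom[1], dom[2], length.out = n_r)
  D <- diffusivity(env, params$r0)
  vapply(theta, function(th) {
    u <- 0.5 * k_theta(th, params) * (r - params$r0)^2 -
      force * r * cos(th) / env$thermal_energy
    w <- u - rpow * log(r / params$r0)
    start <- if (eval_at == "minimum") {
      as.numeric(seq_along(r) == which.min(w))
    } else {
      rep(1, n_r)
    }
    1 / mfpt_profile(r, w, D, "right", start)
  }, 0)
}

# the four transition rates of the two-state reduction at one force;
# `prof` may carry a precomputed angular_profile() for this force
rate_set <- function(force, params, env, measure = "planar",
                     control = numeric_control(),
                     eval_at = c("average", "minimum"), prof = NULL) {
  eval_at <- match.arg(eval_at)
  mo <- measure_opts(measure)
  if (is.null(prof)) {
    prof <- angular_profile(force, params, env, measure, control)
  }
  th <- prof$theta
  W <- prof$W
  D_th <- diffusivity(env, params$r0) / params$r0^2  # rad^2 / s
  S <- prof$small
  idxS <- which(S)
  idxL <- which(!S)
  i_Smin <- idxS[which.min(W[idxS])]
  i_Lmin <- idxL[which.min(W[idxL])]

  # angular barrier crossing: exact MFPT from the equilibrated source basin
  # to the minimum of the target basin (reflecting wall behind the source)
  sel <- i_Lmin:length(th)
  omega_sl <- 1 / mfpt_profile(th[sel], W[sel], D_th, "left",
                               as.numeric(S[sel]))
  sel <- 1:i_Smin
  omega_ls <- 1 / mfpt_profile(th[sel], W[sel], D_th, "right",
                               as.numeric(!S[sel]))

  # rupture rates: radial MFPT rate averaged over the basin's conditional
  # angular density (or evaluated at the basin minimum)
  basin_rup <- function(idx, i_min) {
    if (eval_at == "minimum") {
      return(radial_rupture_rate(th[i_min], force, params, env, mo$rpow,
                                 control$n_r_mfpt))
    }
    nodes <- th[idx][unique(round(seq(1, length(idx),
                                      length.out = control$n_rup_nodes)))]
    lk <- log(radial_rupture_rate(nodes, force, params, env, mo$rpow,
                                  control$n_r_mfpt))
    lk_dense <- if (length(nodes) > 3) {
      stats::spline(nodes, lk, xout = th[idx])$y
    } else {
      stats::approx(nodes, lk, xout = th[idx], rule = 2)$y
    }
    wdens <- exp(-(W[idx] - min(W[idx])))
    trapz(th[idx], wdens * exp(lk_dense)) / trapz(th[idx], wdens)
  }
  omega_s_rup <- basin_rup(idxS, i_Smin)
  omega_l_rup <- basin_rup(idxL, i_Lmin)

  rates <- c(omega_sl = omega_sl, omega_ls = omega_ls,
             omega_s_rup = omega_s_rup, omega_l_rup = omega_l_rup)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("numerical error: non-finite or non-positive transition rate at force ",
         force, " pN", call. = FALSE)
  }
  rates
}

# equilibrium small-angle probability from an angular profile
p_small_from_profile <- function(prof) {
  w <- exp(-(prof$W - min(prof$W)))
  zS <- trapz(prof$theta[prof$small], w[prof$small])
  zL <- trapz(prof$theta[!prof$small], w[!prof$small])
  zS / (zS + zL)
}
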