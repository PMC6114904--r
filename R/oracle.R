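# Numerical ground truths for validating the analytical rate reconstruction:
# a finite-volume mean-first-passage-time solver for the full 2D Smoluchowski
# dynamics, and an overdamped Brownian-dynamics simulator. Both share the
# configuration-space measure (and hence equilibrium) with the landscape
# module through angular_profile()/radial weights.

#' Grid specification for the finite-volume solver
#'
#' @param n_r,n_theta Number of finite-volume cells in the radial and
#'   angular directions (at least 32 each). The absorbing rupture boundary
#'   sits exactly at `r0 + d`; reflecting boundaries at `r_lo`, `theta_min`
#'   and `theta_max`.
#' @param r_lo Lower radial edge in nm; defaults to the bound-region domain
#'   used by the landscape quadratures.
#' @param time_step_hint Optional Brownian-dynamics time step suggestion, s.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(n_r = 96, n_theta = 144, r_lo = NULL,
                      time_step_hint = NULL) {
  stopifnot(n_r >= 32, n_theta >= 32)
  structure(list(n_r = as.integer(n_r), n_theta = as.integer(n_theta),
                 r_lo = r_lo, time_step_hint = time_step_hint),
            class = "grid_spec")
}

# reduced potential w = U/kBT - log(measure weight) on arbitrary (r, theta)
reduced_potential <- function(r, theta, force, params, env, mo) {
  u <- 0.5 * k_theta(theta, params) * (r - params$r0)^2 -
    force * r * cos(theta) / env$thermal_energy +
    C_theta(theta, params)
  w <- u - mo$rpow * log(r / params$r0)
  if (mo$sin) w <- w - log(sin(theta))
  w
}

# Scharfetter-Gummel hop rate D/h^2 * B(dw), B(x) = x / (e^x - 1)
bernoulli_rate <- function(dw) {
  out <- dw / expm1(dw)
  out[abs(dw) < 1e-12] <- 1
  out
}

#' Grid mean first passage time to rupture (Smoluchowski oracle)
#'
#' Discretizes the two-dimensional Smoluchowski generator on the
#' (r, s = r0 theta) rectangle with an exponentially fitted
#' (Scharfetter-Gummel) finite-volume scheme that preserves detailed
#' balance on the grid, reflecting boundaries at `r_lo`, `theta_min`,
#' `theta_max`, and an absorbing boundary at `r = r0 + d`. Solves the
#' backward problem for the mean first passage time and the small-basin
#' rupture committor, then averages over the zero-force equilibrium start
#' distribution (the pre-loading condition).
#'
#' This deterministic solver is the high-barrier ground truth for the
#' analytical rates; Brownian dynamics ([simulate_rupture_times()])
#' complements it at low barriers.
#'
#' @inheritParams transition_rates
#' @param force A single force, pN.
#' @param grid A [grid_spec()].
#' @return A one-row tibble: `tau` (equilibrium-start mean lifetime, s),
#'   `tau_small_start`, `tau_large_start` (means conditioned on the start
#'   basin), `pi_s` (probability that rupture occurs from the small-angle
#'   basin), and the grid size used.
#' @examples
#' \donttest{
#' p <- bond_parameters(E0 = 8, E1 = 2, H = 4, G = 1, d = 0.56, r0 = 1.7,
#'                      alpha_min = 48, alpha_c = 53, alpha_max = 169)
#' solve_mfpt(5, p)
#' }
#' @export
solve_mfpt <- function(force, params, env = bond_environment(),
                       measure = "planar", grid = grid_spec()) {
  params <- as_bond_parameters(params)
  stopifnot(length(force) == 1L, force >= 0)
  mo <- measure_opts(measure)
  dom <- radial_domain(params)
  r_lo <- grid$r_lo %||% dom[1]
  r_hi <- params$r0 + params$d
  n_r <- grid$n_r; n_th <- grid$n_theta
  h_r <- (r_hi - r_lo) / n_r
  th_min <- params$theta_min * pi / 180
  th_max <- params$theta_max * pi / 180
  h_th <- (th_max - th_min) / n_th
  h_s <- params$r0 * h_th
  D <- diffusivity(env, params$r0)

  # warn when the grid does not resolve the thermal well widths
  sig_r <- 1 / sqrt(max(k_theta(th_max, params), 1e-12))
  if (sig_r / h_r < 6) {
    warning("radial grid resolves the well with fewer than 6 points per ",
            "thermal width; refine `n_r`", call. = FALSE)
  }

  r_c <- r_lo + (seq_len(n_r) - 0.5) * h_r
  th_c <- th_min + (seq_len(n_th) - 0.5) * h_th
  idx <- function(i, j) (j - 1L) * n_r + i
  W <- outer(r_c, th_c, function(r, th)
    reduced_potential(r, th, force, params, env, mo))

  n <- n_r * n_th
  diag_acc <- numeric(n)
  rhs_tau <- rep(-1, n)
  rhs_committor <- numeric(n)

  # radial faces (vectorized over the whole grid)
  cr <- D / h_r^2
  dw_r <- W[-1, , drop = FALSE] - W[-n_r, , drop = FALSE]
  up <- cr * bernoulli_rate(dw_r)    # cell (i, j) -> (i+1, j)
  dn <- cr * bernoulli_rate(-dw_r)   # cell (i+1, j) -> (i, j)
  i_lo <- as.vector(outer(seq_len(n_r - 1L), (seq_len(n_th) - 1L) * n_r, "+"))
  i_hi <- i_lo + 1L
  ii <- c(i_lo, i_hi); jj <- c(i_hi, i_lo); xx <- c(as.vector(up), as.vector(dn))
  tmp <- rowsum(c(as.vector(up), as.vector(dn)), c(i_lo, i_hi))
  diag_acc[as.integer(rownames(tmp))] <-
    diag_acc[as.integer(rownames(tmp))] - tmp[, 1]

  # angular faces
  cs <- D / h_s^2
  dw_s <- W[, -1, drop = FALSE] - W[, -n_th, drop = FALSE]
  fw <- cs * bernoulli_rate(dw_s)
  bw <- cs * bernoulli_rate(-dw_s)
  j_lo <- as.vector(outer(seq_len(n_r), (seq_len(n_th - 1L) - 1L) * n_r, "+"))
  j_hi <- j_lo + n_r
  ii <- c(ii, j_lo, j_hi); jj <- c(jj, j_hi, j_lo)
  xx <- c(xx, as.vector(fw), as.vector(bw))
  tmp <- rowsum(c(as.vector(fw), as.vector(bw)), c(j_lo, j_hi))
  diag_acc[as.integer(rownames(tmp))] <-
    diag_acc[as.integer(rownames(tmp))] - tmp[, 1]

  # absorbing top faces at r_hi (boundary value at distance h_r/2)
  w_b <- reduced_potential(r_hi, th_c, force, params, env, mo)
  q_abs <- (2 * D / h_r^2) * bernoulli_rate(w_b - W[n_r, ])
  k_top <- idx(n_r, seq_len(n_th))
  diag_acc[k_top] <- diag_acc[k_top] - q_abs
  in_small <- th_c >= params$theta_c * pi / 180
  rhs_committor[k_top[in_small]] <- -q_abs[in_small]

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_acc), dims = c(n, n))
  tau <- as.numeric(Matrix::solve(A, rhs_tau))
  committor <- as.numeric(Matrix::solve(A, rhs_committor))
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop("numerical error: finite-volume MFPT solve did not converge ",
         "(non-finite or negative passage times)", call. = FALSE)
  }

  # zero-force equilibrium start distribution on the same grid
  W0 <- if (force == 0) W else outer(r_c, th_c, function(r, th)
    reduced_potential(r, th, 0, params, env, mo))
  rho <- exp(-(W0 - min(W0)))
  rho <- rho / sum(rho)
  small <- rep(th_c >= params$theta_c * pi / 180, each = n_r)
  w_all <- as.numeric(rho)
  tau_eq <- sum(w_all * tau)
  tau_S <- sum(w_all[small] * tau[small]) / sum(w_all[small])
  tau_L <- sum(w_all[!small] * tau[!small]) / sum(w_all[!small])
  pi_s <- sum(w_all * committor)
  tibble::tibble(force = force, tau = tau_eq, tau_small_start = tau_S,
                 tau_large_start = tau_L, pi_s = pi_s,
                 n_r = n_r, n_theta = n_th)
}

# sample (r, theta) pairs from the bound-region equilibrium at given force
sample_equilibrium <- function(n, force, params, env, measure, control) {
  mo <- measure_opts(measure)
  prof <- angular_profile(force, params, env, measure, control)
  wt <- exp(-(prof$W - min(prof$W)))
  # cell probabilities by trapezoid mass
  mids <- (wt[-1] + wt[-length(wt)]) / 2 * diff(prof$theta)
  cell <- sample.int(length(mids), n, replace = TRUE, prob = mids)
  theta <- prof$theta[cell] + stats::runif(n) * diff(prof$theta)[cell]
  dom <- radial_domain(params)
  r_grid <- seq(dom[1], dom[2], length.out = 400)
  r <- vapply(theta, function(th) {
    w <- reduced_potential(r_grid, th, force, params, env, mo)
    w <- exp(-(w - min(w)))
    m <- (w[-1] + w[-length(w)]) / 2
    c1 <- sample.int(length(m), 1L, prob = m)
    r_grid[c1] + stats::runif(1L) * (r_grid[2] - r_grid[1])
  }, 0)
  list(r = r, theta = theta)
}

#' Brownian-dynamics rupture ensemble
#'
#' Euler-Maruyama integration of the overdamped Langevin equation in the
#' coordinates (r, s = r0 theta) with isotropic diffusivity D, drift from
#' the reduced potential (including the measure's entropic term), boundary
#' reflection at `r_lo`, `theta_min`, `theta_max`, and absorption at
#' `r = r0 + d`. Initial states are drawn from the zero-force equilibrium.
#' Trajectories still bound at `horizon` are recorded as censored, never
#' dropped. Direct rupture sampling is only feasible at desk scale for
#' barriers up to ~8-10 kBT; use [solve_mfpt()] as the high-barrier oracle.
#'
#' @inheritParams solve_mfpt
#' @param n Number of trajectories.
#' @param seed Integer RNG seed; fixed seeds give identical ensembles.
#' @param dt Time step, s. Defaults to `0.05 / (D * max k(theta))`, and the
#'   stability condition `dt * D * max|U''| / kBT < 0.1` is checked.
#' @param horizon Censoring horizon, s.
#' @param control A [numeric_control()] (used for equilibrium sampling).
#' @return A `rupture_ensemble` tibble with columns `force`, `lifetime`,
#'   `censored` and `basin` (`"small"`/`"large"` at the moment of rupture,
#'   `NA` for censored records); seed, time step and counts in attributes.
#' @export
simulate_rupture_times <- function(force, params, env = bond_environment(),
                                   n = 1000, seed = 1, dt = NULL,
                                   horizon = 0.01, measure = "planar",
                                   control = numeric_control()) {
  params <- as_bond_parameters(params)
  stopifnot(length(force) == 1L, force >= 0, n >= 1)
  mo <- measure_opts(measure)
  D <- diffusivity(env, params$r0)
  th_min <- params$theta_min * pi / 180
  th_max <- params$theta_max * pi / 180
  th_c <- params$theta_c * pi / 180
  k_max <- max(k_theta(th_min, params), k_theta(th_max, params), 1e-9)
  # angular curvature scale away from the cusp, in s = r0*theta units
  curv_ang <- (max(params$H, abs(params$H - params$G), 1e-9) + params$k1 *
                 params$d^2) / max((th_max - th_min) * params$r0, 1e-9)^2
  curv <- max(k_max, curv_ang)
  if (is.null(dt)) {
    # keep both the curvature criterion (dt D U'' < 0.05) and the
    # drift-to-noise ratio at the steep absorbing wall below ~0.2
    slope_max <- k_max * params$d + force / env$thermal_energy
    dt <- min(0.05 / (D * curv), 0.08 / (D * slope_max^2))
  }
  if (dt * D * curv >= 0.1) {
    stop("`dt` too large for stable integration: need dt * D * max|U''| < 0.1",
         call. = FALSE)
  }
  set.seed(seed)
  init <- sample_equilibrium(n, 0, params, env, measure, control)
  r <- init$r
  s <- init$theta * params$r0
  s_min <- th_min * params$r0; s_max <- th_max * params$r0
  r_lo <- radial_domain(params)[1]
  r_hi <- params$r0 + params$d
  fb <- force / env$thermal_energy
  cmin <- cos(th_min); cmax <- cos(th_max)
  cc <- cos(th_c)
  slope_S <- params$H / (cc - cmax)
  slope_L <- (params$H - params$G) / (cc - cmin)

  t_now <- numeric(n)
  lifetime <- rep(NA_real_, n)
  basin <- rep(NA_character_, n)
  active <- rep(TRUE, n)
  sq <- sqrt(2 * D * dt)
  max_steps <- ceiling(horizon / dt)
  for (step in seq_len(max_steps)) {
    if (!any(active)) break
    ra <- r[active]; sa <- s[active]
    th <- sa / params$r0
    ct <- cos(th); st <- sin(th)
    k <- k_theta(th, params)
    du_dr <- k * (ra - params$r0) - fb * ct - mo$rpow / ra
    dC_dth <- ifelse(th >= th_c, -slope_S * st, -slope_L * st)
    du_dth <- -0.5 * params$k1 * st * (ra - params$r0)^2 + fb * ra * st +
      dC_dth
    if (mo$sin) du_dth <- du_dth - ct / st
    du_ds <- du_dth / params$r0
    nr <- length(ra)
    ra_old <- ra
    ra <- ra - D * du_dr * dt + sq * stats::rnorm(nr)
    sa <- sa - D * du_ds * dt + sq * stats::rnorm(nr)
    # reflecting boundaries
    ra <- ifelse(ra < r_lo, 2 * r_lo - ra, ra)
    sa <- ifelse(sa < s_min, 2 * s_min - sa, sa)
    sa <- ifelse(sa > s_max, 2 * s_max - sa, sa)
    # absorbing boundary with Brownian-bridge correction: detect crossings
    # that happen inside a step, removing the O(sqrt(dt)) first-passage bias
    rupt <- ra >= r_hi
    sub <- !rupt
    p_bridge <- exp(-pmax(r_hi - ra_old[sub], 0) * pmax(r_hi - ra[sub], 0) /
                      (D * dt))
    rupt[sub] <- stats::runif(sum(sub)) < p_bridge
    ids <- which(active)
    t_now[ids] <- t_now[ids] + dt
    if (any(rupt)) {
      hit <- ids[rupt]
      lifetime[hit] <- t_now[hit]
      basin[hit] <- ifelse(sa[rupt] / params$r0 >= th_c, "small", "large")
      active[hit] <- FALSE
    }
    r[ids] <- ra; s[ids] <- sa
  }
  censored <- is.na(lifetime)
  lifetime[censored] <- horizon
  out <- tibble::tibble(force = force, lifetime = lifetime,
                        censored = censored, basin = basin)
  attr(out, "seed") <- seed
  attr(out, "dt") <- dt
  attr(out, "horizon") <- horizon
  attr(out, "n_ruptured") <- sum(!censored)
  attr(out, "n_censored") <- sum(censored)
  class(out) <- c("rupture_ensemble", class(out))
  out
}

#' Kaplan-Meier survival estimate of a rupture ensemble
#'
#' Right-censoring-aware empirical survival curve with a Greenwood
#' (plain-scale) 95 percent confidence band, computed with the standard
#' product-limit estimator.
#'
#' @param ensemble A tibble with columns `lifetime` and `censored`
#'   (e.g. from [simulate_rupture_times()] or [sample_lifetimes()]).
#' @param conf_level Confidence level of the Greenwood band.
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `survival`,
#'   `conf_low`, `conf_high`.
#' @export
empirical_survival <- function(ensemble, conf_level = 0.95) {
  stopifnot(all(c("lifetime", "censored") %in% names(ensemble)))
  if (all(ensemble$censored)) {
    stop("cannot estimate survival: every record is censored", call. = FALSE)
  }
  # timefix would round sub-microsecond rupture times into spurious ties
  fit <- survival::survfit(
    survival::Surv(ensemble$lifetime, !ensemble$censored) ~ 1,
    conf.type = "plain", conf.int = conf_level, timefix = FALSE
  )
  tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv,
    conf_low = pmax(fit$lower, 0), conf_high = pmin(fit$upper, 1)
  )
}
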