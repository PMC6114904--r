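#' Negative log-likelihood of a lifetime dataset
#'
#' The probability of observing a rupture between `t` and `t + dt` at
#' force `F` is \eqn{-dt \, d\Sigma_F(t)/dt}, so uncensored records
#' contribute \eqn{-\log(A_1 \lambda_1 e^{-\lambda_1 t} +
#' A_2 \lambda_2 e^{-\lambda_2 t})} and right-censored records
#' \eqn{-\log \Sigma_F(t)}. Densities are evaluated in closed form from the
#' analytical kinetic solution, one solution per distinct force in the
#' dataset. Numerically non-positive densities are clipped at 1e-300 (the
#' number of clipped records is attached as attribute `n_clipped`); the
#' result is never NaN.
#'
#' @param data A lifetime dataset ([lifetime_data()] or compatible tibble
#'   with columns `force`, `lifetime`, optional `censored`).
#' @inheritParams transition_rates
#' @param p_s0 Optional precomputed zero-force equilibrium small-basin
#'   probability.
#' @return The negative log-likelihood (0 for an empty dataset).
#' @export
lifetime_nll <- function(data, params, env = bond_environment(),
                         measure = "planar",
                         rate_eval = c("average", "minimum"),
                         control = numeric_control(), p_s0 = NULL) {
  params <- as_bond_parameters(params)
  rate_eval <- match.arg(rate_eval)
  if (nrow(data) == 0L) return(0)
  censored <- data$censored %||% rep(FALSE, nrow(data))
  if (is.null(data$censored) && !is.null(attr(data, "censored"))) {
    censored <- attr(data, "censored")
  }
  if (is.null(p_s0)) {
    p_s0 <- equilibrium_small_angle_probability(0, params, env, measure,
                                                control)
  }
  ufo <- sort(unique(data$force))
  n_clipped <- 0L
  nll <- 0
  for (f in ufo) {
    rs <- rate_set(f, params, env, measure, control, rate_eval)
    sol <- two_state_solution(rs, p_s0)
    sel <- data$force == f
    t_i <- data$lifetime[sel]
    cen <- censored[sel]
    if (sol$degenerate) {
      l <- sol$lambda1; g <- sol$gamma
      dens <- (l - g + l * g * t_i) * exp(-l * t_i)
      surv <- (1 + g * t_i) * exp(-l * t_i)
    } else {
      dens <- sol$A1 * sol$lambda1 * exp(-sol$lambda1 * t_i) +
        sol$A2 * sol$lambda2 * exp(-sol$lambda2 * t_i)
      surv <- sol$A1 * exp(-sol$lambda1 * t_i) +
        sol$A2 * exp(-sol$lambda2 * t_i)
    }
    bad <- !is.finite(dens) | dens <= 0
    n_clipped <- n_clipped + sum(bad & !cen)
    dens[bad] <- 1e-300
    bad_s <- !is.finite(surv) | surv <= 0
    n_clipped <- n_clipped + sum(bad_s & cen)
    surv[bad_s] <- 1e-300
    nll <- nll - sum(log(dens[!cen])) - sum(log(surv[cen]))
  }
  structure(nll, n_clipped = n_clipped)
}

# ---- parameter transform for unconstrained optimization --------------------
# free parameters with alpha_min and phi fixed:
#   E0, E1, H, H - G, d, r0, alpha_c - alpha_min, alpha_max - alpha_c
# all positive -> optimized on the log scale.
par_to_vec <- function(params) {
  cap <- 179.5 - params$phi
  frac <- (params$alpha_max - params$alpha_c) / (cap - params$alpha_c)
  c(log(params$E0), log(params$E1), log(params$H), log(params$H - params$G),
    log(params$d), log(params$r0),
    log(params$alpha_c - params$alpha_min),
    stats::qlogis(min(max(frac, 1e-4), 1 - 1e-4)))
}

vec_to_par <- function(v, alpha_min, phi) {
  E0 <- exp(v[1]); E1 <- exp(v[2]); H <- exp(v[3]); G <- H - exp(v[4])
  d <- exp(v[5]); r0 <- exp(v[6])
  alpha_c <- alpha_min + exp(v[7])
  # logistic map keeps alpha_max strictly inside (alpha_c, 179.5 - phi),
  # so the optimizer never sees a constraint cliff
  cap <- 179.5 - phi
  if (alpha_c >= cap - 1) return(1e8)
  alpha_max <- alpha_c + (cap - alpha_c) * stats::plogis(v[8])
  out <- tryCatch(bond_parameters(E0, E1, H, G, d, r0, alpha_min, alpha_c,
                                  alpha_max, phi),
                  error = function(e) NULL)
  if (is.null(out)) return(1e8)
  out
}

# Method-of-moments starting point: per-force mean lifetimes give the
# high-force slip slope (-> d), and inverting the 1D rupture-rate formula
# matches the lifetime scale at the force-range ends (-> E0, then E1).
# The angular-barrier parameters are left at neutral values; the profile
# sweep of the fitter is responsible for locating H.
moment_init <- function(data, alpha_min, phi, env, measure = "planar",
                        d_scale = 1) {
  agg <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(data),
                                          .data$force),
                          tau_hat = mean(.data$lifetime), .groups = "drop")
  agg <- dplyr::arrange(agg, .data$force)
  kBT <- env$thermal_energy
  alpha_c0 <- alpha_min + 5
  alpha_max0 <- min(165, 178 - phi)
  th_min0 <- theta_from_alpha(alpha_max0, phi) * pi / 180
  hi <- agg$force >= stats::median(agg$force)
  d0 <- 0.5
  if (sum(hi) >= 3) {
    slope <- stats::coef(stats::lm(log(tau_hat) ~ force, data = agg[hi, ]))[2]
    d0 <- -slope * kBT / cos(th_min0)
  }
  d0 <- min(max(d0 * d_scale, 0.15), 1.9)
  mo <- measure_opts(measure)
  # invert the rupture-rate magnitude for E0 at the lowest force (small-angle
  # basin dominates there), then for E1 at the highest force (large-angle)
  mk <- function(E0, E1) {
    tryCatch(bond_parameters(E0, E1, H = 15, G = 2, d = d0, r0 = 1.5,
                             alpha_min = alpha_min, alpha_c = alpha_c0,
                             alpha_max = alpha_max0, phi = phi),
             error = function(e) NULL)
  }
  rate_at <- function(p, theta_deg, force) {
    radial_rupture_rate(theta_deg * pi / 180, force, p, env, mo$rpow,
                        n_r = 200)
  }
  invert <- function(f, lo, hi) {
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-3)$root
  }
  E0_0 <- invert(function(E0) {
    p <- mk(E0, 0.5)
    if (is.null(p)) return(NA_real_)
    log(rate_at(p, p$theta_max, agg$force[1]) * agg$tau_hat[1] / 0.75)
  }, 6, 39)
  if (!is.finite(E0_0)) E0_0 <- 20
  nF <- nrow(agg)
  E1_0 <- invert(function(E1) {
    p <- mk(E0_0, E1)
    if (is.null(p)) return(NA_real_)
    log(rate_at(p, p$theta_min, agg$force[nF]) * agg$tau_hat[nF])
  }, 0.4, min(15, E0_0 - 1))
  if (!is.finite(E1_0)) E1_0 <- 4
  mk(E0_0, E1_0)
}

# optimization box in the transformed coordinates (broad physical ranges:
# energies ~2-40 kBT, d 0.1-2 nm, r0 0.5-5 nm, angular widths in degrees)
fit_bounds <- function() {
  lower <- c(log(c(E0 = 5, E1 = 0.3, H = 2, HmG = 0.5, d = 0.1, r0 = 0.5,
                   dac = 0.5)), fmax = -4)
  upper <- c(log(c(E0 = 40, E1 = 20, H = 45, HmG = 40, d = 2, r0 = 5,
                   dac = 30)), fmax = 4)
  list(lower = lower, upper = upper)
}

#' Maximum-likelihood fit with fixed hinge geometry (stage two)
#'
#' Maximizes the lifetime likelihood over the eight remaining landscape
#' parameters (`E0`, `E1`, `H`, `G`, `d`, `r0`, `alpha_c`, `alpha_max`)
#' with the minimum inter-domain angle `alpha_min` and the offset angle
#' `phi` held fixed — the inner stage of the two-stage protocol. The
#' optimizer works in log-transformed coordinates that enforce positivity
#' and the angle ordering. Because the likelihood is multimodal in the
#' angular barrier `H` (a shallow quasi-single-exponential shelf at small
#' `H` competes with the double-exponential optimum), the search proceeds
#' in three phases: (1) seeded Latin-hypercube candidates over broad
#' physical bounds (plus the box centre and `init` if given), the most
#' promising `n_optimize` refined with `L-BFGS-B`; (2) a profile sweep
#' that holds `H` at each value of `h_profile` while re-optimizing the
#' other seven parameters, warm-started from the phase-1 optimum; (3) a
#' full eight-parameter polish from the best profile point. Standard
#' errors come from the observed information (inverse Hessian of the
#' negative log-likelihood in natural coordinates).
#'
#' @param data A lifetime dataset with at least two distinct forces.
#' @param alpha_min,phi Fixed geometry, degrees.
#' @inheritParams lifetime_nll
#' @param init Optional [bond_parameters()] used as an additional start.
#' @param n_starts Number of Latin-hypercube candidate starts.
#' @param n_optimize How many of the best-scoring candidates to refine.
#' @param seed RNG seed for the Latin hypercube.
#' @param maxit Iteration cap for each `L-BFGS-B` refinement.
#' @param h_profile Values of the angular barrier `H` (kBT) for the
#'   profile sweep of phase 2; the phase-1 optimum is always included.
#' @return A `bond_fit` object; see [tidy.bond_fit()], [glance.bond_fit()].
#' @examples
#' \donttest{
#' truth <- cca_parameters()
#' d <- sample_lifetimes(experiment_design(n_measurements = 200), truth,
#'                       seed = 1)
#' fit <- fit_lifetimes(d, alpha_min = 48, phi = 0, init = truth,
#'                      n_starts = 2, n_optimize = 1, maxit = 20)
#' }
#' @export
fit_lifetimes <- function(data, alpha_min = 48, phi = 0,
                          env = bond_environment(), init = NULL,
                          n_starts = 8, n_optimize = 2, seed = 1,
                          maxit = 300,
                          h_profile = c(6, 9, 13, 17, 21, 26, 32, 40),
                          measure = "planar",
                          rate_eval = c("average", "minimum"),
                          control = numeric_control(n_theta = 400, n_r = 100,
                                                    n_r_mfpt = 160,
                                                    n_rup_nodes = 12)) {
  rate_eval <- match.arg(rate_eval)
  if (length(unique(data$force)) < 2L) {
    stop("unidentifiable fit: at least 2 distinct forces are required",
         call. = FALSE)
  }
  if (any(data$lifetime <= 0)) stop("lifetimes must be positive", call. = FALSE)
  bounds <- fit_bounds()
  objective <- function(v) {
    p <- vec_to_par(v, alpha_min, phi)
    if (is.numeric(p)) return(p)  # constraint penalty
    out <- tryCatch(
      as.numeric(lifetime_nll(data, p, env, measure, rate_eval, control)),
      error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }
  # phase 1: Latin-hypercube candidates + box centre (+ init); refine the
  # most promising with L-BFGS-B
  set.seed(as.integer(seed))
  lhs_u <- lhs::randomLHS(n_starts, length(bounds$lower))
  starts <- t(t(lhs_u) * (bounds$upper - bounds$lower) + bounds$lower)
  start_list <- lapply(seq_len(n_starts), function(i) starts[i, ])
  start_list <- c(list((bounds$lower + bounds$upper) / 2), start_list)
  # the raw slip slope under-reads d when the large-angle basin is broad,
  # so seed the search at both the literal and a doubled transition distance
  for (dsc in c(2, 1)) {
    mom <- tryCatch(moment_init(data, alpha_min, phi, env, measure, dsc),
                    error = function(e) NULL)
    if (!is.null(mom)) start_list <- c(list(par_to_vec(mom)), start_list)
  }
  if (!is.null(init)) {
    init <- as_bond_parameters(init)
    start_list <- c(list(par_to_vec(init)), start_list)
  }
  cand <- vapply(start_list, objective, 0)
  ord <- order(cand)
  keep <- ord[seq_len(min(n_optimize, length(ord)))]
  fits <- lapply(keep, function(i) {
    tryCatch(
      stats::optim(start_list[[i]], objective, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = ceiling(maxit / 2), factr = 1e7)),
      error = function(e) list(value = Inf, error = conditionMessage(e)))
  })
  vals <- vapply(fits, function(f) f$value, 0)
  if (!any(is.finite(vals))) {
    stop("all optimization starts failed; per-start diagnostics: ",
         paste(vapply(fits, function(f) f$error %||% "no diagnostics", ""),
               collapse = "; "), call. = FALSE)
  }
  best <- fits[[which.min(vals)]]

  # phase 2: profile sweep over the angular barrier H, other parameters
  # re-optimized from the phase-1 optimum (escapes the small-H shelf)
  h_profile <- sort(unique(c(h_profile, exp(best$par[3]))))
  free_i <- setdiff(seq_along(best$par), 3L)
  prof_tab <- tibble::tibble(H = h_profile, nll = NA_real_)
  prof_best <- best
  for (ih in seq_along(h_profile)) {
    v <- best$par
    v[3] <- log(h_profile[ih])
    # keep the reverse barrier H - G at its current scale where possible
    v[4] <- min(v[4], log(max(exp(v[3]) - 1e-3, 1e-3)))
    obj_sub <- function(vs) { vv <- v; vv[free_i] <- vs; objective(vv) }
    o <- tryCatch(
      stats::optim(v[free_i], obj_sub, method = "L-BFGS-B",
                   lower = bounds$lower[free_i], upper = bounds$upper[free_i],
                   control = list(maxit = 30, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(o)) next
    prof_tab$nll[ih] <- o$value
    if (o$value < prof_best$value) {
      vv <- v; vv[free_i] <- o$par
      prof_best <- list(par = vv, value = o$value, convergence = NA_integer_,
                        message = "profile stage")
    }
  }

  # phase 3: full polish from the best point seen
  polish <- tryCatch(
    stats::optim(prof_best$par, objective, method = "L-BFGS-B",
                 lower = bounds$lower, upper = bounds$upper,
                 control = list(maxit = maxit, factr = 1e7)),
    error = function(e) prof_best)
  best <- if (polish$value <= prof_best$value) polish else prof_best
  best_params <- vec_to_par(best$par, alpha_min, phi)

  # observed-information standard errors in natural coordinates
  natural <- c(best_params$E0, best_params$E1, best_params$H, best_params$G,
               best_params$d, best_params$r0, best_params$alpha_c,
               best_params$alpha_max)
  nat_names <- c("E0", "E1", "H", "G", "d", "r0", "alpha_c", "alpha_max")
  nll_natural <- function(x) {
    p <- tryCatch(bond_parameters(x[1], x[2], x[3], x[4], x[5], x[6],
                                  alpha_min, x[7], x[8], phi),
                  error = function(e) NULL)
    if (is.null(p)) return(NA_real_)
    out <- tryCatch(
      as.numeric(lifetime_nll(data, p, env, measure, rate_eval, control)),
      error = function(e) NA_real_)
    out
  }
  se <- rep(NA_real_, length(natural))
  hess <- tryCatch(stats::optimHess(natural, nll_natural), error = function(e) NULL)
  vcov <- NULL
  if (!is.null(hess) && all(is.finite(hess))) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov)) {
      dg <- diag(vcov)
      se <- ifelse(dg > 0, sqrt(dg), NA_real_)
    }
  }
  names(se) <- nat_names
  structure(
    list(
      best_params = best_params,
      log_likelihood = -best$value,
      standard_errors = se,
      vcov = vcov,
      alpha_min = alpha_min, phi = phi,
      starts = tibble::tibble(
        start = seq_along(start_list),
        initial_nll = cand,
        refined = seq_along(start_list) %in% keep,
        final_nll = ifelse(seq_along(start_list) %in% keep,
                           vals[match(seq_along(start_list), keep)], NA_real_)
      ),
      h_profile = prof_tab,
      convergence = best$convergence %||% NA_integer_,
      message = best$message %||% "",
      n_clipped = attr(lifetime_nll(data, best_params, env, measure,
                                    rate_eval, control), "n_clipped"),
      n = nrow(data),
      seed = as.integer(seed),
      measure = measure, rate_eval = rate_eval,
      env = env, control = control,
      data = data
    ),
    class = "bond_fit"
  )
}

#' Two-stage maximum-likelihood fit over a hinge-geometry grid
#'
#' Runs [fit_lifetimes()] for every combination of the fixed angles
#' `alpha_min` and `phi` on the supplied grids (the outer stage of the
#' protocol) and returns the overall optimum together with the profile
#' log-likelihood over the grid.
#'
#' @inheritParams fit_lifetimes
#' @param alpha_min_grid,phi_grid Degree grids for the fixed geometry.
#' @return A `bond_fit` object whose `stage1_grid` field tabulates
#'   (`alpha_min`, `phi`, `log_likelihood`, `ok`); failed cells are
#'   flagged, not fatal.
#' @export
fit_lifetime_grid <- function(data, alpha_min_grid, phi_grid = 0,
                              env = bond_environment(), init = NULL,
                              n_starts = 8, n_optimize = 2, seed = 1,
                              maxit = 300,
                              h_profile = c(6, 9, 13, 17, 21, 26, 32, 40),
                              measure = "planar",
                              rate_eval = c("average", "minimum"),
                              control = numeric_control(n_theta = 400,
                                                        n_r = 100,
                                                        n_r_mfpt = 160,
                                                        n_rup_nodes = 12)) {
  rate_eval <- match.arg(rate_eval)
  if (length(alpha_min_grid) == 0L || length(phi_grid) == 0L) {
    stop("`alpha_min_grid` and `phi_grid` must be non-empty", call. = FALSE)
  }
  if (length(unique(data$force)) < 2L) {
    stop("unidentifiable fit: at least 2 distinct forces are required",
         call. = FALSE)
  }
  cells <- tidyr::expand_grid(alpha_min = alpha_min_grid, phi = phi_grid)
  fits <- purrr::pmap(cells, function(alpha_min, phi) {
    tryCatch(
      fit_lifetimes(data, alpha_min, phi, env, init, n_starts, n_optimize,
                    seed, maxit, h_profile, measure, rate_eval, control),
      error = function(e) e)
  })
  ok <- !vapply(fits, inherits, TRUE, what = "error")
  ll <- vapply(seq_along(fits), function(i)
    if (ok[i]) fits[[i]]$log_likelihood else NA_real_, 0)
  if (!any(ok)) stop("every grid cell failed to fit", call. = FALSE)
  best_i <- which.max(ifelse(ok, ll, -Inf))
  best <- fits[[best_i]]
  best$stage1_grid <- dplyr::bind_cols(
    cells, tibble::tibble(log_likelihood = ll, ok = ok))
  best
}

#' @export
print.bond_fit <- function(x, ...) {
  cat("<bond_fit> maximum-likelihood landscape fit\n")
  cat(sprintf("  n = %d records, logLik = %.2f, fixed alpha_min = %g, phi = %g\n",
              x$n, x$log_likelihood, x$alpha_min, x$phi))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy and glance methods for landscape fits
#'
#' @param x A `bond_fit` from [fit_lifetimes()] or [fit_lifetime_grid()].
#' @param ... Unused.
#' @return `tidy()` gives one row per free parameter with `estimate` and
#'   `std.error`; `glance()` a one-row model summary.
#' @method tidy bond_fit
#' @export
tidy.bond_fit <- function(x, ...) {
  p <- x$best_params
  tibble::tibble(
    term = names(x$standard_errors),
    estimate = c(p$E0, p$E1, p$H, p$G, p$d, p$r0, p$alpha_c, p$alpha_max),
    std.error = unname(x$standard_errors),
    unit = c("kBT", "kBT", "kBT", "kBT", "nm", "nm", "deg", "deg")
  )
}

#' @rdname tidy.bond_fit
#' @method glance bond_fit
#' @export
glance.bond_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood,
    nobs = x$n,
    convergence = x$convergence,
    n_clipped = x$n_clipped %||% 0L,
    alpha_min = x$alpha_min,
    phi = x$phi,
    seed = x$seed
  )
}
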