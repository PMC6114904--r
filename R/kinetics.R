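#' Four-rate reduction of the landscape at given force(s)
#'
#' Reduces the two-basin landscape to four first-order rates: crossing of
#' the angular barrier from the small to the large inter-domain angle basin
#' (`omega_sl`), the reverse crossing (`omega_ls`), and bond rupture
#' directly from each basin (`omega_s_rup`, `omega_l_rup`). Angular rates
#' are exact one-dimensional mean-first-passage-time (MFPT) double
#' integrals on the force-tilted reduced angular free energy, from the
#' equilibrated source basin to the target basin minimum with a reflecting
#' wall behind the source. Rupture rates are radial MFPT rates to the
#' absorbing boundary `r0 + d`, averaged over the basin's conditional
#' angular distribution (or evaluated at the basin minimum when
#' `rate_eval = "minimum"`).
#'
#' @param force Applied force(s), pN; vectorized.
#' @param params A [bond_parameters()] object (or coercible).
#' @param env A [bond_environment()].
#' @param measure Configuration-space measure; see
#'   [equilibrium_small_angle_probability()].
#' @param rate_eval `"average"` (default) thermally averages the rupture
#'   rate over each basin; `"minimum"` evaluates it at the basin minimum.
#' @param control A [numeric_control()].
#' @return A tibble with one row per force and columns `force`, `omega_sl`,
#'   `omega_ls`, `omega_s_rup`, `omega_l_rup` (1/s).
#' @examples
#' transition_rates(c(0, 10), cca_parameters())
#' @export
transition_rates <- function(force, params, env = bond_environment(),
                             measure = "planar",
                             rate_eval = c("average", "minimum"),
                             control = numeric_control()) {
  params <- as_bond_parameters(params)
  rate_eval <- match.arg(rate_eval)
  if (any(force < 0)) stop("`force` must be non-negative", call. = FALSE)
  rows <- lapply(force, function(f) {
    rs <- rate_set(f, params, env, measure, control, rate_eval)
    tibble::tibble(force = f, omega_sl = rs[["omega_sl"]],
                   omega_ls = rs[["omega_ls"]],
                   omega_s_rup = rs[["omega_s_rup"]],
                   omega_l_rup = rs[["omega_l_rup"]])
  })
  dplyr::bind_rows(rows)
}

# closed-form solution of the 2x2 master equation with absorption.
# Returns amplitudes/decay rates of Sigma(t) = A1 exp(-l1 t) + A2 exp(-l2 t),
# tau, tau_L, pi_S. p_s0 is the initial small-basin occupancy.
two_state_solution <- function(rates, p_s0) {
  w_sl <- rates[["omega_sl"]]; w_ls <- rates[["omega_ls"]]
  w_s <- rates[["omega_s_rup"]]; w_l <- rates[["omega_l_rup"]]
  a <- w_sl + w_s
  b <- w_ls + w_l
  p_l0 <- 1 - p_s0
  disc <- sqrt((a - b)^2 + 4 * w_sl * w_ls)
  l1 <- (a + b - disc) / 2
  l2 <- (a + b + disc) / 2
  # time-integrated occupancies (Laplace transform at s = 0)
  det <- a * b - w_sl * w_ls
  xS <- (b * p_s0 + w_ls * p_l0) / det
  xL <- (w_sl * p_s0 + a * p_l0) / det
  tau <- xS + xL
  pi_s <- w_s * xS
  if (disc / max(l2, .Machine$double.xmin) < 1e-10) {
    # confluent (degenerate eigenvalue) limit: Sigma = (1 + g t) exp(-l t)
    l <- (l1 + l2) / 2
    g <- l - (w_s * p_s0 + w_l * p_l0)
    A1 <- NA_real_; A2 <- NA_real_
    list(lambda1 = l, lambda2 = l, A1 = A1, A2 = A2, gamma = g,
         degenerate = TRUE, tau = 1 / l + g / l^2, tau_check = tau,
         pi_s = pi_s, x_s = xS, x_l = xL)
  } else {
    # Sigma(t) = P_S + P_L with the standard 2x2 eigen-decomposition
    A1 <- ((l2 - a + w_sl) * p_s0 + (l2 - b + w_ls) * p_l0) / disc
    A2 <- 1 - A1
    list(lambda1 = l1, lambda2 = l2, A1 = A1, A2 = A2, gamma = 0,
         degenerate = FALSE, tau = A1 / l1 + A2 / l2, tau_check = tau,
         pi_s = pi_s, x_s = xS, x_l = xL)
  }
}

#' Analytical bond kinetics under constant force
#'
#' Solves the two-state-plus-absorption master equation
#' \eqn{dP_S/dt = -(\omega_{SL} + \omega_S) P_S + \omega_{LS} P_L},
#' \eqn{dP_L/dt = \omega_{SL} P_S - (\omega_{LS} + \omega_L) P_L}
#' in closed form, with the initial occupancies equilibrated at zero force
#' (the pre-loading condition of constant-force optical-tweezer assays).
#' The bond survival probability is the double exponential
#' \eqn{\Sigma_F(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}}, the mean
#' lifetime is \eqn{\tau = A_1/\lambda_1 + A_2/\lambda_2}, and the
#' splitting probability \eqn{\pi_S} is the fraction of ruptures that occur
#' from the small-angle basin.
#'
#' @inheritParams transition_rates
#' @param p_s0 Initial small-basin occupancy. Defaults to the zero-force
#'   equilibrium value computed from the landscape.
#' @return A tibble of class `bond_kinetics` with one row per force and
#'   columns `force`, the four rates, `p_s0`, `lambda1`, `lambda2`, `A1`,
#'   `A2`, `gamma` (non-zero only in the degenerate-eigenvalue limit),
#'   `tau` (s), `tau_l` (s), `pi_s` and `p_s` (equilibrium small-basin
#'   probability at that force). Parameters, environment and measure are
#'   attached as attributes.
#' @examples
#' sol <- kinetic_solution(c(5, 15.1), cca_parameters())
#' sol$tau
#' @export
kinetic_solution <- function(force, params, env = bond_environment(),
                             measure = "planar",
                             rate_eval = c("average", "minimum"),
                             control = numeric_control(), p_s0 = NULL) {
  params <- as_bond_parameters(params)
  rate_eval <- match.arg(rate_eval)
  if (any(force < 0)) stop("`force` must be non-negative", call. = FALSE)
  if (is.null(p_s0)) {
    p_s0 <- equilibrium_small_angle_probability(0, params, env, measure,
                                                control)
  }
  stopifnot(p_s0 >= 0, p_s0 <= 1)
  rows <- lapply(force, function(f) {
    prof <- angular_profile(f, params, env, measure, control)
    rs <- rate_set(f, params, env, measure, control, rate_eval, prof = prof)
    sol <- two_state_solution(rs, p_s0)
    tibble::tibble(
      force = f,
      omega_sl = rs[["omega_sl"]], omega_ls = rs[["omega_ls"]],
      omega_s_rup = rs[["omega_s_rup"]], omega_l_rup = rs[["omega_l_rup"]],
      p_s0 = p_s0,
      lambda1 = sol$lambda1, lambda2 = sol$lambda2,
      A1 = sol$A1, A2 = sol$A2, gamma = sol$gamma,
      tau = sol$tau, tau_l = 1 / (rs[["omega_ls"]] + rs[["omega_l_rup"]]),
      pi_s = sol$pi_s,
      p_s = p_small_from_profile(prof)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- params
  attr(out, "env") <- env
  attr(out, "measure") <- measure
  class(out) <- c("bond_kinetics", class(out))
  out
}

#' Survival probability and lifetime density of a kinetic solution
#'
#' @param solution A [kinetic_solution()] result.
#' @param times Time grid in seconds.
#' @return A tibble in long format with columns `force`, `time`, `survival`
#'   and `density` (the rupture-time probability density
#'   \eqn{-d\Sigma_F/dt}).
#' @export
survival_probability <- function(solution, times) {
  stopifnot(inherits(solution, "bond_kinetics"), all(times >= 0))
  purrr::map_dfr(seq_len(nrow(solution)), function(i) {
    row <- solution[i, ]
    if (is.na(row$A1)) {
      # degenerate eigenvalues: Sigma = (1 + g t) exp(-l t)
      s <- (1 + row$gamma * times) * exp(-row$lambda1 * times)
      f <- (row$lambda1 - row$gamma + row$lambda1 * row$gamma * times) *
        exp(-row$lambda1 * times)
    } else {
      s <- row$A1 * exp(-row$lambda1 * times) +
        row$A2 * exp(-row$lambda2 * times)
      f <- row$A1 * row$lambda1 * exp(-row$lambda1 * times) +
        row$A2 * row$lambda2 * exp(-row$lambda2 * times)
    }
    tibble::tibble(force = row$force, time = times, survival = s, density = f)
  })
}

#' Mean bond lifetime
#'
#' The expectation of the rupture time, equal to the time integral of the
#' survival probability.
#'
#' @inheritParams kinetic_solution
#' @return Mean lifetime(s) in seconds, one per force.
#' @examples
#' mean_lifetime(10, cca_parameters())
#' @export
mean_lifetime <- function(force, params, env = bond_environment(),
                          measure = "planar",
                          rate_eval = c("average", "minimum"),
                          control = numeric_control(), p_s0 = NULL) {
  kinetic_solution(force, params, env, measure, rate_eval, control, p_s0)$tau
}

#' Mean duration of the large inter-domain angle state
#'
#' Time from entry into the large-angle basin until it is left again, by
#' either rupture or a transition back to the small-angle basin:
#' \eqn{\tau_L = 1 / (\omega_{LS} + \omega_L)}.
#'
#' @inheritParams transition_rates
#' @return Duration(s) in seconds, one per force.
#' @export
large_state_duration <- function(force, params, env = bond_environment(),
                                 measure = "planar",
                                 rate_eval = c("average", "minimum"),
                                 control = numeric_control()) {
  rt <- transition_rates(force, params, env, measure, rate_eval, control)
  1 / (rt$omega_ls + rt$omega_l_rup)
}

#' Scan a landscape parameter across a force grid
#'
#' Recomputes the kinetic observables while one model parameter steps
#' through a set of values and all others stay fixed — the in-silico
#' mutation protocol (e.g. lowering the angular barrier `H` mimics
#' disrupting hinge salt bridges one by one).
#'
#' @inheritParams kinetic_solution
#' @param param Name of the parameter to vary (one of the
#'   [bond_parameters()] arguments).
#' @param values Numeric values the parameter takes.
#' @param forces Force grid in pN.
#' @return A tibble with columns `value`, `ok` (FALSE for invalid parameter
#'   combinations, whose observable columns are `NA`), and the
#'   [kinetic_solution()] columns.
#' @examples
#' scan_parameter(cca_parameters(), param = "H", values = c(25, 20),
#'                forces = c(7, 12))
#' @export
scan_parameter <- function(params, env = bond_environment(), param, values,
                           forces, measure = "planar",
                           rate_eval = c("average", "minimum"),
                           control = numeric_control()) {
  params <- as_bond_parameters(params)
  rate_eval <- match.arg(rate_eval)
  stopifnot(is.character(param), length(param) == 1L)
  purrr::map_dfr(values, function(v) {
    pv <- tryCatch(do.call(modify_parameters,
                           c(list(params), stats::setNames(list(v), param))),
                   error = function(e) e)
    if (inherits(pv, "error")) {
      return(tibble::tibble(value = v, ok = FALSE, force = NA_real_,
                            note = conditionMessage(pv)))
    }
    sol <- kinetic_solution(forces, pv, env, measure, rate_eval, control)
    dplyr::bind_cols(tibble::tibble(value = v, ok = TRUE),
                     tibble::as_tibble(sol), tibble::tibble(note = NA_character_))
  })
}
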