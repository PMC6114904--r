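test_that("transition rates are positive, finite, and Arrhenius-monotone", {
  p <- tbl1()
  rt <- transition_rates(c(0, 5, 15.1, 33, 50), p, control = ctl_fast())
  rates <- as.matrix(rt[, -1])
  expect_true(all(is.finite(rates)))
  expect_true(all(rates > 0))
  # raising the angular barrier slows the angular transitions only
  p_hi <- bond_parameters(21.8, 5.8, 35, 5, 0.56, 1.7, 48, 53, 169)
  rt_hi <- transition_rates(5, p_hi, control = ctl_fast())
  rt_lo <- transition_rates(5, p, control = ctl_fast())
  expect_lt(rt_hi$omega_sl, rt_lo$omega_sl)
  expect_lt(rt_hi$omega_ls, rt_lo$omega_ls)
  expect_equal(rt_hi$omega_s_rup, rt_lo$omega_s_rup, tolerance = 0.02)
  # effectively infinite barrier shuts the small-to-large channel
  expect_lt(rt_hi$omega_sl / rt_lo$omega_sl, exp(-9) * 10)
  # raising E0 slows both rupture channels
  p_E <- bond_parameters(25, 5.8, 25, 5, 0.56, 1.7, 48, 53, 169)
  rt_E <- transition_rates(5, p_E, control = ctl_fast())
  expect_lt(rt_E$omega_s_rup, rt_lo$omega_s_rup)
  expect_lt(rt_E$omega_l_rup, rt_lo$omega_l_rup)
})

test_that("angular rates satisfy local detailed balance with the basin weights", {
  # the identity omega_SL / omega_LS = Z_L / Z_S holds to the accuracy of
  # the well approximation, i.e. for barriers comfortably above kBT
  env <- env0()
  for (setup in list(list(p = bond_parameters(10, 3, 10, 3, 0.56, 1.7,
                                              48, 53, 169), F = 3),
                     list(p = tbl1(), F = 8),
                     list(p = tbl1(), F = 15.1))) {
    rt <- transition_rates(setup$F, setup$p, env, control = ctl_fast())
    pS <- equilibrium_small_angle_probability(setup$F, setup$p, env,
                                              control = ctl_fast())
    ratio <- (rt$omega_sl / rt$omega_ls) / ((1 - pS) / pS)
    expect_gt(ratio, 0.8)
    expect_lt(ratio, 1.2)
  }
})

test_that("two-state solution closed form agrees with ODE integration", {
  skip_if_not_installed("deSolve")
  p_s0 <- 0.72
  rates <- list(omega_sl = 3.1, omega_ls = 0.4, omega_s_rup = 8.2,
                omega_l_rup = 0.6)
  sol <- catchbond:::two_state_solution(rates, p_s0)
  times <- seq(0, 2, length.out = 40)
  rhs <- function(t, y, parms) {
    list(c(-(rates$omega_sl + rates$omega_s_rup) * y[1] +
             rates$omega_ls * y[2],
           rates$omega_sl * y[1] -
             (rates$omega_ls + rates$omega_l_rup) * y[2]))
  }
  ode <- deSolve::ode(c(p_s0, 1 - p_s0), times, rhs, NULL)
  sigma_ode <- ode[, 2] + ode[, 3]
  sigma_cf <- sol$A1 * exp(-sol$lambda1 * times) +
    sol$A2 * exp(-sol$lambda2 * times)
  expect_equal(sigma_cf, unname(sigma_ode), tolerance = 1e-6)
  # tau identities: amplitude form == Laplace form == numerical quadrature
  expect_equal(sol$tau, sol$tau_check, tolerance = 1e-10)
  tq <- stats::integrate(function(t) sol$A1 * exp(-sol$lambda1 * t) +
                           sol$A2 * exp(-sol$lambda2 * t),
                         0, Inf, rel.tol = 1e-10)$value
  expect_equal(sol$tau, tq, tolerance = 1e-8)
  # pi_S + pi_L = 1
  pi_l <- rates$omega_l_rup * sol$x_l
  expect_equal(sol$pi_s + pi_l, 1, tolerance = 1e-12)
})

test_that("no-interconversion limit gives independent exponential channels", {
  p_s0 <- 0.77
  rates <- list(omega_sl = 1e-14, omega_ls = 1e-14, omega_s_rup = 20,
                omega_l_rup = 0.1)
  sol <- catchbond:::two_state_solution(rates, p_s0)
  expect_equal(sol$pi_s, p_s0, tolerance = 1e-10)
  expect_equal(sol$tau, p_s0 / 20 + (1 - p_s0) / 0.1, tolerance = 1e-10)
})

test_that("degenerate eigenvalues fall back to the confluent closed form", {
  # equal eigenvalues: no coupling, identical exit rates
  rates <- list(omega_sl = 0, omega_ls = 0, omega_s_rup = 5,
                omega_l_rup = 5)
  sol <- catchbond:::two_state_solution(rates, 0.6)
  expect_true(sol$degenerate)
  expect_equal(sol$tau, 1 / 5, tolerance = 1e-10)
  # continuity against a slightly perturbed non-degenerate system
  rates2 <- list(omega_sl = 0, omega_ls = 0, omega_s_rup = 5,
                 omega_l_rup = 5 * (1 + 1e-7))
  sol2 <- catchbond:::two_state_solution(rates2, 0.6)
  expect_equal(sol2$tau, sol$tau, tolerance = 1e-6)
})

test_that("kinetic solution is normalized, monotone, and self-consistent", {
  p <- tbl1()
  sol <- kinetic_solution(c(0, 7, 15.1, 25, 33), p, control = ctl_fast())
  expect_equal(sol$A1 + sol$A2, rep(1, nrow(sol)), tolerance = 1e-10)
  tt <- seq(0, 5, length.out = 300)
  sp <- survival_probability(sol, tt)
  for (f in unique(sp$force)) {
    s <- sp$survival[sp$force == f]
    expect_equal(s[1], 1, tolerance = 1e-10)          # Sigma_F(0) = 1
    expect_true(all(diff(s) <= 1e-12))                # non-increasing
    expect_true(all(sp$density[sp$force == f] >= -1e-12))
  }
  # tau equals the amplitude form and the quadrature of Sigma
  for (i in seq_len(nrow(sol))) {
    expect_equal(sol$tau[i],
                 sol$A1[i] / sol$lambda1[i] + sol$A2[i] / sol$lambda2[i],
                 tolerance = 1e-10)
    tq <- stats::integrate(function(t)
      sol$A1[i] * exp(-sol$lambda1[i] * t) +
        sol$A2[i] * exp(-sol$lambda2[i] * t), 0, Inf,
      rel.tol = 1e-10)$value
    expect_equal(sol$tau[i], tq, tolerance = 1e-8)
  }
  expect_true(all(sol$pi_s >= 0 & sol$pi_s <= 1))
  # tau_l = 1/(omega_ls + omega_l_rup)
  expect_equal(sol$tau_l, 1 / (sol$omega_ls + sol$omega_l_rup),
               tolerance = 1e-12)
  expect_equal(large_state_duration(7, p, control = ctl_fast()),
               sol$tau_l[sol$force == 7], tolerance = 1e-6)
  expect_equal(mean_lifetime(7, p, control = ctl_fast(),
                             p_s0 = sol$p_s0[1]),
               sol$tau[sol$force == 7], tolerance = 1e-6)
})

test_that("reference parameters give a catch bond with an interior maximum", {
  p <- tbl1()
  forces <- seq(0.7, 33, by = 1.4)
  sol <- kinetic_solution(forces, p, control = ctl_fast())
  ipk <- which.max(sol$tau)
  expect_gt(ipk, 1)
  expect_lt(ipk, length(forces))
  expect_gt(sol$tau[ipk], 2 * sol$tau[1])  # clear lifetime enhancement
})

test_that("Bell limit: log tau(F) is linear with slope -d/kBT", {
  # the Bell law is the large-(F r0 / kBT) regime; fit inside it
  p <- bell_params()
  env <- env0()
  forces <- seq(8, 20, by = 2)
  tau <- mean_lifetime(forces, p, env, control = ctl_fast())
  fitl <- stats::lm(log(tau) ~ forces)
  slope_expected <- -p$d / env$thermal_energy
  expect_equal(unname(stats::coef(fitl)[2]), slope_expected,
               tolerance = 0.05)
  # effective rupture-rate ratio follows exp(dF d / kBT)
  tau2 <- mean_lifetime(c(8, 16), p, env, control = ctl_fast())
  expect_equal(log(tau2[1] / tau2[2]), 8 * p$d / env$thermal_energy,
               tolerance = 0.1)
})

test_that("barrier-less wide-angle limit collapses to a single exponential", {
  p <- selectin_params()
  sol <- kinetic_solution(c(2, 8, 15), p, control = ctl_fast())
  minor <- pmin(abs(sol$A1), abs(sol$A2))
  expect_true(all(minor < 1e-3))
})

test_that("parameter scan reproduces the angular-barrier mutation protocol", {
  p <- tbl1()
  sc <- scan_parameter(p, param = "H", values = c(25, 20, 15, 10, 5, 0),
                       forces = 7, control = ctl_fast())
  expect_true(all(sc$ok))
  amp <- pmin(abs(sc$A1), abs(sc$A2)) / pmax(abs(sc$A1), abs(sc$A2))
  # double-exponential at H = 25, mainly single-exponential at H <= 20
  expect_gt(amp[sc$value == 25], 0.05)
  expect_true(all(amp[sc$value <= 20] < 0.05))
  # large-angle state duration collapses by many orders of magnitude at
  # H = 0 (the barrier-less crossing becomes diffusion-limited)
  expect_gt(sc$tau_l[sc$value == 25] / sc$tau_l[sc$value == 0], 1e4)
  expect_lt(sc$tau_l[sc$value == 0], 1e-5)

  # empty scan -> empty table; invalid parameter value -> flagged row
  expect_equal(nrow(scan_parameter(p, param = "H", values = numeric(0),
                                   forces = 7)), 0)
  sc_bad <- scan_parameter(p, param = "d", values = c(0.5, -1),
                           forces = 7, control = ctl_fast())
  expect_true(sc_bad$ok[sc_bad$value == 0.5])
  expect_false(any(sc_bad$ok[sc_bad$value == -1]))
})
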