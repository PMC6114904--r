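test_that("grid MFPT matches the exact 1D passage time when angles decouple", {
  # k1 = 0 and C = 0 make the radial problem independent of theta, so the
  # 2D solver must reproduce the 1D double-integral MFPT
  env <- env0()
  p <- bond_parameters(E0 = 6, E1 = 0, H = 0, G = 0, d = 0.56, r0 = 1.7,
                       alpha_min = 40, alpha_c = 90, alpha_max = 140)
  m <- solve_mfpt(0, p, env, measure = "flat", grid = grid_spec(128, 32))
  dom <- catchbond:::radial_domain(p)
  r <- seq(dom[1], dom[2], length.out = 4000)
  w <- 0.5 * p$k0 * (r - p$r0)^2
  D <- diffusivity(env, p$r0)
  tau_1d <- catchbond:::mfpt_profile(r, w, D, "right", exp(-w) > 0)
  expect_equal(m$tau, tau_1d, tolerance = 0.005)
})

test_that("grid MFPT reproduces free diffusion against an absorbing wall", {
  # nearly flat potential: equilibrium-start MFPT to the wall is L^2/(3D)
  env <- env0()
  p <- bond_parameters(E0 = 1e-9, E1 = 0, H = 0, G = 0, d = 0.56, r0 = 1.7,
                       alpha_min = 40, alpha_c = 90, alpha_max = 140)
  grid <- grid_spec(160, 32, r_lo = 0.9)
  m <- suppressWarnings(solve_mfpt(0, p, env, measure = "flat", grid = grid))
  L <- (p$r0 + p$d) - 0.9
  expect_equal(m$tau, L^2 / (3 * diffusivity(env, p$r0)), tolerance = 0.01)
})

test_that("grid MFPT converges under refinement and matches the analytics", {
  env <- env0()
  p <- low_barrier_params()
  m1 <- solve_mfpt(5, p, env, grid = grid_spec(96, 144))
  m2 <- solve_mfpt(5, p, env, grid = grid_spec(192, 288))
  expect_lt(abs(m2$tau - m1$tau) / m1$tau, 0.01)  # Richardson check
  ana <- kinetic_solution(5, p, env)
  expect_lt(abs(ana$tau - m2$tau) / m2$tau, 0.25)
  expect_gt(m2$pi_s, 0); expect_lt(m2$pi_s, 1)
})

test_that("analytic lifetimes agree with the grid oracle across random landscapes", {
  # cross-validation at barriers scaled into the 4-9 kBT range
  env <- env0()
  set.seed(42)
  worst <- 0
  for (i in 1:8) {
    E0 <- runif(1, 4, 9); E1 <- runif(1, 0.5, 3); H <- runif(1, 2, 6)
    G <- runif(1, 0, min(H, 2)); d <- runif(1, 0.3, 0.9); r0 <- runif(1, 1, 3)
    am <- runif(1, 30, 60); ac <- am + runif(1, 3, 15)
    ax <- ac + runif(1, 50, 110)
    F <- runif(1, 0, 12)
    p <- bond_parameters(E0, E1, H, G, d, r0, am, ac, ax)
    m <- solve_mfpt(F, p, env, grid = grid_spec(128, 160))
    a <- kinetic_solution(F, p, env, control = ctl_fast())
    worst <- max(worst, abs(a$tau / m$tau - 1))
  }
  expect_lt(worst, 0.25)
})

test_that("equilibrium measure is shared between the solver and the landscape", {
  # small-basin weight computed from the solver's own grid equals the
  # landscape quadrature
  env <- env0()
  p <- low_barrier_params()
  mo <- catchbond:::measure_opts("planar")
  dom <- catchbond:::radial_domain(p)
  n_r <- 128; n_th <- 256
  h_r <- (p$r0 + p$d - dom[1]) / n_r
  h_th <- (p$theta_max - p$theta_min) * pi / 180 / n_th
  r_c <- dom[1] + (seq_len(n_r) - 0.5) * h_r
  th_c <- p$theta_min * pi / 180 + (seq_len(n_th) - 0.5) * h_th
  W <- outer(r_c, th_c, function(r, th)
    catchbond:::reduced_potential(r, th, 0, p, env, mo))
  rho <- exp(-(W - min(W)))
  pS_grid <- sum(rho[, th_c >= p$theta_c * pi / 180]) / sum(rho)
  pS_land <- equilibrium_small_angle_probability(0, p, env)
  expect_equal(pS_grid, pS_land, tolerance = 0.01)
})

test_that("Brownian dynamics is reproducible and matches the analytic lifetime", {
  env <- env0()
  p <- bond_parameters(E0 = 6, E1 = 1.5, H = 3, G = 1, d = 0.56, r0 = 1.7,
                       alpha_min = 48, alpha_c = 53, alpha_max = 169)
  b1 <- simulate_rupture_times(5, p, env, n = 60, seed = 9, horizon = 1e-5)
  b2 <- simulate_rupture_times(5, p, env, n = 60, seed = 9, horizon = 1e-5)
  expect_identical(b1$lifetime, b2$lifetime)
  expect_identical(b1$basin, b2$basin)

  bd <- simulate_rupture_times(5, p, env, n = 700, seed = 3, horizon = 2e-5)
  expect_equal(attr(bd, "n_ruptured") + attr(bd, "n_censored"), 700)
  ok <- !bd$censored
  ana <- kinetic_solution(5, p, env, control = ctl_fast())
  mb <- mean(bd$lifetime[ok])
  se <- stats::sd(bd$lifetime[ok]) / sqrt(sum(ok))
  expect_lt(abs(mb - ana$tau) / se, 3)

  # grid oracle agrees with BD within 3 standard errors as well
  m <- solve_mfpt(5, p, env, grid = grid_spec(128, 160))
  expect_lt(abs(mb - m$tau) / se, 3)
})

test_that("high barriers censor desk-scale Brownian dynamics", {
  env <- env0()
  bd <- simulate_rupture_times(0, tbl1(), env, n = 30, seed = 2,
                               horizon = 2e-8)
  expect_equal(attr(bd, "n_censored"), 30)
  expect_true(all(bd$censored))
  expect_error(empirical_survival(bd), "censored")
})

test_that("analytic survival lies within the Brownian-dynamics confidence band", {
  env <- env0()
  p <- bond_parameters(E0 = 6, E1 = 1.5, H = 3, G = 1, d = 0.56, r0 = 1.7,
                       alpha_min = 48, alpha_c = 53, alpha_max = 169)
  bd <- simulate_rupture_times(5, p, env, n = 700, seed = 17, horizon = 2e-5)
  km <- empirical_survival(bd)
  ana <- kinetic_solution(5, p, env, control = ctl_fast())
  use <- km$n_event > 0 & is.finite(km$conf_low) & is.finite(km$conf_high)
  sig <- survival_probability(ana, km$time[use])$survival
  inside <- sig >= km$conf_low[use] & sig <= km$conf_high[use]
  expect_gt(mean(inside), 0.9)
})

test_that("empirical survival is the product-limit estimator", {
  d <- tibble::tibble(lifetime = c(1, 2, 3), censored = FALSE)
  km <- empirical_survival(d)
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # censoring beyond the last event leaves earlier steps unchanged
  d2 <- tibble::tibble(lifetime = c(1, 2, 3, 10), censored = c(F, F, F, T))
  km2 <- empirical_survival(d2)
  expect_equal(km2$survival[km2$n_event > 0], c(3 / 4, 2 / 4, 1 / 4))
})
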