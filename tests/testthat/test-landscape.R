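test_that("spring constant matches its defining energy identities", {
  p <- tbl1()
  expect_equal(spring_constant(90, p), p$k0 + p$k1)
  # k(theta_max) d^2/2 = E0 and k(theta_min) d^2/2 = E0 + E1
  expect_equal(spring_constant(p$theta_max, p) * p$d^2 / 2, p$E0,
               tolerance = 1e-10)
  expect_equal(spring_constant(p$theta_min, p) * p$d^2 / 2, p$E0 + p$E1,
               tolerance = 1e-10)
  expect_equal(spring_constant(p$theta_max, p), 2 * p$E0 / p$d^2,
               tolerance = 1e-10)  # ~139.0 kBT/nm^2
  # strictly decreasing in theta when k1 > 0
  th <- seq(p$theta_min, p$theta_max, length.out = 50)
  expect_true(all(diff(spring_constant(th, p)) < 0))
  expect_error(spring_constant(5, p), "within")
})

test_that("angular potential hits its anchor values and is continuous at the cusp", {
  p <- tbl1()
  expect_equal(angular_potential(p$theta_max, p), 0, tolerance = 1e-12)
  expect_equal(angular_potential(p$theta_min, p), p$G, tolerance = 1e-10)
  eps <- 1e-9
  expect_equal(angular_potential(p$theta_c + eps, p), p$H, tolerance = 1e-6)
  expect_equal(angular_potential(p$theta_c - eps, p), p$H, tolerance = 1e-6)
  # full-landscape continuity at the cusp across a grid of r
  for (r in seq(1.3, p$r0 + p$d, length.out = 7)) {
    dU <- potential_energy(r, p$theta_c + 1e-8, 3, p) -
      potential_energy(r, p$theta_c - 1e-8, 3, p)
    expect_lt(abs(dU), 1e-5)
  }
})

test_that("potential energy matches closed-form anchors", {
  p <- tbl1()
  expect_equal(potential_energy(p$r0, p$theta_max, 0, p), 0, tolerance = 1e-12)
  expect_equal(potential_energy(p$r0 + p$d, p$theta_max, 0, p), p$E0,
               tolerance = 1e-9)
  # E0 + E1 + G at the large-angle end of the rupture boundary
  expect_equal(potential_energy(p$r0 + p$d, p$theta_min, 0, p),
               p$E0 + p$E1 + p$G, tolerance = 1e-9)
})

test_that("force enters as a linear tilt with slope -r cos(theta)", {
  p <- tbl1()
  env <- env0()
  set.seed(7)
  for (i in 1:10) {
    r <- runif(1, 1.3, 2.2)
    th <- runif(1, p$theta_min, p$theta_max)
    dF <- 0.01
    slope <- (potential_energy(r, th, 5 + dF, p, env) -
                potential_energy(r, th, 5 - dF, p, env)) / (2 * dF)
    expect_equal(slope, -r * cos(th * pi / 180) / env$thermal_energy,
                 tolerance = 1e-6)
  }
})

test_that("equilibrium small-angle probability behaves physically", {
  p <- tbl1()
  ps <- equilibrium_small_angle_probability(seq(0, 35, by = 2.5), p,
                                            control = ctl_fast())
  expect_true(all(ps >= 0 & ps <= 1))
  # monotonically non-increasing with force: force favors large angles
  expect_true(all(diff(ps) <= 1e-10))
  # degenerate geometry: alpha_c next to alpha_max leaves no large-angle room
  p_edge <- bond_parameters(E0 = 21.8, E1 = 5.8, H = 25, G = 5, d = 0.56,
                            r0 = 1.7, alpha_min = 48, alpha_c = 168.9,
                            alpha_max = 169)
  expect_gt(equilibrium_small_angle_probability(0, p_edge,
                                                control = ctl_fast()), 0.999)
})

test_that("landscape grid flags the region beyond the rupture boundary", {
  p <- tbl1()
  g <- landscape_grid(p, n_r = 31, n_alpha = 41)
  expect_true(all(c("r", "alpha", "theta", "energy", "ruptured") %in% names(g)))
  expect_true(any(g$ruptured))
  expect_true(all(g$r[g$ruptured] > p$r0 + p$d))
  # grid energies agree with direct evaluation
  i <- c(5, 500, 1000)
  expect_equal(g$energy[i],
               potential_energy(g$r[i], g$theta[i], 0, p))
})

test_that("angular free energy is basin-labelled and shares the measure with p_S", {
  p <- tbl1()
  w <- angular_free_energy(10, p, control = ctl_fast())
  expect_setequal(unique(w$basin), c("small", "large"))
  expect_equal(min(w$free_energy), 0)
  # integrating the profile reproduces the equilibrium probability
  wS <- exp(-w$free_energy[w$basin == "small"])
  wL <- exp(-w$free_energy[w$basin == "large"])
  thS <- w$theta[w$basin == "small"] * pi / 180
  thL <- w$theta[w$basin == "large"] * pi / 180
  trap <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  pS <- trap(thS, wS) / (trap(thS, wS) + trap(thL, wL))
  expect_equal(pS,
               equilibrium_small_angle_probability(10, p, control = ctl_fast()),
               tolerance = 1e-6)
})
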