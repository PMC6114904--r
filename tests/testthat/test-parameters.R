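test_that("angle conversions follow alpha = 180 - theta - phi and round-trip", {
  expect_equal(theta_from_alpha(48, 0), 132)
  expect_equal(theta_from_alpha(169, 0), 11)
  expect_equal(theta_from_alpha(90, 5), 85)
  for (phi in c(-5, 0, 3)) {
    a <- c(10, 48, 90, 169)
    expect_equal(alpha_from_theta(theta_from_alpha(a, phi), phi), a)
  }
  expect_error(theta_from_alpha(0), "between 0 and 180")
  expect_error(theta_from_alpha(180), "between 0 and 180")
})

test_that("stiffness coefficients reproduce the rupture-barrier energies", {
  k <- stiffness_from_energies(21.8, 5.8, 0.56, 11, 132)
  expect_equal(unname(k["k0"]), 131.6166, tolerance = 1e-4)
  expect_equal(unname(k["k1"]), 22.40777, tolerance = 1e-4)
  # independent algebra check: the inverse map returns E0, E1
  e <- energies_from_stiffness(k["k0"], k["k1"], 0.56, 11, 132)
  expect_equal(unname(e["E0"]), 21.8, tolerance = 1e-10)
  expect_equal(unname(e["E1"]), 5.8, tolerance = 1e-10)

  expect_equal(unname(stiffness_from_energies(10, 0, 0.5, 11, 132)),
               c(2 * 10 / 0.25, 0))
  expect_equal(unname(stiffness_from_energies(0, 0, 0.5, 11, 132)), c(0, 0))

  expect_error(stiffness_from_energies(10, 5, 0.5, 100, 100), "degenerate")
  # E1 large enough to drive k0 negative
  expect_error(stiffness_from_energies(0.1, 19, 0.56, 11, 132), "negative")
})

test_that("round-trip (k0,k1) <-> (E0,E1) is identity across random sets", {
  set.seed(1)
  for (i in 1:25) {
    k0 <- runif(1, 0, 300); k1 <- runif(1, 0, 100)
    d <- runif(1, 0.1, 2)
    tmin <- runif(1, 5, 60); tmax <- runif(1, tmin + 10, 170)
    e <- energies_from_stiffness(k0, k1, d, tmin, tmax)
    k <- stiffness_from_energies(e["E0"], e["E1"], d, tmin, tmax)
    expect_equal(unname(k["k0"]), k0, tolerance = 1e-10)
    expect_equal(unname(k["k1"]), k1, tolerance = 1e-10)
    e2 <- energies_from_stiffness(k["k0"], k["k1"], d, tmin, tmax)
    expect_equal(unname(e2), unname(e), tolerance = 1e-10)
  }
})

test_that("parameter constructor validates its constraints", {
  p <- tbl1()
  expect_s3_class(p, "bond_parameters")
  expect_equal(p$theta_min, 11)
  expect_equal(p$theta_c, 127)
  expect_equal(p$theta_max, 132)
  expect_lt(p$theta_min, p$theta_c)
  expect_lt(p$theta_c, p$theta_max)

  args <- list(E0 = 21.8, E1 = 5.8, H = 25, G = 5, d = 0.56, r0 = 1.7,
               alpha_min = 48, alpha_c = 53, alpha_max = 169)
  bad <- function(...) do.call(bond_parameters, modifyList(args, list(...)))
  expect_error(bad(alpha_c = 40), "alpha_min < alpha_c")
  expect_error(bad(alpha_max = 50), "alpha_min < alpha_c")
  expect_error(bad(E0 = 0), "E0")
  expect_error(bad(d = -1), "d")
  expect_error(bad(H = -2), "H")
  expect_error(bad(alpha_max = 181), "0, 180")
  # negative reverse barrier H - G is allowed (mutation scans reach H = 0)
  expect_s3_class(bad(H = 0), "bond_parameters")
})

test_that("tidy() exposes all parameters with units", {
  td <- tidy(tbl1())
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("E0", "E1", "H", "G", "d", "r0", "alpha_min",
                             "alpha_c", "alpha_max", "phi", "k0", "k1"))
  expect_equal(td$estimate[td$term == "E0"], 21.8)
})

test_that("environment carries kB T and Stokes diffusivity", {
  env <- bond_environment()
  # kB * 298.15 K in pN nm, to 4 significant figures
  expect_equal(signif(env$thermal_energy, 4), signif(1.380649e-2 * 298.15, 4))
  D <- diffusivity(env, 1.7)
  expect_equal(D, env$thermal_energy * 1e-21 / (6 * pi * 8.9e-4 * 1.7e-9) * 1e18,
               tolerance = 1e-12)
  # order of magnitude: ~1.4e8 nm^2/s for a 1.7 nm domain in water
  expect_gt(D, 1e8); expect_lt(D, 2e8)
})
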