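test_that("pre-hydrolysis equilibrium conversion matches the bisection oracle", {
  cases <- list(
    list(N0 = 2, P0 = 8, K = 0.15, expect = 0.5078),   # uridine demo system
    list(N0 = 1, P0 = 2.5, K = 0.15, expect = 0.4236),
    list(N0 = 5, P0 = 5, K = 0.8, expect = NA),
    list(N0 = 1, P0 = 20, K = 0.01, expect = NA)
  )
  for (cs in cases) {
    sys <- reaction_system(cs$N0, cs$P0, cs$K)
    c1 <- solve_equilibrium_conversion(sys)
    expect_equal(c1, oracle_conversion(cs$N0, cs$P0, cs$K), tolerance = 1e-8)
    if (!is.na(cs$expect)) expect_equal(c1, cs$expect, tolerance = 1e-3)
    expect_lt(abs(mass_action_residual(sys, c1)), 1e-9 * cs$K)
  }
})

test_that("conversion vanishes as K approaches zero", {
  sys <- reaction_system(2, 8, 1e-10)
  expect_lt(solve_equilibrium_conversion(sys), 1e-4)
})

test_that("K = 1 degeneracy is solved by the linear reduction", {
  sys <- reaction_system(2, 8, 1)
  c1 <- solve_equilibrium_conversion(sys)
  expect_equal(c1, oracle_conversion(2, 8, 1), tolerance = 1e-10)
  expect_lt(abs(mass_action_residual(sys, c1)), 1e-9)
  # and the shifted equilibrium too
  ms <- max_shift(c1, sys)
  expect_equal(ms$c2_max, oracle_conversion(2, 8, 1, h = c1 * 2),
               tolerance = 1e-10)
})

test_that("invalid reaction systems are rejected", {
  expect_error(reaction_system(0, 8, 0.15), "N0")
  expect_error(reaction_system(2, -1, 0.15), "P0")
  expect_error(reaction_system(2, 8, 0), "K")
  expect_error(reaction_system(2, 8, NA), "K")
})

test_that("K is recovered exactly from the equilibrium conversion", {
  expect_equal(estimate_K_from_equilibrium(0.5, 2, 8), 1 / 7,
               tolerance = 1e-12)
  # round trip at the demonstration system
  sys <- uridine_system()
  c1 <- solve_equilibrium_conversion(sys)
  expect_equal(estimate_K_from_equilibrium(c1, 2, 8), 0.15,
               tolerance = 1e-12)
  expect_warning(K0 <- estimate_K_from_equilibrium(0, 2, 8),
                 "no information")
  expect_identical(K0, 0)
  expect_error(estimate_K_from_equilibrium(0.9, 1, 0.8), "infeasible")
})

test_that("K round-trips across the natural-nucleoside regime", {
  for (K in c(0.01, 0.05, 0.15, 0.5, 1)) {
    for (ratio in c(1, 2.5, 4, 10, 20)) {
      sys <- reaction_system(1, ratio, K)
      c1 <- solve_equilibrium_conversion(sys)
      expect_equal(estimate_K_from_equilibrium(c1, 1, ratio), K,
                   tolerance = 1e-9)
    }
  }
})

test_that("hydrolyzed amount reproduces the full-hydrolysis anchor", {
  sys <- uridine_system()
  # 72 % conversion corresponds to full hydrolysis of the ~1 mM pool
  expect_equal(hydrolyzed_amount(0.72, sys), 1.0, tolerance = 0.01)
  expect_equal(hydrolyzed_amount(0.60, sys), 0.4727, tolerance = 1e-4)
  # at the unshifted equilibrium nothing has been lost
  c1 <- solve_equilibrium_conversion(sys)
  expect_equal(hydrolyzed_amount(c1, sys), 0, tolerance = 1e-9)
})

test_that("negative inferred amounts are clamped within tolerance, rejected beyond", {
  sys <- uridine_system()
  c1 <- solve_equilibrium_conversion(sys)
  expect_identical(hydrolyzed_amount(c1 - 1e-5, sys), 0)
  expect_error(hydrolyzed_amount(c1 - 0.05, sys), "inconsistent")
  # unclamped mode returns the raw (negative) value for symmetric-noise fits
  raw <- hydrolyzed_amount(c1 - 1e-5, sys, clamp = FALSE)
  expect_lt(raw, 0)
  expect_error(hydrolyzed_amount(1.2, sys), "fraction")
})

test_that("joint determination of K and the hydrolyzed amount composes the two inverses", {
  res <- hydrolyzed_amount_joint(0.5078, 0.7202, N0 = 2, P0 = 8)
  expect_equal(res$K, 0.150, tolerance = 1e-3)
  expect_equal(res$h, 1.0, tolerance = 2e-3)
  res0 <- hydrolyzed_amount_joint(0.5, 0.5, N0 = 2, P0 = 8)
  expect_identical(res0$h, 0)
  expect_error(hydrolyzed_amount_joint(0.6, 0.5, N0 = 2, P0 = 8),
               "inconsistent")
  # constructed full-hydrolysis case at ratio 2.5
  res2 <- hydrolyzed_amount_joint(0.4236, 0.6278, N0 = 1, P0 = 2.5)
  expect_equal(res2$h, 0.4236, tolerance = 2e-3)
})

test_that("maximum shift solves the full-hydrolysis quadratic", {
  sys <- uridine_system()
  ms <- max_shift(0.50, sys)
  expect_equal(ms$c2_max, 0.7202, tolerance = 1e-4)
  expect_equal(ms$delta_c_max, ms$c2_max - 0.50, tolerance = 1e-12)
  expect_equal(ms$c2_max, oracle_conversion(2, 8, 0.15, h = 1.0),
               tolerance = 1e-8)
  # full-hydrolysis round trip: the ceiling maps back to the whole pool
  expect_equal(hydrolyzed_amount(ms$c2_max, sys), 0.50 * 2,
               tolerance = 1e-9)
  # c1 = 0: nothing was generated, so nothing can hydrolyze
  expect_equal(max_shift(0, sys)$c2_max, solve_equilibrium_conversion(sys),
               tolerance = 1e-12)
  ms2 <- max_shift(0.4236, reaction_system(1, 2.5, 0.15))
  expect_equal(ms2$delta_c_max, 0.204, tolerance = 1e-3)
  expect_error(max_shift(1, sys), "fraction")
  expect_error(max_shift(-0.1, sys), "fraction")
})

test_that("forward model inverts the hydrolyzed-amount closed form", {
  sys <- uridine_system()
  c1 <- solve_equilibrium_conversion(sys)
  expect_equal(conversion_after_hydrolysis(0, sys), c1, tolerance = 1e-12)
  expect_equal(conversion_after_hydrolysis(1.0, sys), 0.7202,
               tolerance = 1e-4)
  expect_equal(conversion_after_hydrolysis(0.4727, sys), 0.600,
               tolerance = 1e-4)
  expect_error(conversion_after_hydrolysis(-0.1, sys), "non-negative")
  expect_error(conversion_after_hydrolysis(1.5, sys), "bound")
})

test_that("hydrolyzed_amount and conversion_after_hydrolysis are mutually inverse", {
  set.seed(101)
  for (i in 1:200) {
    K <- 10^runif(1, -2, 0)
    ratio <- runif(1, 1, 20)
    N0 <- 10^runif(1, -1, 1)
    sys <- reaction_system(N0, ratio * N0, K)
    c1 <- solve_equilibrium_conversion(sys)
    h <- runif(1, 0, c1 * N0)
    c2 <- conversion_after_hydrolysis(h, sys)
    h_back <- hydrolyzed_amount(c2, sys, tol = 1e-6 * N0, clamp = FALSE)
    expect_lt(abs(h_back - h), 1e-9 * max(h, 1e-6 * N0))
    expect_lt(abs(mass_action_residual(sys, c2, h)), 1e-9 * K)
  }
})

test_that("conservation and monotonicity hold along the shift", {
  sys <- uridine_system()
  c1 <- solve_equilibrium_conversion(sys)
  hs <- seq(0, c1 * sys$N0, length.out = 25)
  c2s <- vapply(hs, conversion_after_hydrolysis, numeric(1), system = sys)
  expect_true(all(diff(c2s) > 0))
  for (i in seq_along(hs)) {
    st <- equilibrium_state(sys, c2s[i], hs[i])
    expect_equal(st$B + st$N, sys$N0, tolerance = 1e-12)
    expect_equal(st$P + st$B - st$h, sys$P0, tolerance = 1e-12)
    expect_gte(st$P1P, -1e-12)
  }
  # hydrolyzed_amount strictly increasing in c2 on (c1, c2_max]
  c2grid <- seq(c1 + 1e-4, max_shift(c1, sys)$c2_max, length.out = 25)
  hgrid <- vapply(c2grid, hydrolyzed_amount, numeric(1), system = sys)
  expect_true(all(diff(hgrid) > 0))
})
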