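test_that("commitment rate reproduces the mouse and human colon derivations", {
  # mouse: 6-cell niche of 15 LGR5+ cells dividing at 0.2/day
  expect_equal(commitment_rate(0.2, 6, 15), 1 / 3, tolerance = 1e-12)
  # human colon: weekly division, 36 putative stem cells, niche of 6 or 20
  expect_equal(commitment_rate(1 / 7, 6, 36), 0.172, tolerance = 5e-3)
  expect_equal(commitment_rate(1 / 7, 20, 36), 0.321, tolerance = 5e-3)
  # half-in-niche symmetry: total 2*X1 gives nu = 2*lam for any lam, X1
  for (lam in c(0.1, 0.2, 1 / 7)) for (X1 in c(2, 6, 20))
    expect_equal(commitment_rate(lam, X1, 2 * X1), 2 * lam)
  # the returned nu balances the displaced-pool flux
  nu <- commitment_rate(0.2, 6, 15)
  expect_equal(0.2 * 6 + 0.2 * 9 - nu * 9, 0, tolerance = 1e-12)
  expect_error(commitment_rate(0.2, 6, 6), "displaced")
})

test_that("crypt steady state reproduces the mouse pools and scales in X1", {
  ss <- crypt_steady_state(mouse_crypt())
  expect_equal(ss$X2, 9)
  expect_equal(ss$Y, c(1.5, 3, 6, 12, 24, 48))
  expect_equal(ss$Y_total, 94.5)
  expect_equal(ss$Z, 576)
  # Z* is linear in X1
  doubled <- crypt_parameters(12, 0.2, 1 / 3, 2, 1 / 3, 6)
  expect_equal(crypt_steady_state(doubled)$Z, 2 * ss$Z)
  # nu <= lam is flagged tumorigenic
  expect_warning(bad <- crypt_parameters(6, 0.4, 1 / 3, 2, 1 / 3, 6),
                 "non-homeostatic")
  expect_error(crypt_steady_state(bad), "tumorigenic")
})

test_that("mean-field ODE converges to the closed-form steady state", {
  p <- mouse_crypt()
  ss <- crypt_steady_state(p)
  # starting at the steady state the trajectory stays there
  init <- c(ss$X2, ss$Y, ss$Z)
  sol <- integrate_means(p, init, t_grid = c(0, 50, 100))
  expect_equal(sol$Z, rep(ss$Z, 3), tolerance = 1e-6)
  # from an empty crypt, Z approaches 576 within 0.1% by 200 days
  sol0 <- integrate_means(p, t_grid = c(0, 200))
  expect_equal(sol0$Z[2], 576, tolerance = 1e-3)
  # property: random homeostatic parameter sets agree at long times
  set.seed(42)
  for (i in 1:20) {
    rp <- random_crypt()
    zs <- crypt_steady_state(rp)$Z
    t_end <- 60 / min(rp$nu - rp$lam, rp$delta)  # several slowest timescales
    sol <- integrate_means(rp, t_grid = c(0, t_end))
    expect_equal(sol$Z[2], zs, tolerance = 1e-6)
  }
})

test_that("postmitotic ratio amplifies rate changes and matches steady states", {
  expect_equal(population_ratio(0.2, 0.2, 1 / 3), 1)
  # 10% division-rate drop gives a >21% tissue drop
  expect_equal(population_ratio(0.2, 0.18, 1 / 3), 0.7826087, tolerance = 1e-7)
  # agreement with the ratio of full steady states
  p0 <- mouse_crypt()
  p1 <- crypt_parameters(6, 0.18, 1 / 3, 2, 1 / 3, 6)
  expect_equal(population_ratio(0.2, 0.18, 1 / 3),
               crypt_steady_state(p1)$Z / crypt_steady_state(p0)$Z,
               tolerance = 1e-12)
  # amplification property over a sweep of deleterious changes
  for (lam1 in seq(0.02, 0.19, by = 0.01)) {
    rel_pop <- abs(population_ratio(0.2, lam1, 1 / 3) - 1)
    rel_rate <- abs(lam1 / 0.2 - 1)
    expect_gt(rel_pop, rel_rate)
  }
  # monotonicity on the homeostatic region: increasing in lam, decreasing in nu
  z_of <- function(lam, nu)
    crypt_steady_state(crypt_parameters(6, lam, nu, 2, 1 / 3, 6))$Z
  lams <- seq(0.05, 0.3, by = 0.05)
  expect_true(all(diff(vapply(lams, z_of, numeric(1), nu = 1 / 3)) > 0))
  nus <- seq(0.35, 0.8, by = 0.05)
  expect_true(all(diff(vapply(nus, z_of, numeric(1), lam = 0.2)) < 0))
  # differentiation analogue and its tumorigenic guard
  expect_equal(population_ratio_diff(1 / 3, 1 / 3, 0.2), 1)
  expect_error(population_ratio(0.2, 0.5, 1 / 3), "tumorigenic")
  expect_error(population_ratio_diff(1 / 3, 0.1, 0.2), "tumorigenic")
})

test_that("villus bookkeeping matches the printed crypt arithmetic", {
  ps <- scenario_preset("mouse_si")
  ss <- crypt_steady_state(ps$crypt)
  expect_equal(ps$crypts_per_villus * (ss$Z - ps$z_in_crypt), 3568)
})
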