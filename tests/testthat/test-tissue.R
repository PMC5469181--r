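test_that("Poisson crypt-mutation counts: mass, limits, sampling oracle", {
  # t = 0: every crypt is mutation-free
  n0 <- mutation_count_distribution(1e-5, 0, C = 1e6)
  expect_equal(n0$n_m[n0$m == 0], 1e6)
  expect_equal(sum(n0$n_m[n0$m > 0]), 0)
  # unit mean: n_1 = C/e
  n1 <- mutation_count_distribution(1e-3, 1000, C = 1e6)
  expect_equal(n1$n_m[n1$m == 1], 1e6 * exp(-1), tolerance = 1e-12)
  expect_equal(sum(n1$n_m), 1e6, tolerance = 1e-8)
  expect_error(mutation_count_distribution(1e-3, 1000, m_cap = 2), "tail")
  # sampling oracle: per-crypt Poisson draws reproduce the expected counts
  set.seed(5)
  C <- 2e4
  draws <- stats::rpois(C, 1)
  for (m in 0:3) {
    expected <- C * dpois(m, 1)
    se <- sqrt(C * dpois(m, 1) * (1 - dpois(m, 1)))
    expect_lt(abs(sum(draws == m) - expected), 3 * se)
  }
})

test_that("a no-effect DFE leaves the tissue unchanged", {
  null_dfe <- dfe_parameters(1.26e-4, 1e-9, 1e-9, 0.0575)
  scn <- tissue_scenario(mouse_crypt(), null_dfe, "division", 1095)
  tr <- tissue_trajectory(scn)
  expect_equal(tr$fraction, rep(1, nrow(tr)), tolerance = 1e-6)
})

test_that("mouse attrition curve: magnitude, linearity, slope consistency", {
  scn <- tissue_scenario(mouse_crypt(), yeast(), "division", 1095)
  tr <- tissue_trajectory(scn)
  expect_equal(tr$fraction[1], 1)
  expect_true(all(diff(tr$fraction) < 0))
  # ~0.35% decline over 3 adult years
  expect_equal(1 - tr$fraction[nrow(tr)], 0.0035, tolerance = 0.1)
  # near-linearity: at t = lifetime/10 the curve deviates from slope*t by
  # less than 5% of its own decline
  slope <- attr(tr, "slope_linear")
  t10 <- 109.5
  tr10 <- tissue_trajectory(scn, t_grid = c(0, t10))
  decline <- 1 - tr10$fraction[2]
  expect_lt(abs((1 + slope * t10) - tr10$fraction[2]), 0.05 * decline)
  # numerical derivative at t = 0 matches the linear slope within 1%
  h <- 1
  trh <- tissue_trajectory(scn, t_grid = c(0, h))
  expect_equal((trh$fraction[2] - 1) / h, slope, tolerance = 0.01)
})

test_that("attrition fraction is independent of the crypt count", {
  for (C in c(1, 1e4, 1e7)) {
    scn <- tissue_scenario(mouse_crypt(), yeast(), "division", 1095,
                           n_crypts = C)
    tr <- tissue_trajectory(scn, t_grid = c(0, 500, 1095))
    if (C == 1) ref <- tr$fraction else expect_identical(tr$fraction, ref)
  }
})

test_that("expected-rate and expected-Z constructions differ by a Jensen gap", {
  scn <- tissue_scenario(mouse_crypt(), yeast(), "division", 1095)
  a <- tissue_trajectory(scn, t_grid = c(0, 1095))
  b <- tissue_trajectory(scn, t_grid = c(0, 1095), mode = "expected_z",
                         n_grid = 2048)
  # the steady state is convex in the division rate, so averaging Z over
  # the density gives a smaller decline than plugging in the mean rate
  expect_gt(b$fraction[2], a$fraction[2])
  expect_equal(b$fraction[2], a$fraction[2], tolerance = 2e-3)
})

test_that("linear slope: neutral zero, X1-independence for differentiation", {
  dfe <- yeast()
  # an expected ratio of exactly one gives zero slope
  smry <- fixation_summary(6, dfe, "division", lam0 = 0.2)
  smry$expected_ratio <- 1
  scn <- tissue_scenario(mouse_crypt(), dfe, "division", 1095)
  expect_equal(linear_slope(scn, smry), 0)
  # the differentiation slope is bit-identical across niche sizes
  slopes <- vapply(c(2, 6, 20), function(X1) {
    crypt <- crypt_parameters(X1, 0.2, 1 / 3, 2, 1 / 3, 6)
    scn <- tissue_scenario(crypt, dfe, "differentiation", 1095)
    linear_slope(scn)
  }, numeric(1))
  expect_identical(slopes[1], slopes[2])
  expect_identical(slopes[2], slopes[3])
  # tumorigenic-mean guard
  hot <- dfe_parameters(1e-4, 0.217, 50, 0.999)
  scn_hot <- tissue_scenario(mouse_crypt(), hot, "division", 1095)
  expect_error(linear_slope(scn_hot), "tumorigenic")
})

test_that("human scenarios reproduce the end-of-life declines and ordering", {
  hs <- human_scenarios()
  get <- function(X1, target)
    hs$decline_pct[hs$X1 == X1 & hs$target == target]
  expect_equal(get(20, "division"), 0.5, tolerance = 0.3)
  expect_equal(get(6, "division"), 12, tolerance = 0.3)
  expect_equal(get(20, "differentiation"), 5, tolerance = 0.3)
  expect_gt(get(6, "differentiation"), 20)
  # neutral fixation always erodes faster than selection-filtered fixation
  expect_gt(get(20, "differentiation"), get(20, "division"))
  expect_gt(get(6, "differentiation"), get(6, "division"))
  # smaller niches erode faster
  expect_gt(get(6, "division"), get(20, "division"))
})
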