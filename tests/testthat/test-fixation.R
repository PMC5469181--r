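test_that("ring fixation probability: limits, continuity, monotonicity", {
  expect_equal(fixation_probability(1, 6), 1 / 6)
  expect_equal(fixation_probability(2, 2), 2 / 3)
  for (r in c(0.5, 1, 3)) expect_equal(fixation_probability(r, 1), 1)
  # continuous through the neutral point
  expect_equal(fixation_probability(1 + 1e-9, 6), 1 / 6, tolerance = 1e-6)
  expect_equal(fixation_probability(1 - 1e-9, 6), 1 / 6, tolerance = 1e-6)
  rs <- c(0.2, 0.5, 0.9, 0.99, 1.01, 1.5, 3, 10)
  p <- fixation_probability(rs, 6)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(fixation_probability(-1, 6), "positive")
})

test_that("fixation summary has the right limits in P_B and effect size", {
  # vanishing effects: drift limit p_hat -> 1/X1
  weak <- dfe_parameters(1e-4, 1e-6, 1e-6, 0.0575)
  expect_equal(fixation_summary(6, weak, "division")$p_hat, 1 / 6,
               tolerance = 1e-4)
  # almost-certain large beneficial effects: p_hat -> 1
  strong <- dfe_parameters(1e-4, 0.217, 50, 0.999)
  expect_gt(fixation_summary(6, strong, "division")$p_hat, 0.9)
  # mu_hat bookkeeping is exact
  s <- fixation_summary(6, yeast(), "division", lam0 = 0.2)
  expect_equal(s$mu_hat, s$p_hat * 1.26e-4 * 0.2 * 6)
})

test_that("posterior equals the prior whenever fixation is rate-independent", {
  dfe <- yeast()
  # X1 = 1: every lineage 'fixes'
  post1 <- posterior_fixed_density(0.2, 1, dfe, "division")
  expect_equal(post1$summary$p_hat, 1, tolerance = 1e-9)
  prior <- cryptdrift:::dfe_relative_density(post1$density$grid / 0.2, dfe,
                                             "division") / 0.2
  expect_equal(post1$density$density, prior, tolerance = 1e-3)
  # neutral differentiation target: p_hat = 1/X1 and the posterior is the
  # prior for every niche size
  ref <- NULL
  for (X1 in c(2, 6, 20)) {
    post <- posterior_fixed_density(1 / 3, X1, dfe, "differentiation",
                                    lam0 = 0.2)
    expect_equal(post$summary$p_hat, 1 / X1)
    if (is.null(ref)) ref <- post$density$density
    else expect_identical(post$density$density, ref)
  }
})

test_that("expected fixed division effect is deleterious at reported niche sizes", {
  dfe <- yeast()
  for (X1 in c(6, 10, 20)) {
    s <- fixation_summary(X1, dfe, "division")
    expect_lt(s$expected_ratio, 1)
  }
})

test_that("posterior expectation matches the grid density route", {
  dfe <- yeast()
  post <- posterior_fixed_density(0.2, 6, dfe, "division")
  expect_equal(density_mass(post$density), 1, tolerance = 1e-9)
  expect_equal(density_mean(post$density),
               0.2 * post$summary$expected_ratio, tolerance = 1e-4)
})

test_that("the recursion kernel conserves mass and reproduces scale-free means", {
  dfe <- yeast()
  for (target in c("division", "differentiation")) {
    r0 <- if (target == "division") 0.2 else 1 / 3
    seqs <- density_sequence(r0, 6, dfe, target, m_max = 10, n_grid = 2048,
                             lam0 = 0.2)
    masses <- vapply(seqs$densities, density_mass, numeric(1))
    expect_lt(max(abs(masses - 1)), 1e-6)
    # the posterior relative effect is scale-free, so E[f_m] = r0 * rho^m
    rho <- seqs$summary$expected_ratio
    means <- vapply(seqs$densities, density_mean, numeric(1))
    expect_equal(means, r0 * rho^(1:10), tolerance = 1e-3)
    # division means shrink with every fixation (the somatic ratchet)
    if (target == "division") expect_true(all(diff(means) < 0))
    else expect_true(all(diff(means) > 0))
  }
})

test_that("one kernel step from the posterior equals the two-fixation density", {
  dfe <- yeast()
  seqs <- density_sequence(0.2, 6, dfe, "division", m_max = 2, n_grid = 2048)
  stepped <- iterate_density(seqs$densities[[1]], seqs$kernel)
  expect_equal(stepped$density, seqs$densities[[2]]$density)
  expect_equal(stepped$m, 2L)
})

test_that("grid refinement does not move the recursion results", {
  dfe <- yeast()
  m1 <- density_sequence(0.2, 6, dfe, "division", m_max = 5, n_grid = 2048)
  m2 <- density_sequence(0.2, 6, dfe, "division", m_max = 5, n_grid = 4096)
  e1 <- vapply(m1$densities, density_mean, numeric(1))
  e2 <- vapply(m2$densities, density_mean, numeric(1))
  expect_equal(e1, e2, tolerance = 1e-4)
})

test_that("break-even boundary behaves as selection strength predicts", {
  b <- expected_effect_boundary(c(3, 6, 12, 20), 0.061, 0.0575)
  # at the root the expected ratio is 1
  for (i in seq_len(nrow(b))) {
    dfe <- dfe_parameters(1e-4, b$s_minus_boundary[i], 0.061, 0.0575)
    expect_equal(fixation_summary(b$X1[i], dfe, "division")$expected_ratio,
                 1, tolerance = 1e-6)
  }
  # larger niches tolerate worse deleterious tails before breaking even
  expect_true(all(diff(b$s_minus_boundary) > 0))
  # at X1 = 20 the expected ratio is non-monotone in s_minus: it dips below
  # one and rises again as large-effect mutations stop fixing
  sms <- c(0.05, 0.217, 1.2)
  ratios <- vapply(sms, function(sm)
    fixation_summary(20, dfe_parameters(1e-4, sm, 0.061, 0.0575),
                     "division")$expected_ratio, numeric(1))
  expect_lt(ratios[2], ratios[1])
  expect_gt(ratios[3], ratios[2])
  expect_equal(b$n_roots[b$X1 == 20], 2L)
})
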