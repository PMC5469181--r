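test_that("crossing probabilities: limits, fine-grid cross-check, monotonicity", {
  dfe <- yeast()
  seqs <- density_sequence(0.2, 6, dfe, "division", m_max = 6,
                           n_grid = 2048, extend_to = 0.4)
  # threshold below the support: everything has crossed; far above: error
  expect_equal(crossing_probability(seqs$densities[[1]], 0), 1,
               tolerance = 1e-6)
  expect_error(crossing_probability(seqs$densities[[1]], 10), "beyond the grid")
  # q_1 against direct adaptive quadrature of the one-fixation posterior
  q1_quad <- integrate(function(r)
    fixation_probability(r, 6) *
      cryptdrift:::dfe_relative_density(r, dfe, "division"),
    2, Inf, rel.tol = 1e-11)$value / seqs$summary$p_hat
  q <- crossing_probability(seqs$densities, 0.4)
  expect_equal(q[1], q1_quad, tolerance = 1e-3)
  # while compounding beneficial jumps dominate (early m) the crossing mass
  # grows; much later the deleterious ratchet drags the tail down again
  expect_true(all(diff(q[1:4]) >= 0))
  expect_true(all(q >= 0 & q <= 1))
  # differentiation: nothing can cross a zero threshold
  sqd <- density_sequence(0.4, 6, dfe, "differentiation", m_max = 3,
                          n_grid = 2048, lam0 = 0.2)
  expect_equal(crossing_probability(sqd$densities, 0), rep(0, 3))
})

test_that("tumour probability aggregation: limits and linearity", {
  counts <- mutation_count_distribution(1e-5, 1000, C = 1e5)
  m_cap <- max(counts$m)
  expect_equal(tumor_probability(counts, rep(0, m_cap)), 0)
  # constant q: only the first fixation contributes an increment, so the
  # incremental mode counts crypts whose single fixation did the crossing
  q <- rep(1e-4, m_cap)
  expect_equal(tumor_probability(counts, q),
               counts$n_m[counts$m == 1] * 1e-4)
  # the cumulative mode is the literal weighted sum
  expect_equal(tumor_probability(counts, q, mode = "cumulative"),
               sum(counts$n_m[counts$m >= 1] * q))
  # doubling the crypt count doubles the probability below the cap
  counts2 <- mutation_count_distribution(1e-5, 1000, C = 2e5)
  expect_equal(tumor_probability(counts2, q), 2 * tumor_probability(counts, q))
  # capping warns
  expect_warning(p <- tumor_probability(counts, rep(0.5, m_cap)), "capped")
  expect_equal(p, 1)
})

test_that("division-target scan has an interior tumour-risk minimum", {
  sc <- niche_size_scan(4:10, lam0 = 0.2, dfe = yeast(),
                        lifetime_days = 1095, target = "division",
                        n_grid = 2048)
  argmin <- attr(sc, "argmin_niche")
  expect_gt(sc$p_tumor[1], min(sc$p_tumor))
  expect_gt(sc$p_tumor[nrow(sc)], min(sc$p_tumor))
  expect_true(argmin > 4 && argmin < 10)
  # attrition from drift worsens as niches shrink
  expect_true(all(diff(abs(sc$attrition)) < 0))
})

test_that("differentiation-target scan: risk falls with niche size, attrition invariant", {
  sc <- niche_size_scan(c(3, 6, 12, 20), lam0 = 0.2, dfe = yeast(),
                        lifetime_days = 1095, target = "differentiation",
                        n_grid = 2048)
  expect_true(all(diff(sc$p_tumor) < 0))
  expect_lt(diff(range(sc$attrition)), 1e-10 * abs(mean(sc$attrition)))
})

test_that("normalized scan outputs are invariant to the output scale", {
  a <- niche_size_scan(c(5, 6, 7), lam0 = 0.2, dfe = yeast(),
                       lifetime_days = 1095, target = "division",
                       n_grid = 2048, c_ref = 1)
  b <- niche_size_scan(c(5, 6, 7), lam0 = 0.2, dfe = yeast(),
                       lifetime_days = 1095, target = "division",
                       n_grid = 2048, c_ref = 1e6)
  expect_identical(attr(a, "argmin_niche"), attr(b, "argmin_niche"))
  expect_equal(a$attrition, b$attrition)
  expect_equal(b$p_tumor, 1e6 * a$p_tumor, tolerance = 1e-12)
})

test_that("human scenarios carry more tumour risk and attrition than mouse", {
  sizes <- c(4, 6, 10)
  mouse <- niche_size_scan(sizes, lam0 = 0.2, dfe = yeast(),
                           lifetime_days = 1095, target = "division",
                           n_grid = 2048, c_ref = 1e6, x1_ref = 6)
  human <- niche_size_scan(sizes, lam0 = 1 / 7, dfe = yeast(),
                           lifetime_days = 27375, target = "division",
                           n_grid = 2048, c_ref = 1e7, x1_ref = 6)
  expect_true(all(human$p_tumor > mouse$p_tumor))
  expect_true(all(abs(human$attrition) > abs(mouse$attrition)))
})
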