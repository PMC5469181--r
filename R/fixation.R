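#' Moran-ring fixation probability of a mutant stem-cell lineage
#'
#' Probability that a single mutant with relative division rate `r` (mutant
#' rate over resident rate) takes over a niche of `X1` cells competing by
#' symmetric division on a one-dimensional ring:
#' `pfix(r) = (1 - 1/r) / (1 - r^(-X1))`, with the neutral limit `1/X1` at
#' `r = 1`. The formula suffers catastrophic cancellation near `r = 1`, so
#' values with `|r - 1| < 1e-8` are mapped to the neutral limit.
#'
#' Mutations that do not change the division rate (e.g. mutations to the
#' differentiation rate, a phenotype not expressed inside the niche) fix
#' neutrally: callers should use the constant `1/X1` for those.
#'
#' @param r relative division rate(s), `> 0`.
#' @param X1 niche size (cells, `>= 1`).
#' @return Fixation probabilities in `(0, 1]`.
#' @examples
#' fixation_probability(1, 6)    # neutral: 1/6
#' fixation_probability(2, 2)    # 2/3
#' @export
fixation_probability <- function(r, X1) {
  if (any(r <= 0)) stop("relative rate r must be positive")
  stopifnot(X1 >= 1)
  out <- rep(1 / X1, length(r))
  sel <- abs(r - 1) >= 1e-8
  out[sel] <- (1 - 1 / r[sel]) / (1 - r[sel]^(-X1))
  out
}

#' Fixation summary: total fixation probability and expected fixed effect
#'
#' Adaptive-quadrature summary of the first fixation in a niche:
#' `p_hat`, the total probability that a new fitness-affecting mutant
#' lineage fixes (the normalizer of the post-fixation posterior);
#' `expected_ratio`, the expected rate ratio after one fixed mutation
#' (`r_lambda` or `r_nu`); and `mu_hat = p_hat * mu * lam0 * X1`, the rate
#' at which fixed-lineage sweeps arrive in a crypt. For the neutral
#' differentiation target `p_hat = 1/X1` exactly and the posterior equals
#' the prior DFE.
#'
#' @param X1 niche size (cells).
#' @param dfe a [dfe_parameters()] object.
#' @param target `"division"` or `"differentiation"`.
#' @param lam0 baseline niche division rate (per day), used for `mu_hat`.
#' @param renormalize renormalize the truncated DFE (see [dfe_density()])?
#' @return Object of class `fixation_summary`: list with `p_hat`, `mu_hat`,
#'   `expected_ratio`, plus the configuration.
#' @export
fixation_summary <- function(X1, dfe, target = c("division", "differentiation"),
                             lam0 = 1, renormalize = TRUE) {
  target <- match.arg(target)
  if (target == "differentiation") {
    p_hat <- 1 / X1
    er <- dfe_mean_ratio(dfe, "differentiation", renormalize = TRUE)
  } else {
    # integrate each branch on its own exponential scale (u = effect/scale),
    # so the quadrature stays well-conditioned for arbitrarily small effects
    del_norm <- if (renormalize) 1 - exp(-dfe$beta) else 1
    quad <- function(g) {
      del <- integrate(function(u) {
        r <- 1 - u * dfe$s_minus
        g(r) * exp(-u) * (1 - dfe$P_B) / del_norm
      }, 0, min(dfe$beta, 60), rel.tol = 1e-11, abs.tol = 0)$value
      ben <- integrate(function(u) {
        r <- 1 + u * dfe$s_plus
        g(r) * exp(-u) * dfe$P_B
      }, 0, Inf, rel.tol = 1e-11, abs.tol = 0)$value
      del + ben
    }
    p_hat <- quad(function(r) fixation_probability(r, X1))
    er <- quad(function(r) r * fixation_probability(r, X1)) / p_hat
  }
  structure(list(p_hat = p_hat, mu_hat = p_hat * dfe$mu * lam0 * X1,
                 expected_ratio = er, X1 = X1, target = target,
                 lam0 = lam0, dfe = dfe),
            class = "fixation_summary")
}

#' @export
print.fixation_summary <- function(x, ...) {
  cat(sprintf(
    "Fixation summary (%s, X1 = %d): p_hat = %.5g, E[ratio] = %.5g, mu_hat = %.4g /crypt/day\n",
    x$target, x$X1, x$p_hat, x$expected_ratio, x$mu_hat))
  invisible(x)
}

# Rate grid with the baseline r0 exactly on a node (the DFE has its branch
# junction there, and the recursion kernel its diagonal kink). The rate
# after successive fixations is a product of relative effects, so both
# targets use a log-spaced grid: its relative resolution is constant across
# the multiplicative drift, and every kernel column (posterior width
# proportional to its baseline) is equally resolved. Spans are sized so the
# density mass beyond the grid stays below `tail_eps`, with headroom for
# `m_max` successive fixations; the division lower edge uses the r^(X1-1)
# suppression of the fixation probability near rate zero.
rate_grid <- function(r0, dfe, target, m_max = 1, n = 4096,
                      extend_to = NULL, tail_eps = 1e-12, X1 = 2) {
  stopifnot(r0 > 0, n >= 64)
  span <- log(1 / tail_eps)
  m_max <- max(1, m_max)
  if (target == "division") {
    # escape-limited lower edge: posterior mass below lo ~ g(0) lo^X1 / X1,
    # kept an order below the per-iteration escape tolerance; the bulk
    # (drifting down by roughly 10% per fixation) must stay resolved too
    g0 <- (1 - dfe$P_B) * dfe$beta * exp(-dfe$beta) / (1 - exp(-dfe$beta))
    lo_escape <- (1e-10 * X1 / max(g0, 1e-12))^(1 / X1)
    lo_log <- log(max(1e-9, lo_escape * (1 - dfe$s_minus)^m_max))
    # compound beneficial jumps (fixation-weighted) set the upper tail;
    # equal-split headroom over m fixations, as for the deleterious case
    hi_log <- m_max * log1p(dfe$s_plus * (span + 9) / m_max)
    if (!is.null(extend_to))
      hi_log <- max(hi_log, log(extend_to / r0) + log1p(dfe$s_plus * span))
  } else {
    lo_log <- log(0.04)                 # truncated beneficial tail below this
    # upper tail of m multiplied deleterious factors is equal-split
    # dominated: mass beyond m*log1p(s*y/m) is ~exp(-beta*s*y) = tail_eps
    hi_log <- m_max * log1p(dfe$s_minus) +
      m_max * log1p(dfe$s_minus * (span + 9) / m_max)
    if (!is.null(extend_to))
      hi_log <- max(hi_log, log(extend_to / r0) + log1p(dfe$s_minus * span))
  }
  d <- (hi_log - lo_log) / (n - 1)
  u <- d * seq.int(-ceiling(-lo_log / d), ceiling(hi_log / d))
  x <- r0 * exp(u)
  dx <- diff(x)
  w <- c(dx[1] / 2, (dx[-1] + dx[-length(dx)]) / 2, dx[length(dx)] / 2)
  structure(list(x = x, w = w, r0 = r0, target = target), class = "rate_grid")
}

new_rate_density <- function(grid, density, m, escaped = 0) {
  structure(list(target = grid$target, r0 = grid$r0, grid = grid$x,
                 w = grid$w, density = density, m = m, escaped = escaped),
            class = "rate_density")
}

#' @export
print.rate_density <- function(x, ...) {
  cat(sprintf(
    "Rate density after m = %d fixed %s-rate mutation(s); baseline %.4g, grid [%.3g, %.3g] x %d\n",
    x$m, x$target, x$r0, x$grid[1], x$grid[length(x$grid)], length(x$grid)))
  cat(sprintf("  mean rate = %.5g, escaped mass = %.2g\n",
              density_mean(x), x$escaped))
  invisible(x)
}

#' Moments and mass of a discretized rate density
#'
#' @param f a `rate_density` object.
#' @return `density_mean()`: the expected rate (per day);
#'   `density_mass()`: the total probability mass on the grid.
#' @export
density_mean <- function(f) sum(f$grid * f$density * f$w)

#' @rdname density_mean
#' @export
density_mass <- function(f) sum(f$density * f$w)

#' Posterior density of the rate after one fixed mutation
#'
#' Bayes posterior of the mutated rate given that the lineage fixed:
#' the DFE prior weighted by the fixation probability and normalized,
#' `Phi(rate | r0) = pfix * m(rate; r0) / p_hat`. For the neutral
#' differentiation target the constant `1/X1` cancels and the posterior
#' equals the prior DFE (as it does for `X1 = 1` in the division case).
#'
#' @param r0 baseline rate (per day) of the mutated parameter.
#' @param X1 niche size (cells).
#' @param dfe a [dfe_parameters()] object.
#' @param target `"division"` or `"differentiation"`.
#' @param grid optional `rate_grid`; built automatically otherwise.
#' @param n_grid grid size when `grid` is `NULL`.
#' @param m_max anticipated number of kernel iterations (sizes the grid
#'   span for the differentiation target, whose deleterious tail drifts up).
#' @param extend_to extend the grid at least this far (per day), e.g. to
#'   cover a tumorigenesis threshold.
#' @param lam0 baseline division rate for the `mu_hat` bookkeeping
#'   (defaults to `r0`; pass the division rate when `target` is
#'   `"differentiation"`).
#' @param renormalize renormalize the truncated DFE?
#' @return List with `density` (a `rate_density`, `m = 1`) and `summary`
#'   (a [fixation_summary()]).
#' @export
posterior_fixed_density <- function(r0, X1, dfe,
                                    target = c("division", "differentiation"),
                                    grid = NULL, n_grid = 4096, m_max = 1,
                                    extend_to = NULL, lam0 = r0,
                                    renormalize = TRUE) {
  target <- match.arg(target)
  if (is.null(grid))
    grid <- rate_grid(r0, dfe, target, m_max = m_max, n = n_grid,
                      extend_to = extend_to, X1 = X1)
  stopifnot(inherits(grid, "rate_grid"), grid$target == target)
  smry <- fixation_summary(X1, dfe, target, lam0 = lam0,
                           renormalize = renormalize)
  rel <- grid$x / r0
  dens <- dfe_relative_density(rel, dfe, target, renormalize) / r0
  if (target == "division") dens <- dens * fixation_probability(rel, X1)
  mass <- sum(dens * grid$w)
  # prior mass outside the grid (closed forms for the exponential
  # branches); must be negligible or the grid span is too short
  hi_rel <- grid$x[length(grid$x)] / r0
  lo_rel <- grid$x[1] / r0
  escaped <- if (target == "division") {
    g0 <- (1 - dfe$P_B) * dfe$beta * exp(-dfe$beta) / (1 - exp(-dfe$beta))
    dfe$P_B * exp(-dfe$alpha * (hi_rel - 1)) / smry$p_hat +
      g0 * lo_rel^X1 / (X1 * smry$p_hat)
  } else {
    (1 - dfe$P_B) * exp(-dfe$beta * (hi_rel - 1)) +
      dfe$P_B * (exp(-dfe$alpha * (1 - lo_rel)) - exp(-dfe$alpha)) /
        (1 - exp(-dfe$alpha))
  }
  if (escaped > 1e-8)
    stop(sprintf("prior tail mass %.2g beyond the grid; extend the grid",
                 escaped))
  # discrete mass against the analytic normalizer: a gross mismatch means
  # the grid is too coarse for the DFE scales
  expected_mass <- if (target == "division") smry$p_hat
    else if (renormalize) 1 else dfe_support_mass(dfe, target)
  qerr <- abs(mass - expected_mass) / expected_mass
  if (qerr > 2e-3)
    stop(sprintf(
      "discrete posterior mass off by %.2g relative to quadrature; refine the grid",
      qerr))
  f <- new_rate_density(grid, dens / mass, m = 1, escaped = escaped)
  list(density = f, summary = smry)
}

#' Discrete fixation kernel for the recursion over successive mutations
#'
#' Dense matrix realization of the transition kernel
#' `f_{n+1}(rate) = int Phi(rate | baseline) f_n(baseline) d baseline` on a
#' fixed rate grid. Because the posterior is a normalized density at every
#' baseline, each column of the discrete kernel is normalized to unit
#' trapezoid mass; the recursion therefore conserves probability to machine
#' precision by construction.
#'
#' @inheritParams posterior_fixed_density
#' @param grid a `rate_grid` (shared by all densities in the recursion).
#' @return Object of class `fixation_kernel`.
#' @export
fixation_kernel <- function(grid, X1, dfe,
                            target = c("division", "differentiation"),
                            renormalize = TRUE) {
  target <- match.arg(target)
  stopifnot(inherits(grid, "rate_grid"), grid$target == target)
  x <- grid$x
  n <- length(x)
  ratio <- outer(x, 1 / x)                       # rate over baseline
  K <- dfe_relative_density(ratio, dfe, target, renormalize)
  if (target == "division")
    K <- K * fixation_probability(ratio, X1)
  K <- K * rep(1 / x, each = n)                  # 1/baseline Jacobian
  colmass <- .colSums(K * grid$w, n, n)
  K <- K / rep(colmass, each = n)
  structure(list(K = K, grid = grid, X1 = X1, target = target,
                 colmass_range = range(colmass)),
            class = "fixation_kernel")
}

#' One step of the fixed-mutation recursion
#'
#' Applies the fixation kernel to the density after `m` fixed mutations,
#' giving the density after `m + 1`. Mass escaping past the upper grid edge
#' is monitored: if the top 1% of the grid ever carries more than 1e-8 of
#' the mass, the grid is too short for the requested number of iterations
#' and an error asks for an extended grid.
#'
#' @param f a `rate_density`.
#' @param kernel a [fixation_kernel()] on the same grid.
#' @return A `rate_density` with `m` incremented.
#' @export
iterate_density <- function(f, kernel) {
  stopifnot(inherits(f, "rate_density"), inherits(kernel, "fixation_kernel"),
            identical(f$grid, kernel$grid$x))
  g <- as.vector(kernel$K %*% (f$density * f$w))
  mass <- sum(g * f$w)
  n <- length(g)
  edge <- max(2L, ceiling(0.01 * n))
  hi_mass <- sum((g * f$w)[(n - edge + 1L):n])
  lo_mass <- sum((g * f$w)[1:edge])
  if (hi_mass > 1e-8 || lo_mass > 1e-8)
    stop(sprintf(
      "density mass (%.2g low, %.2g high) reached the grid edge after m = %d; rebuild with a larger m_max/extend_to",
      lo_mass, hi_mass, f$m + 1L))
  new_rate_density(kernel$grid, g / mass, m = f$m + 1L,
                   escaped = f$escaped + abs(1 - mass))
}

#' Densities of the rate after 1..m_max fixed mutations
#'
#' Convenience driver: builds the grid and kernel once, starts from the
#' one-fixation posterior, and iterates the recursion.
#'
#' @inheritParams posterior_fixed_density
#' @param m_max number of fixations.
#' @return List with `densities` (list of `rate_density`, `m = 1..m_max`),
#'   `summary`, `kernel`.
#' @export
density_sequence <- function(r0, X1, dfe,
                             target = c("division", "differentiation"),
                             m_max, n_grid = 4096, extend_to = NULL,
                             lam0 = r0, renormalize = TRUE) {
  target <- match.arg(target)
  grid <- rate_grid(r0, dfe, target, m_max = m_max, n = n_grid,
                    extend_to = extend_to, X1 = X1)
  post <- posterior_fixed_density(r0, X1, dfe, target, grid = grid,
                                  lam0 = lam0, renormalize = renormalize)
  out <- vector("list", m_max)
  out[[1]] <- post$density
  if (m_max > 1) {
    kern <- fixation_kernel(grid, X1, dfe, target, renormalize)
    for (m in 2:m_max) out[[m]] <- iterate_density(out[[m - 1]], kern)
  } else kern <- NULL
  list(densities = out, summary = post$summary, kernel = kern)
}

#' Boundary of the DFE parameter space where fixed mutations break even
#'
#' For each combination of niche size `X1`, beneficial scale `s_plus`, and
#' beneficial probability `P_B`, finds the mean deleterious effect
#' `s_minus` at which the expected division-rate ratio after one fixed
#' mutation equals 1 — the line separating regimes where fixed mutations
#' are expected to be beneficial (above) or deleterious (below). Because
#' at large niche sizes strong selection filters out large-effect
#' deleterious mutations, the expected ratio is not monotone in `s_minus`
#' and more than one root can exist; the smallest root (the onset of the
#' deleterious regime) is returned along with the number of sign changes
#' found, and combinations with no sign change are reported as always
#' beneficial or always deleterious.
#'
#' @param X1 vector of niche sizes.
#' @param s_plus vector of beneficial effect scales.
#' @param P_B vector of beneficial probabilities.
#' @param interval bracket searched for the `s_minus` root.
#' @param mu mutation rate used to build the scratch DFEs (does not affect
#'   the boundary).
#' @return Data frame over the parameter grid with columns `X1`, `s_plus`,
#'   `P_B`, `s_minus_boundary` (NA when no root), `n_roots`, and `regime`.
#' @export
expected_effect_boundary <- function(X1, s_plus, P_B,
                                     interval = c(1e-3, 2), mu = 1e-4) {
  grid <- expand.grid(X1 = X1, s_plus = s_plus, P_B = P_B,
                      KEEP.OUT.ATTRS = FALSE)
  ratio_at <- function(sm, X1, sp, pb)
    fixation_summary(X1, dfe_parameters(mu, sm, sp, pb),
                     "division")$expected_ratio - 1
  res <- lapply(seq_len(nrow(grid)), function(i) {
    X <- grid$X1[i]; sp <- grid$s_plus[i]; pb <- grid$P_B[i]
    # the expected ratio can dip below 1 and rise again (strong selection
    # filters large-effect deleterious mutations), so scan for sign changes
    sm <- exp(seq(log(interval[1]), log(interval[2]), length.out = 41))
    vals <- vapply(sm, ratio_at, numeric(1), X1 = X, sp = sp, pb = pb)
    flips <- which(vals[-1] * vals[-length(vals)] < 0)
    if (length(flips) == 0) {
      return(list(s_minus_boundary = NA_real_, n_roots = 0L,
                  regime = if (vals[1] > 0) "always_beneficial"
                           else "always_deleterious"))
    }
    root <- uniroot(ratio_at, c(sm[flips[1]], sm[flips[1] + 1]),
                    X1 = X, sp = sp, pb = pb, tol = 1e-10)$root
    list(s_minus_boundary = root, n_roots = length(flips),
         regime = "boundary")
  })
  grid$s_minus_boundary <- vapply(res, `[[`, numeric(1), "s_minus_boundary")
  grid$n_roots <- vapply(res, `[[`, integer(1), "n_roots")
  grid$regime <- vapply(res, `[[`, character(1), "regime")
  grid
}
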