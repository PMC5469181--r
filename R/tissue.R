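#' Organism-scale scenario configuration
#'
#' Ties one crypt parameterization and a DFE to an organism: which rate
#' mutations act on, the adult lifetime, and the number of crypts in the
#' tissue. `n_crypts` only scales absolute quantities (crypt counts, tumour
#' probabilities); all attrition fractions are invariant to it.
#'
#' @param crypt a [crypt_parameters()] object.
#' @param dfe a [dfe_parameters()] object.
#' @param target which rate mutations perturb: `"division"` or
#'   `"differentiation"`.
#' @param lifetime_days adult lifetime (days).
#' @param n_crypts number of crypts in the tissue.
#' @param m_cap optional cap on the number of fixed mutations tracked;
#'   defaults to the smallest count with Poisson tail mass below 1e-10 at
#'   the end of life.
#' @return Object of class `tissue_scenario`.
#' @export
tissue_scenario <- function(crypt, dfe, target = c("division", "differentiation"),
                            lifetime_days, n_crypts = 1, m_cap = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(crypt, "crypt_parameters"), inherits(dfe, "dfe_parameters"),
            lifetime_days > 0, n_crypts > 0)
  structure(list(crypt = crypt, dfe = dfe, target = target,
                 lifetime_days = lifetime_days, n_crypts = n_crypts,
                 m_cap = m_cap),
            class = "tissue_scenario")
}

#' Expected number of crypts carrying m fixed mutations
#'
#' Fixed-lineage sweeps arrive in each crypt as a Poisson process with rate
#' `mu_hat`, so at time `t` the number of crypts with `m` fixed mutations is
#' `n_m = C * exp(-mu_hat t) (mu_hat t)^m / m!`.
#'
#' @param mu_hat fixed-lineage arrival rate (per crypt per day).
#' @param t time since adulthood (days).
#' @param C number of crypts.
#' @param m_cap largest `m` reported; defaults to the smallest value whose
#'   Poisson upper-tail mass is below `tail_tol`. Supplying a cap that
#'   leaves more than `tail_tol` of mass in the tail is an error.
#' @param tail_tol tail-mass tolerance.
#' @return Data frame with columns `m` (0..m_cap) and `n_m`.
#' @export
mutation_count_distribution <- function(mu_hat, t, C = 1, m_cap = NULL,
                                        tail_tol = 1e-10) {
  stopifnot(mu_hat >= 0, t >= 0, C > 0)
  lambda <- mu_hat * t
  if (is.null(m_cap)) {
    m_cap <- if (lambda == 0) 1L else
      max(1L, qpois(tail_tol, lambda, lower.tail = FALSE))
  } else if (ppois(m_cap, lambda, lower.tail = FALSE) > tail_tol) {
    stop("m_cap leaves more than tail_tol of Poisson mass in the tail")
  }
  data.frame(m = 0:m_cap, n_m = C * dpois(0:m_cap, lambda))
}

# Steady-state Z ratio of a crypt whose mutated rate is `rate`, relative to
# the unmutated crypt; errors past the tumorigenesis threshold.
z_ratio_at <- function(rate, crypt, target) {
  if (target == "division") {
    if (any(rate >= crypt$nu))
      stop("expected division rate crossed nu: crypt no longer homeostatic; ",
           "tumorigenesis must be handled with crossing_probability()/",
           "tumor_probability()")
    population_ratio(crypt$lam, rate, crypt$nu)
  } else {
    if (any(rate <= crypt$lam))
      stop("expected differentiation rate crossed lam: crypt no longer ",
           "homeostatic; see crossing_probability()/tumor_probability()")
    population_ratio_diff(crypt$nu, rate, crypt$lam)
  }
}

#' Expected whole-epithelium attrition curve
#'
#' Expected postmitotic population over the time since adulthood:
#' `Z*(t) = Z_Total* - sum_m n_m(t) (Z_Normal* - Z_m*)`, reported as the
#' fraction `Z*(t)/Z_Total*`. By default (`mode = "expected_rate"`) each
#' `Z_m*` is the steady state evaluated at the *expected* mutated rate
#' after `m` fixations; the posterior relative effect is scale-free, so
#' that expectation is exactly `r0 * expected_ratio^m`. The alternative
#' `mode = "expected_z"` averages the steady-state pool over the full rate
#' density `f_m` (restricted to the homeostatic region, i.e. conditioning
#' on crypts that have not crossed the tumorigenesis threshold); the
#' difference between the two is a Jensen gap, since the steady state is a
#' convex function of the rate.
#'
#' @param scn a [tissue_scenario()].
#' @param t_grid times (days); defaults to 201 points over the lifetime.
#' @param mode `"expected_rate"` (default) or `"expected_z"`.
#' @param n_grid grid size for the density recursion (`"expected_z"` only).
#' @return Object of class `attrition_curve`: data frame with columns
#'   `time` and `fraction`, with attributes `slope_linear` (the linear
#'   approximation slope, per day) and `summary`.
#' @export
tissue_trajectory <- function(scn, t_grid = NULL,
                              mode = c("expected_rate", "expected_z"),
                              n_grid = 4096) {
  mode <- match.arg(mode)
  stopifnot(inherits(scn, "tissue_scenario"))
  crypt <- scn$crypt
  if (!crypt$homeostatic) stop("scenario crypt is non-homeostatic")
  if (is.null(t_grid)) t_grid <- seq(0, scn$lifetime_days, length.out = 201)
  r0 <- if (scn$target == "division") crypt$lam else crypt$nu
  smry <- fixation_summary(crypt$X1, scn$dfe, scn$target, lam0 = crypt$lam)
  lambda_end <- smry$mu_hat * scn$lifetime_days
  m_cap <- scn$m_cap
  if (is.null(m_cap))
    m_cap <- max(1L, qpois(1e-10, lambda_end, lower.tail = FALSE))
  if (mode == "expected_rate") {
    rates_m <- r0 * smry$expected_ratio^(1:m_cap)
    zr <- z_ratio_at(rates_m, crypt, scn$target)
  } else {
    seqs <- density_sequence(r0, crypt$X1, scn$dfe, scn$target,
                             m_max = m_cap, n_grid = n_grid,
                             lam0 = crypt$lam)
    thr <- if (scn$target == "division") crypt$nu else crypt$lam
    zr <- vapply(seqs$densities, function(f) {
      ok <- if (scn$target == "division") f$grid < thr else f$grid > thr
      wts <- (f$density * f$w)[ok]
      sum(z_ratio_at(f$grid[ok], crypt, scn$target) * wts) / sum(wts)
    }, numeric(1))
  }
  frac <- vapply(t_grid, function(t)
    1 - sum(dpois(1:m_cap, smry$mu_hat * t) * (1 - zr)), numeric(1))
  structure(data.frame(time = t_grid, fraction = frac),
            slope_linear = linear_slope(scn, smry),
            summary = smry, m_cap = m_cap,
            class = c("attrition_curve", "data.frame"))
}

#' Linear approximation slope of the attrition curve
#'
#' First-order (in time and in mutation count) rate of change of the
#' normalized postmitotic population, with `theta = nu/lam0`:
#' division target, `-theta * lam0 * mu * p_hat * X1 * (r - 1)/(r - theta)`;
#' differentiation target, `-mu * lam0 * (r - 1)/(theta r - 1)`. The
#' differentiation slope contains neither `X1` nor `p_hat`: mutations fix
#' neutrally, and the niche's fixation probability (`1/X1`) and its mutation
#' supply (`mu lam0 X1`) are inverses of one another. Because the slope does
#' not involve the TA or postmitotic rates, it extends the model to
#' organisms (humans) where those are unmeasured.
#'
#' @param scn a [tissue_scenario()].
#' @param summary optional precomputed [fixation_summary()].
#' @return Slope of `Z*(t)/Z_Total*` (per day; negative when the expected
#'   fixed effect is deleterious).
#' @export
linear_slope <- function(scn, summary = NULL) {
  stopifnot(inherits(scn, "tissue_scenario"))
  crypt <- scn$crypt
  if (is.null(summary))
    summary <- fixation_summary(crypt$X1, scn$dfe, scn$target,
                                lam0 = crypt$lam)
  theta <- crypt$nu / crypt$lam
  r <- summary$expected_ratio
  mu <- scn$dfe$mu
  if (scn$target == "division") {
    if (r >= theta)
      stop("expected division ratio at or past theta = nu/lam: tumorigenic mean")
    -theta * crypt$lam * mu * summary$p_hat * crypt$X1 * (r - 1) / (r - theta)
  } else {
    if (theta * r <= 1)
      stop("expected differentiation ratio at or below lam/nu: tumorigenic mean")
    -mu * crypt$lam * (r - 1) / (theta * r - 1)
  }
}

#' Human colon attrition scenarios
#'
#' The four human end-of-life projections: niche sizes 6 and 20 (of 36
#' putative stem cells per crypt, dividing weekly) crossed with mutations to
#' the division or differentiation rate, evaluated with the linear slope
#' over 75 adult years. TA and postmitotic rates are unmeasured in humans;
#' the linear slope does not involve them.
#'
#' @param dfe a [dfe_parameters()] object; defaults to [dfe_yeast()].
#' @param lifetime_days adult lifetime (days), default 75 years.
#' @param lam stem-cell division rate (per day), default once per week.
#' @param total_stem putative stem cells per crypt.
#' @param niches niche sizes to evaluate.
#' @return Data frame with one row per (niche, target): `nu`, `p_hat`,
#'   `expected_ratio`, `slope_per_day`, and `decline_pct` (percent decline
#'   at the end of life).
#' @export
human_scenarios <- function(dfe = dfe_yeast(), lifetime_days = 27375,
                            lam = 1 / 7, total_stem = 36,
                            niches = c(6, 20)) {
  rows <- expand.grid(X1 = niches, target = c("division", "differentiation"),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    X1 <- rows$X1[i]; target <- rows$target[i]
    nu <- commitment_rate(lam, X1, total_stem)
    crypt <- crypt_parameters(X1, lam, nu, gamma = 2, delta = 1 / 3, R = 6)
    scn <- tissue_scenario(crypt, dfe, target, lifetime_days)
    smry <- fixation_summary(X1, dfe, target, lam0 = lam)
    slope <- linear_slope(scn, smry)
    data.frame(X1 = X1, target = target, nu = nu, p_hat = smry$p_hat,
               expected_ratio = smry$expected_ratio, slope_per_day = slope,
               decline_pct = -slope * lifetime_days * 100)
  })
  do.call(rbind, res)
}
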