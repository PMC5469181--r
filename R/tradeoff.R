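#' Probability that the rate density has crossed the tumorigenesis threshold
#'
#' Tumorigenesis is the inversion of the homeostatic rate ordering: the
#' niche division rate exceeding the differentiation rate. For mutations to
#' the division rate the crossing mass is the integral of the rate density
#' from `nu` to infinity; for differentiation-rate mutations it is the mass
#' from 0 up to `lam`. The threshold cell is split by linear interpolation
#' of the density.
#'
#' @param densities a `rate_density` or list of them (a recursion sequence
#'   on a shared grid).
#' @param threshold the opposing rate (per day): `nu` for the division
#'   target, `lam` for differentiation.
#' @return Vector `q_m` of crossing probabilities, one per density.
#' @export
crossing_probability <- function(densities, threshold) {
  if (inherits(densities, "rate_density")) densities <- list(densities)
  stopifnot(length(densities) > 0, threshold >= 0)
  target <- densities[[1]]$target
  x <- densities[[1]]$grid
  n <- length(x)
  if (target == "division" && threshold > x[n])
    stop("threshold beyond the grid: rebuild densities with extend_to = threshold")
  dx <- diff(x)
  vapply(densities, function(f) {
    stopifnot(identical(f$grid, x))
    d <- f$density
    # segmentwise trapezoid mass above the threshold, splitting the
    # threshold's segment by linear interpolation of the density
    mass_above <- function(thr) {
      if (thr <= x[1])
        return(density_mass(f))
      if (thr >= x[n]) return(0)
      j <- min(which(x > thr))              # first node past the threshold
      fthr <- d[j - 1] + (d[j] - d[j - 1]) * (thr - x[j - 1]) / dx[j - 1]
      partial <- (x[j] - thr) * (fthr + d[j]) / 2
      full <- if (j < n) sum(dx[j:(n - 1)] * (d[j:(n - 1)] + d[(j + 1):n]) / 2)
              else 0
      partial + full
    }
    if (target == "division") mass_above(threshold)
    else density_mass(f) - mass_above(threshold)
  }, numeric(1))
}

#' Total probability of tumorigenesis in a tissue
#'
#' Aggregates per-mutation crossing probabilities over all crypts. The
#' default `"incremental"` mode attributes to the m-th fixation the
#' increment `dq_m = q_m - q_{m-1}` (a crypt already past the threshold is
#' not counted again; increments are floored at zero since a crossed crypt
#' stays tumorigenic) and sums `n_m(t) * dq_m`; the `"cumulative"` mode is
#' the literal sum `n_m(t) * q_m`. The result is capped at 1; a sum above 1
#' (outside the validity of the linear aggregation) triggers a warning.
#'
#' @param counts data frame from [mutation_count_distribution()]
#'   (columns `m`, `n_m`, starting at `m = 0`).
#' @param q crossing probabilities `q_m` for `m = 1..m_cap`, from
#'   [crossing_probability()].
#' @param mode `"incremental"` or `"cumulative"`.
#' @return Tumorigenesis probability in `[0, 1]`.
#' @export
tumor_probability <- function(counts, q, mode = c("incremental", "cumulative")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(counts), all(c("m", "n_m") %in% names(counts)))
  nm <- counts$n_m[counts$m >= 1][seq_along(q)]
  stopifnot(length(nm) == length(q))
  # a crypt that has crossed the threshold stays tumorigenic: late negative
  # increments (the deleterious ratchet dragging the upper tail back down)
  # are floored at zero rather than subtracted
  P <- if (mode == "incremental") sum(nm * pmax(diff(c(0, q)), 0))
       else sum(nm * q)
  if (P > 1) {
    warning("aggregated tumour probability exceeded 1; capped (sum ",
            "approximation outside its validity)")
    P <- 1
  }
  P
}

#' Niche-size scan of the aging/tumorigenesis trade-off
#'
#' Varies the stem-cell niche size `X1` at constant total tissue output:
#' half of the putative stem cells reside in the niche (so the commitment
#' rate is `nu = 2*lam` for every niche size), and the number of crypts
#' scales as `C(X1) = Z_ref_total / Z*(X1)` so that the summed postmitotic
#' output is fixed. For each niche size the full density recursion gives
#' the tumorigenesis probability at the end of life, and the linear slope
#' gives the fractional tissue change. Setting `nu_fixed` replaces the
#' half-in-niche rule with a constant commitment rate.
#'
#' @param niche_range integer niche sizes (each `>= 2`).
#' @param lam0 niche division rate (per day).
#' @param dfe a [dfe_parameters()] object.
#' @param lifetime_days end-of-life time (days).
#' @param target `"division"` or `"differentiation"`.
#' @param gamma,delta,R downstream crypt rates (used only through the
#'   reference output normalization, which they cancel out of).
#' @param c_ref crypt count at the reference niche size `x1_ref`, fixing
#'   the absolute output scale `Z_ref_total = c_ref * Z*(x1_ref)`.
#'   Normalized outputs (`argmin`, attrition) are invariant to it.
#' @param x1_ref reference niche size; defaults to the first of
#'   `niche_range`.
#' @param nu_fixed optional fixed commitment rate overriding `nu = 2*lam`.
#' @param mode aggregation mode for [tumor_probability()].
#' @param n_grid density grid size per niche size.
#' @return Object of class `tradeoff_scan`: data frame with columns `X1`,
#'   `nu`, `p_hat`, `mu_hat`, `n_crypts`, `p_tumor`, `attrition` (fractional
#'   tissue change at end of life, negative for decline), with attribute
#'   `argmin_niche`.
#' @export
niche_size_scan <- function(niche_range = 2:50, lam0, dfe,
                            lifetime_days,
                            target = c("division", "differentiation"),
                            gamma = 2, delta = 1 / 3, R = 6,
                            c_ref = 1, x1_ref = NULL, nu_fixed = NULL,
                            mode = c("incremental", "cumulative"),
                            n_grid = 2048) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  stopifnot(all(niche_range >= 2), all(niche_range == round(niche_range)))
  if (is.null(x1_ref)) x1_ref <- niche_range[1]
  nu_of <- function(X1) if (is.null(nu_fixed)) 2 * lam0 else nu_fixed
  z_star <- function(X1) {
    crypt_steady_state(crypt_parameters(X1, lam0, nu_of(X1), gamma, delta, R))$Z
  }
  z_ref_total <- c_ref * z_star(x1_ref)

  # neutral fixation: the kernel does not involve X1, build it once
  diff_cache <- NULL
  rows <- lapply(niche_range, function(X1) {
    nu <- nu_of(X1)
    if (nu <= lam0) {
      message("X1 = ", X1, ": non-homeostatic derived parameters, excluded")
      return(NULL)
    }
    crypt <- crypt_parameters(X1, lam0, nu, gamma, delta, R)
    smry <- fixation_summary(X1, dfe, target, lam0 = lam0)
    C <- z_ref_total / z_star(X1)
    m_cap <- max(2L, qpois(1e-12, smry$mu_hat * lifetime_days,
                           lower.tail = FALSE))
    r0 <- if (target == "division") lam0 else nu
    thr <- if (target == "division") nu else lam0
    if (target == "differentiation") {
      # neutral kernel is X1-free: build once, on a finer grid (its
      # deleterious tail drifts upward, widening the span)
      if (is.null(diff_cache) || length(diff_cache$densities) < m_cap)
        diff_cache <<- density_sequence(r0, X1, dfe, target, m_max = m_cap,
                                        n_grid = 2L * n_grid, lam0 = lam0)
      dens <- diff_cache$densities[1:m_cap]
    } else {
      dens <- density_sequence(r0, X1, dfe, target, m_max = m_cap,
                               n_grid = n_grid, extend_to = thr,
                               lam0 = lam0)$densities
    }
    q <- crossing_probability(dens, thr)
    counts <- mutation_count_distribution(smry$mu_hat, lifetime_days, C,
                                          m_cap = m_cap, tail_tol = 1e-10)
    p_tumor <- tumor_probability(counts, q, mode)
    scn <- tissue_scenario(crypt, dfe, target, lifetime_days)
    attr_frac <- linear_slope(scn, smry) * lifetime_days
    data.frame(X1 = X1, nu = nu, p_hat = smry$p_hat, mu_hat = smry$mu_hat,
               n_crypts = C, p_tumor = p_tumor, attrition = attr_frac)
  })
  out <- do.call(rbind, rows)
  structure(out, argmin_niche = out$X1[which.min(out$p_tumor)],
            class = c("tradeoff_scan", "data.frame"))
}

#' @export
print.tradeoff_scan <- function(x, ...) {
  cat(sprintf("Niche-size trade-off scan over X1 in [%d, %d]\n",
              min(x$X1), max(x$X1)))
  cat(sprintf("  tumorigenesis probability minimized at X1 = %d\n",
              attr(x, "argmin_niche")))
  print.data.frame(x, ...)
  invisible(x)
}
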