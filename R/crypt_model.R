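#' Parameters of one crypt system
#'
#' Bundles the rate constants and population sizes of the compartmental crypt
#' model: a niche of `X1` stem cells dividing symmetrically at rate `lam`,
#' a displaced stem-cell pool committing to differentiation at rate `nu`,
#' `R` rounds of transit-amplifying (TA) division at rate `gamma`, and a
#' postmitotic pool dying at rate `delta`.
#'
#' Homeostasis requires `nu > lam`; the displaced pool (and everything
#' downstream) grows without bound otherwise. A configuration with
#' `nu <= lam` is accepted but flagged non-homeostatic (the model's
#' definition of a tumorigenic crypt), and operations that need a steady
#' state refuse it.
#'
#' @param X1 stem-cell niche size (cells, positive integer).
#' @param lam symmetric division rate of niche and displaced stem cells
#'   (per day).
#' @param nu rate at which displaced stem cells commit to differentiation
#'   (per day).
#' @param gamma TA division rate (per day).
#' @param delta postmitotic death rate (per day).
#' @param R rounds of TA division (positive integer).
#' @return An object of class `crypt_parameters`.
#' @seealso [crypt_steady_state()], [integrate_means()], [commitment_rate()]
#' @examples
#' mouse <- crypt_parameters(X1 = 6, lam = 0.2, nu = 1/3, gamma = 2,
#'                           delta = 1/3, R = 6)
#' crypt_steady_state(mouse)$Z
#' @export
crypt_parameters <- function(X1, lam, nu, gamma, delta, R) {
  stopifnot(length(X1) == 1L, length(lam) == 1L, length(nu) == 1L,
            length(gamma) == 1L, length(delta) == 1L, length(R) == 1L)
  if (!is.finite(X1) || X1 < 1 || X1 != round(X1))
    stop("X1 must be a positive integer")
  if (!is.finite(R) || R < 1 || R != round(R))
    stop("R must be a positive integer")
  if (any(c(lam, nu, gamma, delta) <= 0))
    stop("all rates must be strictly positive")
  p <- structure(
    list(X1 = as.integer(X1), lam = lam, nu = nu, gamma = gamma,
         delta = delta, R = as.integer(R), homeostatic = nu > lam),
    class = "crypt_parameters")
  if (!p$homeostatic)
    warning("nu <= lam: non-homeostatic (tumorigenic) crypt configuration")
  p
}

#' @export
print.crypt_parameters <- function(x, ...) {
  cat("Crypt parameters:\n")
  cat(sprintf("  X1 = %d cells, lam = %.4g/d, nu = %.4g/d, gamma = %.4g/d, delta = %.4g/d, R = %d\n",
              x$X1, x$lam, x$nu, x$gamma, x$delta, x$R))
  cat(sprintf("  homeostatic: %s\n", x$homeostatic))
  invisible(x)
}

#' Commitment-to-differentiation rate that holds the stem-cell pool steady
#'
#' Solves the displaced-pool steady state `lam*X1 + lam*X2 - nu*X2 = 0` for
#' `nu`, where `X2 = total_stem - X1` is the displaced stem-cell pool. This
#' is how the mouse value 0.333/d (total pool of 15 LGR5+ cells, 6-cell
#' niche, `lam` = 0.2/d) and the human colon values 0.172/d and 0.321/d
#' (36 putative stem cells, niche of 6 or 20, weekly division) are derived.
#'
#' @param lam symmetric stem-cell division rate (per day).
#' @param X1 niche size (cells).
#' @param total_stem total putative stem-cell pool `X1 + X2` (cells).
#' @return The commitment rate `nu` (per day); always `> lam`.
#' @examples
#' commitment_rate(0.2, 6, 15)    # mouse small intestine, 1/3 per day
#' commitment_rate(1/7, 20, 36)   # human colon, 20-cell niche
#' @export
commitment_rate <- function(lam, X1, total_stem) {
  stopifnot(lam > 0, X1 >= 1)
  if (total_stem <= X1)
    stop("total_stem must exceed X1: no displaced stem-cell pool")
  lam * total_stem / (total_stem - X1)
}

#' Steady state of the crypt compartment model
#'
#' Closed-form steady-state means of all pools: displaced stem cells
#' `X2 = lam*X1/(nu - lam)`, TA pools `Y_1 = nu*X2/gamma` doubling each
#' round, and the postmitotic pool
#' `Z = 2^R * nu * lam * X1 / (delta * (nu - lam))`. `Z` is computed both
#' from the closed form and from the terminal TA flux `2*gamma*Y_R/delta`;
#' the two must agree to relative 1e-12.
#'
#' @param params a [crypt_parameters()] object.
#' @return An object of class `crypt_steady_state`: list with `X2`, `Y`
#'   (vector of `R` TA pool means), `Y_total`, and `Z` (cells).
#' @examples
#' ss <- crypt_steady_state(crypt_parameters(6, 0.2, 1/3, 2, 1/3, 6))
#' ss$Y       # (1.5, 3, 6, 12, 24, 48)
#' ss$Z       # 576
#' @export
crypt_steady_state <- function(params) {
  stopifnot(inherits(params, "crypt_parameters"))
  if (!params$homeostatic)
    stop("non-homeostatic parameters (nu <= lam): no steady state; ",
         "this configuration is tumorigenic")
  X2 <- params$lam * params$X1 / (params$nu - params$lam)
  Y <- params$nu * X2 / params$gamma * 2^(0:(params$R - 1))
  Z_closed <- 2^params$R * params$nu * params$lam * params$X1 /
    (params$delta * (params$nu - params$lam))
  Z_flux <- 2 * params$gamma * Y[params$R] / params$delta
  if (abs(Z_closed - Z_flux) > 1e-12 * Z_closed)
    stop("internal inconsistency between closed-form and flux steady states")
  structure(list(X2 = X2, Y = Y, Y_total = sum(Y), Z = Z_closed),
            class = "crypt_steady_state")
}

#' @export
print.crypt_steady_state <- function(x, ...) {
  cat("Crypt steady state (cells):\n")
  cat("  X2 =", format(x$X2), "\n")
  cat("  Y  =", paste(format(x$Y), collapse = ", "),
      " (total", format(x$Y_total), ")\n")
  cat("  Z  =", format(x$Z), "\n")
  invisible(x)
}

crypt_derivs <- function(t, y, p) {
  R <- p$R
  x2 <- y[1L]; yR <- y[2L:(R + 1L)]; z <- y[R + 2L]
  dx2 <- p$lam * p$X1 + p$lam * x2 - p$nu * x2
  dy <- numeric(R)
  dy[1L] <- p$nu * x2 - p$gamma * yR[1L]
  if (R > 1L)
    dy[2L:R] <- 2 * p$gamma * yR[1L:(R - 1L)] - p$gamma * yR[2L:R]
  dz <- 2 * p$gamma * yR[R] - p$delta * z
  list(c(dx2, dy, dz))
}

#' Integrate the crypt mean-field equations
#'
#' Numerically solves the ODE system for the time-dependent pool means
#' (displaced stem cells, TA pools, postmitotic pool; `X1` is held fixed),
#' with a stiff-capable integrator at relative tolerance 1e-9 — the TA
#' division rate is an order of magnitude faster than the niche rates, so
#' the system is moderately stiff.
#'
#' @param params a [crypt_parameters()] object.
#' @param init named or unnamed non-negative initial pool sizes in order
#'   `X2, Y1..YR, Z`; defaults to all zero (an empty crypt filling up).
#' @param t_grid increasing vector of times (days).
#' @return A data frame with columns `time`, `X2`, `Y1`..`YR`, `Z`.
#' @examples
#' p <- crypt_parameters(6, 0.2, 1/3, 2, 1/3, 6)
#' tail(integrate_means(p, t_grid = seq(0, 200, by = 5)), 1)  # approaches Z* = 576
#' @export
integrate_means <- function(params, init = NULL, t_grid) {
  stopifnot(inherits(params, "crypt_parameters"))
  nstate <- params$R + 2L
  if (is.null(init)) init <- numeric(nstate)
  stopifnot(length(init) == nstate, all(init >= 0),
            all(diff(t_grid) > 0), t_grid[1] >= 0)
  nm <- c("X2", paste0("Y", seq_len(params$R)), "Z")
  sol <- deSolve::ode(y = stats::setNames(as.numeric(init), nm),
                      times = t_grid, func = crypt_derivs, parms = params,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed; diagnostics: ",
         paste(utils::capture.output(deSolve::diagnostics(sol)), collapse = "\n"))
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  out
}

#' Proportional change of the postmitotic pool under a rate mutation
#'
#' The steady-state postmitotic pool responds to a division-rate mutation
#' `lam0 -> lam1` with the ratio
#' `Z1*/Z0* = (lam1/lam0) * (nu - lam0)/(nu - lam1)`: a small proportional
#' change of the division rate is amplified in the tissue (a 10% rate drop
#' shrinks the pool by more than 21% at mouse parameters). The
#' differentiation analogue is
#' `Z1*/Z0* = (nu1/nu0) * (nu0 - lam)/(nu1 - lam)`.
#'
#' @param lam0,lam1 baseline and mutated division rates (per day).
#' @param nu differentiation commitment rate (per day).
#' @return The dimensionless ratio `Z1*/Z0*`.
#' @examples
#' population_ratio(0.2, 0.18, 1/3)  # 10% rate change, ~22% tissue change
#' @export
population_ratio <- function(lam0, lam1, nu) {
  if (any(nu <= lam0) || any(nu <= lam1))
    stop("tumorigenic configuration: nu <= lam, steady-state ratio undefined")
  (lam1 / lam0) * (nu - lam0) / (nu - lam1)
}

#' @rdname population_ratio
#' @param nu0,nu1 baseline and mutated differentiation rates (per day).
#' @param lam division rate (per day).
#' @export
population_ratio_diff <- function(nu0, nu1, lam) {
  if (any(nu0 <= lam) || any(nu1 <= lam))
    stop("tumorigenic configuration: nu <= lam, steady-state ratio undefined")
  (nu1 / nu0) * (nu0 - lam) / (nu1 - lam)
}
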