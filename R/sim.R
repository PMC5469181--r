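#' Configuration for stochastic simulations
#'
#' @param seed integer RNG seed, recorded in all outputs (`NULL` leaves the
#'   RNG state untouched).
#' @param replicates number of independent realizations.
#' @param t_max stopping time (days), where applicable.
#' @param report_interval spacing of recorded time points (days).
#' @param max_steps safety cap on simulation steps per batch.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, replicates = 1L, t_max = NULL,
                       report_interval = NULL, max_steps = 1e7) {
  stopifnot(replicates >= 1)
  structure(list(seed = seed, replicates = as.integer(replicates),
                 t_max = t_max, report_interval = report_interval,
                 max_steps = max_steps),
            class = "sim_config")
}

#' Exact stochastic simulation of the crypt compartment model
#'
#' Gillespie (direct-method) realizations of the crypt transition system
#' with the niche held at fixed size `X1`: displaced stem cells accumulate
#' by niche and self division (`lam`), commit to differentiation (`nu`),
#' TA pools double through `R` rounds (`gamma`), and postmitotic cells die
#' (`delta`). Ensemble means and standard errors at the report times are
#' returned; they converge to the mean-field ODE solution
#' ([integrate_means()]).
#'
#' @param params a [crypt_parameters()] object.
#' @param cfg a [sim_config()]; `t_max` is required, `report_interval`
#'   defaults to `t_max/20`.
#' @param init initial pool sizes `X2, Y1..YR, Z` (default all zero).
#' @return List with `times`, `mean` and `se` (matrices, time x pool),
#'   `replicates`, `seed`.
#' @export
gillespie_crypt <- function(params, cfg, init = NULL) {
  stopifnot(inherits(params, "crypt_parameters"), inherits(cfg, "sim_config"),
            !is.null(cfg$t_max))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dt_rep <- if (is.null(cfg$report_interval)) cfg$t_max / 20 else cfg$report_interval
  times <- seq(0, cfg$t_max, by = dt_rep)
  R <- params$R
  nstate <- R + 2L
  if (is.null(init)) init <- numeric(nstate)
  stopifnot(length(init) == nstate, all(init >= 0))
  # reactions: 1 influx to X2 (niche + self division), 2 commitment,
  # 3..(R+2) TA doublings (the last feeds Z), R+3 postmitotic death
  lam <- params$lam; nu <- params$nu; gam <- params$gamma; del <- params$delta
  X1 <- params$X1
  nrx <- R + 3L
  acc <- matrix(0, length(times), nstate)
  acc2 <- matrix(0, length(times), nstate)
  for (rep in seq_len(cfg$replicates)) {
    s <- as.numeric(init)
    t <- 0
    k <- 1L
    rates <- numeric(nrx)
    repeat {
      rates[1L] <- lam * (X1 + s[1L])
      rates[2L] <- nu * s[1L]
      rates[3L:(R + 2L)] <- gam * s[2L:(R + 1L)]
      rates[nrx] <- del * s[nstate]
      tot <- sum(rates)
      t_next <- if (tot > 0) t + rexp(1L) / tot else Inf
      while (k <= length(times) && times[k] <= t_next) {
        acc[k, ] <- acc[k, ] + s
        acc2[k, ] <- acc2[k, ] + s^2
        k <- k + 1L
      }
      if (k > length(times) || t_next > cfg$t_max) break
      t <- t_next
      j <- findInterval(runif(1L) * tot, cumsum(rates)) + 1L
      if (j == 1L) s[1L] <- s[1L] + 1
      else if (j == 2L) { s[1L] <- s[1L] - 1; s[2L] <- s[2L] + 1 }
      else if (j < nrx) { s[j - 1L] <- s[j - 1L] - 1; s[j] <- s[j] + 2 }
      else s[nstate] <- s[nstate] - 1
      if (sum(s) > 1e6) stop("population explosion guard tripped (>1e6 cells)")
    }
  }
  nrep <- cfg$replicates
  mn <- acc / nrep
  va <- acc2 / nrep - mn^2
  va[va < 0] <- 0
  se <- sqrt(va / nrep)
  pools <- c("X2", paste0("Y", seq_len(R)), "Z")
  colnames(mn) <- colnames(se) <- pools
  list(times = times, mean = mn, se = se, replicates = nrep, seed = cfg$seed)
}

#' Ring-Moran fixation dynamics of a mutant stem-cell lineage
#'
#' Continuous-time simulation of `X1` stem cells on a one-dimensional ring:
#' each cell divides at its own rate (residents `lam0`, the mutant lineage
#' `r * lam0`) and the divider replaces its left or right neighbour with
#' equal probability. A single mutant is introduced and the system is run
#' until the mutant lineage fixes or is lost. All replicates are advanced
#' in lockstep (vectorized over replicates).
#'
#' @param X1 niche size (`>= 2`).
#' @param r mutant relative division rate (`> 0`).
#' @param cfg a [sim_config()] (`replicates`, `seed`).
#' @param lam0 resident division rate (per day); sets the time unit.
#' @return Object of class `fixation_outcomes`: data frame with one row per
#'   replicate (`fixed`, `sweep_time` in days, `divisions` during the
#'   sweep), with attributes `X1`, `r`, `seed`.
#' @export
ring_fixation <- function(X1, r, cfg, lam0 = 1) {
  stopifnot(X1 >= 2, r > 0, inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nrep <- cfg$replicates
  state <- matrix(0L, nrep, X1)
  state[, 1L] <- 1L                      # one mutant cell
  fixed <- logical(nrep)
  sweep_time <- numeric(nrep)
  divisions <- integer(nrep)
  active <- seq_len(nrep)
  t_acc <- numeric(nrep)
  div_acc <- integer(nrep)
  steps <- 0L
  while (length(active) > 0) {
    steps <- steps + 1L
    if (steps > cfg$max_steps)
      stop("max_steps exceeded before all replicates resolved")
    S <- state[active, , drop = FALSE]
    na <- length(active)
    k <- .rowSums(S, na, X1)
    # per-cell division rates; sample the divider by inverse CDF over cells
    w <- matrix(lam0, na, X1) + (r - 1) * lam0 * S
    tot <- lam0 * (X1 + (r - 1) * k)
    cw <- w
    for (j in 2:X1) cw[, j] <- cw[, j - 1L] + cw[, j]
    u <- runif(na) * tot
    idx <- .rowSums(u > cw, na, X1) + 1L
    dir <- sample(c(-1L, 1L), na, replace = TRUE)
    tgt <- ((idx + dir - 1L) %% X1) + 1L
    S[cbind(seq_len(na), tgt)] <- S[cbind(seq_len(na), idx)]
    t_acc[active] <- t_acc[active] + rexp(na) / tot
    div_acc[active] <- div_acc[active] + 1L
    k <- .rowSums(S, na, X1)
    done <- k == 0L | k == X1
    if (any(done)) {
      done_ids <- active[done]
      fixed[done_ids] <- k[done] == X1
      sweep_time[done_ids] <- t_acc[done_ids]
      divisions[done_ids] <- div_acc[done_ids]
      state[active[!done], ] <- S[!done, , drop = FALSE]
      active <- active[!done]
    } else {
      state[active, ] <- S
    }
  }
  structure(data.frame(fixed = fixed, sweep_time = sweep_time,
                       divisions = divisions),
            X1 = X1, r = r, seed = cfg$seed,
            class = c("fixation_outcomes", "data.frame"))
}

#' Summarize ring-fixation outcomes
#'
#' Fixation frequency with its binomial standard error, conditional sweep
#' statistics, and the expected number of new fitness-affecting mutations
#' arising during a sweep (`mu` per division, counting divisions of all
#' niche lineages, since any of them can mutate). Both the unconditional
#' mean over all decided sweeps (most of which are quick losses) and the
#' mean conditional on fixation are reported.
#'
#' @param outcomes a `fixation_outcomes` data frame from [ring_fixation()].
#' @param mu mutation rate per division (for the mutations-per-sweep
#'   estimate); `NULL` omits it.
#' @return List with `freq`, `se`, `n`, `mean_sweep_time_fixed`,
#'   `mean_divisions`, `mean_divisions_fixed`, and (given `mu`)
#'   `mutations_per_sweep`, `mutations_per_sweep_fixed`.
#' @export
summarize_fixation <- function(outcomes, mu = NULL) {
  stopifnot(inherits(outcomes, "fixation_outcomes"))
  n <- nrow(outcomes)
  p <- mean(outcomes$fixed)
  out <- list(freq = p, se = sqrt(p * (1 - p) / n), n = n,
              mean_sweep_time_fixed = mean(outcomes$sweep_time[outcomes$fixed]),
              mean_divisions = mean(outcomes$divisions),
              mean_divisions_fixed = mean(outcomes$divisions[outcomes$fixed]))
  if (!is.null(mu)) {
    out$mutations_per_sweep <- mu * out$mean_divisions
    out$mutations_per_sweep_fixed <- mu * out$mean_divisions_fixed
  }
  out
}

#' Stochastic ratchet: successive fixations in one niche
#'
#' Monte-Carlo counterpart of the fixed-mutation recursion: repeatedly
#' draws a mutant effect from the DFE, accepts it with the Moran-ring
#' fixation probability (neutral `1/X1` for the differentiation target),
#' and multiplies the niche rate by the accepted ratio. The ensemble mean
#' rate after `m` fixations estimates `E[f_m]`.
#'
#' @param X1 niche size.
#' @param dfe a [dfe_parameters()] object.
#' @param cfg a [sim_config()] (`replicates`, `seed`).
#' @param m number of fixations per replicate.
#' @param r0 starting rate (per day).
#' @param target `"division"` or `"differentiation"`.
#' @return Matrix (`replicates` x `m + 1`) of rates after 0..m fixations.
#' @export
serial_ratchet <- function(X1, dfe, cfg, m = 5, r0 = 1,
                           target = c("division", "differentiation")) {
  target <- match.arg(target)
  stopifnot(X1 >= 1, inherits(cfg, "sim_config"), m >= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nrep <- cfg$replicates
  rates <- matrix(r0, nrep, m + 1L)
  for (step in seq_len(m)) {
    pending <- seq_len(nrep)
    ratio <- numeric(nrep)
    while (length(pending) > 0) {
      cand <- dfe_sample(length(pending), dfe, target)
      pacc <- if (target == "division") fixation_probability(cand, X1)
              else rep(1 / X1, length(cand))
      acc <- runif(length(pending)) < pacc
      ratio[pending[acc]] <- cand[acc]
      pending <- pending[!acc]
    }
    rates[, step + 1L] <- rates[, step] * ratio
  }
  colnames(rates) <- paste0("m", 0:m)
  rates
}
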