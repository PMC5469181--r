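#' Built-in organism scenario presets
#'
#' Three parameterizations used throughout the analyses:
#' \describe{
#'   \item{`mouse_si`}{Mouse small intestine: 6-cell niche dividing at
#'     0.2/day, 15 LGR5+ stem cells total (so `nu = 1/3`), TA cells
#'     dividing twice a day through 6 rounds, 3-day postmitotic lifespan
#'     (`delta = 1/3`), adult lifetime 3 years. Reporting constants: 130 of
#'     the 576 postmitotic cells sit inside the crypt, 8 crypts feed a
#'     villus.}
#'   \item{`human_colon_niche6`}{Human colon, 6-cell niche of 36 putative
#'     stem cells, weekly division, 75 adult years.}
#'   \item{`human_colon_niche20`}{As above with a 20-cell niche.}
#' }
#' Human TA and postmitotic rates are not measured; the human pipeline uses
#' the linear attrition slope, which does not involve them (mouse values
#' are carried as placeholders). Total crypt counts are order-of-magnitude
#' conventions that scale absolute tumour probabilities only.
#'
#' @param name one of `"mouse_si"`, `"human_colon_niche6"`,
#'   `"human_colon_niche20"`.
#' @return Object of class `scenario_preset`: list with `name`, `organism`,
#'   `crypt` ([crypt_parameters()]), `dfe` ([dfe_parameters()]),
#'   `lifetime_days`, `total_stem`, `n_crypts`, `z_in_crypt`,
#'   `crypts_per_villus`.
#' @export
scenario_preset <- function(name = c("mouse_si", "human_colon_niche6",
                                     "human_colon_niche20")) {
  name <- match.arg(name)
  dfe <- dfe_yeast()
  p <- switch(name,
    mouse_si = list(
      organism = "mouse", lam = 0.2, X1 = 6L, total_stem = 15,
      gamma = 2, delta = 1 / 3, R = 6L, lifetime_days = 1095,
      n_crypts = 1e6, z_in_crypt = 130, crypts_per_villus = 8),
    human_colon_niche6 = list(
      organism = "human", lam = 1 / 7, X1 = 6L, total_stem = 36,
      gamma = 2, delta = 1 / 3, R = 6L, lifetime_days = 27375,
      n_crypts = 1e7, z_in_crypt = NA_real_, crypts_per_villus = NA_real_),
    human_colon_niche20 = list(
      organism = "human", lam = 1 / 7, X1 = 20L, total_stem = 36,
      gamma = 2, delta = 1 / 3, R = 6L, lifetime_days = 27375,
      n_crypts = 1e7, z_in_crypt = NA_real_, crypts_per_villus = NA_real_))
  nu <- commitment_rate(p$lam, p$X1, p$total_stem)
  crypt <- crypt_parameters(p$X1, p$lam, nu, p$gamma, p$delta, p$R)
  structure(list(name = name, organism = p$organism, crypt = crypt,
                 dfe = dfe, lifetime_days = p$lifetime_days,
                 total_stem = p$total_stem, n_crypts = p$n_crypts,
                 z_in_crypt = p$z_in_crypt,
                 crypts_per_villus = p$crypts_per_villus),
            class = "scenario_preset")
}

#' Read a scenario from a flat key:value config file
#'
#' Parses a YAML-style flat configuration with keys `X1`, `lam`, `nu` (or
#' `total_stem`), `gamma`, `delta`, `R`, `lifetime_days`, `n_crypts`, and
#' optional DFE keys `mu`, `s_minus`, `s_plus`, `P_B` (yeast values
#' otherwise).
#'
#' @param path file path.
#' @return A list like [scenario_preset()] (without the reporting
#'   constants).
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("X1", "lam", "gamma", "delta", "R", "lifetime_days")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop("config is missing keys: ", paste(missing, collapse = ", "))
  nu <- if (!is.null(cfg$nu)) cfg$nu
        else if (!is.null(cfg$total_stem))
          commitment_rate(cfg$lam, cfg$X1, cfg$total_stem)
        else stop("config needs either nu or total_stem")
  dfe <- if (all(c("mu", "s_minus", "s_plus", "P_B") %in% names(cfg)))
    dfe_parameters(cfg$mu, cfg$s_minus, cfg$s_plus, cfg$P_B) else dfe_yeast()
  list(name = if (is.null(cfg$name)) basename(path) else cfg$name,
       crypt = crypt_parameters(cfg$X1, cfg$lam, nu, cfg$gamma, cfg$delta,
                                cfg$R),
       dfe = dfe, lifetime_days = cfg$lifetime_days,
       n_crypts = if (is.null(cfg$n_crypts)) 1 else cfg$n_crypts)
}

#' End-to-end report over scenario presets
#'
#' Recomputes, for each named preset, the headline quantities of the
#' pipeline: the derived commitment rate, crypt steady-state pools, the
#' villus contribution (mouse), and the end-of-life attrition percentages
#' for division- and differentiation-rate mutations. Everything is
#' deterministic: two invocations produce identical tables.
#'
#' @param presets character vector of preset names (see
#'   [scenario_preset()]); an empty vector gives an empty table.
#' @return Data frame with columns `preset`, `quantity`, `value`, `units`.
#' @export
run_report <- function(presets = c("mouse_si", "human_colon_niche6",
                                   "human_colon_niche20")) {
  empty <- data.frame(preset = character(), quantity = character(),
                      value = numeric(), units = character())
  if (length(presets) == 0) return(empty)
  rows <- lapply(presets, function(nm) {
    ps <- scenario_preset(nm)
    crypt <- ps$crypt
    add <- function(quantity, value, units)
      data.frame(preset = nm, quantity = quantity, value = value,
                 units = units)
    out <- list(add("nu", crypt$nu, "per day"))
    if (ps$organism == "mouse") {
      ss <- crypt_steady_state(crypt)
      out <- c(out, list(
        add("Y_total", ss$Y_total, "cells"),
        add("Z_star", ss$Z, "cells"),
        add("villus_contribution",
            ps$crypts_per_villus * (ss$Z - ps$z_in_crypt), "cells")))
    }
    for (tg in c("division", "differentiation")) {
      scn <- tissue_scenario(crypt, ps$dfe, tg, ps$lifetime_days)
      decline <- -linear_slope(scn) * ps$lifetime_days * 100
      out <- c(out, list(
        add(paste0("attrition_", tg), decline, "percent decline")))
    }
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}
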