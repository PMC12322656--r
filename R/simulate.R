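#' Construct a progress curve tibble
#'
#' A progress curve is a tibble with columns `time_min`, `UMP_mM`, `Ura_mM`,
#' `Rib5P_mM`, `PsiMP_mM`, carrying the initial UMP concentration and the
#' kind of experiment (`"hydrolysis"` or `"cascade"`) as attributes.
#'
#' @param time_min,UMP_mM,Ura_mM,Rib5P_mM,PsiMP_mM Numeric vectors of equal
#'   length.
#' @param ump0 Initial UMP concentration in mM.
#' @param kind `"hydrolysis"` or `"cascade"`.
#' @return A tibble of class `progress_curve`.
#' @export
progress_curve <- function(time_min, UMP_mM, Ura_mM, Rib5P_mM, PsiMP_mM,
                           ump0, kind = c("hydrolysis", "cascade")) {
  kind <- match.arg(kind)
  out <- tibble(time_min = time_min, UMP_mM = UMP_mM, Ura_mM = Ura_mM,
                Rib5P_mM = Rib5P_mM, PsiMP_mM = PsiMP_mM)
  attr(out, "ump0") <- ump0
  attr(out, "kind") <- kind
  class(out) <- c("progress_curve", class(out))
  out
}

#' Mass-balance residuals of a progress curve
#'
#' Hydrolysis obeys `UMP + Ura = UMP0` with `Ura = Rib5P`; the cascade obeys
#' `UMP + Ura + PsiMP = UMP0` and `UMP + Rib5P + PsiMP = UMP0`.
#'
#' @param curve A [progress_curve()].
#' @return A tibble with per-time-point absolute residuals of the two
#'   conserved sums.
#' @export
mass_balance_residuals <- function(curve) {
  ump0 <- attr(curve, "ump0")
  tibble(
    time_min = curve$time_min,
    ura_balance = abs(curve$UMP_mM + curve$Ura_mM + curve$PsiMP_mM - ump0),
    rib5p_balance = abs(curve$UMP_mM + curve$Rib5P_mM + curve$PsiMP_mM - ump0)
  )
}

default_solver <- function() list(rtol = 1e-8, atol = 1e-10)

#' Simulate single-enzyme UMP hydrolysis
#'
#' Integrates `dS/dt = -v(S, P)` with the competitive product-inhibition rate
#' law, `P = S0 - S` by the 1:1 mass balance UMP -> Ura + Rib5P. A
#' stiff-capable integrator (`deSolve::lsoda`) is used because the late,
#' inhibition-dominated phase is mildly stiff.
#'
#' @param enzyme An [enzyme_spec()] at the working loading.
#' @param params A [kinetic_params()].
#' @param s0 Initial UMP concentration in mM (positive).
#' @param t_grid Increasing time grid in minutes starting at 0.
#' @param rtol,atol Solver tolerances (relative, and absolute in mM).
#' @return A [progress_curve()] with `Ura = Rib5P = s0 - UMP`.
#' @export
#' @examples
#' ry <- enzyme_spec("RY", 51440, mass_conc = 2.0)
#' p <- kinetic_params(13.4, 15.5, ki = 1.2)
#' curve <- simulate_hydrolysis(ry, p, s0 = 100, t_grid = seq(0, 120, 5))
#' 100 * (1 - curve$UMP_mM[nrow(curve)] / 100)  # percent conversion at 120 min
simulate_hydrolysis <- function(enzyme, params, s0, t_grid,
                                rtol = default_solver()$rtol,
                                atol = default_solver()$atol) {
  if (s0 <= 0) abort("`s0` must be positive (mM)")
  check_time_grid(t_grid)
  rhs <- function(t, y, parms) {
    s <- max(y[[1]], 0)
    list(-rate_inhibited_mm(params, enzyme, s, s0 - s))
  }
  sol <- run_ode(c(S = s0), t_grid, rhs, rtol, atol)
  s <- pmax(sol[, "S"], 0)
  progress_curve(t_grid, s, s0 - s, s0 - s, rep(0, length(s)),
                 ump0 = s0, kind = "hydrolysis")
}

#' Configuration of the one-pot two-enzyme cascade
#'
#' @param ppnn_enzyme,ppnn_params The nucleosidase ([enzyme_spec()] at its
#'   loading, [kinetic_params()]).
#' @param yein_enzyme,yein_params The C-glycosidase ([enzyme_spec()],
#'   [yein_params()]).
#' @param ump0 Initial UMP in mM (positive).
#' @param t_end Simulation horizon in minutes (positive).
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(ppnn_enzyme, ppnn_params, yein_enzyme,
                           yein_params, ump0 = 100, t_end = 120) {
  stopifnot(inherits(ppnn_enzyme, "enzyme_spec"),
            inherits(ppnn_params, "kinetic_params"),
            inherits(yein_enzyme, "enzyme_spec"),
            inherits(yein_params, "yein_params"))
  if (ump0 <= 0) abort("`ump0` must be positive (mM)")
  if (t_end <= 0) abort("`t_end` must be positive (min)")
  structure(list(ppnn_enzyme = ppnn_enzyme, ppnn_params = ppnn_params,
                 yein_enzyme = yein_enzyme, yein_params = yein_params,
                 ump0 = ump0, t_end = t_end),
            class = "cascade_config")
}

#' Simulate the coupled UMP -> PsiMP cascade
#'
#' Integrates the four-species system
#' `d[UMP]/dt = -v1`, `d[Rib5P]/dt = d[Ura]/dt = v1 - v2`,
#' `d[PsiMP]/dt = v2`, where `v1` is the nucleosidase rate with Rib5P as
#' competitive inhibitor and `v2` the C-glycosidase condensation rate.
#'
#' @param config A [cascade_config()].
#' @param t_grid Optional time grid in minutes; defaults to 201 points over
#'   `[0, t_end]`.
#' @inheritParams simulate_hydrolysis
#' @return A [progress_curve()] of kind `"cascade"`.
#' @export
simulate_cascade <- function(config, t_grid = NULL,
                             rtol = default_solver()$rtol,
                             atol = default_solver()$atol) {
  stopifnot(inherits(config, "cascade_config"))
  if (is.null(t_grid)) t_grid <- seq(0, config$t_end, length.out = 201)
  check_time_grid(t_grid)
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    v1 <- rate_inhibited_mm(config$ppnn_params, config$ppnn_enzyme,
                            y[["UMP"]], y[["Rib5P"]])
    v2 <- yein_rate(config$yein_params, config$yein_enzyme,
                    y[["Rib5P"]], y[["Ura"]])
    list(c(UMP = -v1, Rib5P = v1 - v2, Ura = v1 - v2, PsiMP = v2))
  }
  y0 <- c(UMP = config$ump0, Rib5P = 0, Ura = 0, PsiMP = 0)
  sol <- run_ode(y0, t_grid, rhs, rtol, atol)
  progress_curve(t_grid,
                 pmax(sol[, "UMP"], 0), pmax(sol[, "Ura"], 0),
                 pmax(sol[, "Rib5P"], 0), pmax(sol[, "PsiMP"], 0),
                 ump0 = config$ump0, kind = "cascade")
}

#' Vary the YeiN:PpnN mass ratio at constant total protein
#'
#' Splits a fixed total protein loading between the nucleosidase and the
#' C-glycosidase at each requested mass ratio, simulates the cascade, and
#' reports the UMP conversion and PsiMP yield at `t_eval`. This reproduces
#' the kinetic-pull experiment: conversion rises with the YeiN share up to a
#' plateau and collapses when YeiN is strongly sub-stoichiometric.
#'
#' @param total_protein Total protein loading in g/L, fixed across the sweep.
#' @param ratios Numeric vector of YeiN:PpnN mass ratios (positive).
#' @param config A [cascade_config()] template; its enzyme mass
#'   concentrations are overridden by the split.
#' @param t_eval Evaluation time in minutes.
#' @return A tibble of class `ratio_sweep` with one row per ratio:
#'   `ratio`, `ppnn_g_L`, `yein_g_L`, `conversion_pct`, `psimp_pct`.
#' @export
enzyme_ratio_sweep <- function(total_protein, ratios, config, t_eval = 30) {
  if (length(ratios) == 0) abort("`ratios` must be a non-empty numeric vector")
  if (any(ratios < 0)) abort("`ratios` must be non-negative")
  if (total_protein <= 0) abort("`total_protein` must be positive (g/L)")
  rows <- map(ratios, function(r) {
    ppnn_load <- total_protein / (1 + r)
    yein_load <- total_protein - ppnn_load
    cfg <- cascade_config(
      set_mass_conc(config$ppnn_enzyme, ppnn_load), config$ppnn_params,
      set_mass_conc(config$yein_enzyme, yein_load), config$yein_params,
      ump0 = config$ump0, t_end = t_eval)
    curve <- simulate_cascade(cfg, t_grid = c(0, t_eval))
    last <- curve[nrow(curve), ]
    tibble(ratio = r, ppnn_g_L = ppnn_load, yein_g_L = yein_load,
           conversion_pct = 100 * (1 - last$UMP_mM / config$ump0),
           psimp_pct = 100 * last$PsiMP_mM / config$ump0)
  })
  out <- list_rbind(rows)
  class(out) <- c("ratio_sweep", class(out))
  out
}

check_time_grid <- function(t_grid) {
  if (length(t_grid) < 2 || t_grid[1] != 0 || any(diff(t_grid) <= 0)) {
    abort("`t_grid` must be an increasing grid starting at 0 (min)")
  }
  invisible(t_grid)
}

run_ode <- function(y0, t_grid, rhs, rtol, atol) {
  sol <- deSolve::lsoda(y = y0, times = t_grid, func = rhs,
                        rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    abort(paste0("ODE integration failed (lsoda istate = ", diagn[1], ")"))
  }
  if (nrow(sol) < length(t_grid)) {
    abort("ODE integration stopped before the end of the time grid")
  }
  sol
}
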