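# Synthetic-data generation: initial-rate grids, inhibition grids, and
# hydrolysis/cascade time courses from the published parameter presets, with
# a multiplicative measurement-noise model. These are the inputs every
# estimation and simulation stage is exercised against.

#' Measurement-noise model for synthetic data
#'
#' Per-point independent multiplicative Gaussian noise, truncated at zero:
#' `y_obs = max(y * (1 + cv * Z), 0)`. The default coefficient of variation
#' (0.16) reflects the replicate spread typical of the initial-rate assays
#' this generator emulates.
#'
#' @param kind `"none"` or `"multiplicative-gaussian"`.
#' @param cv Coefficient of variation as a fraction (non-negative).
#' @param seed Optional integer seed; an identical seed gives an identical
#'   dataset.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "multiplicative-gaussian"),
                        cv = 0.16, seed = NULL) {
  kind <- match.arg(kind)
  if (cv < 0) abort("`cv` must be non-negative")
  structure(list(kind = kind, cv = cv, seed = seed), class = "noise_model")
}

apply_noise <- function(x, noise) {
  if (noise$kind == "none") return(x)
  perturb <- function() pmax(x * (1 + noise$cv * rnorm(length(x))), 0)
  if (is.null(noise$seed)) perturb() else withr::with_seed(noise$seed, perturb())
}

#' Kinetic parameter presets
#'
#' Published constants for wild-type PpnN (`"WT_PPNN"`: kcat 2.6 1/s, Km
#' 1.1 mM, Ki 0.1 mM), the RY double variant (`"RY"`: 13.4, 15.5, 1.2) and
#' the default calibrated C-glycosidase law (`"YEIN_DEFAULT"`).
#'
#' @param name Preset name.
#' @return A [kinetic_params()] (or [yein_params()] for YeiN).
#' @export
#' @examples
#' preset_params("RY")
preset_params <- function(name = c("WT_PPNN", "RY", "YEIN_DEFAULT")) {
  name <- match.arg(name)
  k <- psi_constants()$kinetics[[name]]
  if (name == "YEIN_DEFAULT") {
    yein_params(km_rib5p = k$km_rib5p, km_ura = k$km_ura,
                calibration_sa = k$calibration$specific_activity,
                calibration_conc = c(k$calibration$rib5p, k$calibration$ura))
  } else {
    kinetic_params(k$kcat, k$km, k$ki)
  }
}

#' Enzyme presets
#'
#' @param name Preset name (`"WT_PPNN"`, `"RY"`, `"YEIN"`).
#' @param mass_conc Working mass concentration in g/L; defaults to the
#'   standard assay loading from the constants table.
#' @return An [enzyme_spec()].
#' @export
preset_enzyme <- function(name = c("WT_PPNN", "RY", "YEIN"),
                          mass_conc = NULL) {
  name <- match.arg(name)
  e <- psi_constants()$enzymes[[if (name == "YEIN") "YEIN" else name]]
  enzyme_spec(name, e$subunit_molar_mass, mass_conc %||% e$assay_mass_conc)
}

#' Default substrate grids for the two nucleosidase presets
#'
#' Six UMP concentrations spanning each enzyme's Km (the true assay grids
#' are unpublished; these are declared stand-ins).
#'
#' @param preset `"WT_PPNN"` or `"RY"`.
#' @return Numeric vector of substrate concentrations in mM.
#' @export
default_s_grid <- function(preset = c("WT_PPNN", "RY")) {
  preset <- match.arg(preset)
  if (preset == "WT_PPNN") c(0.5, 1, 2, 5, 15, 30) else c(2, 5, 10, 20, 40, 80)
}

#' Generate a synthetic initial-rate dataset
#'
#' Evaluates the competitive-inhibition rate law on an `S x I` grid for a
#' parameter preset and perturbs the rates with the noise model.
#'
#' @param preset `"WT_PPNN"` or `"RY"`, or a [kinetic_params()] object.
#' @param s_grid Substrate concentrations in mM (defaults to the preset's
#'   grid).
#' @param i_grid Inhibitor (Rib5P) concentrations in mM; default `0` (use
#'   `c(0, 2, 10)` for an inhibition study).
#' @param noise A [noise_model()]; default no noise.
#' @param enzyme Optional [enzyme_spec()] override.
#' @return A tibble with `S_mM`, `I_mM`, `rate_mM_per_min` and attributes
#'   `enzyme`, `params`, `noise`.
#' @export
#' @examples
#' gen_initial_rates("WT_PPNN", i_grid = c(0, 2, 10))
gen_initial_rates <- function(preset, s_grid = NULL, i_grid = 0,
                              noise = noise_model("none"), enzyme = NULL) {
  if (is.character(preset)) {
    enzyme <- enzyme %||% preset_enzyme(preset)
    params <- preset_params(preset)
    s_grid <- s_grid %||% default_s_grid(preset)
  } else {
    stopifnot(inherits(preset, "kinetic_params"), !is.null(enzyme),
              !is.null(s_grid))
    params <- preset
  }
  if (length(s_grid) == 0 || length(i_grid) == 0) abort("grids must be non-empty")
  if (any(s_grid < 0) || any(i_grid < 0)) abort("grid values must be non-negative")
  grid <- tidyr::expand_grid(I_mM = i_grid, S_mM = s_grid)
  rate <- rate_inhibited_mm(params, enzyme, grid$S_mM, grid$I_mM)
  out <- tibble(S_mM = grid$S_mM, I_mM = grid$I_mM,
                rate_mM_per_min = apply_noise(rate, noise))
  attr(out, "enzyme") <- enzyme
  attr(out, "params") <- params
  attr(out, "noise") <- noise
  out
}

#' Generate a synthetic hydrolysis progress curve
#'
#' Simulates single-enzyme UMP hydrolysis for a preset and overlays
#' observation noise per species and time point. The mass-balance identities
#' hold for the latent (noiseless) curve only.
#'
#' @inheritParams gen_initial_rates
#' @param s0 Initial UMP in mM.
#' @param t_grid Time grid in minutes.
#' @return A [progress_curve()].
#' @export
gen_progress_curve <- function(preset, s0 = 100, t_grid = seq(0, 120, 5),
                               noise = noise_model("none"), enzyme = NULL) {
  if (is.character(preset)) {
    enzyme <- enzyme %||% preset_enzyme(preset, mass_conc = 2.0)
    params <- preset_params(preset)
  } else {
    stopifnot(inherits(preset, "kinetic_params"), !is.null(enzyme))
    params <- preset
  }
  curve <- simulate_hydrolysis(enzyme, params, s0, t_grid)
  noisy_curve(curve, noise)
}

#' Generate a synthetic cascade time course
#'
#' Noisy observation of [simulate_cascade()]. Initial UMP above the
#' solubility limit (~1.5 M) triggers a warning.
#'
#' @param config A [cascade_config()].
#' @param noise A [noise_model()].
#' @param t_grid Optional time grid in minutes.
#' @return A [progress_curve()] of kind `"cascade"`.
#' @export
gen_cascade_curves <- function(config, noise = noise_model("none"),
                               t_grid = NULL) {
  limit <- psi_constants()$solubility_limit_UMP
  if (config$ump0 > limit) {
    warn(sprintf("initial UMP %.0f mM exceeds the ~%.0f mM solubility limit",
                 config$ump0, limit))
  }
  noisy_curve(simulate_cascade(config, t_grid), noise)
}

noisy_curve <- function(curve, noise) {
  if (noise$kind == "none") return(curve)
  species <- c("UMP_mM", "Ura_mM", "Rib5P_mM", "PsiMP_mM")
  perturb <- function() {
    for (sp in species) {
      curve[[sp]] <- pmax(curve[[sp]] * (1 + noise$cv * rnorm(nrow(curve))), 0)
    }
    curve
  }
  if (is.null(noise$seed)) perturb() else withr::with_seed(noise$seed, perturb())
}
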