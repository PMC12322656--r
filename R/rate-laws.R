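#' Michaelis-Menten parameters with optional competitive inhibition
#'
#' Container for the kinetic constants of the nucleosidase reaction
#' UMP -> Ura + Rib5P. When `ki` is present the rate law carries a
#' competitive product-inhibition term for Rib5P; when absent the plain
#' Michaelis-Menten law applies.
#'
#' @param kcat Turnover number in 1/s (non-negative).
#' @param km Michaelis constant for UMP in mM (positive).
#' @param ki Optional competitive inhibition constant for Rib5P in mM
#'   (positive when given).
#' @return An object of class `kinetic_params`.
#' @export
#' @examples
#' kinetic_params(kcat = 13.4, km = 15.5, ki = 1.2)  # the RY variant
kinetic_params <- function(kcat, km, ki = NULL) {
  if (!is.numeric(kcat) || kcat < 0) abort("`kcat` must be non-negative (1/s)")
  if (!is.numeric(km) || km <= 0) abort("`km` must be positive (mM)")
  if (!is.null(ki) && (!is.numeric(ki) || ki <= 0)) {
    abort("`ki` must be positive (mM) when given")
  }
  structure(list(kcat = kcat, km = km, ki = ki), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> kcat = %.4g 1/s, Km = %.4g mM, Ki = %s mM\n",
              x$kcat, x$km,
              if (is.null(x$ki)) "none (no inhibition term)" else format(x$ki)))
  invisible(x)
}

#' Maximum rate from a turnover number and an enzyme loading
#'
#' `Vmax = kcat * [E]`, with the x60 boundary conversion from 1/s to 1/min.
#'
#' @param kcat Turnover number in 1/s.
#' @param enzyme An [enzyme_spec()] whose `mass_conc` sets `[E]`.
#' @return Vmax in mM/min.
#' @export
vmax_from_kcat <- function(kcat, enzyme) {
  60 * kcat * subunit_molarity(enzyme)
}

#' Rate law of the nucleosidase with competitive Rib5P inhibition
#'
#' Evaluates `v = Vmax * S / (Km * (1 + I/Ki) + S)` in mM/min, with
#' `Vmax = kcat * [E]` from the enzyme loading. With `ki` absent or `i = 0`
#' this is the plain Michaelis-Menten law. The law is monotone increasing in
#' `s`, monotone decreasing in `i`, and its saturation limit `Vmax` does not
#' depend on `i` (the competitive signature).
#'
#' @param params A [kinetic_params()].
#' @param enzyme An [enzyme_spec()] with the working mass concentration.
#' @param s Substrate (UMP) concentration in mM (non-negative; vectorised).
#' @param i Inhibitor (Rib5P) concentration in mM (non-negative; vectorised,
#'   recycled against `s`).
#' @return Rate in mM/min.
#' @export
#' @examples
#' ry <- enzyme_spec("RY", 51440, mass_conc = 2.0)
#' p <- kinetic_params(13.4, 15.5, ki = 1.2)
#' rate_inhibited_mm(p, ry, s = 100, i = 0)
rate_inhibited_mm <- function(params, enzyme, s, i = 0) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(s < 0) || any(i < 0)) abort("concentrations must be non-negative")
  vmax <- vmax_from_kcat(params$kcat, enzyme)
  km_app <- if (is.null(params$ki)) params$km else params$km * (1 + i / params$ki)
  vmax * s / (km_app + s)
}

#' Apparent Michaelis constant under competitive inhibition
#'
#' @param params A [kinetic_params()] with `ki` set.
#' @param i Inhibitor concentration in mM.
#' @return `Km * (1 + i/Ki)` in mM.
#' @export
apparent_km <- function(params, i) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(params$ki)) return(rep(params$km, length(i)))
  params$km * (1 + i / params$ki)
}

#' Parameters of the C-glycosidase (YeiN) condensation rate law
#'
#' The condensation Rib5P + Ura -> PsiMP is modelled with an irreversible
#' two-substrate saturation law,
#' `v = Vmax * A/(Km_A + A) * B/(Km_B + B)`. The paper-grade anchor for this
#' enzyme is a single operating point (7.0 U/mg at 15 mM of each substrate);
#' when `kcat` is `NULL` it is calibrated so the law reproduces that anchor
#' exactly at the chosen Km values. The Km defaults (1 mM each) are assumed,
#' not measured; see the methods vignette.
#'
#' @param kcat Turnover number in 1/s, or `NULL` to calibrate from the
#'   specific-activity anchor.
#' @param km_rib5p,km_ura Michaelis constants in mM (positive).
#' @param calibration_sa Anchor specific activity in U/mg.
#' @param calibration_conc Anchor substrate concentrations `c(rib5p, ura)`
#'   in mM.
#' @param enzyme_molar_mass Subunit molar mass used for the calibration,
#'   g/mol.
#' @return An object of class `yein_params`.
#' @export
#' @examples
#' yein_params()  # calibrated to 7.0 U/mg at 15 mM / 15 mM
yein_params <- function(kcat = NULL, km_rib5p = 1, km_ura = 1,
                        calibration_sa = 7.0, calibration_conc = c(15, 15),
                        enzyme_molar_mass = 32909) {
  if (km_rib5p <= 0 || km_ura <= 0) abort("Km values must be positive (mM)")
  if (is.null(kcat)) {
    # observed turnover at the anchor, undone for fractional saturation
    k_obs <- calibration_sa * enzyme_molar_mass / 60000
    sat <- (calibration_conc[1] / (km_rib5p + calibration_conc[1])) *
           (calibration_conc[2] / (km_ura + calibration_conc[2]))
    kcat <- k_obs / sat
  }
  if (kcat <= 0) abort("`kcat` must be positive (1/s)")
  structure(list(kcat = kcat, km_rib5p = km_rib5p, km_ura = km_ura,
                 reversible = FALSE),
            class = "yein_params")
}

#' @export
print.yein_params <- function(x, ...) {
  cat(sprintf(
    "<yein_params> kcat = %.4g 1/s, Km(Rib5P) = %.3g mM, Km(Ura) = %.3g mM, irreversible\n",
    x$kcat, x$km_rib5p, x$km_ura))
  invisible(x)
}

#' Rate of the C-glycosidase condensation
#'
#' @param params A [yein_params()].
#' @param enzyme An [enzyme_spec()] for YeiN with the working mass
#'   concentration.
#' @param rib5p,ura Substrate concentrations in mM (non-negative,
#'   vectorised).
#' @return Rate of PsiMP formation in mM/min.
#' @export
yein_rate <- function(params, enzyme, rib5p, ura) {
  stopifnot(inherits(params, "yein_params"))
  if (any(rib5p < 0) || any(ura < 0)) abort("concentrations must be non-negative")
  vmax <- vmax_from_kcat(params$kcat, enzyme)
  vmax * (rib5p / (params$km_rib5p + rib5p)) * (ura / (params$km_ura + ura))
}
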