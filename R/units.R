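# Canonical internal units: concentrations in mM, time in minutes, rates in
# mM/min. kcat is stored in 1/s and converted (x60) at the rate-law boundary.

#' Describe an enzyme catalyst
#'
#' Bundles the identity, per-subunit molar mass and mass concentration of one
#' catalyst. Kinetics throughout the package are expressed per subunit, so the
#' oligomeric state (wild-type PpnN is a tetramer, RY a monomer) does not
#' enter the molarity calculation.
#'
#' @param name Character label, e.g. `"RY"`.
#' @param subunit_molar_mass Subunit molar mass in g/mol. Must be positive.
#' @param mass_conc Mass concentration in g/L (equivalently mg/mL). Must be
#'   non-negative.
#' @param epsilon_280 Optional molar extinction coefficient at 280 nm in
#'   1/(M cm), for A280 protein quantification.
#' @return An object of class `enzyme_spec`.
#' @export
#' @examples
#' ry <- enzyme_spec("RY", 51440, mass_conc = 2.0)
#' subunit_molarity(ry)  # mM
enzyme_spec <- function(name, subunit_molar_mass, mass_conc = 0,
                        epsilon_280 = NULL) {
  if (!is.numeric(subunit_molar_mass) || subunit_molar_mass <= 0) {
    abort("`subunit_molar_mass` must be a positive number (g/mol)")
  }
  if (!is.numeric(mass_conc) || mass_conc < 0) {
    abort("`mass_conc` must be non-negative (g/L)")
  }
  structure(
    list(name = as.character(name),
         subunit_molar_mass = as.numeric(subunit_molar_mass),
         mass_conc = as.numeric(mass_conc),
         epsilon_280 = epsilon_280),
    class = "enzyme_spec"
  )
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s: %s g/mol per subunit, %.3g g/L (%.4g mM subunit)\n",
              x$name, format(x$subunit_molar_mass, big.mark = ","),
              x$mass_conc, subunit_molarity(x)))
  invisible(x)
}

#' Replace the mass concentration of an enzyme spec
#'
#' @param enzyme An [enzyme_spec()].
#' @param mass_conc New mass concentration in g/L.
#' @return A new `enzyme_spec`.
#' @export
set_mass_conc <- function(enzyme, mass_conc) {
  enzyme_spec(enzyme$name, enzyme$subunit_molar_mass, mass_conc,
              enzyme$epsilon_280)
}

#' Molar subunit concentration of an enzyme preparation
#'
#' Converts a mass concentration (g/L) into the molar concentration of enzyme
#' subunits (mM) by dividing by the subunit molar mass. This is the `[E]`
#' entering `Vmax = kcat * [E]`.
#'
#' @param enzyme An [enzyme_spec()].
#' @return Subunit concentration in mM.
#' @export
subunit_molarity <- function(enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  # g/L divided by g/mol gives mol/L = M; x1000 -> mM
  1000 * enzyme$mass_conc / enzyme$subunit_molar_mass
}

#' Convert a specific activity to a turnover number
#'
#' A unit (U) is 1 umol/min of product released or substrate consumed, so a
#' specific activity in U/mg corresponds to an observed per-subunit turnover
#' `sa * M / 60000` 1/s (with M the subunit molar mass in g/mol). Because the
#' assay runs at a finite substrate concentration, the observed turnover is
#' corrected to saturation by the Michaelis factor `(Km + S)/S`.
#'
#' @param sa Specific activity in U/mg (non-negative).
#' @param enzyme An [enzyme_spec()]; only the subunit molar mass is used.
#' @param substrate_conc Assay substrate concentration in mM (positive).
#' @param km Michaelis constant in mM (non-negative); `km = 0` means the
#'   assay is treated as saturating.
#' @return kcat in 1/s.
#' @seealso [specific_activity_from_kcat()] for the exact inverse.
#' @export
#' @examples
#' ry <- enzyme_spec("RY", 51440)
#' specific_activity_to_kcat(9.8, ry, substrate_conc = 30, km = 15.5)
specific_activity_to_kcat <- function(sa, enzyme, substrate_conc, km = 0) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (!is.numeric(sa) || any(sa < 0)) abort("`sa` must be non-negative (U/mg)")
  if (!is.numeric(km) || km < 0) abort("`km` must be non-negative (mM)")
  if (substrate_conc <= 0) {
    if (km > 0) abort("`substrate_conc` must be positive when km > 0")
    substrate_conc <- 1  # km = 0: factor is 1 regardless
  }
  k_obs <- sa * enzyme$subunit_molar_mass / 60000
  k_obs * (km + substrate_conc) / substrate_conc
}

#' Predicted specific activity from a turnover number
#'
#' Inverse of [specific_activity_to_kcat()]: the U/mg a preparation with the
#' given kcat would show when assayed at `substrate_conc`.
#'
#' @inheritParams specific_activity_to_kcat
#' @param kcat Turnover number in 1/s.
#' @return Specific activity in U/mg.
#' @export
specific_activity_from_kcat <- function(kcat, enzyme, substrate_conc, km = 0) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  if (!is.numeric(kcat) || any(kcat < 0)) abort("`kcat` must be non-negative (1/s)")
  if (substrate_conc <= 0) {
    if (km > 0) abort("`substrate_conc` must be positive when km > 0")
    substrate_conc <- 1
  }
  k_obs <- kcat * substrate_conc / (km + substrate_conc)
  k_obs * 60000 / enzyme$subunit_molar_mass
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' @param a Absorbance (non-negative; vectorised).
#' @param epsilon Molar extinction coefficient in 1/(mM cm), or the name of a
#'   compound in the constants table (`"UMP"`, `"Ura"`, `"PsiMP"`).
#' @param path Optical path length in cm (default 1).
#' @param dilution Fold dilution applied before measurement (default 1).
#' @return Concentration in mM.
#' @export
#' @examples
#' absorbance_to_conc(0.83, "Ura", dilution = 100)  # 10 mM
absorbance_to_conc <- function(a, epsilon, path = 1, dilution = 1) {
  if (is.character(epsilon)) {
    tab <- psi_constants()$extinction_mM
    if (!epsilon %in% names(tab)) {
      abort(paste0("no extinction coefficient for '", epsilon, "'"))
    }
    epsilon <- tab[[epsilon]]$epsilon
  }
  if (any(a < 0)) abort("absorbance must be non-negative")
  if (epsilon <= 0 || path <= 0) abort("`epsilon` and `path` must be positive")
  a * dilution / (epsilon * path)
}
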