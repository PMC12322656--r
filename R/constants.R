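the_constants <- new.env(parent = emptyenv())

#' Physical constants used by the package
#'
#' Reads the versioned constants table shipped with the package: enzyme
#' subunit molar masses, molar extinction coefficients, compound molar masses
#' and the kinetic parameter presets for wild-type PpnN, the RY variant and
#' the YeiN default rate law.
#'
#' The table stores the printed protein A280 coefficient for PpnN/RY even
#' though it is identical to YeiN's and inconsistent with the PpnN subunit
#' mass; that entry carries a `suspect` flag.
#'
#' @return A named list mirroring the YAML structure of
#'   `system.file("extdata", "constants.yml", package = "psicascade")`.
#' @export
#' @examples
#' psi_constants()$enzymes$RY$subunit_molar_mass
psi_constants <- function() {
  if (is.null(the_constants$tab)) {
    path <- system.file("extdata", "constants.yml", package = "psicascade")
    if (path == "") {
      # not installed (e.g. pkgload); fall back to the source tree
      path <- file.path("inst", "extdata", "constants.yml")
    }
    the_constants$tab <- yaml::read_yaml(path)
  }
  the_constants$tab
}

#' Molar mass of a compound tracked by the package
#'
#' @param compound One of `"PsiMP_free_acid"`, `"PsiMP_disodium"`,
#'   `"UMP_free_acid"`, `"UMP_disodium"`, `"Psi"`, `"Ura"`, `"Rib5P"`.
#'   Mass-based process metrics use the anhydrous free acid for PsiMP;
#'   the disodium salt mass applies to the isolated, gravimetric product.
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(compound) {
  mm <- psi_constants()$molar_mass
  if (!compound %in% names(mm)) {
    abort(paste0("unknown compound '", compound, "'; available: ",
                 paste(names(mm), collapse = ", ")))
  }
  mm[[compound]]
}
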