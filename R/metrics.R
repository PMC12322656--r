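# Biocatalytic process metrics: conversion yield, space-time yield,
# mass-based total turnover number, E-factor and scale-up volume, plus a
# consistency checker for the route-comparison table.

#' Describe the outcome of a preparative reaction
#'
#' @param substrate_in Substrate charged, mmol.
#' @param product_out Product recovered, mmol. May be derived from an
#'   isolated mass via [mmol_from_mass()].
#' @param titer Final product concentration, mM.
#' @param duration Reaction time, h.
#' @param volume Reaction volume, L.
#' @param enzyme_load Total enzyme loading, g/L.
#' @param product_molar_mass Product molar mass used for mass-based metrics,
#'   g/mol. Defaults to the anhydrous free acid of PsiMP; use the disodium
#'   mass only for gravimetric yields of the isolated salt.
#' @return A one-row tibble of class `reaction_outcome`.
#' @export
#' @examples
#' out <- reaction_outcome(substrate_in = 5,
#'                         product_out = mmol_from_mass(1.60, molar_mass("PsiMP_disodium")),
#'                         titer = 950, duration = 1, volume = 0.005,
#'                         enzyme_load = 3.0)
#' conversion_yield(out)
reaction_outcome <- function(substrate_in, product_out, titer = NA_real_,
                             duration = NA_real_, volume = NA_real_,
                             enzyme_load = NA_real_,
                             product_molar_mass = molar_mass("PsiMP_free_acid")) {
  vals <- c(substrate_in, product_out, titer, duration, volume, enzyme_load,
            product_molar_mass)
  if (any(vals < 0, na.rm = TRUE)) abort("all fields must be non-negative")
  if (!is.na(product_out) && product_out > substrate_in * (1 + 1e-9)) {
    abort("product_out cannot exceed substrate_in (1:1 stoichiometry)")
  }
  out <- tibble(substrate_in = substrate_in, product_out = product_out,
                titer = titer, duration = duration, volume = volume,
                enzyme_load = enzyme_load,
                product_molar_mass = product_molar_mass)
  class(out) <- c("reaction_outcome", class(out))
  out
}

#' Millimoles from an isolated mass
#'
#' @param mass_g Mass in g.
#' @param molar_mass_g_mol Molar mass in g/mol.
#' @return Amount in mmol.
#' @export
mmol_from_mass <- function(mass_g, molar_mass_g_mol) {
  1000 * mass_g / molar_mass_g_mol
}

#' Conversion yield of a reaction outcome
#'
#' @param outcome A [reaction_outcome()].
#' @param digits Rounding for display; the raw value is kept as attribute
#'   `raw`.
#' @return Percent yield (rounded to `digits`), with attribute `raw`.
#' @export
conversion_yield <- function(outcome, digits = 0) {
  if (outcome$substrate_in <= 0) abort("substrate_in must be positive")
  raw <- 100 * outcome$product_out / outcome$substrate_in
  structure(round(raw, digits), raw = raw)
}

#' Space-time yield in molar and mass units
#'
#' The two members are linked exactly by the product molar mass:
#' `g/L/h = mM/h x M / 1000`.
#'
#' @param outcome A [reaction_outcome()] with `titer` and `duration`.
#' @return A one-row tibble with `molar_mM_h` and `mass_g_L_h`.
#' @export
productivity <- function(outcome) {
  if (is.na(outcome$duration) || outcome$duration <= 0) {
    abort("duration must be positive (h)")
  }
  molar <- outcome$titer / outcome$duration
  tibble(molar_mM_h = molar,
         mass_g_L_h = molar * outcome$product_molar_mass / 1000)
}

#' Mass-based total turnover number
#'
#' Grams of product formed per gram of enzyme used, from the final titer:
#' `TON = titer x M / 1000 / enzyme_load`.
#'
#' @param outcome A [reaction_outcome()] with `titer` and `enzyme_load`.
#' @return TON in g product per g enzyme.
#' @export
ton_mass_based <- function(outcome) {
  if (is.na(outcome$enzyme_load) || outcome$enzyme_load <= 0) {
    abort("enzyme_load must be positive (g/L)")
  }
  (outcome$titer * outcome$product_molar_mass / 1000) / outcome$enzyme_load
}

#' Build a mass ledger for E-factor accounting
#'
#' @param inputs A data frame with columns `name`, `mass_g` and `category`
#'   (one of `"substrate"`, `"water"`, `"salt"`, `"base"`, `"enzyme"`).
#' @param product_mass_g Isolated product mass in g (positive).
#' @return A list of class `mass_ledger`.
#' @export
mass_ledger <- function(inputs, product_mass_g) {
  inputs <- as_tibble(inputs)
  stopifnot(all(c("name", "mass_g", "category") %in% names(inputs)))
  if (any(inputs$mass_g < 0)) abort("input masses must be non-negative")
  if (product_mass_g <= 0) abort("product mass must be positive")
  bad <- setdiff(inputs$category,
                 c("substrate", "water", "salt", "base", "enzyme"))
  if (length(bad)) abort(paste("unknown category:", paste(bad, collapse = ", ")))
  structure(list(inputs = inputs, product_mass_g = product_mass_g),
            class = "mass_ledger")
}

#' E-factor from a mass ledger
#'
#' `E = (sum of counted input masses - product mass) / product mass`,
#' floored at 0. The default accounting includes water and excludes the
#' enzymes, matching the usual convention for biocatalytic routes where the
#' enzyme production chain is kept outside the balance; both toggles are
#' exposed because E-factor accounting choices are rarely fully standard.
#'
#' @param ledger A [mass_ledger()].
#' @param include_water Count water among the inputs (default `TRUE`).
#' @param exclude_enzymes Leave enzymes out of the inputs (default `TRUE`).
#' @return Dimensionless E-factor.
#' @export
e_factor <- function(ledger, include_water = TRUE, exclude_enzymes = TRUE) {
  stopifnot(inherits(ledger, "mass_ledger"))
  inp <- ledger$inputs
  if (!include_water) inp <- inp[inp$category != "water", ]
  if (exclude_enzymes) inp <- inp[inp$category != "enzyme", ]
  max((sum(inp$mass_g) - ledger$product_mass_g) / ledger$product_mass_g, 0)
}

#' Reaction volume required for a target product mass
#'
#' @param target_product_mass Target mass in g.
#' @param titer Product titer in mM.
#' @param product_molar_mass Product molar mass in g/mol.
#' @return Required volume in L.
#' @export
#' @examples
#' scaleup_volume(1000, titer = 1000)  # ~3.1 L per kg at 1.0 M
scaleup_volume <- function(target_product_mass, titer,
                           product_molar_mass = molar_mass("PsiMP_free_acid")) {
  if (titer <= 0) abort("titer must be positive (mM)")
  target_product_mass / (titer * product_molar_mass / 1000)
}

#' Read the shipped route-comparison records
#'
#' @param path Optional path to a route CSV; defaults to the table shipped
#'   with the package (the four published biocatalytic routes to PsiMP/Psi).
#' @return A tibble of route records.
#' @export
read_route_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "route_table.csv", package = "psicascade")
    if (path == "") path <- file.path("inst", "extdata", "route_table.csv")
  }
  readr::read_csv(path, show_col_types = FALSE)
}

#' Check and format a route-comparison table
#'
#' Verifies the internal consistency of each record — the productivity pair
#' must be linked by the product molar mass (within `pair_tol` relative),
#' and the mass-based TON must follow from titer, molar mass and enzyme
#' loading (within `ton_tol`). Inconsistencies are flagged, never silently
#' corrected.
#'
#' @param records A tibble with columns `route_id`, `product`,
#'   `productivity_g_L_h`, `productivity_mM_h`, `ton_g_g`,
#'   `enzyme_loading_g_L`, `titer_mM` (other columns pass through).
#' @param pair_tol Relative tolerance for the productivity pair.
#' @param ton_tol Relative tolerance for the TON check.
#' @return The records with added columns `mass_from_molar`, `ton_expected`,
#'   `pair_consistent`, `ton_consistent`, `flags`.
#' @export
build_route_table <- function(records, pair_tol = 0.005, ton_tol = 0.025) {
  records <- as_tibble(records)
  if (nrow(records) == 0) abort("need at least one route record")
  mm <- map_dbl(records$product, function(p) {
    switch(p, PsiMP = molar_mass("PsiMP_free_acid"), Psi = molar_mass("Psi"),
           abort(paste("unknown product", p)))
  })
  out <- records |>
    mutate(
      mass_from_molar = .data$productivity_mM_h * mm / 1000,
      ton_expected = .data$titer_mM * mm / 1000 / .data$enzyme_loading_g_L,
      pair_consistent = abs(.data$mass_from_molar - .data$productivity_g_L_h) /
        .data$productivity_g_L_h <= pair_tol,
      ton_consistent = abs(.data$ton_expected - .data$ton_g_g) /
        .data$ton_g_g <= ton_tol
    )
  out$flags <- pmap(list(out$pair_consistent, out$ton_consistent),
                    function(p, t) {
                      f <- character()
                      if (!p) f <- c(f, "productivity pair inconsistent")
                      if (!t) f <- c(f, "TON inconsistent with titer/loading")
                      paste(f, collapse = "; ")
                    }) |> unlist()
  out
}
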