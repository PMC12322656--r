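#' Tidy a kinetic fit
#'
#' @param x A fit from [fit_michaelis_menten()],
#'   [fit_competitive_inhibition()] or [fit_ki_from_progress_curve()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`. Units: `Vmax`
#'   mM/min, `Km`/`Ki` mM, `kcat` 1/s.
#' @exportS3Method generics::tidy
tidy.kin_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of a kinetic fit
#'
#' @inheritParams tidy.kin_fit
#' @return A one-row tibble with `residual_norm` (mM/min), `n_points`,
#'   `converged`, and the derived quantities `efficiency` (kcat/Km,
#'   1/(s mM)) and `km_over_ki` when defined.
#' @exportS3Method generics::glance
glance.kin_fit <- function(x, ...) {
  p <- x$params
  tibble(
    residual_norm = x$residual_norm,
    n_points = x$n_points,
    converged = x$converged,
    efficiency = if (!is.null(p)) p$kcat / p$km else NA_real_,
    km_over_ki = if (!is.null(p) && !is.null(p$ki)) p$km / p$ki else NA_real_,
    notes = if (length(x$notes)) paste(x$notes, collapse = "; ") else NA_character_
  )
}

#' @export
print.kin_fit <- function(x, ...) {
  kind <- class(x)[1]
  label <- c(mm_fit = "Michaelis-Menten fit",
             ci_fit = "competitive-inhibition fit (global)",
             ki_fit = "Ki fit from progress curve")[[kind]]
  cat("<", label, "> on ", x$n_points, " points (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  if (!is.null(x$params)) print(x$params)
  df <- as.data.frame(x$estimates)
  print(df, row.names = FALSE, digits = 4)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
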