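#' Plot a progress curve
#'
#' Species concentrations against time.
#'
#' @param object A [progress_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.progress_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_min",
                              names_to = "species", values_to = "conc_mM")
  long$species <- sub("_mM$", "", long$species)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$conc_mM,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (mM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an initial-rate fit
#'
#' Data points with the fitted hyperbola, one curve per inhibitor level.
#'
#' @param object A fit of class `kin_fit` from the initial-rate fitters.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.kin_fit <- function(object, ...) {
  d <- object$data
  if (!all(c("S_mM", "rate_mM_per_min") %in% names(d))) {
    abort("autoplot is available for initial-rate fits only")
  }
  s_line <- seq(0, max(d$S_mM) * 1.05, length.out = 200)
  levels <- sort(unique(d$I_mM))
  pred <- list_rbind(map(levels, function(i) {
    tibble(S_mM = s_line, I_mM = i,
           rate_mM_per_min = rate_inhibited_mm(object$params, object$enzyme,
                                               s_line, i))
  }))
  ggplot2::ggplot(d, ggplot2::aes(.data$S_mM, .data$rate_mM_per_min,
                                  colour = factor(.data$I_mM))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred) +
    ggplot2::labs(x = "[UMP] (mM)", y = "rate (mM/min)",
                  colour = "[Rib5P] (mM)") +
    ggplot2::theme_minimal()
}

#' Plot an enzyme-ratio sweep
#'
#' Conversion and product yield against the YeiN:PpnN mass ratio.
#'
#' @param object A tibble from [enzyme_ratio_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ratio_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("conversion_pct", "psimp_pct"),
                              names_to = "metric", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(.data$ratio, .data$pct,
                                     colour = .data$metric)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "YeiN : PpnN mass ratio", y = "percent of initial UMP",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
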