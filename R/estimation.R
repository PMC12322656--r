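# Nonlinear least-squares estimation of kinetic constants from initial-rate
# grids and from progress curves. Parameters are fitted on the log scale to
# enforce positivity; the loss is unweighted squared residuals on rates
# (matching the conventions of standard initial-rate regression software).

new_kin_fit <- function(subclass, estimates, params, enzyme, data,
                        residual_norm, n_points, converged, notes = character()) {
  structure(
    list(estimates = estimates, params = params, enzyme = enzyme,
         data = data, residual_norm = residual_norm, n_points = n_points,
         converged = converged, notes = notes),
    class = c(subclass, "kin_fit"))
}

check_rate_data <- function(data, need_inhibitor = FALSE) {
  data <- as_tibble(data)
  if (!all(c("S_mM", "rate_mM_per_min") %in% names(data))) {
    abort("data must have columns `S_mM` and `rate_mM_per_min`")
  }
  if (!"I_mM" %in% names(data)) data$I_mM <- 0
  if (any(data$S_mM < 0) || any(data$I_mM < 0)) {
    abort("concentrations must be non-negative")
  }
  if (any(data$rate_mM_per_min < 0)) abort("rates must be non-negative")
  data
}

mm_start <- function(s, rate) {
  # Vmax0 = 1.2 x max rate; Km0 = S nearest half of Vmax0; Ki0 = Km0/10
  v0 <- 1.2 * max(rate)
  k0 <- s[which.min(abs(rate - v0 / 2))]
  if (k0 <= 0) k0 <- stats::median(s[s > 0])
  list(v0 = v0, k0 = k0)
}

# Back-transform log-scale coefficients and their standard errors (delta
# method) into a broom-style estimates tibble.
log_coef_tibble <- function(fit, terms) {
  sm <- summary(fit)$coefficients
  est <- exp(sm[, "Estimate"])
  se <- est * sm[, "Std. Error"]
  tibble(term = terms, estimate = unname(est), std.error = unname(se))
}

#' Fit the Michaelis-Menten law to uninhibited initial rates
#'
#' Least-squares estimation of `Vmax` and `Km` from `(S, rate)` pairs, with
#' `kcat` recovered through `Vmax = kcat * [E]` from the enzyme loading.
#'
#' @param data A data frame with columns `S_mM` and `rate_mM_per_min`
#'   (an `I_mM` column, if present, must be all zero). At least 4 distinct
#'   substrate concentrations are required.
#' @param enzyme The [enzyme_spec()] used to collect the rates (its
#'   `mass_conc` converts `Vmax` to `kcat`).
#' @return An object of class `mm_fit` (also `kin_fit`) with broom-style
#'   [tidy()] and [glance()] methods. Non-convergence is reported through the
#'   `converged` flag, not as an error.
#' @export
#' @examples
#' wt <- preset_enzyme("WT_PPNN")
#' d <- gen_initial_rates("WT_PPNN", s_grid = c(0.5, 1, 2, 5, 15, 30))
#' fit <- fit_michaelis_menten(d, wt)
#' tidy(fit)
fit_michaelis_menten <- function(data, enzyme) {
  data <- check_rate_data(data)
  if (any(data$I_mM > 0)) {
    abort("data contains inhibited points; use fit_competitive_inhibition()")
  }
  if (n_distinct(data$S_mM) < 4) {
    abort("need at least 4 distinct substrate concentrations")
  }
  st <- mm_start(data$S_mM, data$rate_mM_per_min)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate_mM_per_min ~ exp(lv) * S_mM / (exp(lk) + S_mM),
      data = data, start = list(lv = log(st$v0), lk = log(st$k0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  finish_rate_fit("mm_fit", fit, c("Vmax", "Km"), data, enzyme)
}

#' Globally fit the competitive-inhibition rate law
#'
#' Simultaneous least-squares estimation of `Vmax` (hence `kcat`), `Km` and
#' `Ki` over an initial-rate grid spanning several inhibitor levels, using
#' `v = Vmax S / (Km (1 + I/Ki) + S)`.
#'
#' If the data carry no inhibitor variation (all `I_mM` zero) `Ki` is not
#' identifiable; the fit falls back to the plain Michaelis-Menten law and is
#' flagged through its `notes`.
#'
#' @param data A data frame with columns `S_mM`, `I_mM`, `rate_mM_per_min`.
#' @inheritParams fit_michaelis_menten
#' @return An object of class `ci_fit` (also `kin_fit`).
#' @export
fit_competitive_inhibition <- function(data, enzyme) {
  data <- check_rate_data(data)
  if (n_distinct(data$S_mM) < 4) {
    abort("need at least 4 distinct substrate concentrations")
  }
  if (all(data$I_mM == 0)) {
    out <- fit_michaelis_menten(data, enzyme)
    out$notes <- c(out$notes,
                   "Ki unidentifiable: no inhibitor variation in the data")
    class(out) <- c("ci_fit", "kin_fit")
    return(out)
  }
  base <- data[data$I_mM == 0, ]
  if (nrow(base) == 0) {
    abort("global inhibition fit requires an uninhibited (I = 0) series")
  }
  st <- mm_start(base$S_mM, base$rate_mM_per_min)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate_mM_per_min ~ exp(lv) * S_mM / (exp(lk) * (1 + I_mM / exp(li)) + S_mM),
      data = data,
      start = list(lv = log(st$v0), lk = log(st$k0), li = log(st$k0 / 10)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  finish_rate_fit("ci_fit", fit, c("Vmax", "Km", "Ki"), data, enzyme)
}

finish_rate_fit <- function(subclass, fit, terms, data, enzyme) {
  if (is.null(fit)) {
    est <- tibble(term = c(terms, "kcat"), estimate = NA_real_,
                  std.error = NA_real_)
    return(new_kin_fit(subclass, est, NULL, enzyme, data,
                       residual_norm = NA_real_, n_points = nrow(data),
                       converged = FALSE, notes = "optimizer failed"))
  }
  est <- log_coef_tibble(fit, terms)
  e_mM <- subunit_molarity(enzyme)
  vrow <- est[est$term == "Vmax", ]
  kcat <- vrow$estimate / (60 * e_mM)  # mM/min -> 1/s
  est <- bind_rows(est, tibble(term = "kcat", estimate = kcat,
                               std.error = vrow$std.error / (60 * e_mM)))
  km <- est$estimate[est$term == "Km"]
  ki <- if ("Ki" %in% est$term) est$estimate[est$term == "Ki"] else NULL
  params <- kinetic_params(kcat, km, ki)
  new_kin_fit(subclass, est, params, enzyme, data,
              residual_norm = sqrt(sum(stats::resid(fit)^2)),
              n_points = nrow(data), converged = TRUE)
}

#' Per-inhibitor-level apparent Michaelis-Menten fits
#'
#' Fits the plain Michaelis-Menten law independently at each inhibitor level.
#' Under purely competitive inhibition the apparent `kcat` is constant across
#' levels while `Km_app(I)/Km_app(0) = 1 + I/Ki`.
#'
#' @inheritParams fit_competitive_inhibition
#' @return A tibble with one row per inhibitor level: `I_mM`, `kcat_app`,
#'   `km_app`, their standard errors, `fold_km` (relative to the `I = 0`
#'   level when present) and `converged`.
#' @export
fit_apparent_km <- function(data, enzyme) {
  data <- check_rate_data(data)
  levels <- sort(unique(data$I_mM))
  rows <- map(levels, function(i) {
    sub <- data[data$I_mM == i, c("S_mM", "rate_mM_per_min")]
    f <- fit_michaelis_menten(sub, enzyme)
    td <- tidy(f)
    tibble(I_mM = i,
           kcat_app = td$estimate[td$term == "kcat"],
           kcat_se = td$std.error[td$term == "kcat"],
           km_app = td$estimate[td$term == "Km"],
           km_se = td$std.error[td$term == "Km"],
           converged = f$converged)
  })
  out <- list_rbind(rows)
  km0 <- out$km_app[out$I_mM == 0]
  out$fold_km <- if (length(km0) == 1) out$km_app / km0 else NA_real_
  out
}

#' Estimate Ki from a hydrolysis progress curve
#'
#' Single-parameter fit of the competitive inhibition constant: `kcat` and
#' `Km` are held fixed at their initial-rate values and `Ki` is chosen to
#' minimise the squared deviation between the observed and the simulated
#' UMP time course (the simulation uses [simulate_hydrolysis()] at the
#' curve's own time points).
#'
#' Curves carrying no inhibition signal push the estimate to very large `Ki`;
#' estimates above `1000 x Km` are flagged as "no inhibition detectable".
#'
#' @param curve A data frame with columns `time_min` and `UMP_mM` (at least
#'   4 points); typically a [progress_curve()].
#' @param kcat,km Fixed values from the initial-rate characterisation
#'   (1/s, mM).
#' @param enzyme The [enzyme_spec()] at the loading used for the curve.
#' @param ki_range Search interval for `Ki` in mM.
#' @return An object of class `ki_fit` (also `kin_fit`).
#' @export
fit_ki_from_progress_curve <- function(curve, kcat, km, enzyme,
                                       ki_range = c(1e-4, 1e5)) {
  curve <- as_tibble(curve)
  if (!all(c("time_min", "UMP_mM") %in% names(curve))) {
    abort("curve must have columns `time_min` and `UMP_mM`")
  }
  if (nrow(curve) < 4) abort("progress curve must have at least 4 points")
  curve <- arrange(curve, .data$time_min)
  s0 <- curve$UMP_mM[1]
  conv <- 1 - min(curve$UMP_mM) / s0
  if (conv < 0.5) {
    warn(sprintf(
      "progress curve covers only %.0f%% conversion; Ki may be poorly determined",
      100 * conv))
  }
  t_grid <- curve$time_min
  if (t_grid[1] != 0) t_grid <- c(0, t_grid)
  loss <- function(lki) {
    p <- kinetic_params(kcat, km, exp(lki))
    sim <- simulate_hydrolysis(enzyme, p, s0, t_grid)
    pred <- sim$UMP_mM[match(curve$time_min, sim$time_min)]
    sum((curve$UMP_mM - pred)^2)
  }
  opt <- optimize(loss, log(ki_range), tol = 1e-9)
  ki <- exp(opt$minimum)
  # curvature-based standard error: var(Ki) ~ 2 sigma^2 / d2SS/dKi2
  h <- 1e-3
  d2 <- (loss(log(ki) + h) - 2 * opt$objective + loss(log(ki) - h)) / h^2
  sigma2 <- opt$objective / max(nrow(curve) - 1, 1)
  se <- if (d2 > 0) ki * sqrt(2 * sigma2 / d2) else NA_real_
  notes <- character()
  if (ki >= 1000 * km) notes <- "no inhibition detectable (Ki >= 1000 x Km)"
  if (ki <= ki_range[1] * 1.01 || ki >= ki_range[2] * 0.99) {
    notes <- c(notes, "Ki estimate at the edge of the search interval")
  }
  est <- tibble(term = "Ki", estimate = ki, std.error = se)
  new_kin_fit("ki_fit", est, kinetic_params(kcat, km, ki), enzyme, curve,
              residual_norm = sqrt(opt$objective), n_points = nrow(curve),
              converged = TRUE, notes = notes)
}

#' Initial rate from the early phase of a time course
#'
#' Implements the below-20%-conversion rule: the rate is the slope of a
#' linear fit over the prefix of points with substrate conversion under the
#' cutoff (at least `min_points` points are always used).
#'
#' @param timecourse A data frame with columns `time_min` and `conc_mM`.
#' @param s0 Initial substrate concentration in mM.
#' @param species Whether `conc_mM` tracks the `"product"` (rising) or the
#'   `"substrate"` (falling).
#' @param max_conversion Conversion cutoff as a fraction (default 0.2).
#' @param min_points Minimum number of points in the linear fit.
#' @return The initial rate in mM/min (positive), with the number of points
#'   used as attribute `n_used`.
#' @export
initial_rate_from_timecourse <- function(timecourse, s0,
                                         species = c("product", "substrate"),
                                         max_conversion = 0.2,
                                         min_points = 3) {
  species <- match.arg(species)
  tc <- arrange(as_tibble(timecourse), .data$time_min)
  if (!all(c("time_min", "conc_mM") %in% names(tc))) {
    abort("timecourse must have columns `time_min` and `conc_mM`")
  }
  conv <- if (species == "product") tc$conc_mM / s0 else 1 - tc$conc_mM / s0
  keep <- max(which(conv <= max_conversion), min_points)
  keep <- min(max(keep, min_points), nrow(tc))
  if (nrow(tc) < min_points) abort("time course has too few points")
  sl <- coef(lm(conc_mM ~ time_min, data = tc[seq_len(keep), ]))[["time_min"]]
  structure(abs(sl), n_used = keep)
}

#' Bootstrap confidence intervals for an initial-rate fit
#'
#' Resamples data points with replacement, refits, and reports percentile
#' confidence intervals for every parameter.
#'
#' @param data Initial-rate data as for the `fitter`.
#' @param enzyme An [enzyme_spec()].
#' @param fitter One of [fit_michaelis_menten()] or
#'   [fit_competitive_inhibition()].
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with `term`, `estimate` (full-data fit), `conf.low`,
#'   `conf.high`, and `n_boot_ok` (replicates that converged).
#' @export
bootstrap_fit <- function(data, enzyme, fitter = fit_michaelis_menten,
                          n_boot = 500, level = 0.95, seed = NULL) {
  data <- check_rate_data(data)
  full <- fitter(data, enzyme)
  one <- function() {
    idx <- sample.int(nrow(data), replace = TRUE)
    f <- tryCatch(fitter(data[idx, ], enzyme), error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NULL)
    setNames(f$estimates$estimate, f$estimates$term)
  }
  draw_all <- function() purrr::compact(map(seq_len(n_boot), ~ one()))
  draws <- if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
  mat <- do.call(rbind, draws)
  alpha <- (1 - level) / 2
  td <- tidy(full)
  ci <- map(td$term, function(tm) {
    qs <- quantile(mat[, tm], c(alpha, 1 - alpha), names = FALSE)
    tibble(term = tm, conf.low = qs[1], conf.high = qs[2])
  })
  left_join(td[, c("term", "estimate")], list_rbind(ci), by = "term") |>
    mutate(n_boot_ok = nrow(mat))
}
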