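test_that("Michaelis-Menten fit recovers noiseless generating values exactly", {
  cases <- list(list(preset = "WT_PPNN", kcat = 2.6, km = 1.1, eff = 2.4),
                list(preset = "RY", kcat = 13.4, km = 15.5, eff = 0.9))
  for (cs in cases) {
    e <- preset_enzyme(cs$preset)
    d <- gen_initial_rates(cs$preset)
    f <- fit_michaelis_menten(d, e)
    expect_true(f$converged)
    td <- tidy(f)
    expect_equal(td$estimate[td$term == "kcat"], cs$kcat, tolerance = 1e-3)
    expect_equal(td$estimate[td$term == "Km"], cs$km, tolerance = 1e-3)
    expect_equal(round(glance(f)$efficiency, 1), cs$eff)
    expect_lt(f$residual_norm, 1e-8)
  }
})

test_that("Michaelis-Menten fit rejects degenerate or inhibited data", {
  e <- preset_enzyme("WT_PPNN")
  flat <- tibble::tibble(S_mM = rep(5, 6), rate_mM_per_min = 1:6 / 10)
  expect_error(fit_michaelis_menten(flat, e), "distinct")
  d <- gen_initial_rates("WT_PPNN", i_grid = c(0, 10))
  expect_error(fit_michaelis_menten(d, e), "fit_competitive_inhibition")
})

test_that("global competitive fit recovers kcat, Km and Ki exactly", {
  for (preset in c("WT_PPNN", "RY")) {
    e <- preset_enzyme(preset)
    p <- preset_params(preset)
    d <- gen_initial_rates(preset, i_grid = c(0, 2, 10))
    f <- fit_competitive_inhibition(d, e)
    td <- tidy(f)
    expect_equal(td$estimate[td$term == "kcat"], p$kcat, tolerance = 1e-3)
    expect_equal(td$estimate[td$term == "Km"], p$km, tolerance = 1e-3)
    expect_equal(td$estimate[td$term == "Ki"], p$ki, tolerance = 1e-3)
  }
})

test_that("global fits reproduce the derived Km/Ki ratios and Ki fold-difference", {
  fits <- lapply(c("WT_PPNN", "RY"), function(preset) {
    fit_competitive_inhibition(gen_initial_rates(preset, i_grid = c(0, 2, 10)),
                               preset_enzyme(preset))
  })
  ratios <- vapply(fits, function(f) glance(f)$km_over_ki, numeric(1))
  expect_equal(round(ratios[1]), 11)       # wild type: 1.1 / 0.1
  expect_equal(ratios[2], 12.9167, tolerance = 1e-3)  # RY: 15.5 / 1.2 -> 13
  expect_equal(round(ratios[2]), 13)
  kis <- vapply(fits, function(f) f$params$ki, numeric(1))
  expect_equal(kis[2] / kis[1], 12, tolerance = 1e-3)
})

test_that("Ki is flagged unidentifiable without inhibitor variation", {
  d <- gen_initial_rates("WT_PPNN")  # all I = 0
  f <- fit_competitive_inhibition(d, preset_enzyme("WT_PPNN"))
  expect_true(f$converged)
  expect_match(paste(f$notes, collapse = " "), "unidentifiable")
  expect_null(f$params$ki)
})

test_that("fitters are invariant to point order and dataset duplication", {
  d <- gen_initial_rates("RY", i_grid = c(0, 2, 10),
                         noise = noise_model("multiplicative-gaussian",
                                             cv = 0.1, seed = 3))
  e <- preset_enzyme("RY")
  ref <- tidy(fit_competitive_inhibition(d, e))$estimate
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(tidy(fit_competitive_inhibition(shuffled, e))$estimate, ref,
               tolerance = 1e-6)
  doubled <- dplyr::bind_rows(d, d)
  expect_equal(tidy(fit_competitive_inhibition(doubled, e))$estimate, ref,
               tolerance = 1e-6)
})

test_that("with 10% noise the median Ki error over 200 replicates is <= 15%", {
  e <- preset_enzyme("WT_PPNN")
  set.seed(202)
  errs <- replicate(200, {
    d <- gen_initial_rates("WT_PPNN", i_grid = c(0, 2, 10),
                           noise = noise_model("multiplicative-gaussian",
                                               cv = 0.10))
    f <- fit_competitive_inhibition(d, e)
    td <- tidy(f)
    abs(td$estimate[td$term == "Ki"] - 0.1) / 0.1
  })
  expect_lte(median(errs), 0.15)
})

test_that("per-level fits show constant kcat and the competitive Km fold-change", {
  # wild type: at 10 mM Rib5P the apparent Km is Km (1 + 10/0.1) = 111.1 mM
  wt_data <- gen_initial_rates("WT_PPNN", s_grid = c(0.5, 1, 2, 5, 15, 30,
                                                     100, 300, 1000),
                               i_grid = c(0, 2, 10))
  app <- fit_apparent_km(wt_data, preset_enzyme("WT_PPNN"))
  expect_equal(app$km_app[app$I_mM == 10], 111.1, tolerance = 1e-3)
  expect_lt(diff(range(app$kcat_app)) / mean(app$kcat_app), 0.01)
  expect_equal(app$kcat_app[app$I_mM == 0], 2.6, tolerance = 1e-3)
  # the I = 0 level reproduces the uninhibited fit
  mm <- tidy(fit_michaelis_menten(gen_initial_rates("WT_PPNN",
                                                    s_grid = c(0.5, 1, 2, 5, 15,
                                                               30, 100, 300, 1000)),
                                  preset_enzyme("WT_PPNN")))
  expect_equal(app$km_app[app$I_mM == 0], mm$estimate[mm$term == "Km"])
  # RY: fold-change 1 + 10/1.2 = 9.33 (the model's prediction)
  ry_data <- gen_initial_rates("RY", s_grid = c(2, 5, 10, 20, 40, 80, 200, 600),
                               i_grid = c(0, 10))
  app_ry <- fit_apparent_km(ry_data, preset_enzyme("RY"))
  expect_equal(app_ry$fold_km[app_ry$I_mM == 10], 1 + 10 / 1.2,
               tolerance = 1e-3)
})

test_that("Ki is recovered from noiseless progress curves", {
  cases <- list(list(enz = ry_enzyme(), kcat = 13.4, km = 15.5, ki = 1.2,
                     t_end = 180),
                list(enz = wt_enzyme(), kcat = 2.6, km = 1.1, ki = 0.1,
                     t_end = 600))
  for (cs in cases) {
    p <- kinetic_params(cs$kcat, cs$km, cs$ki)
    curve <- simulate_hydrolysis(cs$enz, p, 100, seq(0, cs$t_end, 2))
    f <- fit_ki_from_progress_curve(curve, cs$kcat, cs$km, cs$enz)
    expect_equal(f$params$ki, cs$ki, tolerance = 5e-3)
  }
})

test_that("an uninhibited progress curve is flagged as no inhibition", {
  e <- ry_enzyme()
  curve <- simulate_hydrolysis(e, kinetic_params(13.4, 15.5), 100,
                               seq(0, 60, 2))
  f <- fit_ki_from_progress_curve(curve, 13.4, 15.5, e)
  expect_gte(f$params$ki, 1000 * 15.5)
  expect_match(paste(f$notes, collapse = " "), "no inhibition")
  short <- curve[1:3, ]
  expect_error(fit_ki_from_progress_curve(short, 13.4, 15.5, e), "4 points")
})

test_that("the below-20%-conversion rule extracts the initial rate", {
  # uninhibited curve: the early phase is close to linear, so the rule is
  # accurate (under strong product inhibition it is biased low by design)
  e <- ry_enzyme(0.1)
  p <- kinetic_params(13.4, 15.5)
  curve <- simulate_hydrolysis(e, p, 100, seq(0, 40, 1))
  tc <- tibble::tibble(time_min = curve$time_min, conc_mM = curve$Ura_mM)
  v0 <- initial_rate_from_timecourse(tc, s0 = 100, species = "product")
  true_v0 <- rate_inhibited_mm(p, e, 100, 0)
  expect_equal(as.numeric(v0), true_v0, tolerance = 0.05)
  sub <- tibble::tibble(time_min = curve$time_min, conc_mM = curve$UMP_mM)
  v0s <- initial_rate_from_timecourse(sub, s0 = 100, species = "substrate")
  expect_equal(as.numeric(v0s), true_v0, tolerance = 0.05)
})

test_that("bootstrap intervals cover the generating parameters", {
  # scaled-down check of the coverage property (full sweep in the vignette's
  # conditions): 30 duplicated-grid datasets at CV = 10%, 300 replicates
  e <- preset_enzyme("WT_PPNN")
  s_grid <- rep(default_s_grid("WT_PPNN"), 2)
  set.seed(11)
  cover <- replicate(30, {
    d <- gen_initial_rates("WT_PPNN", s_grid = s_grid,
                           noise = noise_model("multiplicative-gaussian",
                                               cv = 0.10))
    b <- bootstrap_fit(d, e, n_boot = 300)
    b$conf.low[b$term == "Km"] <= 1.1 && b$conf.high[b$term == "Km"] >= 1.1
  })
  expect_gte(mean(cover), 0.9)
})
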