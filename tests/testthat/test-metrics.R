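preparative_outcome <- function() {
  reaction_outcome(
    substrate_in = 5,
    product_out = mmol_from_mass(1.60, molar_mass("PsiMP_disodium")),
    titer = 950, duration = 1, volume = 0.005, enzyme_load = 3.0)
}

test_that("conversion yield matches the gravimetric worked example", {
  out <- preparative_outcome()
  y <- conversion_yield(out)
  expect_equal(as.numeric(y), 87)              # display value
  expect_equal(attr(y, "raw"), 86.9, tolerance = 1e-3)
  expect_equal(as.numeric(conversion_yield(reaction_outcome(3, 3))), 100)
  expect_equal(as.numeric(conversion_yield(reaction_outcome(100, 95))), 95)
  expect_error(conversion_yield(reaction_outcome(0, 0)), "positive")
  expect_error(reaction_outcome(5, 6), "stoichiometry")
})

test_that("productivity pair is linked exactly by the product molar mass", {
  out <- reaction_outcome(10, 9, titer = 906, duration = 1)
  p <- productivity(out)
  expect_equal(p$molar_mM_h, 906)
  expect_equal(p$mass_g_L_h, 293.7, tolerance = 1e-3)   # prints as 294
  out4 <- reaction_outcome(10, 9, titer = 117, duration = 1)
  expect_equal(productivity(out4)$mass_g_L_h, 37.9, tolerance = 1e-2)
  zero <- productivity(reaction_outcome(10, 9, titer = 0, duration = 2))
  expect_equal(unlist(zero), c(molar_mM_h = 0, mass_g_L_h = 0))
  expect_error(productivity(reaction_outcome(10, 9, titer = 5, duration = 0)),
               "duration")
})

test_that("mass-based TON matches the worked examples and is homogeneous", {
  out <- reaction_outcome(10, 9.5, titer = 950, enzyme_load = 3.0)
  expect_equal(ton_mass_based(out), 102.7, tolerance = 1e-3)
  expect_gte(ton_mass_based(out), 100)
  r1 <- reaction_outcome(10, 9.7, titer = 970, enzyme_load = 4.3)
  expect_equal(ton_mass_based(r1), 73.1, tolerance = 1e-2)  # prints as 74
  doubled <- reaction_outcome(10, 9.5, titer = 950, enzyme_load = 6.0)
  expect_equal(ton_mass_based(doubled), ton_mass_based(out) / 2)
  expect_error(ton_mass_based(reaction_outcome(10, 9, titer = 1,
                                               enzyme_load = 0)), "enzyme")
})

preparative_ledger <- function(water_g = 4.5) {
  mass_ledger(
    tibble::tibble(
      name = c("UMP disodium", "MnCl2", "water", "NaOH", "RY", "YeiN"),
      mass_g = c(1.84, 0.009, water_g, 0.04, 0.005, 0.010),
      category = c("substrate", "salt", "water", "base", "enzyme", "enzyme")),
    product_mass_g = 1.60)
}

test_that("E-factor arithmetic, floor and monotonicity", {
  simple <- mass_ledger(tibble::tibble(name = "in", mass_g = 4.0,
                                       category = "substrate"),
                        product_mass_g = 1.6)
  expect_equal(e_factor(simple), 1.5)
  even <- mass_ledger(tibble::tibble(name = "in", mass_g = 1.6,
                                     category = "substrate"),
                      product_mass_g = 1.6)
  expect_equal(e_factor(even), 0)
  expect_error(mass_ledger(tibble::tibble(name = "x", mass_g = 1,
                                          category = "substrate"), 0),
               "positive")
})

test_that("the preparative ledger lands near the reported E-factor of 3", {
  ef <- e_factor(preparative_ledger())
  expect_gt(ef, 2.5)
  expect_lt(ef, 3.5)
  # accounting sensitivity: excluding water collapses the balance
  expect_lt(e_factor(preparative_ledger(), include_water = FALSE), 0.5)
  # counting the enzymes raises it only marginally
  with_enz <- e_factor(preparative_ledger(), exclude_enzymes = FALSE)
  expect_gt(with_enz, ef)
  expect_lt(with_enz - ef, 0.05)
})

test_that("scale-up volume reproduces the 3.1 L per kg example", {
  expect_equal(scaleup_volume(1000, titer = 1000), 3.08, tolerance = 1e-2)
  expect_equal(scaleup_volume(0, titer = 1000), 0)
  expect_equal(scaleup_volume(1000, titer = 950), 3.25, tolerance = 1e-2)
  expect_error(scaleup_volume(1000, titer = 0), "positive")
})

test_that("metrics are invariant to simultaneous volume scaling", {
  small <- reaction_outcome(5, 4.35, titer = 950, duration = 1,
                            volume = 0.005, enzyme_load = 3.0)
  big <- reaction_outcome(5000, 4350, titer = 950, duration = 1,
                          volume = 5, enzyme_load = 3.0)
  expect_equal(as.numeric(conversion_yield(small)),
               as.numeric(conversion_yield(big)))
  expect_equal(productivity(small), productivity(big))
  expect_equal(ton_mass_based(small), ton_mass_based(big))
})

test_that("TON x enzyme load equals the titer in mass units", {
  set.seed(5)
  for (r in 1:20) {
    out <- reaction_outcome(10, 9, titer = runif(1, 100, 1500),
                            enzyme_load = runif(1, 0.5, 10))
    expect_equal(ton_mass_based(out) * out$enzyme_load,
                 out$titer * out$product_molar_mass / 1000)
  }
})

test_that("published route records round-trip through the consistency check", {
  routes <- read_route_table()
  checked <- build_route_table(routes)
  expect_equal(nrow(checked), 4)
  expect_true(all(checked$pair_consistent))
  # the Rib/Ura route's printed TON does not follow from titer and loading
  expect_false(checked$ton_consistent[checked$route_id == 4])
  expect_true(all(checked$ton_consistent[checked$route_id != 4]))
  # a 900 mM/h molar member against 294 g/L/h is flagged
  bad <- routes[routes$route_id == 5, ]
  bad$productivity_mM_h <- 900
  expect_false(build_route_table(bad)$pair_consistent)
  # single-record table works
  expect_equal(nrow(build_route_table(routes[1, ])), 1)
  expect_error(build_route_table(routes[0, ]), "at least one")
})
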