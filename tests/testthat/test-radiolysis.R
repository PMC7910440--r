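test_that("production rate reproduces a single-term hand calculation", {
  # A = 1e6 decays/yr/g, rho(1-phi) = 2.5*0.2, E = 5 MeV, G = 1 per 100 eV
  acts <- structure(c(X = 1e6), class = "isotope_activity")
  energies <- data.frame(row.names = "X", alpha = 5, beta = 0, gamma = 0)
  yields <- data.frame(medium = "test", radiation = c("alpha", "gamma"),
                       G_mean = c(1.0, 0))
  p <- production_rate(acts, 2.5, 0.8, "test", energies, yields)
  expect_equal(p$molecules_cm3_yr, 1e6 * 0.5 * 5e6 * 0.01, tolerance = 1e-12)
  expect_equal(p$mol_cm3_yr, p$molecules_cm3_yr / 6.02214076e23, tolerance = 1e-12)
})

test_that("production is zero without activity or solid phase, and validates inputs", {
  zero <- activities(isotope_abundances(elemental_composition(0, 0, K2O_wt_pct = 0)))
  expect_equal(production_rate(zero, 2.6, 0.5, "abyssal_clay")$molecules_cm3_yr, 0)
  a <- activities(isotope_abundances(clay_comp()))
  expect_equal(production_rate(a, 2.6, 1, "abyssal_clay")$molecules_cm3_yr, 0)
  expect_error(production_rate(a, 2.6, 1.2, "abyssal_clay"), "phi")
  expect_error(production_rate(a, 2.6, 0.5, "basalt"), "basalt")
})

test_that("production is linear in each activity and in (1 - phi)", {
  a <- activities(isotope_abundances(clay_comp()))
  p1 <- production_rate(a, 2.6, 0.8, "abyssal_clay")$molecules_cm3_yr
  a2 <- structure(unclass(a) * 3, class = "isotope_activity")
  expect_equal(production_rate(a2, 2.6, 0.8, "abyssal_clay")$molecules_cm3_yr,
               3 * p1, tolerance = 1e-12)
  # additive over isotopes
  parts <- vapply(seq_along(a), function(i) {
    ai <- unclass(a) * 0; ai[i] <- unclass(a)[i]
    production_rate(structure(ai, class = "isotope_activity"),
                    2.6, 0.8, "abyssal_clay")$molecules_cm3_yr
  }, numeric(1))
  expect_equal(sum(parts), p1, tolerance = 1e-12)
  # linear in solid fraction
  p_half <- production_rate(a, 2.6, 0.9, "abyssal_clay")$molecules_cm3_yr
  expect_equal(p_half / p1, 0.1 / 0.2, tolerance = 1e-12)
})

test_that("oxidant production equals H2 production in electron equivalents, exactly", {
  a <- activities(isotope_abundances(clay_comp()))
  for (phi in c(0, 0.3, 0.83, 0.999)) {
    p <- production_rate(a, 2.6, phi, "abyssal_clay")
    expect_identical(oxidant_production(p), p$eeq_mol_cm3_yr)
    expect_identical(p$eeq_mol_cm3_yr, 2 * p$mol_cm3_yr)
  }
  expect_equal(oxidant_production(structure(list(eeq_mol_cm3_yr = 0,
    by_radiation = 0, molecules_cm3_yr = 0, mol_cm3_yr = 0),
    class = "production_rate")), 0)
})

test_that("electron-equivalent ledger applies the stoichiometric factors", {
  expect_equal(to_electron_equivalents(1, "H2"), 2)
  expect_equal(to_electron_equivalents(1, "O2"), 4)
  expect_equal(to_electron_equivalents(1, "organic_C"), 4)
  expect_equal(to_electron_equivalents(0, "O2"), 0)
  expect_error(to_electron_equivalents(1, "CH4"))
})

test_that("yield lookups follow the beta = gamma substitution and flag gaps", {
  yt <- yield_table()
  expect_identical(yield_lookup(yt, "abyssal_clay", "beta"),
                   yield_lookup(yt, "abyssal_clay", "gamma"))
  expect_equal(yield_lookup(yt, "pure_water", "alpha"), 1.30, tolerance = 0.13 / 1.30)
  expect_error(yield_lookup(yt, "basalt", "alpha"), "basalt")
  expect_true(all(yt$G_mean >= 0))
  # sediment yields exceed pure water for the same radiation type
  for (r in c("alpha", "gamma")) {
    pw <- yield_lookup(yt, "pure_water", r)
    for (m in c("abyssal_clay", "siliceous_ooze", "calcareous_marl",
                "calcareous_ooze", "lithogenous"))
      expect_gt(yield_lookup(yt, m, r), pw)
  }
})

test_that("beta-assumption sensitivity agrees with a direct perturbation identity", {
  a <- activities(isotope_abundances(clay_comp()))
  s <- beta_assumption_sensitivity(a, 2.6, 0.83, "abyssal_clay")
  # oracle: perturbing only the beta term of the sum
  ep <- energy_partition()
  Ebw <- sum(unclass(a) * ep[names(a), "beta"]) * 1e6 / 100    # eV-scaled
  yt <- yield_table()
  G_gamma <- yield_lookup(yt, "abyssal_clay", "gamma")
  p0 <- production_rate(a, 2.6, 0.83, "abyssal_clay")
  t0 <- sum(p0$by_radiation)
  pert <- abs(Ebw * 2.6 * (yield_lookup(yt, "pure_water", "gamma") - G_gamma)) / t0
  expect_equal(unname(s$sensitivity["pure_water"]), pert, tolerance = 1e-12)
  pert_a <- abs(Ebw * 2.6 * (yield_lookup(yt, "abyssal_clay", "alpha") - G_gamma)) / t0
  expect_equal(unname(s$sensitivity["alpha"]), pert_a, tolerance = 1e-12)
  expect_equal(unname(s$beta_fraction), Ebw * 2.6 * G_gamma / t0, tolerance = 1e-12)
})

test_that("sensitivity vanishes when beta deposits no energy", {
  acts <- structure(c(X = 1e6), class = "isotope_activity")
  energies <- data.frame(row.names = "X", alpha = 5, beta = 0, gamma = 1)
  yields <- data.frame(medium = c("test", "test", "pure_water"),
                       radiation = c("alpha", "gamma", "gamma"),
                       G_mean = c(10, 1, 0.45))
  s <- beta_assumption_sensitivity(acts, 2.5, 0.5, "test", energies, yields)
  expect_equal(unname(s$sensitivity), c(0, 0))
  expect_equal(s$beta_fraction, 0)
})
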