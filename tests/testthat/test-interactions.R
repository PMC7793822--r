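mk_perp <- function(regimen = 0, dose = 80, ka = 2, v = 20, cl = 10,
                    fu = 0.1, mw = 400)
  perpetrator_spec("perp", dose = dose, regimen = regimen, ka = ka, v = v,
                   cl = cl, fu_plasma = fu, mw = mw)

test_that("perpetrator concentration follows the Bateman superposition", {
  sp <- mk_perp(regimen = c(0, 24))
  expect_identical(perpetrator_concentration(sp, -1), 0)
  expect_lt(perpetrator_concentration(sp, 5000), 1e-12)
  # hand-evaluated Bateman value at t = 2 h after a single 80 mg dose
  sp1 <- mk_perp(regimen = 0)
  k <- 10 / 20
  d_nmol <- 80e6 / 400
  expected_total <- d_nmol * 2 / (20 * (2 - k)) *
    (exp(-k * 2) - exp(-2 * 2)) / 1000
  expect_equal(perpetrator_concentration(sp1, 2, unbound = FALSE),
               expected_total, tolerance = 1e-9)
  expect_equal(perpetrator_concentration(sp1, 2), 0.1 * expected_total,
               tolerance = 1e-9)
  # degenerate ka = CL/V uses the limiting form
  spd <- mk_perp(regimen = 0, ka = 0.5, v = 20, cl = 10)
  expect_equal(perpetrator_concentration(spd, 2, unbound = FALSE),
               d_nmol * 0.5 * 2 * exp(-0.5 * 2) / 20 / 1000,
               tolerance = 1e-9)
  # superposition: two doses add
  expect_equal(perpetrator_concentration(sp, 26, unbound = FALSE),
               perpetrator_concentration(sp1, 26, unbound = FALSE) +
                 perpetrator_concentration(sp1, 2, unbound = FALSE),
               tolerance = 1e-12)
})

test_that("gut lumen surrogate decays with the absorption rate", {
  sp <- mk_perp(regimen = 0)
  c0 <- gut_lumen_concentration(sp, 0, v_lumen = 0.25)
  expect_equal(c0, 80e6 / 400 / 0.25 / 1000)
  expect_equal(gut_lumen_concentration(sp, 1, v_lumen = 0.25),
               c0 * exp(-2), tolerance = 1e-12)
})

test_that("reversible inhibition factor", {
  expect_identical(reversible_inhibition_factor(0, 0.11), 1)
  expect_equal(reversible_inhibition_factor(0.11, 0.11), 0.5)
  expect_equal(reversible_inhibition_factor(0.22, 0.11), 1 / 3)
  expect_error(reversible_inhibition_factor(1, 0),
               class = "vicapkpd_validation_error")
})

test_that("mechanism-based inactivation: limits and closed-form steady state", {
  t <- seq(0, 5000, 10)
  e0 <- mbi_active_enzyme(function(t) 0, k_inact = 2.4, k_i_app = 8.5,
                          k_deg = 0.001, times = t)
  expect_true(all(e0$E == 1))
  e_no <- mbi_active_enzyme(function(t) 100, k_inact = 0, k_i_app = 8.5,
                            k_deg = 0.001, times = t)
  expect_true(all(abs(e_no$E - 1) < 1e-9))
  # constant inhibitor: E(inf) = k_deg / (k_deg + k_inact * I/(KI + I)),
  # approaching k_deg / (k_deg + k_inact) as I saturates
  e_sat <- mbi_active_enzyme(function(t) 1e6, k_inact = 0.5, k_i_app = 8.5,
                             k_deg = 0.001, times = t)
  sat <- 1e6 / (8.5 + 1e6)
  expect_equal(e_sat$E[length(t)], 0.001 / (0.001 + 0.5 * sat),
               tolerance = 1e-6)
  expect_equal(e_sat$E[length(t)], 0.001 / 0.501, tolerance = 1e-4)
  expect_true(all(e_sat$E > 0 & e_sat$E <= 1))
})

test_that("a dose-free or infinitely weak perpetrator leaves the victim unchanged", {
  reg <- ref_registry()
  sys <- build_system(reg, drug = "vicagrel")
  rgm <- dosing_regimen("vicagrel", 24, 6, 2)
  g <- simulation_grid(48, dt_dosing = 0.25)
  base <- simulate_individual(sys, rgm, g)

  p0 <- reg$perpetrators$simvastatin
  p0$spec$regimen <- numeric(0)  # never dosed
  same <- simulate_individual(coadminister(sys, p0$spec, p0$inhibition),
                              rgm, g)
  expect_lt(max(abs(same$conc - base$conc)), 1e-12)

  weak <- coadminister(sys, mk_perp(regimen = c(0, 24)),
                       inhibition_spec(ki = c(CES1 = 1e12, CES2 = 1e12)))
  near <- simulate_individual(weak, rgm, g, rtol = 1e-10, atol = 1e-12)
  base <- simulate_individual(sys, rgm, g, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(near$conc - base$conc)) / max(base$conc), 1e-9)
})

test_that("strengthening CES1 inhibition monotonically raises clopidogrel AM-H4", {
  reg <- ref_registry()
  sys <- build_system(reg, drug = "clopidogrel")
  rgm <- dosing_regimen("clopidogrel", 300)
  g <- simulation_grid(24, dt_dosing = 0.25)
  base <- auc_interval(simulate_individual(sys, rgm, g), "AM-H4", 0, 24)
  sp <- mk_perp(regimen = 0, dose = 80, ka = 1.3, v = 100, cl = 50,
                fu = 0.5, mw = 418.6)
  ratios <- vapply(c(10, 1, 0.1, 0.01), function(ki) {
    s <- coadminister(sys, sp, inhibition_spec(ki = c(CES1 = ki)))
    auc_interval(simulate_individual(s, rgm, g), "AM-H4", 0, 24) / base
  }, 1)
  # CES1 inactivates clopidogrel, 2-oxo and AM-H4: inhibiting it raises
  # active-metabolite exposure, the more so the smaller the Ki
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios >= 1 - 1e-9))
})

test_that("inhibition spec validation", {
  expect_error(inhibition_spec(ki = c(CES1 = -1)),
               class = "vicapkpd_validation_error")
  expect_error(inhibition_spec(ki = c(1)), "named",
               class = "vicapkpd_validation_error")
  expect_error(inhibition_spec(mbi = list(CYP2C19 = list(k_i_app = 1,
                                                         k_inact = 0))),
               class = "vicapkpd_validation_error")
})
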