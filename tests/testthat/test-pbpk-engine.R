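test_that("intrinsic-clearance scaling converts uL/min/mg to L/h", {
  expect_identical(scale_clint(0, 12345), 0)
  expect_equal(scale_clint(100, 40 * 1500), 360)
  expect_equal(scale_clint(2305, 3000), 414.9)
  expect_error(scale_clint(-1, 10), class = "vicapkpd_validation_error")
})

test_that("gut extraction fraction follows the Qgut algebra", {
  expect_identical(fraction_escaping_gut(0, 14), 1)
  expect_lt(fraction_escaping_gut(1e12, 14), 1e-9)
  expect_equal(fraction_escaping_gut(56, 14, 1), 0.2)
  expect_error(fraction_escaping_gut(10, 0), class = "vicapkpd_validation_error")
})

test_that("well-stirred hepatic clearance has the right limits and value", {
  expect_equal(wellstirred_hepatic_clearance(90, 0.5, 1e15), 90,
               tolerance = 1e-6)
  expect_identical(wellstirred_hepatic_clearance(90, 0, 1000), 0)
  expect_equal(wellstirred_hepatic_clearance(90, 0.02, 50000), 90000 / 1090)
  expect_error(wellstirred_hepatic_clearance(0, 0.5, 10),
               class = "vicapkpd_validation_error")
})

test_that("system topology matches the metabolic scheme of each prodrug", {
  reg <- ref_registry()
  sc <- build_system(reg, drug = "clopidogrel")
  expect_length(sc$gut$enzymes, 0)   # clopidogrel is activated hepatically
  expect_equal(sc$n_core, 4 + 3 * 2) # parent + two sequential metabolites
  expect_setequal(sc$compounds, c("clopidogrel", "2-oxo-clopidogrel", "AM-H4"))
  sv <- build_system(reg, drug = "vicagrel")
  expect_setequal(sv$gut$enzymes, c("CES2", "AADAC"))
  expect_equal(sv$n_core, 4 + 3 * 2)
  expect_setequal(sv$compounds, c("vicagrel", "2-oxo-clopidogrel", "AM-H4"))

  # a poor metabolizer has zero CYP2C19 intrinsic clearance everywhere
  pm <- build_system(reg, reference_individual(phenotype = "PM"),
                     "clopidogrel")
  r2c19 <- vapply(Filter(function(p) p$enzyme == "CYP2C19", pm$liver_paths),
                  function(p) p$rate, 1)
  expect_true(all(r2c19 == 0))
  expect_error(build_system(reg, drug = "AM-H4"), "ka",
               class = "vicapkpd_validation_error")
})

test_that("zero dose yields an identically zero profile", {
  reg <- chain_registry()
  sys <- build_system(reg, drug = "parent")
  pr <- simulate_individual(sys, dosing_regimen("parent", 0),
                            seq(0, 24, 0.5))
  expect_true(all(pr$conc == 0))
  expect_true(all(pr$amounts == 0))
})

test_that("with no metabolism the profile matches the oral one-compartment closed form", {
  ka <- 1.2; fa <- 0.8; v <- 50; cl <- 5; dose <- 10; mw <- 300
  reg <- one_compartment_registry(ka, fa, v, cl)
  sys <- build_system(reg, drug = "drugx")
  t <- seq(0, 48, 0.25)
  pr <- simulate_individual(sys, dosing_regimen("drugx", dose), t,
                            rtol = 1e-10, atol = 1e-12)
  k <- cl / v
  a_nmol <- fa * dose * 1e6 / mw
  expected <- a_nmol * ka / (v * (ka - k)) * (exp(-k * t) - exp(-ka * t)) *
    mw / 1000
  expect_equal(pr$conc[, "drugx"], expected, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("moles are conserved and states stay non-negative", {
  reg <- ref_registry()
  for (drug in c("vicagrel", "clopidogrel")) {
    dd <- if (drug == "vicagrel") c(24, 6) else c(300, 75)
    sys <- build_system(reg, drug = drug)
    pr <- simulate_individual(sys, dosing_regimen(drug, dd[1], dd[2], 3),
                              simulation_grid(72, dt_dosing = 0.25))
    expect_lt(max(mole_balance(pr)$rel_error), 1e-6)
    expect_true(all(pr$amounts > -1e-9))
    expect_true(all(pr$conc[1, ] == 0))  # nothing systemic before first dose
  }
})

test_that("the linear system is exactly dose-proportional", {
  reg <- ref_registry()
  sys <- build_system(reg, drug = "vicagrel")
  g <- simulation_grid(48, dt_dosing = 0.25)
  p1 <- simulate_individual(sys, dosing_regimen("vicagrel", 24, 6, 2), g,
                            rtol = 1e-10, atol = 1e-12)
  p2 <- simulate_individual(sys, dosing_regimen("vicagrel", 48, 12, 2), g,
                            rtol = 1e-10, atol = 1e-12)
  scale <- max(p2$conc)
  expect_lt(max(abs(2 * p1$conc - p2$conc)) / scale, 1e-9)
})

test_that("AADAC compensates when gut CES2 is knocked out", {
  reg <- ref_registry()
  ind <- reference_individual()
  ind$enzyme_multipliers["CES2"] <- 0
  sys <- build_system(reg, ind, "vicagrel")
  fg <- fraction_escaping_gut(sum(sys$gut$clint_lh), sys$gut$q_gut,
                              sys$gut$fu_gut)
  expect_gt(1 - fg, 0.99)   # gut activation persists through AADAC
  pr <- simulate_individual(sys, dosing_regimen("vicagrel", 24),
                            seq(0, 24, 0.25))
  expect_gt(max(pr$conc[, "AM-H4"]), 0)
})

test_that("solver output matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  reg <- chain_registry()
  sys <- build_system(reg, drug = "parent")
  dose <- 5
  t <- c(0, 0.5, 1, 2, 5, 10, 24)
  pr <- simulate_individual(sys, dosing_regimen("parent", dose), t,
                            rtol = 1e-11, atol = 1e-13)
  y0 <- rep(0, nrow(sys$A))
  y0[sys$gut$lumen] <- dose * 1e6 / 350  # fa = 1
  for (i in seq_along(t)) {
    yexp <- as.vector(Matrix::expm(sys$A * t[i]) %*% y0)
    expect_equal(unname(pr$amounts[i, ]), yexp,
                 tolerance = 1e-8)
  }
})
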