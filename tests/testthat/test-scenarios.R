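# Scenario campaigns exercised at reduced cohort sizes; the full-size runs
# live in the acceptance suite.

test_that("CYP2C19 phenotype ladder: clopidogrel collapses, vicagrel shrugs", {
  reg <- ref_registry()
  sc_c <- run_phenotype_comparison("clopidogrel", reg, n_subjects = 6,
                                   n_days = 4, dt_dosing = 0.5, seed = 21)
  sc_v <- run_phenotype_comparison("vicagrel", reg, n_subjects = 6,
                                   n_days = 4, dt_dosing = 0.5, seed = 21)
  auc_c <- sc_c$auc_first_by_phenotype
  auc_v <- sc_v$auc_first_by_phenotype
  expect_true(auc_c[["EM"]] > auc_c[["IM"]] &&
                auc_c[["IM"]] > auc_c[["PM"]])
  expect_true(auc_v[["EM"]] > auc_v[["IM"]] &&
                auc_v[["IM"]] > auc_v[["PM"]])
  # vicagrel retains most of its activation in poor metabolizers
  expect_gt(sc_v$pm_em_ratio, sc_c$pm_em_ratio)
  expect_lt(sc_v$pm_em_ratio, 1)
})

test_that("CES2 defect alleles move the parent but not the active metabolite", {
  reg <- ref_registry()
  sc <- run_genotype_scenario("CES2_defect", reg, n_subjects = 6,
                              dt_dosing = 0.5, seed = 31)
  s <- sc$summary
  r_parent <- s$ratio_auc_first[s$compound == "vicagrel"]
  r_amh4 <- s$ratio_auc_first[s$compound == "AM-H4"]
  expect_lt(r_parent, 0.7)            # parent exposure rises in the defect arm
  expect_equal(r_amh4, 1, tolerance = 0.05)
})

test_that("CES1 428 G/A carriers gain active-metabolite exposure", {
  reg <- ref_registry()
  sc <- run_genotype_scenario("CES1_428GA", reg, n_subjects = 6,
                              dt_dosing = 0.5, seed = 31)
  s <- sc$summary
  r_amh4 <- s$ratio_auc_first[s$compound == "AM-H4"]
  expect_lt(r_amh4, 1)      # G/G over G/A: variant arm has higher AM-H4
  expect_gt(r_amh4, 0.8)
})

test_that("omeprazole hits clopidogrel harder than vicagrel", {
  reg <- ref_registry()
  sc_v <- run_ddi_scenario("omeprazole", "vicagrel", reg, n_subjects = 4,
                           dt_dosing = 0.5, seed = 41)
  sc_c <- run_ddi_scenario("omeprazole", "clopidogrel", reg, n_subjects = 4,
                           dt_dosing = 0.5, seed = 41)
  r_v <- sc_v$summary$ratio_auc_first[sc_v$summary$compound == "AM-H4"]
  r_c <- sc_c$summary$ratio_auc_first[sc_c$summary$compound == "AM-H4"]
  expect_gt(r_v, 1)            # without/with > 1: exposure falls on inhibitor
  expect_lt(r_v, 1.3)          # but only slightly for vicagrel
  expect_gt(abs(1 - r_c), abs(1 - r_v))
  # platelet inhibition follows the exposure loss
  expect_lte(max(sc_v$mean_ipa$with_$ipa), max(sc_v$mean_ipa$without$ipa) + 1e-9)
})

test_that("simvastatin leaves active-metabolite exposure essentially unchanged", {
  reg <- ref_registry()
  sc <- run_ddi_scenario("simvastatin", "vicagrel", reg, n_subjects = 4,
                         dt_dosing = 0.5, seed = 41)
  s <- sc$summary
  expect_equal(s$ratio_auc_first[s$compound == "AM-H4"], 1, tolerance = 0.05)
  # the parent, in contrast, accumulates when its gut hydrolysis is inhibited
  expect_lt(s$ratio_auc_first[s$compound == "vicagrel"], 0.9)
})

test_that("Ki sensitivity: monotone in CES1, flat in CES2, CES1-dominant", {
  reg <- ref_registry()
  sc <- run_ki_sensitivity(reg, n_grid = 3, dt_dosing = 0.5)
  r <- sc$ratio
  # along CES1 (rows index ki_CES1): ratio falls as ki grows
  expect_true(all(apply(r, 2, diff) <= 1e-9))
  expect_gt(r[1, 1], r[3, 1])
  # along CES2 the luminal inhibitor saturates the enzyme across the whole
  # grid, so the axis is flat to numerical accuracy
  expect_true(all(abs(apply(r, 1, diff)) < 1e-4))
  # CES1 axis dominates by orders of magnitude at matched low Ki
  expect_gt(abs(r[1, 1] - r[3, 1]), 100 * abs(r[1, 1] - r[1, 3]))
  # at the published Ki pair the grid reproduces the default DDI ratio
  ind <- reference_individual()
  reg5 <- dosing_regimen("vicagrel", 24, 6, 1, start_h = 120)
  g <- simulation_grid(144, dt_dosing = 0.5)
  sys <- build_system(reg, ind, "vicagrel")
  p <- reg$perpetrators$simvastatin
  p$spec$regimen <- 24 * (0:5)
  base <- simulate_individual(sys, reg5, g)
  withp <- simulate_individual(coadminister(sys, p$spec, p$inhibition),
                               reg5, g)
  direct <- auc_interval(withp, "AM-H4", 120, 144) /
    auc_interval(base, "AM-H4", 120, 144)
  expect_equal(r[3, 3], direct, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("washout recovery sits near seven days and scales with kout", {
  reg <- ref_registry()
  sc <- run_washout_recovery(reg, n_subjects = 8, dt_dosing = 0.5, seed = 51)
  expect_equal(sc$recovery_days, 7, tolerance = 1.5 / 7)

  # doubling the platelet turnover roughly halves the recovery time
  reg2 <- reg
  reg2$pd <- pd_spec(kin = 2 * reg$pd$kout, kout = 2 * reg$pd$kout,
                     kirre = reg$pd$kirre, mpa0 = reg$pd$mpa0,
                     cv_kout = reg$pd$cv_kout, cv_kirre = reg$pd$cv_kirre,
                     cv_mpa0 = reg$pd$cv_mpa0)
  sc2 <- run_washout_recovery(reg2, n_subjects = 8, dt_dosing = 0.5,
                              seed = 51)
  expect_equal(sc2$recovery_days / sc$recovery_days, 0.5, tolerance = 0.3)

  # no irreversible inactivation, no inhibition to recover from
  reg0 <- reg
  reg0$pd <- pd_spec(kin = reg$pd$kin, kout = reg$pd$kout, kirre = 0,
                     mpa0 = reg$pd$mpa0)
  sc0 <- run_washout_recovery(reg0, n_subjects = 4, dt_dosing = 0.5,
                              seed = 51)
  expect_true(all(abs(sc0$mean_ipa$ipa) < 1e-9))
  expect_identical(sc0$recovery_h, 0)
})

test_that("scenario reruns with the same seed are byte-identical on disk", {
  reg <- ref_registry()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- run_genotype_scenario("CES2_defect", reg, n_subjects = 3,
                              dt_dosing = 1, seed = 61)
  s2 <- run_genotype_scenario("CES2_defect", reg, n_subjects = 3,
                              dt_dosing = 1, seed = 61)
  write_scenario(s1, d1)
  write_scenario(s2, d2)
  for (f in c("profiles.csv", "pd.csv", "summary.csv", "manifest.yaml")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("the scenario dispatcher knows every packaged campaign", {
  reg <- ref_registry()
  expect_length(list_scenarios(), 9)
  sc <- run_scenario("genotype_CES2_defect", reg, n_subjects = 2,
                     dt_dosing = 1, seed = 71)
  expect_s3_class(sc, "pkpd_scenario")
  expect_error(run_scenario("nope", reg), class = "vicapkpd_validation_error")
})
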