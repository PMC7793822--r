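test_that("packaged defaults load with the four activation-cascade compounds", {
  reg <- default_registry()
  expect_setequal(names(reg$compounds),
                  c("clopidogrel", "vicagrel", "2-oxo-clopidogrel", "AM-H4"))
  expect_setequal(parent_compounds(reg), c("clopidogrel", "vicagrel"))
  expect_silent(validate_registry(reg))
})

test_that("default parameterization satisfies its printed constraint anchors", {
  reg <- default_registry()
  clop <- reg$compounds$clopidogrel
  clints <- vapply(clop$pathways, function(p) p$clint, 1)
  enz <- vapply(clop$pathways, function(p) p$enzyme, "")
  cyp <- sum(clints[grepl("^CYP", enz)])
  ces1 <- clints[enz == "CES1"]
  # oxidative route share of clopidogrel hepatic intrinsic clearance
  expect_equal(cyp / (cyp + ces1), 0.15, tolerance = 1e-12,
               ignore_attr = TRUE)
  # AADAC share of vicagrel gut hydrolysis
  vic <- reg$compounds$vicagrel
  g <- vapply(vic$pathways, function(p) p$clint, 1)
  names(g) <- vapply(vic$pathways, function(p) p$enzyme, "")
  expect_equal(unname(g["AADAC"] / sum(g)), 0.53, tolerance = 1e-12)
  # CES1 428 G/A scaling reproduces the printed variant clearances
  expect_equal(unname(0.8 * ces1), 240, tolerance = 1e-12)
  oxo_ces1 <- Filter(function(p) p$enzyme == "CES1",
                     reg$compounds$`2-oxo-clopidogrel`$pathways)[[1]]$clint
  expect_equal(0.8 * oxo_ces1, 16, tolerance = 1e-12)
  # 20-fold CES2 defect reduction reproduces the printed deficient clearance
  expect_equal(unname(g["CES2"] / 20), 2305, tolerance = 1e-12)
})

test_that("field range violations raise validation errors naming the field", {
  expect_error(
    compound_spec("x", molecular_weight = 300, fa = 1.3, fu_plasma = 0.5,
                  blood_plasma_ratio = 1, v_sys = 10),
    "fa", class = "vicapkpd_validation_error")
  expect_error(
    enzyme_pathway("CYP3A4", "gut", 10),
    "site", class = "vicapkpd_validation_error")
  expect_error(
    physiology_spec(q_hepatic_total = 90, q_portal = 50,
                    q_hepatic_arterial = 22.5, q_gut = 14,
                    liver_weight = 1500, mppgl = 40, gut_protein = 3000,
                    v_portal = 1, v_liver = 1.5),
    "q_hepatic_total", class = "vicapkpd_validation_error")
  expect_error(
    pd_spec(kin = 0.01, kout = 0.02, kirre = 1, mpa0 = 55),
    "kin", class = "vicapkpd_validation_error")
  expect_error(
    population_spec("Chinese", c(EM = 0.5, IM = 0.4, PM = 0.2)),
    "phenotype_frequencies", class = "vicapkpd_validation_error")
})

test_that("referential and structural registry checks reject bad networks", {
  mk <- function(product) new_registry(
    compounds = list(
      a = compound_spec("a", 300, ka = 1, fa = 1, fu_plasma = 1,
                        blood_plasma_ratio = 1, v_sys = 10,
                        pathways = list(enzyme_pathway("CES1", "liver", 10,
                                                       product = product)))),
    physiology = physiology_spec(90, 67.5, 22.5, 14, 1500, 40, 3000, 1, 1.5),
    pd = pd_spec(0.0124, 0.0124, 40, 55))
  expect_error(mk("ghost"), "not a registered compound",
               class = "vicapkpd_validation_error")

  cyc <- list(
    a = compound_spec("a", 300, ka = 1, fa = 1, fu_plasma = 1,
                      blood_plasma_ratio = 1, v_sys = 10,
                      pathways = list(enzyme_pathway("CES1", "liver", 10,
                                                     product = "b"))),
    b = compound_spec("b", 300, fu_plasma = 1, blood_plasma_ratio = 1,
                      v_sys = 10,
                      pathways = list(enzyme_pathway("CES2", "liver", 10,
                                                     product = "a"))))
  expect_error(
    new_registry(cyc,
                 physiology_spec(90, 67.5, 22.5, 14, 1500, 40, 3000, 1, 1.5),
                 pd_spec(0.0124, 0.0124, 40, 55)),
    "cycle", class = "vicapkpd_validation_error")
})

test_that("schema errors name the missing key", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("physiology: {q_portal: 1}", f)
  expect_error(load_config(f), "compounds", class = "vicapkpd_schema_error")
  expect_error(load_config(file.path(tempdir(), "no-such-file.yaml")),
               "does not exist", class = "vicapkpd_schema_error")
})

test_that("write_config / load_config round-trips the registry", {
  reg <- default_registry()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(reg, f)
  reg2 <- load_config(f)
  expect_equal(reg2, reg, tolerance = 1e-12)
})
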