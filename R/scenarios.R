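# The simulation campaigns: CYP2C19 phenotype comparison, CES1/CES2 genotype
# arms, perpetrator DDI arms, Ki sensitivity, washout recovery.  Paired arms
# always reuse the identical sampled subjects, changing only the
# genotype/phenotype/inhibitor factor, so ratio-of-means estimates are nearly
# noise-free at cohort sizes of 100.

default_regimens <- list(
  vicagrel = c(loading = 24, maintenance = 6),
  clopidogrel = c(loading = 300, maintenance = 75))

#' Simulate a cohort of subjects under one arm
#'
#' @param registry A validated `pkpd_registry`.
#' @param individuals List of `virtual_individual` objects.
#' @param drug Parent drug.
#' @param regimen A [dosing_regimen()].
#' @param t_grid Output grid, h.
#' @param arm Arm label stamped on each profile.
#' @param modify Function applied to each individual before building its
#'   system (e.g. a genotype or phenotype override).
#' @param perpetrator Optional list with elements `spec` and `inhibition`
#'   (plus optional `inhibit_gut`/`inhibit_liver`) attached to every
#'   subject's system.
#' @return List of `concentration_profile` objects.
#' @export
simulate_cohort <- function(registry, individuals, drug, regimen, t_grid,
                            arm = "", modify = identity, perpetrator = NULL) {
  lapply(individuals, function(ind) {
    sys <- build_system(registry, modify(ind), drug)
    if (!is.null(perpetrator))
      sys <- coadminister(sys, perpetrator$spec, perpetrator$inhibition,
                          inhibit_gut = !identical(perpetrator$inhibit_gut, FALSE),
                          inhibit_liver = !identical(perpetrator$inhibit_liver, FALSE))
    pr <- simulate_individual(sys, regimen, t_grid, arm = arm)
    pr$amounts <- pr$amounts[, 0, drop = FALSE]  # drop audit states in cohorts
    pr
  })
}

mean_profile <- function(profiles) {
  conc <- Reduce(`+`, lapply(profiles, function(p) p$conc)) / length(profiles)
  p <- profiles[[1]]
  p$conc <- conc
  p$subject <- NA_integer_
  p
}

cohort_pd <- function(profiles, registry, individuals = NULL) {
  lapply(seq_along(profiles), function(i)
    simulate_platelet_inhibition(profiles[[i]], registry$pd,
                                 individual = individuals[[i]]))
}

mean_ipa <- function(pds) {
  ipa <- Reduce(`+`, lapply(pds, function(p) p$ipa)) / length(pds)
  r <- pds[[1]]
  r$ipa <- ipa
  r$P <- 1 - ipa / 100
  r$mpa <- Reduce(`+`, lapply(pds, function(p) p$mpa)) / length(pds)
  r$subject <- NA_integer_
  r
}

new_scenario <- function(name, ...) {
  structure(c(list(name = name), list(...)), class = "pkpd_scenario")
}

#' @export
print.pkpd_scenario <- function(x, ...) {
  cat(sprintf("scenario '%s'\n", x$name))
  if (!is.null(x$summary)) {
    cat("  arm-ratio summary (first-dose AUC0-24 ratios):\n")
    s <- x$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("    %-18s %s / %s = %.4g\n", s$compound[i], s$arm_a[i],
                  s$arm_b[i], s$ratio_auc_first[i]))
  }
  if (!is.null(x$recovery_days))
    cat(sprintf("  recovery time: %.2f days\n", x$recovery_days))
  invisible(x)
}

#' CYP2C19 phenotype comparison
#'
#' Simulates the same virtual subjects three times with the CYP2C19
#' phenotype forced to EM, IM and PM (frequency 1 in each arm), under a
#' 7-day loading/maintenance regimen, and summarises the active-metabolite
#' exposure and mean platelet inhibition per arm.
#'
#' @param drug `"vicagrel"` (24/6 mg) or `"clopidogrel"` (300/75 mg).
#' @param registry A validated `pkpd_registry`.
#' @param population Name of the population block (default `"chinese"`).
#' @param n_subjects Optional cohort-size override.
#' @param n_days Dosing days (default 7).
#' @param dt_dosing Output grid spacing during dosing, h.
#' @param seed Optional seed override for population sampling.
#' @return A `pkpd_scenario` with per-arm profiles, mean AM-H4 profiles,
#'   mean IPA curves and an AUC summary.
#' @export
run_phenotype_comparison <- function(drug, registry, population = "chinese",
                                     n_subjects = NULL, n_days = 7,
                                     dt_dosing = 0.1, seed = NULL) {
  pop <- override_pop(registry$populations[[population]], n_subjects, seed)
  inds <- sample_population(pop, registry)
  dd <- default_regimens[[drug]]
  reg <- dosing_regimen(drug, dd[["loading"]], dd[["maintenance"]], n_days)
  grid <- simulation_grid(24 * n_days, dt_dosing = dt_dosing)

  arms <- lapply(stats::setNames(PHENOTYPES, PHENOTYPES), function(ph) {
    profs <- simulate_cohort(registry, inds, drug, reg, grid, arm = ph,
                             modify = function(i) apply_phenotype(i, ph))
    pds <- cohort_pd(profs, registry, inds)
    list(profiles = profs, metrics = pk_metrics(profs, "AM-H4"),
         mean_amh4 = mean_profile(profs), mean_ipa = mean_ipa(pds))
  })
  auc <- vapply(arms, function(a) attr(a$metrics, "mean")[["auc_first"]], 1)
  new_scenario(paste0("phenotype_", drug), drug = drug, arms = arms,
               auc_first_by_phenotype = auc,
               pm_em_ratio = unname(auc["PM"] / auc["EM"]),
               seed = pop$seed)
}

override_pop <- function(pop, n_subjects = NULL, seed = NULL) {
  if (!is.null(n_subjects)) {
    pop$n_subjects <- as.integer(n_subjects)
    pop$n_trials <- max(1L, min(pop$n_trials, pop$n_subjects))
    while (pop$n_subjects %% pop$n_trials != 0) pop$n_trials <- pop$n_trials - 1L
  }
  if (!is.null(seed)) pop$seed <- as.integer(seed)
  pop
}

#' Carboxylesterase genotype scenario
#'
#' Paired wild-type vs variant arms on identical subjects for vicagrel
#' (24 mg loading, 6 mg/day maintenance, 4 days): `CES1_428GA` scales every
#' CES1 clearance to 80% (Caucasian population), `CES2_defect` divides every
#' CES2 clearance by 20 (Chinese population).  Ratios are wild over variant.
#'
#' @param label `"CES1_428GA"` or `"CES2_defect"`.
#' @param registry A validated `pkpd_registry`.
#' @param n_subjects Optional cohort-size override.
#' @param n_days Dosing days (default 4).
#' @param dt_dosing Output grid spacing, h.
#' @param seed Optional population seed override.
#' @return A `pkpd_scenario`; `$summary` holds the paired-arm ratio table
#'   for vicagrel and AM-H4.
#' @export
run_genotype_scenario <- function(label, registry, n_subjects = NULL,
                                  n_days = 4, dt_dosing = 0.1, seed = NULL) {
  if (!label %in% GENOTYPE_LABELS)
    stop_validation("unknown genotype label '%s'", label)
  population <- if (label == "CES1_428GA") "caucasian" else "chinese"
  pop <- override_pop(registry$populations[[population]], n_subjects, seed)
  inds <- sample_population(pop, registry)
  reg <- dosing_regimen("vicagrel", 24, 6, n_days)
  grid <- simulation_grid(24 * n_days, dt_dosing = dt_dosing)
  arm_names <- if (label == "CES1_428GA") c("CES1_GG", "CES1_GA")
               else c("CES2_wild", "CES2_defect")

  wild <- simulate_cohort(registry, inds, "vicagrel", reg, grid,
                          arm = arm_names[1])
  variant <- simulate_cohort(registry, inds, "vicagrel", reg, grid,
                             arm = arm_names[2],
                             modify = function(i) apply_genotype(i, label))
  summ <- do.call(rbind, lapply(c("vicagrel", "AM-H4"), function(cmp)
    arm_ratio_summary(pk_metrics(wild, cmp), pk_metrics(variant, cmp))))
  pd_wild <- mean_ipa(cohort_pd(wild, registry, inds))
  pd_var <- mean_ipa(cohort_pd(variant, registry, inds))
  new_scenario(paste0("genotype_", label), label = label,
               arms = list(wild = wild, variant = variant),
               summary = summ, mean_ipa = list(wild = pd_wild,
                                               variant = pd_var),
               seed = pop$seed)
}

perp_schedule <- function(registry, perpetrator, n_pre_days, n_covered_days) {
  p <- registry$perpetrators[[perpetrator]]
  if (is.null(p)) stop_validation("unknown perpetrator '%s'", perpetrator)
  p$spec$regimen <- 24 * (seq_len(n_pre_days + n_covered_days) - 1)
  p
}

#' Perpetrator drug-drug interaction scenario
#'
#' The perpetrator is dosed daily for `n_pre_days` days; the victim's
#' loading dose follows on the next day with daily maintenance doses, while
#' the perpetrator continues to be co-administered.  Paired with/without
#' arms on identical subjects; the time axis is anchored at the first
#' perpetrator dose.  Ratios are without over with.
#'
#' @param perpetrator `"omeprazole"` (CYP2C19 mechanism-based inhibitor) or
#'   `"simvastatin"` (CES1/CES2 reversible co-inhibitor).
#' @param victim `"vicagrel"` or `"clopidogrel"`.
#' @param registry A validated `pkpd_registry`.
#' @param population Population block (default `"chinese"`).
#' @param n_subjects Optional cohort-size override.
#' @param n_pre_days Perpetrator-only run-in days (default 5).
#' @param n_victim_days Victim dosing days (default 4).
#' @param dt_dosing Output grid spacing, h.
#' @param seed Optional population seed override.
#' @param continue_perpetrator Keep dosing the perpetrator during victim
#'   days (default `TRUE`).
#' @return A `pkpd_scenario`; `$summary` holds without/with ratios for the
#'   victim parent and AM-H4.
#' @export
run_ddi_scenario <- function(perpetrator, victim = "vicagrel", registry,
                             population = "chinese", n_subjects = NULL,
                             n_pre_days = 5, n_victim_days = 4,
                             dt_dosing = 0.1, seed = NULL,
                             continue_perpetrator = TRUE) {
  pop <- override_pop(registry$populations[[population]], n_subjects, seed)
  inds <- sample_population(pop, registry)
  dd <- default_regimens[[victim]]
  start <- 24 * n_pre_days
  reg <- dosing_regimen(victim, dd[["loading"]], dd[["maintenance"]],
                        n_victim_days, start_h = start)
  grid <- simulation_grid(start + 24 * n_victim_days, dt_dosing = dt_dosing)
  perp <- perp_schedule(registry, perpetrator, n_pre_days,
                        if (continue_perpetrator) n_victim_days else 0)

  without <- simulate_cohort(registry, inds, victim, reg, grid,
                             arm = "without_perpetrator")
  with_ <- simulate_cohort(registry, inds, victim, reg, grid,
                           arm = "with_perpetrator", perpetrator = perp)
  summ <- do.call(rbind, lapply(c(victim, "AM-H4"), function(cmp)
    arm_ratio_summary(pk_metrics(without, cmp), pk_metrics(with_, cmp))))
  pd_wo <- mean_ipa(cohort_pd(without, registry, inds))
  pd_w <- mean_ipa(cohort_pd(with_, registry, inds))
  new_scenario(sprintf("ddi_%s_%s", perpetrator, victim),
               perpetrator = perpetrator, victim = victim,
               arms = list(without = without, with_ = with_),
               summary = summ,
               mean_ipa = list(without = pd_wo, with_ = pd_w),
               seed = pop$seed)
}

#' Ki sensitivity analysis for the carboxylesterase inhibitor
#'
#' Recomputes the simvastatin DDI on a single representative subject (all
#' variability off) over a log-spaced grid of reversible inhibition
#' constants on CES1 and CES2, reporting the with/without ratio of the
#' active-metabolite first-dose AUC(0-24) at each grid point.
#'
#' @param registry A validated `pkpd_registry`.
#' @param ki_ces1,ki_ces2 Grid bounds, uM (defaults 0.001-0.11 and
#'   0.001-0.67, the published Ki values as upper ends).
#' @param n_grid Points per axis (>= 3, log-spaced including the bounds).
#' @param n_pre_days,n_victim_days,dt_dosing Scenario geometry as in
#'   [run_ddi_scenario()].
#' @return A `pkpd_scenario`; `$ratio` is the matrix of with/without AUC
#'   ratios (rows: CES1 Ki, columns: CES2 Ki).
#' @export
run_ki_sensitivity <- function(registry, ki_ces1 = c(0.001, 0.11),
                               ki_ces2 = c(0.001, 0.67), n_grid = 5,
                               n_pre_days = 5, n_victim_days = 1,
                               dt_dosing = 0.1) {
  if (n_grid < 3) stop_validation("n_grid must be >= 3")
  g1 <- exp(seq(log(ki_ces1[1]), log(ki_ces1[2]), length.out = n_grid))
  g2 <- exp(seq(log(ki_ces2[1]), log(ki_ces2[2]), length.out = n_grid))
  ind <- reference_individual()
  start <- 24 * n_pre_days
  reg <- dosing_regimen("vicagrel", 24, 6, n_victim_days, start_h = start)
  grid <- simulation_grid(start + 24 * n_victim_days, dt_dosing = dt_dosing)
  perp0 <- perp_schedule(registry, "simvastatin", n_pre_days, n_victim_days)

  sys0 <- build_system(registry, ind, "vicagrel")
  base <- simulate_individual(sys0, reg, grid, arm = "without")
  auc0 <- auc_interval(base, "AM-H4", start, start + 24)

  ratio <- matrix(NA_real_, n_grid, n_grid,
                  dimnames = list(ki_CES1 = signif(g1, 4),
                                  ki_CES2 = signif(g2, 4)))
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    inh <- inhibition_spec(ki = c(CES1 = g1[i], CES2 = g2[j]))
    sys <- coadminister(sys0, perp0$spec, inh)
    pr <- simulate_individual(sys, reg, grid, arm = "with")
    ratio[i, j] <- auc_interval(pr, "AM-H4", start, start + 24) / auc0
  }
  new_scenario("ki_sensitivity", ki_ces1 = g1, ki_ces2 = g2, ratio = ratio,
               auc_without = auc0)
}

#' Washout recovery of platelet function
#'
#' Simulates the default vicagrel regimen (24 mg loading, 6 mg/day
#' maintenance) for `n_days_dosing` days followed by a washout window,
#' computes the population-mean IPA curve, and reports the time from the
#' last dose until mean IPA first falls below the recovery threshold.
#'
#' @param registry A validated `pkpd_registry`.
#' @param population Population block (default `"chinese"`).
#' @param n_subjects Optional cohort-size override.
#' @param n_days_dosing Dosing days (default 7).
#' @param washout_days Washout window after the last dose, days (default 14).
#' @param threshold_ipa Recovery threshold, IPA percentage points
#'   (default 10).
#' @param dt_dosing Grid spacing during dosing, h (washout uses 1 h).
#' @param seed Optional population seed override.
#' @return A `pkpd_scenario` with `$recovery_days`, `$recovery_h` and the
#'   mean IPA curve.
#' @export
run_washout_recovery <- function(registry, population = "chinese",
                                 n_subjects = NULL, n_days_dosing = 7,
                                 washout_days = 14, threshold_ipa = 10,
                                 dt_dosing = 0.1, seed = NULL) {
  pop <- override_pop(registry$populations[[population]], n_subjects, seed)
  inds <- sample_population(pop, registry)
  reg <- dosing_regimen("vicagrel", 24, 6, n_days_dosing)
  grid <- simulation_grid(24 * n_days_dosing,
                          24 * (n_days_dosing + washout_days),
                          dt_dosing = dt_dosing)
  profs <- simulate_cohort(registry, inds, "vicagrel", reg, grid,
                           arm = "washout")
  pds <- cohort_pd(profs, registry, inds)
  mipa <- mean_ipa(pds)
  mipa$pd <- list(kout = registry$pd$kout)
  rec_h <- recovery_time(mipa, threshold_ipa)
  new_scenario("washout_recovery", mean_ipa = mipa, recovery_h = rec_h,
               recovery_days = rec_h / 24, threshold_ipa = threshold_ipa,
               seed = pop$seed)
}

#' Write scenario outputs to a directory
#'
#' Emits `profiles.csv` (long-format concentrations), `pd.csv` (mean IPA
#' curves, when present), `summary.csv` (paired-arm ratio table, when
#' present) and `manifest.yaml` (scenario name, seed, grid sizes) for
#' provenance.  Reruns with the same seed produce byte-identical files.
#'
#' @param scenario A `pkpd_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profs <- list()
  if (!is.null(scenario$arms)) {
    for (arm in names(scenario$arms)) {
      a <- scenario$arms[[arm]]
      plist <- if (!is.null(a$profiles)) a$profiles else a
      if (inherits(plist, "concentration_profile")) plist <- list(plist)
      profs <- c(profs, lapply(plist, as.data.frame))
    }
    utils::write.csv(do.call(rbind, profs),
                     file.path(dir, "profiles.csv"), row.names = FALSE)
  }
  pd_curves <- scenario$mean_ipa
  if (inherits(pd_curves, "pd_result")) pd_curves <- list(mean = pd_curves)
  if (!is.null(pd_curves) && length(pd_curves)) {
    pd_df <- do.call(rbind, lapply(names(pd_curves), function(nm) {
      d <- as.data.frame(pd_curves[[nm]]); d$arm <- nm; d
    }))
    utils::write.csv(pd_df, file.path(dir, "pd.csv"), row.names = FALSE)
  }
  if (!is.null(scenario$summary))
    utils::write.csv(scenario$summary, file.path(dir, "summary.csv"),
                     row.names = FALSE)
  manifest <- list(scenario = scenario$name,
                   seed = if (is.null(scenario$seed)) NA else scenario$seed,
                   package = "vicapkpd",
                   version = as.character(utils::packageVersion("vicapkpd")))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Names of the packaged simulation scenarios
#' @return Character vector of scenario identifiers understood by the
#'   command-line wrapper.
#' @export
list_scenarios <- function() {
  c("phenotype_vicagrel", "phenotype_clopidogrel",
    "genotype_CES1_428GA", "genotype_CES2_defect",
    "ddi_omeprazole_vicagrel", "ddi_omeprazole_clopidogrel",
    "ddi_simvastatin_vicagrel", "ki_sensitivity", "washout_recovery")
}

#' Run a packaged scenario by name
#'
#' Dispatch wrapper used by the command-line interface.
#'
#' @param name One of [list_scenarios()].
#' @param registry A validated `pkpd_registry`.
#' @param n_subjects,seed Optional overrides forwarded to the scenario.
#' @param ... Further arguments forwarded to the scenario function.
#' @return A `pkpd_scenario`.
#' @export
run_scenario <- function(name, registry, n_subjects = NULL, seed = NULL, ...) {
  switch(name,
    phenotype_vicagrel = run_phenotype_comparison("vicagrel", registry,
      n_subjects = n_subjects, seed = seed, ...),
    phenotype_clopidogrel = run_phenotype_comparison("clopidogrel", registry,
      n_subjects = n_subjects, seed = seed, ...),
    genotype_CES1_428GA = run_genotype_scenario("CES1_428GA", registry,
      n_subjects = n_subjects, seed = seed, ...),
    genotype_CES2_defect = run_genotype_scenario("CES2_defect", registry,
      n_subjects = n_subjects, seed = seed, ...),
    ddi_omeprazole_vicagrel = run_ddi_scenario("omeprazole", "vicagrel",
      registry, n_subjects = n_subjects, seed = seed, ...),
    ddi_omeprazole_clopidogrel = run_ddi_scenario("omeprazole", "clopidogrel",
      registry, n_subjects = n_subjects, seed = seed, ...),
    ddi_simvastatin_vicagrel = run_ddi_scenario("simvastatin", "vicagrel",
      registry, n_subjects = n_subjects, seed = seed, ...),
    ki_sensitivity = run_ki_sensitivity(registry, ...),
    washout_recovery = run_washout_recovery(registry,
      n_subjects = n_subjects, seed = seed, ...),
    stop_validation("unknown scenario '%s'", name))
}
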