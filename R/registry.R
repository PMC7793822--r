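ENZYMES <- c("CYP1A2", "CYP2B6", "CYP2C9", "CYP2C19", "CYP3A4",
             "CES1", "CES2", "AADAC")
GUT_ENZYMES <- c("CES2", "AADAC")
PHENOTYPES <- c("EM", "IM", "PM")
GENOTYPE_LABELS <- c("CES1_428GA", "CES2_defect")

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("vicapkpd_validation_error", "error")))
}

stop_schema <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("vicapkpd_schema_error", "error")))
}

check_num <- function(x, field, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (is.null(x)) stop_schema("missing required key '%s'", field)
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_validation("field '%s' must be a single finite number", field)
  if (x < lower || x > upper)
    stop_validation("field '%s' = %g outside allowed range [%g, %g]",
                    field, x, lower, upper)
  invisible(x)
}

#' Define one enzymatic pathway
#'
#' A pathway is an enzyme acting on a compound at a metabolic site, with an
#' in-vitro intrinsic clearance and an optional product compound.  An empty
#' product marks an inactivating route (the cleared material leaves the
#' metabolite cascade).
#'
#' @param enzyme Enzyme name, one of CYP1A2, CYP2B6, CYP2C9, CYP2C19, CYP3A4,
#'   CES1, CES2, AADAC.
#' @param site `"gut"` or `"liver"`.  Gut pathways are restricted to the
#'   intestinal hydrolases CES2 and AADAC.
#' @param clint Intrinsic clearance, uL/min/mg protein (microsomal-equivalent
#'   protein for liver pathways, total intestinal enzyme-bearing protein for
#'   gut pathways).
#' @param product Name of the compound formed, or `""` for an inactivating
#'   route.
#' @param cv Log-normal coefficient of variation for inter-individual
#'   variability of `clint` (fraction, e.g. `0.4`).
#' @return An object of class `enzyme_pathway`.
#' @export
enzyme_pathway <- function(enzyme, site = c("liver", "gut"), clint,
                           product = "", cv = 0) {
  site <- match.arg(site)
  if (!enzyme %in% ENZYMES)
    stop_validation("field 'enzyme': unknown enzyme '%s'", enzyme)
  if (site == "gut" && !enzyme %in% GUT_ENZYMES)
    stop_validation(
      "field 'site': gut pathways are limited to intestinal hydrolases (CES2, AADAC); got '%s'",
      enzyme)
  check_num(clint, "clint", lower = 0)
  check_num(cv, "cv", lower = 0)
  structure(list(enzyme = enzyme, site = site, clint = clint,
                 product = product, cv = cv),
            class = "enzyme_pathway")
}

#' Define a compound (parent drug or metabolite)
#'
#' @param name Compound identifier.
#' @param molecular_weight g/mol, used only at input/output boundaries
#'   (mg to nmol, ng/mL to uM).
#' @param ka First-order absorption rate, 1/h.  `NA` for metabolites, which
#'   are never dosed.
#' @param fa Fraction of an oral dose absorbed, in `[0, 1]` (`NA` for
#'   metabolites).
#' @param fu_plasma Unbound fraction in plasma, in `[0, 1]`.
#' @param blood_plasma_ratio Blood-to-plasma concentration ratio, > 0.
#' @param v_sys Apparent systemic (plasma) volume of distribution, L.
#' @param renal_cl Non-hepatic systemic clearance, L/h; for the chemically
#'   unstable active metabolite this absorbs plasma degradation as well as
#'   renal elimination.
#' @param pathways List of [enzyme_pathway()] objects.
#' @param cv_ka,cv_v_sys Log-normal CVs for inter-individual variability of
#'   `ka` and `v_sys`.
#' @return An object of class `compound_spec`.
#' @export
compound_spec <- function(name, molecular_weight, ka = NA_real_, fa = NA_real_,
                          fu_plasma, blood_plasma_ratio, v_sys, renal_cl = 0,
                          pathways = list(), cv_ka = 0, cv_v_sys = 0) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop_validation("field 'name' must be a non-empty string")
  check_num(molecular_weight, "molecular_weight", lower = 1e-9)
  check_num(ka, "ka", lower = 0, allow_na = TRUE)
  check_num(fa, "fa", lower = 0, upper = 1, allow_na = TRUE)
  check_num(fu_plasma, "fu_plasma", lower = 0, upper = 1)
  check_num(blood_plasma_ratio, "blood_plasma_ratio", lower = 1e-9)
  check_num(v_sys, "v_sys", lower = 1e-9)
  check_num(renal_cl, "renal_cl", lower = 0)
  check_num(cv_ka, "cv_ka", lower = 0)
  check_num(cv_v_sys, "cv_v_sys", lower = 0)
  if (!all(vapply(pathways, inherits, TRUE, "enzyme_pathway")))
    stop_validation("field 'pathways' must be a list of enzyme_pathway objects")
  structure(list(name = name, molecular_weight = molecular_weight,
                 ka = ka, fa = fa, fu_plasma = fu_plasma,
                 blood_plasma_ratio = blood_plasma_ratio, v_sys = v_sys,
                 renal_cl = renal_cl, pathways = pathways,
                 cv_ka = cv_ka, cv_v_sys = cv_v_sys),
            class = "compound_spec")
}

#' Define the shared physiology block
#'
#' Flows and organ sizes of the reduced (minimal) PBPK topology:
#' gut lumen, portal vein, well-stirred liver, one lumped systemic
#' compartment.
#'
#' @param q_hepatic_total Total hepatic blood flow, L/h; must equal
#'   `q_portal + q_hepatic_arterial`.
#' @param q_portal Portal vein flow, L/h.
#' @param q_hepatic_arterial Hepatic artery flow, L/h.
#' @param q_gut Effective villous blood flow used by the algebraic gut
#'   first-pass extraction, L/h.
#' @param liver_weight g.
#' @param mppgl mg microsomal-equivalent protein per g liver.
#' @param gut_protein mg total intestinal enzyme-bearing protein.
#' @param v_portal,v_liver Compartment volumes, L.
#' @param v_gut_lumen Luminal fluid volume used as the surrogate for
#'   inhibitor concentration at the gut wall, L.
#' @param fu_gut Unbound fraction in the enterocyte compartment (1 by
#'   convention).
#' @return An object of class `physiology_spec`.
#' @export
physiology_spec <- function(q_hepatic_total, q_portal, q_hepatic_arterial,
                            q_gut, liver_weight, mppgl, gut_protein,
                            v_portal, v_liver, v_gut_lumen = 0.25,
                            fu_gut = 1) {
  check_num(q_hepatic_total, "q_hepatic_total", lower = 1e-9)
  check_num(q_portal, "q_portal", lower = 1e-9)
  check_num(q_hepatic_arterial, "q_hepatic_arterial", lower = 0)
  check_num(q_gut, "q_gut", lower = 1e-9)
  check_num(liver_weight, "liver_weight", lower = 1e-9)
  check_num(mppgl, "mppgl", lower = 1e-9)
  check_num(gut_protein, "gut_protein", lower = 1e-9)
  check_num(v_portal, "v_portal", lower = 1e-9)
  check_num(v_liver, "v_liver", lower = 1e-9)
  check_num(v_gut_lumen, "v_gut_lumen", lower = 1e-9)
  check_num(fu_gut, "fu_gut", lower = 0, upper = 1)
  if (abs(q_hepatic_total - (q_portal + q_hepatic_arterial)) >
      1e-9 * q_hepatic_total)
    stop_validation(
      "field 'q_hepatic_total' must equal q_portal + q_hepatic_arterial")
  structure(list(q_hepatic_total = q_hepatic_total, q_portal = q_portal,
                 q_hepatic_arterial = q_hepatic_arterial, q_gut = q_gut,
                 liver_weight = liver_weight, mppgl = mppgl,
                 gut_protein = gut_protein, v_portal = v_portal,
                 v_liver = v_liver, v_gut_lumen = v_gut_lumen,
                 fu_gut = fu_gut),
            class = "physiology_spec")
}

#' Define the platelet turnover / irreversible inactivation PD block
#'
#' Parameters of the turnover model
#' `dP/dt = kin - P*kout - P*C*kirre`, where `P` is the platelet
#' reactivity pool normalised to a baseline of 1 (so `kin = kout`
#' numerically) and `C` is the molar concentration of the active
#' metabolite.
#'
#' @param kin Zero-order platelet production, pool-units/h.  Must equal
#'   `kout` under the baseline-1 normalisation.
#' @param kout First-order platelet degradation, 1/h.
#' @param kirre Second-order irreversible inactivation constant, 1/(uM h).
#' @param mpa0 Baseline maximal platelet aggregation, percent.
#' @param cv_kin,cv_kout,cv_kirre,cv_mpa0 Log-normal inter-individual CVs.
#'   `cv_kin` is tied to `cv_kout`: one shared multiplier is sampled so the
#'   normalised baseline `kin/kout = 1` holds for every subject.
#' @return An object of class `pd_spec`.
#' @export
pd_spec <- function(kin, kout, kirre, mpa0,
                    cv_kin = 0, cv_kout = 0, cv_kirre = 0, cv_mpa0 = 0) {
  check_num(kin, "kin", lower = 1e-12)
  check_num(kout, "kout", lower = 1e-12)
  check_num(kirre, "kirre", lower = 0)
  check_num(mpa0, "mpa0", lower = 1e-9, upper = 100)
  for (f in c("cv_kin", "cv_kout", "cv_kirre", "cv_mpa0"))
    check_num(get(f), f, lower = 0)
  if (abs(kin - kout) > 1e-9 * kout)
    stop_validation(
      "field 'kin' must equal kout (platelet pool normalised to baseline 1)")
  structure(list(kin = kin, kout = kout, kirre = kirre, mpa0 = mpa0,
                 cv_kin = cv_kin, cv_kout = cv_kout, cv_kirre = cv_kirre,
                 cv_mpa0 = cv_mpa0),
            class = "pd_spec")
}

#' Define a virtual population
#'
#' @param ethnicity Text tag (`"Chinese"` or `"Caucasian"`); selects a
#'   CYP2C19 phenotype frequency block.
#' @param phenotype_frequencies Named numeric vector over `EM`, `IM`, `PM`,
#'   summing to 1.
#' @param genotype_settings Named logical vector of genotype labels applied to
#'   every subject (e.g. `c(CES1_428GA = TRUE)`).
#' @param n_subjects Total number of virtual subjects.
#' @param n_trials Number of virtual trials the subjects are grouped into
#'   (`n_subjects` must be a multiple).
#' @param seed Integer RNG seed making sampling reproducible.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(ethnicity, phenotype_frequencies,
                            genotype_settings = logical(0),
                            n_subjects = 100, n_trials = 10, seed = 1L) {
  if (!is.character(ethnicity) || length(ethnicity) != 1)
    stop_validation("field 'ethnicity' must be a string")
  pf <- unlist(phenotype_frequencies)
  if (is.null(names(pf)) || !all(names(pf) %in% PHENOTYPES))
    stop_validation("field 'phenotype_frequencies' must be named over EM/IM/PM")
  freq <- stats::setNames(numeric(3), PHENOTYPES)
  freq[names(pf)] <- pf
  if (any(freq < 0))
    stop_validation("field 'phenotype_frequencies' must be non-negative")
  if (abs(sum(freq) - 1) > 1e-9)
    stop_validation("field 'phenotype_frequencies' must sum to 1 (got %g)",
                    sum(freq))
  check_num(n_subjects, "n_subjects", lower = 1)
  check_num(n_trials, "n_trials", lower = 1)
  if (n_subjects %% n_trials != 0)
    stop_validation("field 'n_subjects' must be a multiple of n_trials")
  gs <- unlist(genotype_settings)
  if (length(gs) && (!all(names(gs) %in% GENOTYPE_LABELS)))
    stop_validation("field 'genotype_settings': unknown label(s) %s",
                    paste(setdiff(names(gs), GENOTYPE_LABELS), collapse = ", "))
  structure(list(ethnicity = ethnicity, phenotype_frequencies = freq,
                 genotype_settings = stats::setNames(as.logical(gs), names(gs)),
                 n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "population_spec")
}

#' Assemble and validate a model registry
#'
#' The registry bundles every input of a simulation: compound specifications
#' (with their metabolic pathway network), shared physiology, PD constants,
#' population blocks and perpetrator (inhibitor) models.
#'
#' @param compounds Named list of [compound_spec()] objects.
#' @param physiology A [physiology_spec()].
#' @param pd A [pd_spec()].
#' @param populations Named list of [population_spec()] blocks.
#' @param perpetrators Named list of perpetrator definitions (see
#'   [perpetrator_spec()]), may be empty.
#' @return A validated object of class `pkpd_registry`.
#' @export
new_registry <- function(compounds, physiology, pd, populations = list(),
                         perpetrators = list()) {
  reg <- structure(list(compounds = compounds, physiology = physiology,
                        pd = pd, populations = populations,
                        perpetrators = perpetrators),
                   class = "pkpd_registry")
  validate_registry(reg)
  reg
}

#' Validate a registry
#'
#' Re-checks every field invariant plus the cross-compound constraints: all
#' pathway products must name registered compounds and the product graph must
#' be acyclic.
#'
#' @param registry A `pkpd_registry`.
#' @return The registry, invisibly; errors on violation.
#' @export
validate_registry <- function(registry) {
  if (!inherits(registry, "pkpd_registry"))
    stop_validation("not a pkpd_registry")
  cmp <- registry$compounds
  if (!length(cmp)) stop_schema("missing required key 'compounds'")
  if (is.null(names(cmp)) || any(!nzchar(names(cmp))))
    stop_validation("field 'compounds' must be a named list")
  for (nm in names(cmp)) {
    cs <- cmp[[nm]]
    if (!inherits(cs, "compound_spec"))
      stop_validation("compound '%s' is not a compound_spec", nm)
    if (!identical(cs$name, nm))
      stop_validation("compound '%s': name field '%s' disagrees with key",
                      nm, cs$name)
    for (pw in cs$pathways) {
      if (nzchar(pw$product) && !pw$product %in% names(cmp))
        stop_validation(
          "compound '%s': pathway product '%s' is not a registered compound",
          nm, pw$product)
    }
  }
  # acyclicity of the product graph by repeated leaf removal
  edges <- list()
  for (nm in names(cmp))
    edges[[nm]] <- unique(unlist(lapply(cmp[[nm]]$pathways, function(p)
      if (nzchar(p$product)) p$product else character(0))))
  left <- names(cmp)
  repeat {
    leaves <- left[vapply(left, function(n)
      length(intersect(edges[[n]], left)) == 0, TRUE)]
    if (!length(leaves)) {
      if (length(left))
        stop_validation("field 'pathways': metabolite product graph has a cycle (%s)",
                        paste(left, collapse = " -> "))
      break
    }
    left <- setdiff(left, leaves)
    if (!length(left)) break
  }
  if (!inherits(registry$physiology, "physiology_spec"))
    stop_schema("missing required key 'physiology'")
  if (!inherits(registry$pd, "pd_spec"))
    stop_schema("missing required key 'pd'")
  for (nm in names(registry$populations))
    if (!inherits(registry$populations[[nm]], "population_spec"))
      stop_validation("population '%s' is not a population_spec", nm)
  invisible(registry)
}

#' Parent drugs of a registry
#'
#' Compounds with a finite absorption rate constant are orally dosable
#' parents; the rest are metabolites.
#' @param registry A `pkpd_registry`.
#' @return Character vector of parent compound names.
#' @export
parent_compounds <- function(registry) {
  names(Filter(function(c) is.finite(c$ka), registry$compounds))
}

#' @export
print.pkpd_registry <- function(x, ...) {
  cat("PBPK/PD model registry\n")
  cat(sprintf("  compounds:   %s\n", paste(names(x$compounds), collapse = ", ")))
  cat(sprintf("  parents:     %s\n", paste(parent_compounds(x), collapse = ", ")))
  npw <- sum(vapply(x$compounds, function(c) length(c$pathways), 1L))
  cat(sprintf("  pathways:    %d enzymatic routes\n", npw))
  cat(sprintf("  populations: %s\n",
              paste(names(x$populations), collapse = ", ")))
  cat(sprintf("  perpetrators: %s\n",
              if (length(x$perpetrators)) paste(names(x$perpetrators), collapse = ", ")
              else "(none)"))
  invisible(x)
}
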