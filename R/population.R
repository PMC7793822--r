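# Virtual-subject sampling, CYP2C19 phenotypes and CES genotype scaling.

lognormal_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sdlog))   # median 1
}

#' A reference individual with no variability
#'
#' All sampled multipliers are 1 and the phenotype is extensive metabolizer;
#' simulating this subject reproduces the registry's central parameter values
#' exactly.
#'
#' @param id Subject identifier.
#' @param phenotype CYP2C19 phenotype label (`"EM"`, `"IM"`, `"PM"`).
#' @return An object of class `virtual_individual`.
#' @export
reference_individual <- function(id = 0L, phenotype = "EM") {
  ind <- structure(list(id = as.integer(id),
                        multipliers = numeric(0),
                        enzyme_multipliers =
                          stats::setNames(rep(1, length(ENZYMES)), ENZYMES),
                        phenotype = phenotype,
                        genotypes = character(0),
                        seed_token = NA_integer_),
                   class = "virtual_individual")
  apply_phenotype(ind)
}

ind_mult <- function(ind, key) {
  m <- ind$multipliers[key]
  ifelse(is.na(m), 1, m)
}

#' Sample a virtual population
#'
#' Draws `n_subjects` virtual individuals.  Every varying parameter gets an
#' independent log-normal multiplier with median 1 and the configured CV
#' (`sigma^2 = log(1 + CV^2)`): one multiplier per enzymatic pathway
#' intrinsic clearance, per-compound `ka` and `v_sys`, and the PD constants
#' (`kin`/`kout` share one multiplier so the normalised platelet baseline
#' stays at 1).  CYP2C19 phenotypes are drawn from the block's frequencies
#' and converted to enzyme abundance multipliers; genotype settings of the
#' block are applied to every subject.  Sampling is deterministic given the
#' block's seed and leaves the caller's RNG state untouched.
#'
#' @param pop A [population_spec()].
#' @param registry A validated `pkpd_registry`.
#' @return List of `virtual_individual` objects.
#' @export
sample_population <- function(pop, registry) {
  stopifnot(inherits(pop, "population_spec"))
  validate_registry(registry)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(pop$seed)

  n <- pop$n_subjects
  keys <- character(0); cvs <- numeric(0)
  for (nm in names(registry$compounds)) {
    cs <- registry$compounds[[nm]]
    if (is.finite(cs$ka)) {
      keys <- c(keys, paste0("ka:", nm)); cvs <- c(cvs, cs$cv_ka)
    }
    keys <- c(keys, paste0("v_sys:", nm)); cvs <- c(cvs, cs$cv_v_sys)
    for (p in cs$pathways) {
      keys <- c(keys, sprintf("clint:%s:%s:%s", nm, p$enzyme, p$site))
      cvs <- c(cvs, p$cv)
    }
  }
  pdspec <- registry$pd
  keys <- c(keys, "pd:kout", "pd:kirre", "pd:mpa0")
  cvs <- c(cvs, pdspec$cv_kout, pdspec$cv_kirre, pdspec$cv_mpa0)

  phen <- sample(PHENOTYPES, n, replace = TRUE,
                 prob = pop$phenotype_frequencies[PHENOTYPES])
  lapply(seq_len(n), function(i) {
    mult <- stats::setNames(vapply(cvs, function(cv) lognormal_mult(1, cv), 1),
                            keys)
    ind <- structure(list(id = i,
                          multipliers = mult,
                          enzyme_multipliers =
                            stats::setNames(rep(1, length(ENZYMES)), ENZYMES),
                          phenotype = phen[i],
                          genotypes = character(0),
                          seed_token = pop$seed + i),
                     class = "virtual_individual")
    ind <- apply_phenotype(ind)
    for (g in names(pop$genotype_settings))
      if (isTRUE(pop$genotype_settings[[g]])) ind <- apply_genotype(ind, g)
    ind
  })
}

#' Apply a CYP2C19 phenotype as an enzyme abundance multiplier
#'
#' Extensive metabolizers keep full CYP2C19 activity (multiplier 1),
#' intermediate metabolizers carry one functional allele (0.5, gene-dose
#' proportionality), poor metabolizers carry two null alleles (0).  Other
#' enzymes are untouched.
#'
#' @param individual A `virtual_individual` with its `phenotype` field set.
#' @param phenotype Optional phenotype overriding the individual's own label.
#' @return The modified individual.
#' @export
apply_phenotype <- function(individual, phenotype = NULL) {
  ph <- if (is.null(phenotype)) individual$phenotype else phenotype
  if (!ph %in% PHENOTYPES)
    stop_validation("unknown CYP2C19 phenotype label '%s'", ph)
  individual$phenotype <- ph
  individual$enzyme_multipliers["CYP2C19"] <-
    c(EM = 1, IM = 0.5, PM = 0)[[ph]]
  individual
}

#' Apply a carboxylesterase genotype scaling
#'
#' `CES1_428GA` multiplies every CES1 intrinsic clearance by 0.8 (the
#' reported ~20% activity loss of the 428 G>A variant); `CES2_defect`
#' divides every CES2 intrinsic clearance by 20 (functionally deficient
#' alleles).
#'
#' @param individual A `virtual_individual`.
#' @param label `"CES1_428GA"` or `"CES2_defect"`.
#' @return The modified individual.
#' @export
apply_genotype <- function(individual, label) {
  if (!label %in% GENOTYPE_LABELS)
    stop_validation("unknown genotype label '%s'", label)
  if (label %in% individual$genotypes) return(individual)
  if (label == "CES1_428GA")
    individual$enzyme_multipliers["CES1"] <-
      individual$enzyme_multipliers["CES1"] * 0.8
  else
    individual$enzyme_multipliers["CES2"] <-
      individual$enzyme_multipliers["CES2"] / 20
  individual$genotypes <- c(individual$genotypes, label)
  individual
}

#' Effective intrinsic clearance for one pathway of one individual
#'
#' The registry value times the individual's sampled pathway multiplier and
#' enzyme abundance multiplier (phenotype/genotype).
#'
#' @param registry A `pkpd_registry`.
#' @param individual A `virtual_individual`.
#' @param compound,enzyme,site Pathway coordinates.
#' @return Effective clint in uL/min/mg protein.
#' @export
effective_clint <- function(registry, individual, compound, enzyme, site) {
  cs <- registry$compounds[[compound]]
  if (is.null(cs)) stop_validation("unknown compound '%s'", compound)
  hit <- Filter(function(p) p$enzyme == enzyme && p$site == site, cs$pathways)
  if (!length(hit))
    stop_validation("compound '%s' has no %s pathway at site '%s'",
                    compound, enzyme, site)
  key <- sprintf("clint:%s:%s:%s", compound, enzyme, site)
  hit[[1]]$clint * ind_mult(individual, key) *
    individual$enzyme_multipliers[[enzyme]]
}

#' Dump a population to a data frame
#'
#' One row per subject, one column per sampled multiplier plus phenotype and
#' genotype flags; intended for CSV audit trails.
#'
#' @param individuals List of `virtual_individual` objects.
#' @return A `data.frame`.
#' @export
population_table <- function(individuals) {
  keys <- names(individuals[[1]]$multipliers)
  m <- t(vapply(individuals, function(i) i$multipliers[keys],
                numeric(length(keys))))
  colnames(m) <- keys
  data.frame(subject = vapply(individuals, function(i) i$id, 1L),
             phenotype = vapply(individuals, function(i) i$phenotype, ""),
             genotypes = vapply(individuals, function(i)
               paste(i$genotypes, collapse = "+"), ""),
             m, check.names = FALSE)
}

#' @export
print.virtual_individual <- function(x, ...) {
  cat(sprintf("virtual individual #%d  phenotype=%s%s\n", x$id, x$phenotype,
              if (length(x$genotypes))
                paste0("  genotypes=", paste(x$genotypes, collapse = "+"))
              else ""))
  nm <- x$enzyme_multipliers[x$enzyme_multipliers != 1]
  if (length(nm))
    cat("  enzyme multipliers:",
        paste(sprintf("%s=%g", names(nm), nm), collapse = ", "), "\n")
  cat(sprintf("  %d sampled parameter multipliers\n", length(x$multipliers)))
  invisible(x)
}
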