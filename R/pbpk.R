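# Minimal PBPK engine: gut lumen -> algebraic gut first-pass -> portal vein ->
# well-stirred liver -> lumped systemic compartment, with mole-conserving
# hand-off of sequentially formed metabolites.  All internal amounts are nmol;
# molecular weight enters only at the dosing and concentration-output
# boundaries, so metabolite transfer is conserving by construction.

#' Scale an in-vitro intrinsic clearance to organ level
#'
#' Standard in-vitro-to-in-vivo extrapolation: clearance per mg enzyme-bearing
#' protein times the organ's protein content, converted from uL/min to L/h.
#'
#' @param clint Intrinsic clearance, uL/min/mg protein.
#' @param protein_mg Protein content of the organ, mg (liver:
#'   `mppgl * liver_weight`; gut: total intestinal enzyme-bearing protein).
#' @return Scaled intrinsic clearance, L/h.
#' @export
scale_clint <- function(clint, protein_mg) {
  if (any(clint < 0) || any(protein_mg < 0))
    stop_validation("scale_clint: inputs must be >= 0")
  clint * protein_mg * 60 / 1e6
}

#' Fraction of absorbed drug escaping gut-wall metabolism
#'
#' Algebraic gut first-pass extraction: the fraction of absorbed drug that
#' escapes the gut wall is `Qgut / (Qgut + fu_gut * CLint_gut)`.  The
#' complement is converted mole-for-mole into the gut metabolite product.
#'
#' @param clint_gut_scaled Total scaled gut intrinsic clearance, L/h.
#' @param q_gut Effective villous blood flow, L/h; must be > 0.
#' @param fu_gut Unbound fraction at the gut wall.
#' @return Fraction escaping, in (0, 1].
#' @export
fraction_escaping_gut <- function(clint_gut_scaled, q_gut, fu_gut = 1) {
  if (any(q_gut <= 0)) stop_validation("fraction_escaping_gut: q_gut must be > 0")
  if (any(clint_gut_scaled < 0))
    stop_validation("fraction_escaping_gut: clint must be >= 0")
  q_gut / (q_gut + fu_gut * clint_gut_scaled)
}

#' Well-stirred hepatic clearance
#'
#' `CLh = Qh * fu * CLint / (Qh + fu * CLint)`; flow-limited for very
#' efficient enzymes, capacity-limited for poorly extracted compounds.
#'
#' @param q_h Hepatic blood flow, L/h; must be > 0.
#' @param fu_blood Unbound fraction in blood.
#' @param clint_u_total Total scaled unbound intrinsic clearance, L/h.
#' @return Hepatic clearance, L/h.
#' @export
wellstirred_hepatic_clearance <- function(q_h, fu_blood, clint_u_total) {
  if (any(q_h <= 0)) stop_validation("wellstirred_hepatic_clearance: q_h must be > 0")
  q_h * fu_blood * clint_u_total / (q_h + fu_blood * clint_u_total)
}

compound_closure <- function(registry, drug) {
  seen <- drug
  queue <- drug
  while (length(queue)) {
    nm <- queue[1]; queue <- queue[-1]
    for (p in registry$compounds[[nm]]$pathways) {
      if (nzchar(p$product) && !p$product %in% seen) {
        seen <- c(seen, p$product)
        queue <- c(queue, p$product)
      }
    }
  }
  seen
}

#' Build the ODE system for one subject and one parent drug
#'
#' Assembles the linear state-space model for the parent and every metabolite
#' reachable through its pathway network.  The parent has lumen, portal,
#' liver and systemic states; metabolites have portal, liver and systemic
#' states; one cumulative-elimination accumulator per compound (auxiliary,
#' not part of the core state count) closes the mole balance.  Every pathway
#' intrinsic clearance is multiplied by the subject's sampled pathway
#' multiplier and enzyme abundance multiplier (phenotype/genotype) before
#' in-vitro-to-in-vivo scaling.
#'
#' @param registry A validated `pkpd_registry`.
#' @param individual A `virtual_individual`; defaults to the no-variability
#'   reference subject.
#' @param drug Parent compound to dose (must have a finite `ka`).
#' @return An object of class `pbpk_system`.
#' @export
build_system <- function(registry, individual = reference_individual(),
                         drug = "vicagrel") {
  validate_registry(registry)
  if (!drug %in% names(registry$compounds))
    stop_validation("unknown compound '%s'", drug)
  if (!is.finite(registry$compounds[[drug]]$ka))
    stop_validation("compound '%s' has no ka; only parents can be dosed", drug)

  phys <- registry$physiology
  comps <- compound_closure(registry, drug)
  ncomp <- length(comps)
  liver_protein <- phys$mppgl * phys$liver_weight

  state_names <- c(paste0("lumen_", drug),
                   as.vector(t(outer(c("portal_", "liver_", "sys_"), comps,
                                     paste0))),
                   paste0("elim_", comps))
  n_core <- 1 + 3 * ncomp
  nst <- length(state_names)
  idx <- function(kind, comp) match(paste0(kind, "_", comp), state_names)

  v_sys <- vapply(comps, function(c)
    registry$compounds[[c]]$v_sys * ind_mult(individual, paste0("v_sys:", c)),
    1)
  mw <- vapply(comps, function(c) registry$compounds[[c]]$molecular_weight, 1)
  fu_liver <- vapply(comps, function(c) {
    cs <- registry$compounds[[c]]
    cs$fu_plasma / cs$blood_plasma_ratio
  }, 1)

  A <- matrix(0, nst, nst, dimnames = list(state_names, state_names))
  liver_paths <- list()

  for (c in comps) {
    cs <- registry$compounds[[c]]
    p <- idx("portal", c); l <- idx("liver", c); s <- idx("sys", c)
    e <- idx("elim", c)
    A[p, s] <- A[p, s] + phys$q_portal / v_sys[c]
    A[p, p] <- A[p, p] - phys$q_portal / phys$v_portal
    A[l, p] <- A[l, p] + phys$q_portal / phys$v_portal
    A[l, s] <- A[l, s] + phys$q_hepatic_arterial / v_sys[c]
    A[l, l] <- A[l, l] - phys$q_hepatic_total / phys$v_liver
    A[s, l] <- A[s, l] + phys$q_hepatic_total / phys$v_liver
    A[s, s] <- A[s, s] - (phys$q_portal + phys$q_hepatic_arterial +
                            cs$renal_cl) / v_sys[c]
    A[e, s] <- A[e, s] + cs$renal_cl / v_sys[c]
    for (pw in Filter(function(x) x$site == "liver", cs$pathways)) {
      clint_eff <- pw$clint *
        ind_mult(individual, sprintf("clint:%s:%s:liver", c, pw$enzyme)) *
        individual$enzyme_multipliers[[pw$enzyme]]
      rate <- fu_liver[c] * scale_clint(clint_eff, liver_protein) / phys$v_liver
      dest <- if (nzchar(pw$product)) idx("liver", pw$product) else e
      A[l, l] <- A[l, l] - rate
      A[dest, l] <- A[dest, l] + rate
      liver_paths[[length(liver_paths) + 1]] <-
        list(compound = c, enzyme = pw$enzyme, rate = rate, src = l,
             dest = dest)
    }
  }

  # parent absorption and algebraic gut first-pass split
  cs <- registry$compounds[[drug]]
  ka_eff <- cs$ka * ind_mult(individual, paste0("ka:", drug))
  lum <- idx("lumen", drug)
  gut_pw <- Filter(function(x) x$site == "gut", cs$pathways)
  gut <- list(lumen = lum, parent_portal = idx("portal", drug),
              ka = ka_eff, q_gut = phys$q_gut, fu_gut = phys$fu_gut,
              enzymes = vapply(gut_pw, function(x) x$enzyme, ""),
              clint_lh = vapply(gut_pw, function(x)
                scale_clint(x$clint *
                  ind_mult(individual,
                           sprintf("clint:%s:%s:gut", drug, x$enzyme)) *
                  individual$enzyme_multipliers[[x$enzyme]],
                  phys$gut_protein), 1),
              dest = vapply(gut_pw, function(x)
                if (nzchar(x$product)) idx("portal", x$product)
                else idx("elim", drug), 1L))
  set_gut_column <- function(A, factors = rep(1, length(gut$clint_lh))) {
    cl <- gut$clint_lh * factors
    fg <- fraction_escaping_gut(sum(cl), gut$q_gut, gut$fu_gut)
    A[, lum] <- 0
    A[lum, lum] <- -ka_eff
    A[gut$parent_portal, lum] <- ka_eff * fg
    if (length(cl) && sum(cl) > 0) {
      share <- cl / sum(cl)
      for (j in seq_along(cl))
        A[gut$dest[j], lum] <- A[gut$dest[j], lum] +
          ka_eff * (1 - fg) * share[j]
    }
    A
  }
  A <- set_gut_column(A)

  structure(list(parent = drug, compounds = comps, state_names = state_names,
                 n_core = n_core, A = A, idx = idx, gut = gut,
                 set_gut_column = set_gut_column,
                 liver_paths = liver_paths, v_sys = v_sys, mw = mw,
                 fa = cs$fa, phys = phys, pd = registry$pd,
                 individual = individual, perpetrator = NULL),
            class = "pbpk_system")
}

#' @export
print.pbpk_system <- function(x, ...) {
  cat(sprintf("PBPK system for %s (%d compounds, %d core states)\n",
              x$parent, length(x$compounds), x$n_core))
  cat("  compounds:", paste(x$compounds, collapse = " -> "), "\n")
  if (length(x$gut$enzymes))
    cat("  gut first-pass enzymes:", paste(x$gut$enzymes, collapse = ", "),
        sprintf(" (Fg = %.3g)\n",
                fraction_escaping_gut(sum(x$gut$clint_lh), x$gut$q_gut,
                                      x$gut$fu_gut)))
  else cat("  no gut-wall metabolism (Fg = 1)\n")
  if (!is.null(x$perpetrator))
    cat("  co-administered perpetrator:", x$perpetrator$spec$name, "\n")
  invisible(x)
}

#' Build a loading-dose / maintenance-dose regimen
#'
#' @param drug Parent compound name.
#' @param loading_dose mg given at `start_h`.
#' @param maintenance_dose mg/day on the following days.
#' @param n_days Total dosing days (day 1 = loading dose).
#' @param start_h Time of the first dose, h.
#' @return A `data.frame` with columns `time_h`, `dose_mg` and attribute
#'   `drug`, of class `dosing_regimen`.
#' @export
dosing_regimen <- function(drug, loading_dose, maintenance_dose = loading_dose,
                           n_days = 1, start_h = 0) {
  if (loading_dose < 0 || maintenance_dose < 0)
    stop_validation("doses must be >= 0")
  times <- start_h + 24 * (seq_len(n_days) - 1)
  reg <- data.frame(time_h = times,
                    dose_mg = c(loading_dose,
                                rep(maintenance_dose, n_days - 1)))
  structure(reg, drug = drug, class = c("dosing_regimen", "data.frame"))
}

#' Output time grid for a dosing + washout window
#'
#' Dense (default 0.1 h) spacing while doses are given, coarser (default 1 h)
#' spacing during washout.
#'
#' @param dosing_end_h End of the dosing period, h.
#' @param washout_end_h End of the simulation, h (defaults to no washout).
#' @param dt_dosing,dt_washout Grid spacings, h.
#' @param start_h Grid start.
#' @return Numeric vector of times.
#' @export
simulation_grid <- function(dosing_end_h, washout_end_h = dosing_end_h,
                            dt_dosing = 0.1, dt_washout = 1, start_h = 0) {
  g <- seq(start_h, dosing_end_h, by = dt_dosing)
  if (washout_end_h > dosing_end_h)
    g <- c(g, seq(dosing_end_h + dt_washout, washout_end_h, by = dt_washout))
  unique(g)
}

rhs_factory <- function(system) {
  A <- system$A
  perp <- system$perpetrator
  if (is.null(perp)) {
    return(list(
      rhs = function(t, y, parms) list(A %*% y),
      y0_extra = numeric(0)))
  }

  spec <- perp$spec
  inh <- perp$inhibition
  opts <- perp$options
  nst <- nrow(A)
  mbi_enzymes <- names(inh$mbi)
  n_mbi <- length(mbi_enzymes)

  # per-enzyme liver delta matrices: A(t) = A_base + sum_e (f_e - 1) D_e
  affected <- unique(c(names(inh$ki), mbi_enzymes))
  D <- list()
  for (e in affected) {
    De <- matrix(0, nst, nst)
    for (lp in system$liver_paths) {
      if (lp$enzyme == e) {
        De[lp$src, lp$src] <- De[lp$src, lp$src] - lp$rate
        De[lp$dest, lp$src] <- De[lp$dest, lp$src] + lp$rate
      }
    }
    if (any(De != 0)) D[[e]] <- De
  }
  gut_inhibited <- isTRUE(opts$inhibit_gut) &&
    any(system$gut$enzymes %in% names(inh$ki))
  liver_on <- !identical(opts$inhibit_liver, FALSE)

  rhs <- function(t, y, parms) {
    yc <- y[seq_len(nst)]
    E <- if (n_mbi) y[nst + seq_len(n_mbi)] else numeric(0)
    i_u <- perpetrator_concentration(spec, t)
    At <- A
    if (liver_on) {
      for (e in names(D)) {
        f <- 1
        if (!is.null(inh$ki[e]) && !is.na(inh$ki[e]))
          f <- f * reversible_inhibition_factor(i_u, inh$ki[[e]])
        if (e %in% mbi_enzymes) f <- f * E[match(e, mbi_enzymes)]
        if (f != 1) At <- At + (f - 1) * D[[e]]
      }
    }
    if (gut_inhibited) {
      i_g <- gut_lumen_concentration(spec, t, system$phys$v_gut_lumen)
      fac <- vapply(system$gut$enzymes, function(e) {
        if (!is.null(inh$ki[e]) && !is.na(inh$ki[e]))
          reversible_inhibition_factor(i_g, inh$ki[[e]]) else 1
      }, 1)
      At <- system$set_gut_column(At, fac)
    }
    dy <- as.vector(At %*% yc)
    if (n_mbi) {
      dE <- vapply(seq_len(n_mbi), function(j) {
        m <- inh$mbi[[mbi_enzymes[j]]]
        m$k_deg * (1 - E[j]) -
          m$k_inact * i_u / (m$k_i_app + i_u) * E[j]
      }, 1)
      dy <- c(dy, dE)
    }
    list(dy)
  }
  list(rhs = rhs, y0_extra = rep(1, n_mbi),
       extra_names = if (n_mbi) paste0("E_", mbi_enzymes) else character(0))
}

#' Simulate one subject under a dosing regimen
#'
#' Integrates the linear PBPK system with a stiff-capable solver
#' (`deSolve::lsoda`, relative tolerance 1e-8, absolute tolerance 1e-10
#' nmol).  Doses enter the gut lumen as boluses of
#' `fa * dose_mg * 1e6 / MW` nmol; plasma concentrations are
#' `systemic amount / v_sys * MW / 1000` in ng/mL.
#'
#' @param system A `pbpk_system` from [build_system()] (optionally carrying a
#'   perpetrator via [coadminister()]).
#' @param regimen A [dosing_regimen()] for the system's parent drug.
#' @param t_grid Output times, h; must cover every dose time.
#' @param subject,arm Labels stored on the profile.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `concentration_profile`.
#' @export
simulate_individual <- function(system, regimen, t_grid,
                                subject = system$individual$id, arm = "",
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "pbpk_system"))
  if (!identical(attr(regimen, "drug"), system$parent))
    stop_validation("regimen drug '%s' does not match system parent '%s'",
                    attr(regimen, "drug"), system$parent)
  if (any(regimen$dose_mg < 0)) stop_validation("doses must be >= 0")
  if (min(t_grid) > min(regimen$time_h) || max(t_grid) < max(regimen$time_h))
    stop_validation("t_grid must cover all dose times")

  fac <- rhs_factory(system)
  nst <- nrow(system$A)
  y0 <- stats::setNames(rep(0, nst), system$state_names)
  if (length(fac$y0_extra))
    y0 <- c(y0, stats::setNames(fac$y0_extra, fac$extra_names))

  mw_parent <- system$mw[[system$parent]]
  bolus <- system$fa * regimen$dose_mg * 1e6 / mw_parent
  lumen_name <- system$state_names[system$gut$lumen]

  times <- sort(unique(c(t_grid, regimen$time_h)))
  # apply a dose at the very first time point directly to the initial state
  # (solver event machinery only fires strictly inside the integration window)
  first <- regimen$time_h <= times[1]
  if (any(first)) y0[lumen_name] <- y0[lumen_name] + sum(bolus[first])
  ev <- NULL
  if (any(!first))
    ev <- list(data = data.frame(var = lumen_name,
                                 time = regimen$time_h[!first],
                                 value = bolus[!first], method = "add"))

  out <- deSolve::lsoda(y = y0, times = times, func = fac$rhs, parms = NULL,
                        rtol = rtol, atol = atol, events = ev, maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("ODE integration failed near t = %.3f h",
                 out[nrow(out), "time"]))
  keep <- times %in% t_grid
  amounts <- out[keep, -1, drop = FALSE]
  tout <- out[keep, 1]

  conc <- vapply(system$compounds, function(c)
    amounts[, paste0("sys_", c)] / system$v_sys[[c]] * system$mw[[c]] / 1000,
    numeric(sum(keep)))
  colnames(conc) <- system$compounds

  structure(list(times = tout, conc = conc, amounts = amounts,
                 compounds = system$compounds, mw = system$mw,
                 v_sys = system$v_sys, subject = subject, arm = arm,
                 regimen = regimen, parent = system$parent,
                 dosed_nmol = data.frame(time_h = regimen$time_h,
                                         nmol = bolus),
                 n_core = system$n_core),
            class = "concentration_profile")
}

#' Mole balance of a simulated profile
#'
#' Total moles in every compartment (including the cumulative-elimination
#' accumulators) compared with the absorbed dose at each output time.
#'
#' @param profile A `concentration_profile`.
#' @return A `data.frame` with columns `time_h`, `total_nmol`, `dosed_nmol`
#'   and `rel_error`.
#' @export
mole_balance <- function(profile) {
  core_cols <- !grepl("^E_", colnames(profile$amounts))
  total <- rowSums(profile$amounts[, core_cols, drop = FALSE])
  t0 <- min(profile$times)
  # output at a dose instant is recorded before the bolus is applied; only
  # the initial dose (folded into the start state) is included at its time
  dosed <- vapply(profile$times, function(t)
    sum(profile$dosed_nmol$nmol[profile$dosed_nmol$time_h < t |
                                  profile$dosed_nmol$time_h <= t0]), 1)
  data.frame(time_h = profile$times, total_nmol = total, dosed_nmol = dosed,
             rel_error = ifelse(dosed > 0, abs(total - dosed) / dosed, 0))
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  do.call(rbind, lapply(x$compounds, function(c)
    data.frame(subject = x$subject, arm = x$arm, compound = c,
               time_h = x$times, conc_ng_ml = x$conc[, c])))
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("concentration profile: %s, subject %s%s\n", x$parent,
              x$subject, if (nzchar(x$arm)) paste0(", arm ", x$arm) else ""))
  cat(sprintf("  %d time points over %.1f h\n", length(x$times),
              max(x$times) - min(x$times)))
  for (c in x$compounds)
    cat(sprintf("  %-18s Cmax %.4g ng/mL\n", c, max(x$conc[, c])))
  invisible(x)
}

#' @export
plot.concentration_profile <- function(x, compounds = x$compounds,
                                       log = "", ...) {
  cc <- x$conc[, compounds, drop = FALSE]
  matplot(x$times, cc, type = "l", lty = 1, col = seq_along(compounds),
          xlab = "time (h)", ylab = "plasma concentration (ng/mL)",
          log = log, ...)
  legend("topright", legend = compounds, col = seq_along(compounds),
         lty = 1, bty = "n")
  invisible(x)
}
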