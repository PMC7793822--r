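# Perpetrator forcing functions and enzyme inhibition: reversible
# (competitive) inhibition and mechanism-based inactivation.  Perpetrator
# pharmacokinetics are deterministic one-compartment oral models evaluated
# in closed form; victim inter-individual variability dominates ratio noise
# under the paired-arm design.

#' Define a perpetrator (inhibitor) drug
#'
#' A deterministic one-compartment oral PK model used as a forcing function
#' on the victim system.
#'
#' @param name Drug name.
#' @param dose mg per administration.
#' @param regimen Administration times, h (absolute time axis shared with the
#'   victim).
#' @param ka First-order absorption rate, 1/h.
#' @param v Apparent volume, L.
#' @param cl Apparent clearance, L/h.
#' @param fu_plasma Unbound fraction in plasma.
#' @param mw g/mol.
#' @return An object of class `perpetrator_spec`.
#' @export
perpetrator_spec <- function(name, dose, regimen = numeric(0), ka, v, cl,
                             fu_plasma, mw) {
  check_num(dose, "dose", lower = 0)
  check_num(ka, "ka", lower = 1e-12)
  check_num(v, "v", lower = 1e-12)
  check_num(cl, "cl", lower = 1e-12)
  check_num(fu_plasma, "fu_plasma", lower = 0, upper = 1)
  check_num(mw, "mw", lower = 1e-9)
  structure(list(name = name, dose = dose, regimen = sort(regimen),
                 ka = ka, v = v, cl = cl, fu_plasma = fu_plasma, mw = mw),
            class = "perpetrator_spec")
}

#' Define inhibition constants
#'
#' @param ki Named numeric vector of reversible (competitive) inhibition
#'   constants in uM, one per enzyme, or `NULL`.
#' @param mbi Named list per enzyme of mechanism-based-inactivation
#'   constants, each a list with `k_i_app` (uM), `k_inact` (1/h) and
#'   `k_deg` (1/h), or `NULL`.
#' @return An object of class `inhibition_spec`.
#' @export
inhibition_spec <- function(ki = NULL, mbi = NULL) {
  if (!is.null(ki)) {
    if (is.null(names(ki)) || any(!names(ki) %in% ENZYMES))
      stop_validation("field 'ki' must be named by enzyme")
    if (any(ki <= 0)) stop_validation("field 'ki' must be > 0")
  }
  if (!is.null(mbi)) {
    for (e in names(mbi)) {
      m <- mbi[[e]]
      for (k in c("k_i_app", "k_inact", "k_deg"))
        if (is.null(m[[k]]) || m[[k]] <= 0)
          stop_validation("field 'mbi.%s.%s' must be > 0", e, k)
    }
  }
  structure(list(ki = ki, mbi = mbi), class = "inhibition_spec")
}

#' Perpetrator plasma concentration (closed form)
#'
#' Superposition of one-compartment first-order absorption (Bateman)
#' solutions over the administration times; returns the unbound plasma
#' concentration in uM.  The degenerate case `ka = CL/V` uses the limiting
#' form `D*ka*t*exp(-ka*t)/V`.
#'
#' @param spec A [perpetrator_spec()] with its `regimen` set.
#' @param t Times, h (vectorised).
#' @param unbound If `FALSE`, return total plasma concentration.
#' @return Concentration in uM.
#' @export
perpetrator_concentration <- function(spec, t, unbound = TRUE) {
  k <- spec$cl / spec$v
  d_nmol <- spec$dose * 1e6 / spec$mw
  conc <- numeric(length(t))
  for (td in spec$regimen) {
    tau <- t - td
    on <- tau >= 0
    if (!any(on)) next
    tt <- tau[on]
    if (abs(spec$ka - k) < 1e-9 * spec$ka)
      ci <- d_nmol * spec$ka * tt * exp(-spec$ka * tt) / spec$v
    else
      ci <- d_nmol * spec$ka / (spec$v * (spec$ka - k)) *
        (exp(-k * tt) - exp(-spec$ka * tt))
    conc[on] <- conc[on] + ci
  }
  conc <- conc / 1000  # nmol/L -> uM
  if (unbound) conc * spec$fu_plasma else conc
}

#' Perpetrator concentration at the gut wall (surrogate)
#'
#' The inhibitor concentration experienced by intestinal enzymes is
#' approximated by the dose amount still unabsorbed in the lumen divided by
#' the luminal fluid volume: `sum_d D*exp(-ka*(t - t_d)) / V_lumen` in uM.
#'
#' @param spec A [perpetrator_spec()].
#' @param t Times, h (vectorised).
#' @param v_lumen Luminal fluid volume, L.
#' @return Total luminal concentration in uM.
#' @export
gut_lumen_concentration <- function(spec, t, v_lumen = 0.25) {
  d_nmol <- spec$dose * 1e6 / spec$mw
  conc <- numeric(length(t))
  for (td in spec$regimen) {
    tau <- t - td
    on <- tau >= 0
    conc[on] <- conc[on] + d_nmol * exp(-spec$ka * tau[on]) / v_lumen
  }
  conc / 1000
}

#' Reversible (competitive) inhibition factor
#'
#' The fraction of enzyme activity remaining at unbound inhibitor
#' concentration `i_u`: `1 / (1 + i_u/ki)`, applied multiplicatively to the
#' affected intrinsic clearance.
#'
#' @param i_u Unbound inhibitor concentration, uM, >= 0.
#' @param ki Inhibition constant, uM, > 0.
#' @return Factor in (0, 1].
#' @export
reversible_inhibition_factor <- function(i_u, ki) {
  if (any(ki <= 0)) stop_validation("reversible_inhibition_factor: ki must be > 0")
  if (any(i_u < 0)) stop_validation("reversible_inhibition_factor: i_u must be >= 0")
  1 / (1 + i_u / ki)
}

#' Active enzyme fraction under mechanism-based inactivation
#'
#' Integrates `dE/dt = k_deg*(1 - E) - k_inact*I/(k_i_app + I)*E` with
#' `E(0) = 1`, where `I(t)` is the unbound inhibitor concentration.  With a
#' constant saturating inhibitor the steady state is
#' `k_deg / (k_deg + k_inact)`.
#'
#' @param i_fun Function of time returning unbound inhibitor concentration
#'   in uM (e.g. a closure over [perpetrator_concentration()]).
#' @param k_inact Maximal inactivation rate, 1/h.
#' @param k_i_app Apparent half-maximal inactivation concentration, uM.
#' @param k_deg Enzyme turnover (degradation/resynthesis) rate, 1/h.
#' @param times Output times, h.
#' @return A `data.frame` with columns `time_h` and `E`.
#' @export
mbi_active_enzyme <- function(i_fun, k_inact, k_i_app, k_deg, times) {
  check_num(k_i_app, "k_i_app", lower = 1e-12)
  check_num(k_deg, "k_deg", lower = 1e-12)
  check_num(k_inact, "k_inact", lower = 0)
  rhs <- function(t, y, p) {
    i <- i_fun(t)
    list(k_deg * (1 - y[1]) - k_inact * i / (k_i_app + i) * y[1])
  }
  out <- deSolve::lsoda(c(E = 1), times = times, func = rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  data.frame(time_h = out[, "time"], E = pmin(pmax(out[, "E"], 0), 1))
}

#' Attach a perpetrator to a victim system
#'
#' The victim's ODE right-hand side then evaluates the inhibition factors
#' from the perpetrator forcing function at the current time: reversible
#' factors `1/(1 + I_u/Ki)` on the affected hepatic pathways (and, using the
#' luminal surrogate concentration, on intestinal pathways), and for
#' mechanism-based inhibition an additional active-enzyme state multiplying
#' the affected clearances.  With an empty perpetrator regimen the combined
#' system reproduces the victim system exactly.
#'
#' @param system A `pbpk_system`.
#' @param spec A [perpetrator_spec()] with its `regimen` set.
#' @param inhibition An [inhibition_spec()].
#' @param inhibit_gut Apply reversible inhibition to gut-wall enzymes
#'   (default `TRUE`).
#' @param inhibit_liver Apply inhibition to hepatic enzymes (default `TRUE`).
#' @return The system with the perpetrator attached.
#' @export
coadminister <- function(system, spec, inhibition, inhibit_gut = TRUE,
                         inhibit_liver = TRUE) {
  stopifnot(inherits(system, "pbpk_system"),
            inherits(spec, "perpetrator_spec"),
            inherits(inhibition, "inhibition_spec"))
  system$perpetrator <- list(spec = spec, inhibition = inhibition,
                             options = list(inhibit_gut = inhibit_gut,
                                            inhibit_liver = inhibit_liver))
  system
}
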