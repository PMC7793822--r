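# Irreversible-inactivation turnover PD model driven by the active
# metabolite concentration:  dP/dt = kin - P*kout - P*C*kirre.
# P is the platelet reactivity pool normalised to a baseline of 1
# (kin = kout), MPA(t) = MPA0 * P(t), IPA(t) = (MPA0 - MPA(t))/MPA0 * 100.

pd_params_for <- function(pd, individual = NULL) {
  if (is.null(individual))
    return(list(kout = pd$kout, kirre = pd$kirre, mpa0 = pd$mpa0))
  list(kout = pd$kout * ind_mult(individual, "pd:kout"),
       kirre = pd$kirre * ind_mult(individual, "pd:kirre"),
       mpa0 = pd$mpa0 * ind_mult(individual, "pd:mpa0"))
}

#' Simulate platelet inhibition from an active-metabolite profile
#'
#' Integrates the turnover model `dP/dt = kin - P*kout - P*C(t)*kirre` with
#' the active-metabolite plasma concentration converted from ng/mL to uM and
#' interpolated piecewise-linearly between profile samples.  The platelet
#' pool starts at its drug-free steady state `P(0) = kin/kout = 1`.
#'
#' @param profile A `concentration_profile` containing the driving compound.
#' @param pd A [pd_spec()].
#' @param individual Optional `virtual_individual` whose PD multipliers are
#'   applied.
#' @param compound Driving compound; defaults to the active metabolite
#'   `"AM-H4"`.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `pd_result` with fields `times`, `P`, `mpa`
#'   and `ipa`.
#' @export
simulate_platelet_inhibition <- function(profile, pd, individual = NULL,
                                         compound = "AM-H4",
                                         rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(profile, "concentration_profile"), inherits(pd, "pd_spec"))
  if (!compound %in% profile$compounds)
    stop_validation("profile has no compound '%s'", compound)
  conc <- profile$conc[, compound]
  if (any(conc < -1e-12))
    stop_validation("negative concentration in driving profile")
  conc_um <- pmax(conc, 0) / profile$mw[[compound]]  # ng/mL -> uM
  cfun <- stats::approxfun(profile$times, conc_um, rule = 2)
  par <- pd_params_for(pd, individual)

  rhs <- function(t, y, p)
    list(par$kout * (1 - y[1]) - y[1] * cfun(t) * par$kirre)
  out <- deSolve::lsoda(c(P = 1), times = profile$times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  P <- pmin(pmax(out[, "P"], 0), 1)
  structure(list(times = profile$times, P = P,
                 mpa = par$mpa0 * P,
                 ipa = (1 - P) * 100,
                 pd = par, subject = profile$subject, arm = profile$arm,
                 last_dose_time = max(profile$regimen$time_h)),
            class = "pd_result")
}

#' Inhibition of platelet aggregation from MPA values
#'
#' `IPA (%) = (MPA0 - MPAt) / MPA0 * 100`.
#'
#' @param mpa0 Baseline maximal platelet aggregation, percent; must be > 0.
#' @param mpa_t MPA at time t, percent, >= 0.
#' @return IPA in percent.
#' @export
ipa_from_mpa <- function(mpa0, mpa_t) {
  if (any(mpa0 <= 0)) stop_validation("ipa_from_mpa: mpa0 must be > 0")
  if (any(mpa_t < 0)) stop_validation("ipa_from_mpa: mpa_t must be >= 0")
  (mpa0 - mpa_t) / mpa0 * 100
}

#' Time to recovery of platelet function
#'
#' First time after the last dose at which IPA falls below the threshold,
#' found by linear interpolation between grid points.  Returns 0 if IPA is
#' already below the threshold at the last dose and `Inf` if the threshold
#' is never reached inside the simulated window (a warning is raised when
#' the post-dose window is shorter than one turnover time `1/kout`, since
#' recovery cannot then be resolved reliably).
#'
#' @param pd_result A `pd_result` (or any list with `times`, `ipa` and a
#'   `last_dose_time`).
#' @param threshold_ipa Recovery threshold in IPA percentage points
#'   (default 10).
#' @param last_dose_time Override for the time of the final dose, h.
#' @return Time from the last dose to recovery, h.
#' @export
recovery_time <- function(pd_result, threshold_ipa = 10,
                          last_dose_time = pd_result$last_dose_time) {
  t <- pd_result$times
  ipa <- pd_result$ipa
  win <- t >= last_dose_time
  if (!any(win)) stop_validation("no samples after the last dose")
  kout <- if (!is.null(pd_result$pd)) pd_result$pd$kout else NA_real_
  if (is.finite(kout) && (max(t) - last_dose_time) < 1 / kout)
    warning("post-dose window is shorter than the platelet turnover time 1/kout")
  tw <- t[win]; iw <- ipa[win]
  if (iw[1] < threshold_ipa) return(0)
  below <- which(iw < threshold_ipa)
  if (!length(below)) return(Inf)
  j <- below[1]
  # linear interpolation across the crossing
  t_cross <- tw[j - 1] + (threshold_ipa - iw[j - 1]) *
    (tw[j] - tw[j - 1]) / (iw[j] - iw[j - 1])
  t_cross - last_dose_time
}

#' Estimate kout from a post-washout IPA recovery curve
#'
#' After washout `IPA(t) = IPA0 * exp(-kout * t)`, so the slope of a
#' log-linear regression of IPA on time recovers the platelet turnover rate.
#'
#' @param times Times, h.
#' @param ipa IPA values, percent; values <= 0 are dropped.
#' @return Estimated `kout`, 1/h.
#' @export
fit_kout <- function(times, ipa) {
  keep <- is.finite(ipa) & ipa > 0
  if (sum(keep) < 3) stop_validation("need at least 3 positive IPA samples")
  -unname(stats::coef(stats::lm(log(ipa[keep]) ~ times[keep]))[2])
}

#' @export
as.data.frame.pd_result <- function(x, ...) {
  data.frame(subject = x$subject, arm = x$arm, time_h = x$times, P = x$P,
             mpa_pct = if (is.null(x$mpa)) NA_real_ else x$mpa,
             ipa_pct = x$ipa)
}

#' @export
print.pd_result <- function(x, ...) {
  cat(sprintf("platelet inhibition, subject %s%s\n", x$subject,
              if (nzchar(x$arm)) paste0(", arm ", x$arm) else ""))
  cat(sprintf("  peak IPA %.1f%% ; IPA at end %.1f%%\n",
              max(x$ipa), x$ipa[length(x$ipa)]))
  invisible(x)
}

#' @export
plot.pd_result <- function(x, ...) {
  plot(x$times, x$ipa, type = "l", xlab = "time (h)", ylab = "IPA (%)",
       ylim = c(0, 100), ...)
  invisible(x)
}
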