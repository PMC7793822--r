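# Non-compartmental summaries and verification statistics.

interp_conc <- function(profile, compound, t) {
  stats::approx(profile$times, profile$conc[, compound], xout = t,
                rule = 2)$y
}

#' Interval AUC by the linear trapezoid rule
#'
#' Integrates the concentration-time curve over `[t_start, t_end]` on the
#' simulation output grid (endpoints interpolated linearly if they fall
#' between grid points).  No extrapolation is performed.
#'
#' @param profile A `concentration_profile`.
#' @param compound Compound name.
#' @param t_start,t_end Interval bounds, h; must lie inside the grid.
#' @return AUC in ng h/mL.
#' @export
auc_interval <- function(profile, compound, t_start, t_end) {
  t <- profile$times
  if (t_start < min(t) - 1e-9 || t_end > max(t) + 1e-9 || t_end <= t_start)
    stop_validation("AUC interval [%g, %g] outside simulation grid",
                    t_start, t_end)
  inside <- t > t_start & t < t_end
  tt <- c(t_start, t[inside], t_end)
  cc <- c(interp_conc(profile, compound, t_start),
          profile$conc[inside, compound],
          interp_conc(profile, compound, t_end))
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Maximum concentration on an interval
#'
#' @inheritParams auc_interval
#' @return Cmax in ng/mL.
#' @export
cmax_interval <- function(profile, compound, t_start, t_end) {
  t <- profile$times
  inside <- t >= t_start - 1e-9 & t <= t_end + 1e-9
  if (!any(inside))
    stop_validation("Cmax interval [%g, %g] outside simulation grid",
                    t_start, t_end)
  max(profile$conc[inside, compound])
}

#' Ratio of group means
#'
#' `mean(a) / mean(b)` - the ratio of means, not the mean of per-subject
#' ratios.
#'
#' @param group_a,group_b Numeric vectors of per-subject values.
#' @return Dimensionless ratio.
#' @export
ratio_of_means <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop_validation("ratio_of_means: both groups must be nonempty")
  mb <- mean(group_b)
  if (mb == 0) stop_validation("ratio_of_means: denominator mean is zero")
  mean(group_a) / mb
}

#' Fold error between prediction and observation
#'
#' `max(predicted/observed, observed/predicted)`, always >= 1; symmetric in
#' its arguments.  The conventional acceptance criterion for PBPK model
#' verification is a fold error below 2.
#'
#' @param predicted,observed Positive values (vectorised).
#' @return Fold errors >= 1.
#' @export
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0))
    stop_validation("fold_error: inputs must be > 0")
  pmax(predicted / observed, observed / predicted)
}

#' Per-arm PK summary table
#'
#' Computes first-dose and last-dose interval AUC(0-24) and Cmax for one
#' compound across a list of profiles, with group mean and SD, mirroring the
#' layout of a paired-arm comparison table.
#'
#' @param profiles List of `concentration_profile` objects (one arm).
#' @param compound Compound to summarise.
#' @return A `data.frame` with one row per subject and attributes `mean`
#'   and `sd` (named vectors over the four metrics).
#' @export
pk_metrics <- function(profiles, compound) {
  reg <- profiles[[1]]$regimen
  t_first <- min(reg$time_h)
  t_last <- max(reg$time_h)
  rows <- lapply(profiles, function(pr) {
    data.frame(subject = pr$subject, arm = pr$arm, compound = compound,
               auc_first = auc_interval(pr, compound, t_first, t_first + 24),
               cmax_first = cmax_interval(pr, compound, t_first, t_first + 24),
               auc_last = auc_interval(pr, compound, t_last, t_last + 24),
               cmax_last = cmax_interval(pr, compound, t_last, t_last + 24))
  })
  out <- do.call(rbind, rows)
  metr <- c("auc_first", "cmax_first", "auc_last", "cmax_last")
  attr(out, "mean") <- vapply(out[metr], mean, 1)
  attr(out, "sd") <- vapply(out[metr], stats::sd, 1)
  out
}

#' Paired-arm comparison table
#'
#' Ratios of arm means (upper arm divided by lower arm) for first/last dose
#' AUC(0-24) and Cmax, in the style of a genotype- or inhibitor-comparison
#' summary table.
#'
#' @param metrics_a,metrics_b Outputs of [pk_metrics()] for the two arms
#'   (numerator and denominator respectively).
#' @return A one-row `data.frame` of ratios plus per-arm means and SDs.
#' @export
arm_ratio_summary <- function(metrics_a, metrics_b) {
  metr <- c("auc_first", "cmax_first", "auc_last", "cmax_last")
  ma <- attr(metrics_a, "mean"); mb <- attr(metrics_b, "mean")
  out <- data.frame(compound = metrics_a$compound[1],
                    arm_a = metrics_a$arm[1], arm_b = metrics_b$arm[1])
  for (m in metr) {
    out[[paste0("mean_a_", m)]] <- ma[[m]]
    out[[paste0("sd_a_", m)]] <- attr(metrics_a, "sd")[[m]]
    out[[paste0("mean_b_", m)]] <- mb[[m]]
    out[[paste0("sd_b_", m)]] <- attr(metrics_b, "sd")[[m]]
    out[[paste0("ratio_", m)]] <- ratio_of_means(metrics_a[[m]],
                                                 metrics_b[[m]])
  }
  out
}
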