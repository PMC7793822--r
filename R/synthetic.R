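# Synthetic "observed" clinical datasets: sparse samples of the model's own
# predictions with a residual-error model, emulating the structure of
# digitized trial data so the fold-error verification workflow is fully
# testable without external data.  No claim is made of matching real
# clinical observations.

#' Generate a synthetic observed dataset
#'
#' Samples a concentration profile (or a PD result) at sparse times and adds
#' residual error: multiplicative log-normal noise (median-unbiased, CV =
#' `residual_cv`) on concentrations, additive normal noise truncated to
#' [0, 100] (SD = `ipa_sd` percentage points) on IPA.  Deterministic given
#' the seed; the caller's RNG state is untouched.
#'
#' @param x A `concentration_profile` or `pd_result`.
#' @param times Sampling times, h; must lie inside the simulated window.
#' @param residual_cv Residual CV on concentrations (fraction).
#' @param seed Integer seed.
#' @param compound Compound sampled from a profile (default `"AM-H4"`).
#' @param ipa_sd Residual SD on IPA, percentage points.
#' @param trial,arm Labels.
#' @return A `data.frame` of class `observed_dataset` with columns
#'   `trial`, `arm`, `subject`, `time_h`, `analyte`, `value`, `unit`.
#' @export
generate_observed <- function(x, times, residual_cv = 0.2, seed = 1L,
                              compound = "AM-H4", ipa_sd = 5,
                              trial = "synthetic", arm = x$arm) {
  if (residual_cv < 0) stop_validation("residual_cv must be >= 0")
  if (min(times) < min(x$times) - 1e-9 || max(times) > max(x$times) + 1e-9)
    stop_validation("sampling times outside the simulated window")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  if (inherits(x, "concentration_profile")) {
    pred <- stats::approx(x$times, x$conc[, compound], xout = times)$y
    val <- pred * lognormal_mult(length(times), residual_cv)
    analyte <- compound; unit <- "ng/mL"
  } else if (inherits(x, "pd_result")) {
    pred <- stats::approx(x$times, x$ipa, xout = times)$y
    noise <- if (ipa_sd > 0) stats::rnorm(length(times), 0, ipa_sd) else 0
    val <- pmin(pmax(pred + noise, 0), 100)
    analyte <- "IPA"; unit <- "%"
  } else stop_validation("x must be a concentration_profile or pd_result")

  structure(data.frame(trial = trial, arm = arm,
                       subject = if (is.null(x$subject)) NA_integer_ else x$subject,
                       time_h = times, analyte = analyte, value = val,
                       unit = unit),
            predicted = pred, seed = seed,
            class = c("observed_dataset", "data.frame"))
}

#' Fold-error verification report
#'
#' Pairs predicted and observed summary values by key, computes the fold
#' error of each pair, and reports how many fall below the conventional
#' 2-fold and 1.5-fold acceptance bounds.
#'
#' @param predicted,observed Data frames with columns `key` and `value`
#'   (any further columns are carried along from `predicted`).
#' @return A list of class `verification_report` with elements `table`
#'   (per-pair fold errors), `n`, `n_below_2`, `n_below_1.5`,
#'   `frac_below_2`, `frac_below_1.5` and `pass_2fold` /`pass_1.5fold`
#'   flags (all pairs below the bound).
#' @export
verification_report <- function(predicted, observed) {
  for (d in list(predicted, observed))
    if (!all(c("key", "value") %in% names(d)))
      stop_validation("predicted and observed need columns 'key' and 'value'")
  unmatched <- c(setdiff(predicted$key, observed$key),
                 setdiff(observed$key, predicted$key))
  if (length(unmatched))
    stop_validation("unmatched prediction/observation keys: %s",
                    paste(unique(unmatched), collapse = ", "))
  obs <- observed$value[match(predicted$key, observed$key)]
  fe <- fold_error(predicted$value, obs)
  tab <- data.frame(key = predicted$key, predicted = predicted$value,
                    observed = obs, fold_error = fe)
  structure(list(table = tab, n = nrow(tab),
                 n_below_2 = sum(fe < 2), n_below_1.5 = sum(fe < 1.5),
                 frac_below_2 = mean(fe < 2), frac_below_1.5 = mean(fe < 1.5),
                 pass_2fold = all(fe < 2), pass_1.5fold = all(fe < 1.5)),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("verification: %d prediction/observation pairs\n", x$n))
  cat(sprintf("  fold error < 2:   %d/%d (%.1f%%)%s\n", x$n_below_2, x$n,
              100 * x$frac_below_2, if (x$pass_2fold) "  PASS" else ""))
  cat(sprintf("  fold error < 1.5: %d/%d (%.1f%%)\n", x$n_below_1.5, x$n,
              100 * x$frac_below_1.5))
  invisible(x)
}
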