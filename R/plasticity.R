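# Quantification of synaptic-strength change from EPSC sweep series, and
# correlation of the change with spike-train predictors.

#' Series-resistance quality control
#'
#' A recording fails QC if the access resistance of any sweep deviates by more
#' than `max_change` (default 20%) from its initial value.
#'
#' @param series an [epsc_series()] carrying `series_resistance_mohm`.
#' @param max_change maximal tolerated fractional change (strict inequality:
#'   a drift of exactly `max_change` passes).
#' @param on_missing what to do when the series has no resistance record:
#'   `"warn"` (pass with a warning), `"pass"`, or `"fail"`.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qc_series_resistance <- function(series, max_change = 0.20,
                                 on_missing = c("warn", "pass", "fail")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(series, "epsc_series"), max_change > 0)
  rs <- series$series_resistance_mohm
  if (is.null(rs) || !length(rs)) {
    return(switch(on_missing,
      warn = { warning("qc_series_resistance: no resistance record; passing"); TRUE },
      pass = TRUE,
      fail = FALSE
    ))
  }
  all(abs(rs - rs[1L]) / rs[1L] <= max_change)
}

#' Average sweeps into one point per minute
#'
#' Consecutive non-overlapping groups of `group_size` sweeps (six at 0.1 Hz =
#' one point per minute) are averaged; a partial trailing group is dropped.
#'
#' @param series an [epsc_series()] with at least `group_size` sweeps.
#' @param group_size sweeps per point.
#' @return An [epsc_series()] of group means; point times are the means of the
#'   grouped sweep times.
#' @export
minute_average <- function(series, group_size = 6L) {
  stopifnot(inherits(series, "epsc_series"), group_size >= 1L)
  n <- length(series$sweep_times_s)
  if (n < group_size) {
    stop("minute_average: fewer than ", group_size, " sweeps")
  }
  ng <- n %/% group_size
  idx <- rep(seq_len(ng), each = group_size)
  keep <- seq_len(ng * group_size)
  epsc_series(
    sweep_times_s = as.numeric(tapply(series$sweep_times_s[keep], idx, mean)),
    amplitudes_pa = as.numeric(tapply(series$amplitudes_pa[keep], idx, mean)),
    pathway = series$pathway,
    induction_time_s = series$induction_time_s
  )
}

#' Normalize an amplitude series to its baseline
#'
#' Divides every point by the mean of the baseline-window points (the
#' `baseline_min` minutes preceding the induction marker), so the baseline mean
#' of the output is 1.
#'
#' @param series an [epsc_series()] with a non-`NA` `induction_time_s`.
#' @param baseline_min baseline window length, minutes.
#' @return The normalized [epsc_series()] (dimensionless amplitudes).
#' @export
normalize_to_baseline <- function(series, baseline_min = 5) {
  stopifnot(inherits(series, "epsc_series"))
  t_ind <- series$induction_time_s
  if (is.na(t_ind)) stop("normalize_to_baseline: no induction marker on series")
  sel <- series$sweep_times_s < t_ind &
    series$sweep_times_s >= t_ind - baseline_min * 60
  if (!any(sel)) stop("normalize_to_baseline: no baseline points before induction")
  b <- mean(series$amplitudes_pa[sel])
  if (b == 0) stop("normalize_to_baseline: zero baseline mean")
  epsc_series(
    series$sweep_times_s, series$amplitudes_pa / b,
    pathway = series$pathway, induction_time_s = t_ind,
    series_resistance_mohm = series$series_resistance_mohm
  )
}

# mean normalized response of one series inside a post-induction window (min)
window_mean <- function(series, window_min) {
  t_ind <- series$induction_time_s
  if (is.na(t_ind)) stop("window_mean: no induction marker on series")
  sel <- series$sweep_times_s >= t_ind + window_min[1] * 60 &
    series$sweep_times_s < t_ind + window_min[2] * 60
  if (!any(sel)) {
    stop("window_mean: no points in the ", window_min[1], "-", window_min[2],
         " min window")
  }
  mean(series$amplitudes_pa[sel])
}

#' Compare test and control pathways across experiments
#'
#' Computes each experiment's mean normalized response inside the comparison
#' window (default 25-30 min after induction, also used as the "final 5 min"
#' window), runs a paired two-tailed t test across experiments, and reports
#' the relative change in synaptic strength: mean test minus mean control
#' response over that window.
#'
#' @param test,control lists of normalized [epsc_series()], paired by index
#'   (one entry per experiment); must be the same length, n >= 2.
#' @param window_min (lo, hi) comparison window, minutes after induction.
#' @return A list of class `plasticity_outcome`: `norm_test_final`,
#'   `norm_control_final` (means across experiments), `relative_change`,
#'   `p_value`, `n`, and the per-experiment `test_means` / `control_means`.
#'   When all paired differences are exactly zero the t statistic is undefined
#'   and `p_value` is reported as 1.
#' @export
compare_pathways <- function(test, control, window_min = c(25, 30)) {
  if (inherits(test, "epsc_series")) test <- list(test)
  if (inherits(control, "epsc_series")) control <- list(control)
  if (length(test) != length(control)) {
    stop("compare_pathways: unequal numbers of test and control experiments")
  }
  n <- length(test)
  if (n < 2L) stop("compare_pathways: need at least 2 experiments")
  tm <- vapply(test, window_mean, numeric(1), window_min = window_min)
  cm <- vapply(control, window_mean, numeric(1), window_min = window_min)
  d <- tm - cm
  p <- if (stats::sd(d) == 0) {
    if (mean(d) == 0) 1 else 0
  } else {
    stats::t.test(tm, cm, paired = TRUE)$p.value
  }
  structure(
    list(
      norm_test_final = mean(tm), norm_control_final = mean(cm),
      relative_change = mean(tm) - mean(cm),
      p_value = p, n = n, test_means = tm, control_means = cm,
      window_min = window_min
    ),
    class = "plasticity_outcome"
  )
}

#' @export
print.plasticity_outcome <- function(x, ...) {
  cat(sprintf(
    "<plasticity_outcome> test %.3f, control %.3f, relative change %.3f (p = %.3g, n = %d, window %g-%g min)\n",
    x$norm_test_final, x$norm_control_final, x$relative_change,
    x$p_value, x$n, x$window_min[1], x$window_min[2]
  ))
  invisible(x)
}

#' Correlate synaptic change with a spike-train predictor
#'
#' Ordinary least-squares fit of the relative change in synaptic strength on a
#' predictor count, reporting the coefficient of determination.
#'
#' @param changes relative changes, one per protocol/condition (>= 3 points).
#' @param predictor predictor counts, same length; must have nonzero variance.
#' @return A list of class `predictor_fit`: `r_squared`, `slope`, `intercept`,
#'   `n`.
#' @export
correlate_predictor <- function(changes, predictor) {
  stopifnot(is.numeric(changes), is.numeric(predictor),
            length(changes) == length(predictor))
  if (length(changes) < 3L) stop("correlate_predictor: need at least 3 points")
  if (stats::var(predictor) == 0) {
    stop("correlate_predictor: predictor has zero variance")
  }
  fit <- stats::lm(changes ~ predictor)
  # a perfectly collinear input is legitimate here (e.g. constructed checks);
  # summary.lm warns about it
  structure(
    list(
      r_squared = suppressWarnings(summary(fit)$r.squared),
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      n = length(changes)
    ),
    class = "predictor_fit"
  )
}

#' @export
print.predictor_fit <- function(x, ...) {
  cat(sprintf(
    "<predictor_fit> r^2 = %.3f, slope = %.4g, n = %d\n",
    x$r_squared, x$slope, x$n
  ))
  invisible(x)
}
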