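#' Construct an LFP trace
#'
#' A uniformly sampled single-channel local field potential segment. Amplitude
#' units are arbitrary (the detector works in SD units); `rate_hz` must support
#' the ripple band (at least 4 x the band's upper edge, i.e. 1 kHz for a
#' 250 Hz band).
#'
#' @param samples numeric vector of amplitudes.
#' @param rate_hz sampling rate in Hz.
#' @param t0_s time of the first sample in seconds.
#' @return An object of class `lfp_trace` with elements `samples`, `rate_hz`,
#'   `t0_s`.
#' @export
lfp_trace <- function(samples, rate_hz, t0_s = 0) {
  stopifnot(is.numeric(samples), is_number(rate_hz), rate_hz > 0, is_number(t0_s))
  structure(
    list(samples = as.numeric(samples), rate_hz = rate_hz, t0_s = t0_s),
    class = "lfp_trace"
  )
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf(
    "<lfp_trace> %d samples @ %g Hz, t0 = %g s (%.2f s)\n",
    length(x$samples), x$rate_hz, x$t0_s, length(x$samples) / x$rate_hz
  ))
  invisible(x)
}

# time axis of a trace
lfp_times <- function(trace) {
  trace$t0_s + (seq_along(trace$samples) - 1L) / trace$rate_hz
}

#' Construct a spike train
#'
#' Timestamped action potentials of one unit with its region label.
#'
#' @param times_s spike times in seconds; sorted internally, duplicates are an
#'   error (a unit cannot fire twice at the same instant).
#' @param unit_id unit label, e.g. `"CA3a"`.
#' @param region `"CA3"` or `"CA1"`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times_s, unit_id = "unit", region = c("CA1", "CA3")) {
  region <- match.arg(region)
  stopifnot(is.numeric(times_s))
  times_s <- sort(as.numeric(times_s))
  if (anyDuplicated(times_s)) {
    stop("spike_train: duplicate spike times in unit '", unit_id, "'")
  }
  structure(
    list(unit_id = as.character(unit_id), region = region, times_s = times_s),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf(
    "<spike_train> %s [%s]: %d spikes%s\n",
    x$unit_id, x$region, length(x$times_s),
    if (length(x$times_s)) {
      sprintf(" over %.2f-%.2f s", min(x$times_s), max(x$times_s))
    } else ""
  ))
  invisible(x)
}

#' Construct a table of ripple events
#'
#' @param onset_s,offset_s event boundaries in seconds (the 2 SD envelope
#'   crossings around each supra-threshold excursion).
#' @param peak_sd envelope peak inside each event, in SD units.
#' @return A `data.frame` with class `ripple_events`, sorted by onset, with a
#'   `duration_s` column. Events must be non-overlapping (enforce by merging
#'   at detection time).
#' @export
ripple_events <- function(onset_s = numeric(), offset_s = numeric(),
                          peak_sd = rep(NA_real_, length(onset_s))) {
  stopifnot(length(onset_s) == length(offset_s))
  o <- order(onset_s)
  onset_s <- as.numeric(onset_s[o])
  offset_s <- as.numeric(offset_s[o])
  peak_sd <- as.numeric(peak_sd[o])
  if (any(offset_s <= onset_s)) stop("ripple_events: offset must exceed onset")
  if (length(onset_s) > 1L && any(onset_s[-1L] < offset_s[-length(offset_s)])) {
    stop("ripple_events: events overlap; merge before constructing")
  }
  structure(
    data.frame(
      onset_s = onset_s, offset_s = offset_s, peak_sd = peak_sd,
      duration_s = offset_s - onset_s
    ),
    class = c("ripple_events", "data.frame")
  )
}

#' Construct an EPSC sweep-amplitude series
#'
#' Per-sweep EPSC amplitudes of one stimulation pathway, with the induction
#' marker carried as explicit metadata (never inferred from the data).
#'
#' @param sweep_times_s sweep times in seconds, increasing.
#' @param amplitudes_pa EPSC amplitudes in pA (finite).
#' @param pathway `"test"`, `"control"`, or `"ripple"`.
#' @param induction_time_s time of plasticity induction in seconds (`NA` if the
#'   series has no induction, e.g. a pure baseline recording).
#' @param series_resistance_mohm optional per-sweep access resistance for QC.
#' @return An object of class `epsc_series`.
#' @export
epsc_series <- function(sweep_times_s, amplitudes_pa,
                        pathway = c("test", "control", "ripple"),
                        induction_time_s = NA_real_,
                        series_resistance_mohm = NULL) {
  pathway <- match.arg(pathway)
  stopifnot(
    is.numeric(sweep_times_s), is.numeric(amplitudes_pa),
    length(sweep_times_s) == length(amplitudes_pa)
  )
  if (is.unsorted(sweep_times_s, strictly = TRUE)) {
    stop("epsc_series: sweep times must be strictly increasing")
  }
  if (!all(is.finite(amplitudes_pa))) stop("epsc_series: amplitudes must be finite")
  if (!is.null(series_resistance_mohm)) {
    stopifnot(length(series_resistance_mohm) == length(sweep_times_s))
    series_resistance_mohm <- as.numeric(series_resistance_mohm)
  }
  structure(
    list(
      sweep_times_s = as.numeric(sweep_times_s),
      amplitudes_pa = as.numeric(amplitudes_pa),
      pathway = pathway,
      induction_time_s = induction_time_s,
      series_resistance_mohm = series_resistance_mohm
    ),
    class = "epsc_series"
  )
}

#' @export
print.epsc_series <- function(x, ...) {
  cat(sprintf(
    "<epsc_series> %s pathway: %d sweeps, induction at %s s\n",
    x$pathway, length(x$sweep_times_s),
    if (is.na(x$induction_time_s)) "NA" else format(x$induction_time_s)
  ))
  invisible(x)
}
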