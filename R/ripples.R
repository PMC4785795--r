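#' Ripple detection configuration
#'
#' Parameters of the SD-threshold ripple detector. Defaults follow the
#' standard offline procedure for hippocampal CA1 LFP: band-pass 120-250 Hz,
#' classify envelope deflections greater than 5 SDs above the mean as ripple
#' events, and bound each event locally at the surrounding 2 SD crossings.
#'
#' @param band_hz (low, high) pass band in Hz.
#' @param detect_sd detection threshold in SDs above the envelope mean.
#' @param bound_sd boundary threshold (onset/offset crossings), SDs.
#' @param smooth_ms SD of the Gaussian envelope-smoothing kernel, ms; prevents
#'   intra-ripple envelope troughs from splitting one event. The 12 ms default
#'   was calibrated on synthetic sessions so the 2 SD boundary crossing has
#'   zero median bias against the planted onset (lighter smoothing leaves the
#'   crossing systematically late, heavier pulls it early and costs recall on
#'   short ripples).
#' @param merge_ms events separated by less than this gap are merged, ms.
#' @param min_dur_ms events shorter than this are dropped, ms.
#' @param sd_estimate `"iterative"` (default: a first global pass flags
#'   samples above `bound_sd`; the envelope mean/SD are re-estimated from the
#'   remaining ripple-free segments and detection re-run) or `"global"`
#'   (single pass on trace-wide statistics; under-detects when ripples occupy
#'   an appreciable fraction of the trace, since they inflate the SD).
#' @return A list of class `ripple_detect_config`.
#' @export
ripple_detect_config <- function(band_hz = c(120, 250), detect_sd = 5,
                                 bound_sd = 2, smooth_ms = 12, merge_ms = 20,
                                 min_dur_ms = 20,
                                 sd_estimate = c("iterative", "global")) {
  sd_estimate <- match.arg(sd_estimate)
  stopifnot(
    length(band_hz) == 2L, band_hz[1] > 0, band_hz[1] < band_hz[2],
    is_number(detect_sd), is_number(bound_sd),
    detect_sd > bound_sd, bound_sd > 0,
    smooth_ms >= 0, merge_ms >= 0, min_dur_ms >= 0
  )
  structure(
    list(
      band_hz = band_hz, detect_sd = detect_sd, bound_sd = bound_sd,
      smooth_ms = smooth_ms, merge_ms = merge_ms, min_dur_ms = min_dur_ms,
      sd_estimate = sd_estimate
    ),
    class = "ripple_detect_config"
  )
}

#' Zero-phase band-pass filter an LFP trace
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`), so
#' event onset times are not biased by filter delay.
#'
#' @param trace an [lfp_trace()].
#' @param band_hz (low, high) corner frequencies, Hz; must lie below Nyquist.
#' @param order filter order (per direction).
#' @return A filtered [lfp_trace()] of the same length and time base.
#' @export
bandpass_lfp <- function(trace, band_hz = c(120, 250), order = 4L) {
  stopifnot(inherits(trace, "lfp_trace"), length(band_hz) == 2L)
  nyq <- trace$rate_hz / 2
  if (band_hz[1] <= 0 || band_hz[2] >= nyq) {
    stop(sprintf(
      "bandpass_lfp: band (%g, %g) Hz outside (0, Nyquist = %g) Hz",
      band_hz[1], band_hz[2], nyq
    ))
  }
  bf <- signal::butter(order, band_hz / nyq, type = "pass")
  out <- lfp_trace(signal::filtfilt(bf, trace$samples), trace$rate_hz, trace$t0_s)
  attr(out, "filter") <- sprintf(
    "butterworth order %d, %g-%g Hz, zero-phase", order, band_hz[1], band_hz[2]
  )
  out
}

#' Instantaneous envelope of a band-passed trace
#'
#' Analytic-signal (Hilbert) magnitude, smoothed with a Gaussian kernel.
#'
#' @param filtered a band-passed [lfp_trace()].
#' @param smooth_ms Gaussian kernel SD in ms (0 disables smoothing).
#' @return An [lfp_trace()] of non-negative envelope samples.
#' @export
lfp_envelope <- function(filtered, smooth_ms = 8) {
  stopifnot(inherits(filtered, "lfp_trace"), smooth_ms >= 0)
  env <- Mod(analytic_signal(filtered$samples))
  env <- gauss_smooth(env, smooth_ms / 1000 * filtered$rate_hz)
  lfp_trace(env, filtered$rate_hz, filtered$t0_s)
}

# Expand each supra-threshold run to the surrounding bound_sd crossings,
# union overlaps, merge near gaps, apply the duration floor.
events_from_z <- function(z, rate, t0, cfg) {
  above_det <- z > cfg$detect_sd
  if (!any(above_det)) return(ripple_events())
  below_bound <- which(z < cfg$bound_sd)
  runs <- rle(above_det)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  det_start <- starts[runs$values]
  det_end <- ends[runs$values]

  on_idx <- integer(length(det_start))
  off_idx <- integer(length(det_start))
  n <- length(z)
  for (i in seq_along(det_start)) {
    prev <- below_bound[below_bound < det_start[i]]
    on_idx[i] <- if (length(prev)) max(prev) + 1L else 1L
    nxt <- below_bound[below_bound > det_end[i]]
    off_idx[i] <- if (length(nxt)) min(nxt) - 1L else n
  }
  # union overlapping / abutting expansions, then merge across short gaps
  o <- order(on_idx)
  on_idx <- on_idx[o]; off_idx <- off_idx[o]
  gap_samp <- cfg$merge_ms / 1000 * rate
  m_on <- on_idx[1L]; m_off <- off_idx[1L]
  res_on <- integer(0); res_off <- integer(0)
  for (i in seq_along(on_idx)[-1L]) {
    if (on_idx[i] <= m_off + gap_samp) {
      m_off <- max(m_off, off_idx[i])
    } else {
      res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
      m_on <- on_idx[i]; m_off <- off_idx[i]
    }
  }
  res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)

  dur <- (res_off - res_on) / rate
  keep <- dur >= cfg$min_dur_ms / 1000
  res_on <- res_on[keep]; res_off <- res_off[keep]
  if (!length(res_on)) return(ripple_events())
  peak <- vapply(
    seq_along(res_on),
    function(i) max(z[res_on[i]:res_off[i]]), numeric(1)
  )
  # sub-sample linear interpolation of the bound_sd crossings
  onset_t <- vapply(res_on, function(i) {
    if (i <= 1L || z[i] <= z[i - 1L]) return((i - 1L) / rate)
    frac <- (cfg$bound_sd - z[i - 1L]) / (z[i] - z[i - 1L])
    (i - 2L + min(max(frac, 0), 1)) / rate
  }, numeric(1))
  offset_t <- vapply(res_off, function(i) {
    if (i >= n || z[i] <= z[i + 1L]) return((i - 1L) / rate)
    frac <- (z[i] - cfg$bound_sd) / (z[i] - z[i + 1L])
    (i - 1L + min(max(frac, 0), 1)) / rate
  }, numeric(1))
  ripple_events(
    onset_s = t0 + onset_t,
    offset_s = t0 + offset_t,
    peak_sd = peak
  )
}

#' Detect sharp-wave ripple events in an LFP trace
#'
#' Band-pass filters the trace, extracts the smoothed analytic envelope,
#' z-scores it against the trace-wide mean and SD, and reports one event per
#' excursion above `detect_sd`, bounded by the nearest surrounding `bound_sd`
#' crossings. Events closer than `merge_ms` are merged and events shorter than
#' `min_dur_ms` dropped.
#'
#' @param trace an [lfp_trace()] of at least 1 s (SD estimation).
#' @param cfg a [ripple_detect_config()].
#' @return A [ripple_events()] data frame with a `config` attribute echoing all
#'   detection parameters for provenance.
#' @export
detect_ripples <- function(trace, cfg = ripple_detect_config()) {
  stopifnot(inherits(trace, "lfp_trace"))
  if (length(trace$samples) / trace$rate_hz < 1) {
    stop("detect_ripples: trace shorter than 1 s; cannot estimate SD")
  }
  if (stats::sd(trace$samples) == 0) {
    stop("detect_ripples: constant trace has zero SD; degenerate input")
  }
  env <- lfp_envelope(bandpass_lfp(trace, cfg$band_hz), cfg$smooth_ms)$samples
  mu <- mean(env); sdev <- stats::sd(env)
  if (sdev == 0) stop("detect_ripples: zero envelope SD; degenerate input")
  if (cfg$sd_estimate == "iterative") {
    # re-estimate mean/SD from ripple-free segments: drop everything the
    # first global pass puts above the boundary threshold
    keep <- (env - mu) / sdev < cfg$bound_sd
    if (sum(keep) >= trace$rate_hz) {   # need >= 1 s of background
      mu <- mean(env[keep]); sdev <- stats::sd(env[keep])
      if (sdev == 0) stop("detect_ripples: zero ripple-free envelope SD")
    }
  }
  ev <- events_from_z((env - mu) / sdev, trace$rate_hz, trace$t0_s, cfg)
  attr(ev, "config") <- cfg
  ev
}

#' Shift ripple events in time
#'
#' Used to test the timing specificity of SWR-associated input, e.g. shifting
#' detected ripples 100 ms earlier relative to the spike times.
#'
#' @param events a [ripple_events()] table.
#' @param dt_s shift in seconds (negative = earlier).
#' @return The shifted [ripple_events()]; durations and peaks unchanged.
#' @export
offset_ripples <- function(events, dt_s) {
  stopifnot(inherits(events, "ripple_events"), is_number(dt_s))
  ripple_events(events$onset_s + dt_s, events$offset_s + dt_s, events$peak_sd)
}
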