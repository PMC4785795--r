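# Three-channel stimulation schedules for in vitro replay experiments.
# Channels: presynaptic test-pathway EPSP stimulation (at CA3 spike times),
# postsynaptic somatic current pulses evoking APs (2 ms / 2 nA, at CA1 spike
# times), and a ripple pathway receiving five-pulse 100 Hz trains at SWR times.

new_stim_protocol <- function(presyn, postsyn, ripple_starts, mode, duration_s,
                              n_pulses = 5L, pulse_rate_hz = 100,
                              holding_mv = NA_real_) {
  stopifnot(duration_s > 0)
  all_t <- c(presyn, postsyn, ripple_starts)
  if (length(all_t) && (min(all_t) < 0 || max(all_t) > duration_s)) {
    stop("stim_protocol: event times outside [0, duration_s]")
  }
  ripple_starts <- sort(ripple_starts)
  train_len <- if (n_pulses > 1L) (n_pulses - 1L) / pulse_rate_hz else 0
  if (length(ripple_starts) > 1L &&
      any(diff(ripple_starts) < train_len)) {
    stop("stim_protocol: ripple-path trains overlap")
  }
  structure(
    list(
      presyn_test_times_s = sort(presyn),
      postsyn_ap_times_s = sort(postsyn),
      ripple_trains = data.frame(
        start_s = ripple_starts,
        n_pulses = rep(as.integer(n_pulses), length(ripple_starts)),
        rate_hz = rep(pulse_rate_hz, length(ripple_starts))
      ),
      ap_pulse_ms = 2, ap_pulse_na = 2,
      mode = mode, duration_s = duration_s, holding_mv = holding_mv
    ),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> mode '%s': %d EPSPs, %d APs, %d ripple trains over %g s\n",
    x$mode, length(x$presyn_test_times_s), length(x$postsyn_ap_times_s),
    nrow(x$ripple_trains), x$duration_s
  ))
  invisible(x)
}

#' All ripple-pathway pulse times of a protocol
#'
#' Expands each five-pulse 100 Hz train into individual pulse times.
#'
#' @param protocol a `stim_protocol`.
#' @return Numeric vector of pulse times, seconds.
#' @export
ripple_pulse_times <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  tr <- protocol$ripple_trains
  if (nrow(tr) == 0L) return(numeric(0))
  unlist(lapply(seq_len(nrow(tr)), function(i) {
    tr$start_s[i] + (seq_len(tr$n_pulses[i]) - 1L) / tr$rate_hz[i]
  }))
}

#' Build a spike-train replay induction protocol
#'
#' Schedules presynaptic EPSP stimulation at CA3 spike times, postsynaptic AP
#' pulses at CA1 spike times, and (depending on mode) five-pulse 100 Hz trains
#' on a third ripple pathway at detected SWR onset times -- replaying a rest
#' epoch's reactivation activity onto a slice.
#'
#' @param ca3,ca1 [spike_train()]s restricted to the induction epoch.
#' @param events [ripple_events()] detected in the same epoch.
#' @param swr_mode `"with"` (ripple trains at SWR onsets), `"without"` (no
#'   ripple-path stimulation), or `"offset_100ms_early"` (ripple trains shifted
#'   100 ms earlier relative to the spikes).
#' @param epoch_s induction epoch length, seconds (default 300: the first
#'   5 min of the post-run rest period).
#' @return A `stim_protocol`.
#' @export
build_replay_protocol <- function(ca3, ca1, events,
                                  swr_mode = c("with", "without",
                                               "offset_100ms_early"),
                                  epoch_s = 300) {
  swr_mode <- match.arg(swr_mode)
  stopifnot(
    inherits(ca3, "spike_train"), inherits(ca1, "spike_train"),
    inherits(events, "ripple_events")
  )
  spikes <- c(ca3$times_s, ca1$times_s)
  if (length(spikes) && (min(spikes) < 0 || max(spikes) > epoch_s)) {
    stop("build_replay_protocol: spikes outside the induction epoch")
  }
  starts <- switch(swr_mode,
    with = events$onset_s,
    without = numeric(0),
    offset_100ms_early = events$onset_s - 0.1
  )
  starts <- starts[starts >= 0 & starts <= epoch_s]
  new_stim_protocol(
    ca3$times_s, ca1$times_s, starts,
    mode = paste0("replay_", swr_mode), duration_s = epoch_s
  )
}

#' Build an artificial timed-pairing protocol
#'
#' 300 repetitions at 5 Hz (200 ms period). Each repetition contains, per
#' variant: a ripple-path five-pulse train at the repetition start (variants
#' with SWR-associated stimulation), one subthreshold EPSP at the configured
#' delay after it, and one AP 10 ms after the EPSP (omitted for the EPSP-only
#' variant).
#'
#' @param variant `"pairing_only"` (EPSP + AP, no ripple train),
#'   `"pairing_at_13ms"` (EPSP 13 ms after the ripple-train onset),
#'   `"pairing_at_53ms"` (EPSP 53 ms after onset, i.e. 40 ms later), or
#'   `"epsp_only_at_13ms"` (no AP).
#' @param n_reps number of repetitions.
#' @param rep_rate_hz repetition rate, Hz.
#' @param epsp_ap_gap_ms EPSP -> AP interval, ms.
#' @return A `stim_protocol` with `duration_s = n_reps / rep_rate_hz`.
#' @export
build_pairing_protocol <- function(variant = c("pairing_only",
                                               "pairing_at_13ms",
                                               "pairing_at_53ms",
                                               "epsp_only_at_13ms"),
                                   n_reps = 300L, rep_rate_hz = 5,
                                   epsp_ap_gap_ms = 10) {
  variant <- match.arg(variant)
  period <- 1 / rep_rate_hz
  t0 <- (seq_len(n_reps) - 1L) * period
  delay_s <- switch(variant,
    pairing_only = 0,
    pairing_at_13ms = 0.013,
    pairing_at_53ms = 0.053,
    epsp_only_at_13ms = 0.013
  )
  with_swr <- variant != "pairing_only"
  with_ap <- variant != "epsp_only_at_13ms"
  epsp <- t0 + delay_s
  new_stim_protocol(
    presyn = epsp,
    postsyn = if (with_ap) epsp + epsp_ap_gap_ms / 1000 else numeric(0),
    ripple_starts = if (with_swr) t0 else numeric(0),
    mode = variant, duration_s = n_reps / rep_rate_hz
  )
}

#' Sine-wave somatic current command at SWR times
#'
#' A sampled current waveform that is zero at baseline and, during each ripple
#' event, contains one full sine cycle spanning onset to offset (frequency
#' scaled by the SWR's duration), with peak and valley at +/-`max_pa`. A
#' somatic surrogate for the SWR-associated membrane-potential deflection.
#'
#' @param events non-overlapping [ripple_events()].
#' @param max_pa peak current, pA.
#' @param rate_hz waveform sampling rate (default 10 kHz).
#' @param duration_s waveform length; defaults to the last offset rounded up.
#' @param cycles sine cycles per event (default 1).
#' @return A list of class `current_waveform`: `samples_pa`, `rate_hz`.
#' @export
sine_wave_command <- function(events, max_pa = 100, rate_hz = 10000,
                              duration_s = NULL, cycles = 1) {
  stopifnot(inherits(events, "ripple_events"), max_pa >= 0, rate_hz > 0)
  if (is.null(duration_s)) {
    duration_s <- if (nrow(events)) ceiling(max(events$offset_s)) else 1
  }
  n <- round(duration_s * rate_hz)
  x <- numeric(n)
  tt <- (seq_len(n) - 1L) / rate_hz
  for (i in seq_len(nrow(events))) {
    dur <- events$offset_s[i] - events$onset_s[i]
    sel <- which(tt >= events$onset_s[i] & tt <= events$offset_s[i])
    x[sel] <- max_pa * sin(2 * pi * cycles * (tt[sel] - events$onset_s[i]) / dur)
  }
  structure(list(samples_pa = x, rate_hz = rate_hz), class = "current_waveform")
}

#' Write a stimulation protocol as a plain-text schedule
#'
#' One line per event (`channel time_s param1 param2`), preceded by a
#' commented header carrying mode, duration and pulse parameters. Times are
#' printed with 17 significant digits so that a written protocol re-reads
#' bit-identically.
#'
#' @param protocol a `stim_protocol`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  fmt <- function(x) sprintf("%.17g", x)
  hdr <- c(
    sprintf("# swrtools stim_protocol"),
    sprintf("# mode=%s", protocol$mode),
    sprintf("# duration_s=%s", fmt(protocol$duration_s)),
    sprintf("# ap_pulse_ms=%s ap_pulse_na=%s",
            fmt(protocol$ap_pulse_ms), fmt(protocol$ap_pulse_na)),
    sprintf("# holding_mv=%s",
            if (is.na(protocol$holding_mv)) "NA" else fmt(protocol$holding_mv)),
    "# channel time_s param1 param2"
  )
  lines <- c(
    hdr,
    sprintf("epsp %s 0 0", fmt(protocol$presyn_test_times_s)),
    sprintf("ap %s %s %s", fmt(protocol$postsyn_ap_times_s),
            fmt(protocol$ap_pulse_ms), fmt(protocol$ap_pulse_na)),
    if (nrow(protocol$ripple_trains)) {
      sprintf("ripple %s %d %s",
              fmt(protocol$ripple_trains$start_s),
              protocol$ripple_trains$n_pulses,
              fmt(protocol$ripple_trains$rate_hz))
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a stimulation protocol written by [write_protocol()]
#'
#' @param path file path.
#' @return A `stim_protocol`.
#' @export
read_protocol <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_hdr <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    sub(sprintf("^# %s=", key), "", m[1L])
  }
  mode <- get_hdr("mode")
  duration_s <- as.numeric(get_hdr("duration_s"))
  holding <- get_hdr("holding_mv")
  holding_mv <- if (is.na(holding) || holding == "NA") NA_real_ else as.numeric(holding)
  parts <- strsplit(body, " +")
  ch <- vapply(parts, `[`, character(1), 1L)
  tm <- as.numeric(vapply(parts, `[`, character(1), 2L))
  p1 <- as.numeric(vapply(parts, `[`, character(1), 3L))
  p2 <- as.numeric(vapply(parts, `[`, character(1), 4L))
  ripple_idx <- ch == "ripple"
  new_stim_protocol(
    presyn = tm[ch == "epsp"],
    postsyn = tm[ch == "ap"],
    ripple_starts = tm[ripple_idx],
    mode = mode, duration_s = duration_s,
    n_pulses = if (any(ripple_idx)) as.integer(p1[ripple_idx][1L]) else 5L,
    pulse_rate_hz = if (any(ripple_idx)) p2[ripple_idx][1L] else 100,
    holding_mv = holding_mv
  )
}
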