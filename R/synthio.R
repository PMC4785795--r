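#' Configuration for the synthetic session generators
#'
#' Defines the study conditions the generators emulate: rest-epoch LFP with
#' ripple-band transients at known times, SWR-locked reactivation spiking with
#' a controllable number of planted causal CA3->CA1 pairs, Gaussian place
#' fields on a 200 cm linear track, and two-pathway EPSC series. Defaults
#' follow the recorded session this pipeline was designed around: 2 kHz LFP,
#' 0.19 ripples/s (57 per 300 s), 150 Hz ripple oscillation, 40-80 ms ripple
#' durations, one CA3 and four CA1 place cells.
#'
#' @param seed master seed; every generator derives deterministic sub-streams
#'   from it, so identical configs give bit-identical sessions.
#' @param duration_s session length in seconds.
#' @param lfp_rate_hz LFP sampling rate (>= 1 kHz for a 250 Hz band).
#' @param ripple_rate_hz mean SWR rate, events/s.
#' @param ripple_freq_hz intra-ripple oscillation frequency (within 120-250 Hz).
#' @param ripple_dur_range_s (min, max) ripple duration in seconds.
#' @param ripple_snr peak of the smoothed ripple-band envelope, in SDs of the
#'   background envelope above its mean -- i.e. the peak detection z-score of
#'   a planted ripple.
#' @param snr_ref_smooth_ms envelope-smoothing kernel SD (ms) that `ripple_snr`
#'   is referenced to; match it to the detector's `smooth_ms`.
#' @param ripple_placement `"poisson"` for a thinned Poisson process or
#'   `"jittered_grid"` for a deterministic event count at jittered regular
#'   spacing.
#' @param pink_background logical; 1/f (pink) background noise if `TRUE`
#'   (closer to hippocampal LFP and the harder case for SD thresholds),
#'   white Gaussian otherwise.
#' @param n_ca3,n_ca1 number of CA3 / CA1 units.
#' @param baseline_rate_hz Poisson firing rate outside SWRs, per unit.
#' @param swr_gain multiplicative reactivation gain: in-ripple firing rate is
#'   `baseline_rate_hz * (1 + swr_gain)`, so `baseline_rate_hz = 0` silences
#'   everything except planted pairs.
#' @param planted_pairs_per_train integer vector, one per CA1 unit: number of
#'   causal pairs planted into that train (CA3 partner spikes are inserted
#'   into the first CA3 train).
#' @param pair_lag_range_ms (min, max) CA3->CA1 lag of planted pairs; must lie
#'   strictly inside (0, 30) ms so pairs satisfy the causal rule.
#' @param pair_phase_range planted CA3 anchor position as a fraction of ripple
#'   duration relative to onset, within [-0.3, +0.6] (the causal window).
#' @param pair_burst_spikes CA1 spikes per planted pair (>= 2 makes the CA1
#'   partner a burst; extra spikes at `burst_isi_ms` spacing).
#' @param burst_isi_ms intra-burst inter-spike interval used when planting
#'   burst partners.
#' @param track_length_cm,speed_cm_s,traj_rate_hz,traj_jitter_cm linear-track
#'   trajectory parameters: track length, constant running speed, position
#'   sampling rate, and Gaussian position jitter.
#' @param field_centers_cm place-field centers, one per unit (CA3 units first,
#'   then CA1); default spreads them evenly along the track.
#' @param field_sigma_cm,field_peak_hz,field_baseline_hz Gaussian field width,
#'   in-field peak rate and out-of-field floor rate.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         duration_s = 200,
                         lfp_rate_hz = 2000,
                         ripple_rate_hz = 0.19,
                         ripple_freq_hz = 150,
                         ripple_dur_range_s = c(0.04, 0.08),
                         ripple_snr = 8,
                         snr_ref_smooth_ms = 12,
                         ripple_placement = c("poisson", "jittered_grid"),
                         pink_background = TRUE,
                         n_ca3 = 1L,
                         n_ca1 = 4L,
                         baseline_rate_hz = 0.5,
                         swr_gain = 10,
                         planted_pairs_per_train = rep(2L, n_ca1),
                         pair_lag_range_ms = c(5, 25),
                         pair_phase_range = c(0, 0.5),
                         pair_burst_spikes = 1L,
                         burst_isi_ms = 5,
                         track_length_cm = 200,
                         speed_cm_s = 20,
                         traj_rate_hz = 50,
                         traj_jitter_cm = 1,
                         field_centers_cm = NULL,
                         field_sigma_cm = 15,
                         field_peak_hz = 10,
                         field_baseline_hz = 0.1) {
  ripple_placement <- match.arg(ripple_placement)
  cfg <- list(
    seed = as.integer(seed), duration_s = duration_s, lfp_rate_hz = lfp_rate_hz,
    ripple_rate_hz = ripple_rate_hz, ripple_freq_hz = ripple_freq_hz,
    ripple_dur_range_s = ripple_dur_range_s, ripple_snr = ripple_snr,
    snr_ref_smooth_ms = snr_ref_smooth_ms,
    ripple_placement = ripple_placement, pink_background = isTRUE(pink_background),
    n_ca3 = as.integer(n_ca3), n_ca1 = as.integer(n_ca1),
    baseline_rate_hz = baseline_rate_hz, swr_gain = swr_gain,
    planted_pairs_per_train = as.integer(planted_pairs_per_train),
    pair_lag_range_ms = pair_lag_range_ms, pair_phase_range = pair_phase_range,
    pair_burst_spikes = as.integer(pair_burst_spikes), burst_isi_ms = burst_isi_ms,
    track_length_cm = track_length_cm, speed_cm_s = speed_cm_s,
    traj_rate_hz = traj_rate_hz, traj_jitter_cm = traj_jitter_cm,
    field_centers_cm = field_centers_cm, field_sigma_cm = field_sigma_cm,
    field_peak_hz = field_peak_hz, field_baseline_hz = field_baseline_hz
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(
    is_number(cfg$duration_s), cfg$duration_s > 0,
    is_number(cfg$lfp_rate_hz), cfg$lfp_rate_hz >= 1000,
    is_number(cfg$ripple_rate_hz), cfg$ripple_rate_hz >= 0,
    is_number(cfg$ripple_freq_hz),
    cfg$ripple_freq_hz >= 120, cfg$ripple_freq_hz <= 250,
    length(cfg$ripple_dur_range_s) == 2L,
    cfg$ripple_dur_range_s[1] > 0,
    cfg$ripple_dur_range_s[2] >= cfg$ripple_dur_range_s[1],
    is_number(cfg$ripple_snr), cfg$ripple_snr >= 0,
    cfg$n_ca3 >= 1L, cfg$n_ca1 >= 1L,
    is_number(cfg$baseline_rate_hz), cfg$baseline_rate_hz >= 0,
    is_number(cfg$swr_gain), cfg$swr_gain >= 0,
    length(cfg$planted_pairs_per_train) == cfg$n_ca1,
    all(cfg$planted_pairs_per_train >= 0L),
    length(cfg$pair_lag_range_ms) == 2L,
    cfg$pair_lag_range_ms[1] > 0,
    cfg$pair_lag_range_ms[2] < 30,
    cfg$pair_lag_range_ms[2] >= cfg$pair_lag_range_ms[1],
    length(cfg$pair_phase_range) == 2L,
    cfg$pair_phase_range[1] >= -0.3,
    cfg$pair_phase_range[2] <= 0.6,
    cfg$pair_phase_range[2] >= cfg$pair_phase_range[1],
    cfg$pair_burst_spikes >= 1L
  )
  invisible(cfg)
}

# Draw non-overlapping ripple intervals kept away from the session edges.
draw_ripple_times <- function(cfg) {
  margin <- 1.0   # keep ripples >= 1 s from either edge
  lo <- margin
  hi <- cfg$duration_s - margin
  if (hi <= lo || cfg$ripple_rate_hz <= 0) {
    return(data.frame(onset_s = numeric(), offset_s = numeric()))
  }
  durs0 <- cfg$ripple_dur_range_s
  min_gap <- 0.1   # enforced inter-ripple gap, s
  if (cfg$ripple_placement == "jittered_grid") {
    n <- max(0L, round(cfg$ripple_rate_hz * cfg$duration_s))
    if (n == 0L) return(data.frame(onset_s = numeric(), offset_s = numeric()))
    pitch <- (hi - lo) / n
    onsets <- lo + (seq_len(n) - 0.5) * pitch +
      stats::runif(n, -0.2, 0.2) * max(pitch - durs0[2] - min_gap, 0)
    durs <- stats::runif(n, durs0[1], durs0[2])
    return(data.frame(onset_s = sort(onsets), offset_s = sort(onsets) + durs))
  }
  # Poisson candidates, accepted sequentially if non-overlapping
  n_cand <- stats::rpois(1L, cfg$ripple_rate_hz * (hi - lo) * 1.5)
  cand <- sort(stats::runif(n_cand, lo, hi))
  durs <- stats::runif(n_cand, durs0[1], durs0[2])
  target <- cfg$ripple_rate_hz * (hi - lo)
  onset <- numeric(0); offset <- numeric(0); last_end <- -Inf
  for (i in seq_len(n_cand)) {
    if (length(onset) >= target) break
    if (cand[i] > last_end + min_gap && cand[i] + durs[i] < hi) {
      onset <- c(onset, cand[i])
      offset <- c(offset, cand[i] + durs[i])
      last_end <- cand[i] + durs[i]
    }
  }
  data.frame(onset_s = onset, offset_s = offset)
}

# Piecewise-constant-rate Poisson spikes: baseline everywhere, elevated inside
# ripples by the multiplicative reactivation gain.
draw_background_spikes <- function(cfg, ripples) {
  rmax <- cfg$baseline_rate_hz * (1 + cfg$swr_gain)
  if (rmax <= 0) return(numeric(0))
  n <- stats::rpois(1L, rmax * cfg$duration_s)
  t <- sort(stats::runif(n, 0, cfg$duration_s))
  if (length(t) == 0L) return(t)
  inside <- rep(FALSE, length(t))
  if (nrow(ripples) > 0L) {
    idx <- findInterval(t, ripples$onset_s)
    inside <- idx >= 1L & t <= ripples$offset_s[pmax(idx, 1L)]
  }
  p_accept <- ifelse(inside, 1, cfg$baseline_rate_hz / rmax)
  t[stats::runif(length(t)) < p_accept]
}

#' Generate a synthetic rest-epoch session with ground truth
#'
#' Produces a rest-box session: an LFP trace made of 1/f background noise plus
#' Gaussian-windowed ripple-band oscillations at known times, CA3/CA1 spike
#' trains with Poisson background, SWR-locked reactivation, and a configured
#' number of planted causal CA3->CA1 pairs per CA1 train. The planted pairs
#' satisfy the causal-pair rule by construction (lag strictly inside (0, 30) ms,
#' CA3 anchor inside the fractional window) and each occupies its own ripple,
#' so with `baseline_rate_hz = 0` the classifier must recover exactly the
#' planted set.
#'
#' @param cfg a [synth_config()].
#' @return A list with elements `lfp` ([lfp_trace()]), `trains` (list of
#'   [spike_train()], CA3 units first), and `truth`, a list carrying
#'   `ripples` (data.frame onset_s/offset_s) and `planted_pairs` (data.frame
#'   unit_id, ca3_time_s, ca1_time_s, ripple_index, plus a `ca1_member_times_s`
#'   list column).
#' @export
gen_rest_session <- function(cfg) {
  validate_synth_config(cfg)
  ripples <- with_seed(sub_seed(cfg$seed, 1L), draw_ripple_times(cfg))
  n_pairs_total <- sum(cfg$planted_pairs_per_train)
  if (n_pairs_total > nrow(ripples)) {
    stop(sprintf(
      "gen_rest_session: %d planted pairs requested but only %d ripples available; config is over-constrained",
      n_pairs_total, nrow(ripples)
    ))
  }

  # --- LFP -------------------------------------------------------------------
  n <- round(cfg$duration_s * cfg$lfp_rate_hz)
  noise <- with_seed(
    sub_seed(cfg$seed, 2L),
    if (cfg$pink_background) pink_noise(n) else stats::rnorm(n)
  )
  x <- noise
  if (nrow(ripples) > 0L && cfg$ripple_snr > 0) {
    # Calibrate burst amplitude against the background's own band envelope so
    # that the smoothed (detection-statistic) envelope peaks ripple_snr SDs
    # above the background mean. Gaussian smoothing of a Gaussian-windowed
    # burst attenuates its envelope peak by sd_env/sqrt(sd_env^2 + s^2); the
    # injected amplitude compensates per ripple so that ripple_snr is the
    # peak detection z-score regardless of duration.
    s_ref <- cfg$snr_ref_smooth_ms / 1000
    bg <- lfp_trace(noise, cfg$lfp_rate_hz)
    bg_env <- lfp_envelope(
      bandpass_lfp(bg, c(120, 250)), smooth_ms = cfg$snr_ref_smooth_ms
    )$samples
    peak_target <- mean(bg_env) + cfg$ripple_snr * stats::sd(bg_env)
    tt <- (seq_len(n) - 1L) / cfg$lfp_rate_hz
    for (i in seq_len(nrow(ripples))) {
      dur <- ripples$offset_s[i] - ripples$onset_s[i]
      ctr <- ripples$onset_s[i] + dur / 2
      sd_env <- dur / 4   # 2 SD of the Gaussian window lands on onset/offset
      atten <- sd_env / sqrt(sd_env^2 + s_ref^2)
      amp <- peak_target / atten
      sel <- which(tt >= ctr - dur & tt <= ctr + dur)
      x[sel] <- x[sel] + amp * exp(-(tt[sel] - ctr)^2 / (2 * sd_env^2)) *
        sin(2 * pi * cfg$ripple_freq_hz * (tt[sel] - ctr))
    }
  }
  lfp <- lfp_trace(x, cfg$lfp_rate_hz)

  # --- spikes ----------------------------------------------------------------
  planted <- data.frame(
    unit_id = character(), ca3_time_s = numeric(), ca1_time_s = numeric(),
    ripple_index = integer()
  )
  members <- list()
  pair_rows <- with_seed(sub_seed(cfg$seed, 3L), {
    ripple_pool <- if (nrow(ripples)) sample.int(nrow(ripples)) else integer(0)
    used <- 0L
    out <- vector("list", cfg$n_ca1)
    for (u in seq_len(cfg$n_ca1)) {
      k <- cfg$planted_pairs_per_train[u]
      if (k == 0L) { out[[u]] <- NULL; next }
      ridx <- ripple_pool[used + seq_len(k)]
      used <- used + k
      dur <- ripples$offset_s[ridx] - ripples$onset_s[ridx]
      phase <- stats::runif(k, cfg$pair_phase_range[1], cfg$pair_phase_range[2])
      lag_s <- stats::runif(k, cfg$pair_lag_range_ms[1], cfg$pair_lag_range_ms[2]) / 1000
      t3 <- ripples$onset_s[ridx] + phase * dur
      t1 <- t3 + lag_s
      mem <- lapply(t1, function(t0) {
        t0 + (seq_len(cfg$pair_burst_spikes) - 1L) * cfg$burst_isi_ms / 1000
      })
      out[[u]] <- list(
        df = data.frame(
          unit_id = sprintf("CA1%s", letters[u + 1L]),
          ca3_time_s = t3, ca1_time_s = t1, ripple_index = ridx
        ),
        members = mem
      )
    }
    out
  })
  for (u in seq_along(pair_rows)) {
    if (is.null(pair_rows[[u]])) next
    planted <- rbind(planted, pair_rows[[u]]$df)
    members <- c(members, pair_rows[[u]]$members)
  }
  planted$ca1_member_times_s <- members

  trains <- vector("list", cfg$n_ca3 + cfg$n_ca1)
  for (j in seq_len(cfg$n_ca3)) {
    bg <- with_seed(sub_seed(cfg$seed, 10L + j), draw_background_spikes(cfg, ripples))
    t <- bg
    if (j == 1L && nrow(planted) > 0L) t <- c(t, planted$ca3_time_s)
    trains[[j]] <- spike_train(unique(t), sprintf("CA3%s", letters[j]), "CA3")
  }
  for (u in seq_len(cfg$n_ca1)) {
    bg <- with_seed(sub_seed(cfg$seed, 50L + u), draw_background_spikes(cfg, ripples))
    t <- bg
    uid <- sprintf("CA1%s", letters[u + 1L])
    if (nrow(planted) > 0L) {
      mine <- planted$unit_id == uid
      t <- c(t, unlist(planted$ca1_member_times_s[mine]))
    }
    trains[[cfg$n_ca3 + u]] <- spike_train(unique(t), uid, "CA1")
  }

  list(
    lfp = lfp,
    trains = trains,
    truth = list(ripples = ripples, planted_pairs = planted)
  )
}

#' Generate a synthetic linear-track session
#'
#' A back-and-forth constant-speed trajectory on a linear track plus place-cell
#' spike trains: each unit fires as an inhomogeneous Poisson process whose rate
#' is a Gaussian function of position (a place field) on top of a low floor
#' rate.
#'
#' @param cfg a [synth_config()].
#' @return A list with `trajectory` (data.frame `times_s`, `position_cm`),
#'   `trains` (list of [spike_train()], CA3 first then CA1), and
#'   `field_centers_cm` (the planted centers, one per unit).
#' @export
gen_track_session <- function(cfg) {
  validate_synth_config(cfg)
  n_units <- cfg$n_ca3 + cfg$n_ca1
  centers <- cfg$field_centers_cm
  if (is.null(centers)) {
    centers <- cfg$track_length_cm * (seq_len(n_units) - 0.5) / n_units
  }
  stopifnot(length(centers) == n_units)

  dt <- 1 / cfg$traj_rate_hz
  times <- seq(0, cfg$duration_s, by = dt)
  # triangular wave: 0 -> L -> 0 at constant speed
  period <- 2 * cfg$track_length_cm / cfg$speed_cm_s
  ph <- (times %% period) / period
  pos <- ifelse(ph < 0.5, 2 * ph, 2 * (1 - ph)) * cfg$track_length_cm
  pos <- with_seed(
    sub_seed(cfg$seed, 4L),
    pmin(pmax(pos + stats::rnorm(length(pos), 0, cfg$traj_jitter_cm), 0),
         cfg$track_length_cm)
  )
  traj <- data.frame(times_s = times, position_cm = pos)

  trains <- vector("list", n_units)
  for (j in seq_len(n_units)) {
    rate <- cfg$field_baseline_hz + cfg$field_peak_hz *
      exp(-(pos - centers[j])^2 / (2 * cfg$field_sigma_cm^2))
    spikes <- with_seed(sub_seed(cfg$seed, 100L + j), {
      counts <- stats::rpois(length(times) - 1L, rate[-length(rate)] * dt)
      t <- rep(times[-length(times)], counts) +
        stats::runif(sum(counts), 0, dt)
      sort(t)
    })
    reg <- if (j <= cfg$n_ca3) "CA3" else "CA1"
    uid <- if (j <= cfg$n_ca3) sprintf("CA3%s", letters[j]) else {
      sprintf("CA1%s", letters[j - cfg$n_ca3 + 1L])
    }
    trains[[j]] <- spike_train(unique(spikes), uid, reg)
  }
  list(trajectory = traj, trains = trains, field_centers_cm = centers)
}

#' Generate a synthetic EPSC amplitude series
#'
#' Emulates a pathway's sweep series in an induction experiment: constant
#' baseline mean for `n_baseline_min` minutes, then a slow sigmoidal rise
#' toward `true_factor` x baseline (LTP in these experiments develops slowly,
#' with no short-term facilitatory component), with multiplicative Gaussian
#' noise of coefficient of variation `noise_cv`. Sweeps are delivered at
#' 0.1 Hz, so six sweeps average to one point per minute.
#'
#' @param n_baseline_min baseline duration, minutes.
#' @param n_post_min post-induction duration, minutes.
#' @param true_factor asymptotic post/baseline amplitude ratio (> 0).
#' @param noise_cv coefficient of variation of multiplicative sweep noise.
#' @param seed RNG seed.
#' @param pathway pathway label for the series.
#' @param baseline_pa baseline mean amplitude, pA.
#' @param sweep_interval_s inter-sweep interval, seconds (default 10 = 0.1 Hz).
#' @param rise_mid_min,rise_tau_min midpoint and time constant (minutes after
#'   induction) of the logistic rise; defaults saturate to within 0.1% of
#'   `true_factor` by 25 min.
#' @return An [epsc_series()] with `induction_time_s` set to the end of the
#'   baseline period.
#' @export
gen_epsc_series <- function(n_baseline_min = 5, n_post_min = 30,
                            true_factor = 2, noise_cv = 0.1, seed = 1L,
                            pathway = "test", baseline_pa = 30,
                            sweep_interval_s = 10,
                            rise_mid_min = 10, rise_tau_min = 2) {
  stopifnot(is_number(true_factor), true_factor > 0, noise_cv >= 0)
  t_ind <- n_baseline_min * 60
  t_end <- t_ind + n_post_min * 60
  times <- seq(sweep_interval_s, t_end, by = sweep_interval_s)
  post_min <- pmax(times - t_ind, 0) / 60
  rise <- ifelse(
    times <= t_ind, 0,
    stats::plogis((post_min - rise_mid_min) / rise_tau_min)
  )
  mean_amp <- baseline_pa * (1 + (true_factor - 1) * rise)
  amp <- with_seed(
    sub_seed(seed, 7L),
    mean_amp * (1 + noise_cv * stats::rnorm(length(times)))
  )
  epsc_series(times, amp, pathway = pathway, induction_time_s = t_ind)
}
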