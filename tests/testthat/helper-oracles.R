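# Brute-force reference implementations, independent of the package's code
# paths. These enumerate instead of scanning and are used to validate the
# production algorithms on small inputs.

# Run-length burst finder: group spikes wherever the gap to the previous spike
# is <= isi; groups of >= 2 are bursts.
oracle_bursts <- function(times, burst_isi_ms = 10) {
  times <- sort(times)
  if (length(times) < 2L) return(list())
  groups <- list()
  cur <- times[1L]
  for (i in 2:length(times)) {
    if (times[i] - times[i - 1L] <= burst_isi_ms / 1000) {
      cur <- c(cur, times[i])
    } else {
      if (length(cur) >= 2L) groups[[length(groups) + 1L]] <- cur
      cur <- times[i]
    }
  }
  if (length(cur) >= 2L) groups[[length(groups) + 1L]] <- cur
  groups
}

# Exhaustive O(n^2) causal-pair classifier honoring the same greedy
# left-to-right tie-break policy: each CA3 spike (in time order) takes the
# earliest unconsumed CA1 spike/burst-onset strictly within (0, max_lag).
oracle_classify <- function(ca3_times, ca1_times, events,
                            max_lag_ms = 30, pre_frac = 0.3, post_frac = 0.6,
                            burst_isi_ms = 10) {
  ca3_times <- sort(ca3_times)
  ca1_times <- sort(ca1_times)
  bursts <- oracle_bursts(ca1_times, burst_isi_ms)
  in_burst <- ca1_times %in% unlist(bursts)
  anchors <- c(vapply(bursts, `[`, numeric(1), 1L), ca1_times[!in_burst])
  members <- c(bursts, as.list(ca1_times[!in_burst]))
  o <- order(anchors)
  anchors <- anchors[o]
  members <- members[o]
  consumed <- rep(FALSE, length(anchors))

  res3 <- numeric(0); res1 <- numeric(0); resmem <- list()
  for (t3 in ca3_times) {
    ev_hit <- NA_integer_
    for (e in seq_len(nrow(events))) {
      dur <- events$offset_s[e] - events$onset_s[e]
      if (t3 >= events$onset_s[e] - pre_frac * dur &&
          t3 <= events$onset_s[e] + post_frac * dur) {
        ev_hit <- e
        break
      }
    }
    if (is.na(ev_hit)) next
    for (j in seq_along(anchors)) {
      if (consumed[j]) next
      lag <- anchors[j] - t3
      if (lag > 0 && lag < max_lag_ms / 1000) {
        consumed[j] <- TRUE
        res3 <- c(res3, t3)
        res1 <- c(res1, anchors[j])
        resmem[[length(resmem) + 1L]] <- members[[j]]
        break
      }
      if (lag >= max_lag_ms / 1000) break  # anchors sorted: nothing later fits
    }
  }
  list(ca3 = res3, ca1 = res1, members = resmem)
}

# Nested-loop cross-correlogram: all (ca1, ca3) pairs with lag in [-L, L),
# half-open bins.
oracle_crosscorr_counts <- function(ca3_times, ca1_times, lag_ms = 100,
                                    bin_ms = 10) {
  edges <- seq(-lag_ms, lag_ms, by = bin_ms)
  counts <- numeric(length(edges) - 1L)
  for (t3 in ca3_times) {
    for (t1 in ca1_times) {
      lag <- (t1 - t3) * 1000
      if (lag >= -lag_ms && lag < lag_ms) {
        b <- findInterval(lag, edges)
        counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

# Random small session for classifier cross-validation: a handful of ripples
# plus uniform random trains.
random_session <- function(seed, t_max = 30, max_spikes = 100) {
  set.seed(seed)
  n_ev <- sample(3:10, 1)
  onset <- sort(runif(n_ev, 1, t_max - 1))
  dur <- runif(n_ev, 0.04, 0.1)
  # enforce non-overlap incl. a gap
  keep <- c(TRUE, diff(onset) > 0.3)
  onset <- onset[keep]; dur <- dur[keep]
  ev <- ripple_events(onset, onset + dur)
  # diffuse background plus event-locked spikes so the rule is exercised
  n3 <- sample(5:(max_spikes %/% 2), 1)
  n1 <- sample(5:(max_spikes %/% 2), 1)
  t3 <- runif(n3, 0, t_max)
  t1 <- runif(n1, 0, t_max)
  for (o in onset) {
    loc3 <- o + runif(rpois(1, 2), -0.05, 0.1)
    t3 <- c(t3, loc3)
    for (l in loc3) t1 <- c(t1, l + runif(rpois(1, 1.5), 0, 0.05))
  }
  list(
    ev = ev,
    ca3 = spike_train(unique(t3), "CA3a", "CA3"),
    ca1 = spike_train(unique(t1), "CA1b", "CA1")
  )
}

# Fixture mirroring the necessity/sufficiency editing experiment: 8 causal
# events whose CA1 partners comprise 10 spikes (6 singles + 2 two-spike
# bursts), plus distractor spikes that never form events.
make_editing_fixture <- function() {
  onsets <- seq(1, 8) * 1.0
  ev <- ripple_events(onsets, onsets + 0.08)
  ca3_anchor <- onsets + 0.010
  ca1_single <- ca3_anchor[1:6] + 0.012
  ca1_burst1 <- ca3_anchor[7] + c(0.012, 0.018)
  ca1_burst2 <- ca3_anchor[8] + c(0.012, 0.018)
  # distractors: CA3 far outside any window; CA1 anti-causal and beyond 30 ms
  ca3_extra <- onsets + 0.5
  ca1_extra <- c(onsets - 0.3, onsets + 0.6)
  list(
    ev = ev,
    ca3 = spike_train(c(ca3_anchor, ca3_extra), "CA3a", "CA3"),
    ca1 = spike_train(c(ca1_single, ca1_burst1, ca1_burst2, ca1_extra),
                      "CA1d", "CA1"),
    n_events = 8L,
    n_member_spikes = 10L
  )
}

# mean normalized response in a post-induction window (minutes), computed
# directly from the series fields
window_mean_of <- function(series, window_min) {
  t_ind <- series$induction_time_s
  sel <- series$sweep_times_s >= t_ind + window_min[1] * 60 &
    series$sweep_times_s < t_ind + window_min[2] * 60
  mean(series$amplitudes_pa[sel])
}
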