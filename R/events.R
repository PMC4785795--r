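#' Causal-pair rule configuration
#'
#' Parameters of the plasticity-potent event rule: a CA3 spike followed less
#' than `max_lag_ms` later by a CA1 spike or burst, occurring either just
#' before a ripple (within `pre_frac` of the SWR duration before onset) or
#' during its first part (within `post_frac` of the duration after onset).
#'
#' @param max_lag_ms maximum CA3->CA1 lag, ms (strict inequality).
#' @param pre_frac window extent before onset, as a fraction of SWR duration.
#' @param post_frac window extent after onset, as a fraction of SWR duration.
#' @param burst_isi_ms maximum inter-spike interval within a CA1 burst, ms
#'   (CA1 complex-spike bursts have 3-10 ms ISIs).
#' @param anchor which spike is tested against the fractional window:
#'   `"ca3"` (the presynaptic spike initiates the pairing; default) or
#'   `"ca1"`.
#' @return A list of class `event_rule_config`.
#' @export
event_rule_config <- function(max_lag_ms = 30, pre_frac = 0.3, post_frac = 0.6,
                              burst_isi_ms = 10, anchor = c("ca3", "ca1")) {
  anchor <- match.arg(anchor)
  stopifnot(
    is_number(max_lag_ms), max_lag_ms > 0,
    is_number(pre_frac), pre_frac >= 0,
    is_number(post_frac), post_frac >= 0,
    is_number(burst_isi_ms), burst_isi_ms > 0
  )
  structure(
    list(
      max_lag_ms = max_lag_ms, pre_frac = pre_frac, post_frac = post_frac,
      burst_isi_ms = burst_isi_ms, anchor = anchor
    ),
    class = "event_rule_config"
  )
}

#' Detect bursts in a spike train
#'
#' Maximal runs of two or more spikes whose successive inter-spike intervals
#' are all at most `burst_isi_ms`. Singleton spikes are not bursts.
#'
#' @param train a [spike_train()].
#' @param burst_isi_ms ISI threshold, ms.
#' @return data.frame with `onset_s`, `n_spikes` and a `member_times_s` list
#'   column; zero rows if no bursts.
#' @export
detect_bursts <- function(train, burst_isi_ms = 10) {
  stopifnot(inherits(train, "spike_train"), burst_isi_ms > 0)
  t <- train$times_s
  if (length(t) < 2L) {
    return(data.frame(
      onset_s = numeric(), n_spikes = integer(),
      member_times_s = I(list())
    ))
  }
  joined <- diff(t) <= burst_isi_ms / 1000
  runs <- rle(joined)
  onset <- numeric(0); nsp <- integer(0); members <- list()
  pos <- 1L
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i]) {
      idx <- pos:(pos + runs$lengths[i])
      onset <- c(onset, t[idx[1L]])
      nsp <- c(nsp, length(idx))
      members <- c(members, list(t[idx]))
    }
    pos <- pos + runs$lengths[i]
  }
  data.frame(onset_s = onset, n_spikes = nsp, member_times_s = I(members))
}

# Group a CA1 train into pairing units: each burst is one unit anchored at its
# onset; spikes outside bursts are singleton units.
ca1_units <- function(train, burst_isi_ms) {
  bursts <- detect_bursts(train, burst_isi_ms)
  in_burst <- train$times_s %in% unlist(bursts$member_times_s)
  singles <- train$times_s[!in_burst]
  anchor <- c(bursts$onset_s, singles)
  members <- c(bursts$member_times_s, as.list(singles))
  o <- order(anchor)
  list(anchor = anchor[o], members = members[o])
}

empty_pair_events <- function() {
  structure(
    data.frame(
      ca3_time_s = numeric(), ca1_time_s = numeric(), lag_ms = numeric(),
      ripple_index = integer(), phase = numeric(), is_burst = logical(),
      ca1_member_times_s = I(list())
    ),
    class = c("causal_pair_events", "data.frame")
  )
}

#' Classify causal CA3->CA1 spike pairs around SWR onsets
#'
#' Implements the plasticity-potent event rule: each CA3 spike whose anchor
#' lies within `[onset - pre_frac * dur, onset + post_frac * dur]` of a ripple
#' is paired with the first CA1 spike or burst onset strictly within
#' `(0, max_lag_ms)` ms after it. Pairing is greedy left-to-right: each CA1
#' spike/burst is consumed by at most one event and each CA3 spike produces at
#' most one event. A CA1 burst qualifies if its onset is inside the lag window
#' even if later members straddle it.
#'
#' @param ca3,ca1 [spike_train()]s.
#' @param events sorted, non-overlapping [ripple_events()].
#' @param cfg an [event_rule_config()].
#' @return A `causal_pair_events` data frame: `ca3_time_s`, `ca1_time_s`
#'   (spike or burst onset), `lag_ms`, `ripple_index`, `phase`
#'   (`(anchor - onset)/duration`), `is_burst`, and list column
#'   `ca1_member_times_s` with every CA1 spike constituting the event.
#' @export
classify_pairs <- function(ca3, ca1, events, cfg = event_rule_config()) {
  stopifnot(
    inherits(ca3, "spike_train"), inherits(ca1, "spike_train"),
    inherits(events, "ripple_events"), inherits(cfg, "event_rule_config")
  )
  if (nrow(events) > 1L &&
      any(events$onset_s[-1L] < events$offset_s[-nrow(events)])) {
    stop("classify_pairs: overlapping ripple events; phase is ambiguous")
  }
  if (nrow(events) == 0L || !length(ca3$times_s) || !length(ca1$times_s)) {
    return(empty_pair_events())
  }
  dur <- events$offset_s - events$onset_s
  w_lo <- events$onset_s - cfg$pre_frac * dur
  w_hi <- events$onset_s + cfg$post_frac * dur
  max_lag_s <- cfg$max_lag_ms / 1000

  units <- ca1_units(ca1, cfg$burst_isi_ms)
  consumed <- rep(FALSE, length(units$anchor))
  # earliest window containing a time (windows may overlap even when events
  # do not; the earliest-onset event wins, deterministically)
  window_of <- function(t) {
    hit <- which(w_lo <= t & t <= w_hi)
    if (length(hit)) hit[1L] else NA_integer_
  }

  rows <- empty_pair_events()
  for (t3 in ca3$times_s) {
    if (cfg$anchor == "ca3") {
      ev <- window_of(t3)
      if (is.na(ev)) next
      j <- which(!consumed & units$anchor > t3 &
                   units$anchor < t3 + max_lag_s)
      if (!length(j)) next
      j <- j[1L]
    } else {
      j <- which(!consumed & units$anchor > t3 &
                   units$anchor < t3 + max_lag_s)
      if (length(j)) {
        in_win <- !is.na(vapply(units$anchor[j], window_of, integer(1)))
        j <- j[in_win]
      }
      if (!length(j)) next
      j <- j[1L]
      ev <- window_of(units$anchor[j])
    }
    consumed[j] <- TRUE
    anchor_t <- if (cfg$anchor == "ca3") t3 else units$anchor[j]
    rows <- rbind(rows, structure(
      data.frame(
        ca3_time_s = t3, ca1_time_s = units$anchor[j],
        lag_ms = (units$anchor[j] - t3) * 1000,
        ripple_index = ev,
        phase = (anchor_t - events$onset_s[ev]) / dur[ev],
        is_burst = length(units$members[[j]]) >= 2L,
        ca1_member_times_s = I(units$members[j])
      ),
      class = c("causal_pair_events", "data.frame")
    ))
  }
  rows
}

# greedy unrestricted pairing of CA3 spikes with CA1 units (burst-only option);
# used for the whole-train burst-pair predictor
greedy_pair_count <- function(ca3_times, units, max_lag_s, bursts_only = FALSE) {
  eligible <- if (bursts_only) {
    vapply(units$members, length, integer(1)) >= 2L
  } else {
    rep(TRUE, length(units$anchor))
  }
  consumed <- rep(FALSE, length(units$anchor))
  n <- 0L
  for (t3 in ca3_times) {
    j <- which(eligible & !consumed & units$anchor > t3 &
                 units$anchor < t3 + max_lag_s)
    if (!length(j)) next
    consumed[j[1L]] <- TRUE
    n <- n + 1L
  }
  n
}

#' Spike-train predictors of plasticity
#'
#' The three candidate predictors of induced synaptic change: the number of
#' causal CA3->CA1 pairs inside SWR windows, the number of CA3 spikes followed
#' by a CA1 burst within the lag window, and the total number of CA1 spikes in
#' the train. Because it is ambiguous whether the burst predictor should be
#' restricted to SWR windows, both variants are returned.
#'
#' @inheritParams classify_pairs
#' @return A list: `n_pairs`, `n_ca3_burst_pairs` (burst-partner events inside
#'   the SWR window), `n_ca1_spikes` (whole train),
#'   `n_ca3_burst_pairs_unrestricted` (whole-train greedy count, no window).
#' @export
count_predictors <- function(ca3, ca1, events, cfg = event_rule_config()) {
  found <- classify_pairs(ca3, ca1, events, cfg)
  units <- ca1_units(ca1, cfg$burst_isi_ms)
  list(
    n_pairs = nrow(found),
    n_ca3_burst_pairs = sum(found$is_burst),
    n_ca1_spikes = length(ca1$times_s),
    n_ca3_burst_pairs_unrestricted = greedy_pair_count(
      ca3$times_s, units, cfg$max_lag_ms / 1000, bursts_only = TRUE
    )
  )
}

#' Remove the CA1 spikes constituting classified events
#'
#' Deletes every CA1 member spike of the given events from the train, leaving
#' all other spikes untouched (the "necessity" manipulation: is the train
#' still plasticity-potent without these spikes?).
#'
#' @param ca1 the [spike_train()] the events were classified from.
#' @param found a `causal_pair_events` table from [classify_pairs()].
#' @return The shortened [spike_train()].
#' @export
remove_event_spikes <- function(ca1, found) {
  stopifnot(inherits(ca1, "spike_train"), inherits(found, "causal_pair_events"))
  members <- unlist(found$ca1_member_times_s)
  if (is.null(members)) members <- numeric(0)
  if (!all(members %in% ca1$times_s)) {
    stop("remove_event_spikes: event member times absent from train; stale event list")
  }
  spike_train(
    ca1$times_s[!(ca1$times_s %in% members)],
    unit_id = ca1$unit_id, region = ca1$region
  )
}

#' Keep only the spikes constituting classified events
#'
#' Retains exactly the CA3 anchor spikes and CA1 member spikes of the events
#' (the "sufficiency" manipulation: are these events alone plasticity-potent?).
#'
#' @param ca3,ca1 the [spike_train()]s the events were classified from.
#' @param found a `causal_pair_events` table from [classify_pairs()].
#' @return A list of two [spike_train()]s, `ca3` and `ca1`.
#' @export
isolate_events <- function(ca3, ca1, found) {
  stopifnot(
    inherits(ca3, "spike_train"), inherits(ca1, "spike_train"),
    inherits(found, "causal_pair_events")
  )
  members <- unlist(found$ca1_member_times_s)
  if (is.null(members)) members <- numeric(0)
  if (!all(found$ca3_time_s %in% ca3$times_s) || !all(members %in% ca1$times_s)) {
    stop("isolate_events: event times absent from trains; stale event list")
  }
  list(
    ca3 = spike_train(found$ca3_time_s, ca3$unit_id, ca3$region),
    ca1 = spike_train(members, ca1$unit_id, ca1$region)
  )
}
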