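# SWR-conditioned spike statistics: spikes per SWR, peri-SWR time histograms,
# population co-activity and SWR-restricted CA3 x CA1 cross-correlograms.

# count spikes falling inside [onset, offset] of each event
count_in_events <- function(times, events) {
  vapply(
    seq_len(nrow(events)),
    function(i) sum(times >= events$onset_s[i] & times <= events$offset_s[i]),
    numeric(1)
  )
}

#' Spikes per SWR
#'
#' Counts a unit's spikes inside each ripple event and summarizes across
#' events. Reported per-cell, these are the statistics behind "median spikes
#' per SWR" comparisons between CA3 and CA1 populations.
#'
#' @param train a [spike_train()].
#' @param events a non-empty [ripple_events()] table.
#' @return A list: `counts` (per event), `mean`, `median`, `q1`, `q3`,
#'   `n_events`.
#' @export
spikes_per_swr <- function(train, events) {
  stopifnot(inherits(train, "spike_train"), inherits(events, "ripple_events"))
  if (nrow(events) == 0L) stop("spikes_per_swr: no events; statistic undefined")
  counts <- count_in_events(train$times_s, events)
  qs <- stats::quantile(counts, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(
    counts = counts, mean = mean(counts), median = qs[2],
    q1 = qs[1], q3 = qs[3], n_events = nrow(events)
  )
}

#' Peri-SWR time histogram per region
#'
#' Re-references every spike to each ripple onset, histograms the relative
#' times, and averages across events and units within each region, in Hz.
#'
#' @param trains list of [spike_train()]s.
#' @param events a [ripple_events()] table.
#' @param window_s (lo, hi) window around onset, seconds.
#' @param bin_s bin width, seconds.
#' @return A list per region (`CA3`, `CA1`), each of class `psth_result` with
#'   `bin_edges_s`, `rate_hz`, `n_events`, `n_units`. Regions with no units are
#'   omitted.
#' @export
peri_swr_psth <- function(trains, events, window_s = c(-0.2, 0.5), bin_s = 0.01) {
  stopifnot(length(window_s) == 2L, window_s[1] < window_s[2], bin_s > 0)
  edges <- seq(window_s[1], window_s[2], by = bin_s)
  nb <- length(edges) - 1L
  regions <- unique(vapply(trains, function(tr) tr$region, character(1)))
  out <- list()
  for (reg in regions) {
    units <- Filter(function(tr) tr$region == reg, trains)
    counts <- numeric(nb)
    for (tr in units) {
      for (i in seq_len(nrow(events))) {
        rel <- tr$times_s - events$onset_s[i]
        rel <- rel[rel >= window_s[1] & rel < window_s[2]]
        if (length(rel)) {
          # half-open bins [lo, hi): edge spikes belong to the later bin
          counts <- counts + tabulate(findInterval(rel, edges), nbins = nb)
        }
      }
    }
    denom <- max(nrow(events), 1L) * length(units) * bin_s
    out[[reg]] <- structure(
      list(
        bin_edges_s = edges, rate_hz = counts / denom,
        n_events = nrow(events), n_units = length(units)
      ),
      class = "psth_result"
    )
  }
  out
}

#' Population co-activity trace
#'
#' Number of units with at least one spike per time bin (1 s default), bounded
#' above by the number of units.
#'
#' @param trains list of [spike_train()]s.
#' @param bin_s bin width, seconds.
#' @param t_range (start, end) of the binning grid; defaults to 0 up to the
#'   last spike.
#' @return data.frame with `bin_start_s` and `n_active`.
#' @export
coactivity <- function(trains, bin_s = 1, t_range = NULL) {
  stopifnot(bin_s > 0)
  all_t <- unlist(lapply(trains, function(tr) tr$times_s))
  if (is.null(t_range)) {
    t_range <- c(0, if (length(all_t)) max(all_t) else bin_s)
  }
  edges <- seq(t_range[1], t_range[2] + bin_s, by = bin_s)
  nb <- length(edges) - 1L
  active <- matrix(0L, nrow = nb, ncol = length(trains))
  for (j in seq_along(trains)) {
    ts <- trains[[j]]$times_s
    ts <- ts[ts >= edges[1] & ts < edges[length(edges)]]
    if (length(ts)) {
      active[unique(findInterval(ts, edges)), j] <- 1L
    }
  }
  data.frame(bin_start_s = edges[-length(edges)], n_active = rowSums(active))
}

#' SWR-restricted CA3 x CA1 cross-correlogram
#'
#' Using only spikes inside a restriction window around each ripple onset
#' (default 50 ms before to 150 ms after), histograms the CA1 - CA3 spike-time
#' differences in +/-`lag_ms` at `bin_ms` pitch, and normalizes the counts by
#' the total number of CA1 spikes occurring within SWR event intervals.
#' Positive lag means the CA1 spike follows the CA3 spike.
#'
#' @param ca3,ca1 [spike_train()]s.
#' @param events sorted [ripple_events()].
#' @param restrict_s (lo, hi) restriction window around each onset, seconds.
#' @param lag_ms half-width of the correlogram, ms.
#' @param bin_ms bin width, ms.
#' @param restrict `"both"` restricts both trains to the window, `"ca1"` only
#'   the CA1 train.
#' @param normalizer `"swr_spikes"` divides by CA1 spikes inside event
#'   intervals; `"restrict_window"` divides by CA1 spikes inside the
#'   restriction windows.
#' @return A list of class `crosscorr_result`: `lag_bin_edges_ms`,
#'   `counts` (raw pair counts), `normalized_counts`, `n_ca1_in_swr`,
#'   `lag_convention`.
#' @export
swr_crosscorr <- function(ca3, ca1, events, restrict_s = c(-0.05, 0.15),
                          lag_ms = 100, bin_ms = 10,
                          restrict = c("both", "ca1"),
                          normalizer = c("swr_spikes", "restrict_window")) {
  restrict <- match.arg(restrict)
  normalizer <- match.arg(normalizer)
  stopifnot(
    inherits(ca3, "spike_train"), inherits(ca1, "spike_train"),
    inherits(events, "ripple_events")
  )
  in_restrict <- function(times) {
    if (nrow(events) == 0L) return(rep(FALSE, length(times)))
    hit <- rep(FALSE, length(times))
    for (i in seq_len(nrow(events))) {
      hit <- hit | (times >= events$onset_s[i] + restrict_s[1] &
                      times < events$onset_s[i] + restrict_s[2])
    }
    hit
  }
  t3 <- if (restrict == "both") ca3$times_s[in_restrict(ca3$times_s)] else ca3$times_s
  t1 <- ca1$times_s[in_restrict(ca1$times_s)]

  edges <- seq(-lag_ms, lag_ms, by = bin_ms)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  if (length(t3) && length(t1)) {
    lags <- as.vector(outer(t1, t3, "-")) * 1000
    lags <- lags[lags >= -lag_ms & lags < lag_ms]  # half-open on the right
    if (length(lags)) counts <- tabulate(findInterval(lags, edges), nbins = nb)
  }

  n_norm <- if (normalizer == "swr_spikes") {
    sum(count_in_events(ca1$times_s, events))
  } else {
    length(t1)
  }
  if (n_norm == 0 && sum(counts) > 0) {
    stop("swr_crosscorr: zero normalizer with nonzero counts; inconsistent restriction")
  }
  structure(
    list(
      lag_bin_edges_ms = edges, counts = counts,
      normalized_counts = if (n_norm > 0) counts / n_norm else counts,
      n_ca1_in_swr = n_norm,
      lag_convention = "positive lag = CA1 after CA3"
    ),
    class = "crosscorr_result"
  )
}
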