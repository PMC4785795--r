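#' Place-field rate map on a linear track
#'
#' Divides the track into fixed-pitch bins (10 cm default, matching a
#' 200 x 10 cm track collapsed to 20 x 1 bins), accumulates occupancy from the
#' trajectory sampling intervals, assigns spikes to bins by linear
#' interpolation of position at spike time, and reports the
#' occupancy-normalized firing rate per bin.
#'
#' Trajectory gaps longer than `gap_s` are excluded from occupancy. Bins the
#' animal never visited are reported as `NA` rate (flagged, not zero-filled).
#'
#' @param spikes a [spike_train()]; all spike times must fall inside the
#'   trajectory time span.
#' @param traj data.frame with strictly increasing `times_s` and `position_cm`
#'   within `[0, track_cm]`.
#' @param bin_cm bin pitch, cm.
#' @param track_cm track length, cm.
#' @param gap_s trajectory gaps longer than this are dropped from occupancy.
#' @param smooth_sd_cm optional Gaussian smoothing SD for the rate map in cm
#'   (0 = unsmoothed, the default).
#' @return A list of class `rate_map`: `bin_edges_cm`, `occupancy_s`,
#'   `spike_counts`, `rate_hz` (NA where occupancy is 0), `mean_rate_hz`.
#' @export
rate_map <- function(spikes, traj, bin_cm = 10, track_cm = 200, gap_s = 0.5,
                     smooth_sd_cm = 0) {
  stopifnot(inherits(spikes, "spike_train"), is.data.frame(traj))
  tt <- traj$times_s
  pp <- traj$position_cm
  if (is.unsorted(tt, strictly = TRUE)) stop("rate_map: trajectory times must increase")
  if (any(pp < 0 | pp > track_cm)) stop("rate_map: positions outside track bounds")
  edges <- seq(0, track_cm, by = bin_cm)
  nb <- length(edges) - 1L

  st <- spikes$times_s
  bad <- st < tt[1L] | st > tt[length(tt)]
  if (any(bad)) {
    stop(
      "rate_map: spikes outside trajectory time span: ",
      paste(format(st[bad]), collapse = ", ")
    )
  }

  # occupancy: each inter-sample interval assigned to the bin of its midpoint
  dt <- diff(tt)
  mid <- (pp[-length(pp)] + pp[-1L]) / 2
  ok <- dt <= gap_s
  bin_of <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), nb)
  occ <- vapply(
    seq_len(nb),
    function(b) sum(dt[ok & bin_of(mid) == b]),
    numeric(1)
  )

  pos_at_spike <- stats::approx(tt, pp, xout = st)$y
  counts <- tabulate(bin_of(pos_at_spike), nbins = nb)
  if (length(st) == 0L) counts <- rep(0L, nb)

  rate <- ifelse(occ > 0, counts / occ, NA_real_)
  if (smooth_sd_cm > 0) {
    vis <- !is.na(rate)
    sm <- gauss_smooth(ifelse(vis, rate, 0), smooth_sd_cm / bin_cm)
    wt <- gauss_smooth(as.numeric(vis), smooth_sd_cm / bin_cm)
    rate[vis] <- (sm / pmax(wt, .Machine$double.eps))[vis]
  }
  structure(
    list(
      bin_edges_cm = edges, occupancy_s = occ, spike_counts = counts,
      rate_hz = rate,
      mean_rate_hz = if (sum(occ) > 0) sum(counts) / sum(occ) else NA_real_
    ),
    class = "rate_map"
  )
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(
    "<rate_map> %d bins of %g cm, %d spikes, mean rate %.3g Hz\n",
    length(x$rate_hz), diff(x$bin_edges_cm[1:2]), sum(x$spike_counts),
    x$mean_rate_hz
  ))
  invisible(x)
}

# Segment a trajectory into monotone traversals using turning-point detection
# with displacement hysteresis: a turn is declared once position retreats more
# than `hysteresis_cm` from the running extreme. Positions are lightly smoothed
# first (Gaussian, `smooth_s` SD) so per-sample tracking jitter cannot fake a
# retreat; spike positions elsewhere always use the raw trace.
segment_runs <- function(traj, hysteresis_cm = 5, smooth_s = 0.2) {
  pp <- traj$position_cm
  n <- length(pp)
  if (n > 2L && smooth_s > 0) {
    dt <- stats::median(diff(traj$times_s))
    if (is.finite(dt) && dt > 0) pp <- gauss_smooth(pp, smooth_s / dt)
  }
  if (n < 2L) return(data.frame(start = integer(), end = integer(), dir = integer()))
  turns <- integer(0)
  dir <- 0L
  min_p <- pp[1L]; min_i <- 1L
  max_p <- pp[1L]; max_i <- 1L
  for (i in 2:n) {
    if (pp[i] > max_p) { max_p <- pp[i]; max_i <- i }
    if (pp[i] < min_p) { min_p <- pp[i]; min_i <- i }
    if (dir != -1L && pp[i] < max_p - hysteresis_cm) {
      if (dir == 1L) turns <- c(turns, max_i)
      dir <- -1L
      min_p <- pp[i]; min_i <- i
    } else if (dir != 1L && pp[i] > min_p + hysteresis_cm) {
      if (dir == -1L) turns <- c(turns, min_i)
      dir <- 1L
      max_p <- pp[i]; max_i <- i
    }
  }
  bounds <- unique(c(1L, turns, n))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  keep <- ends > starts
  data.frame(
    start = starts[keep], end = ends[keep],
    dir = sign(pp[ends[keep]] - pp[starts[keep]])
  )
}

#' Per-trial firing positions on the track
#'
#' Splits the trajectory into maximal monotone traversals (trials) covering at
#' least `min_frac` of the track length in the requested direction and returns
#' the track positions of the unit's spikes on each trial. Trials without
#' spikes are included as empty rows.
#'
#' @param spikes a [spike_train()].
#' @param traj trajectory data.frame (`times_s`, `position_cm`).
#' @param direction `"outbound"` (increasing position, 0 -> end of track) or
#'   `"inbound"` (decreasing).
#' @param track_cm track length, cm.
#' @param min_frac minimum fraction of the track a traversal must cover to
#'   count as a trial.
#' @param hysteresis_cm displacement hysteresis for turning-point detection.
#' @param smooth_s Gaussian SD (seconds) of the position smoothing used only
#'   for turn detection, so tracking jitter cannot fake a turn.
#' @return A list of numeric vectors, one per trial, of spike positions (cm);
#'   empty list if no complete traversals exist.
#' @export
trial_raster <- function(spikes, traj, direction = c("outbound", "inbound"),
                         track_cm = 200, min_frac = 0.8, hysteresis_cm = 5,
                         smooth_s = 0.2) {
  direction <- match.arg(direction)
  stopifnot(inherits(spikes, "spike_train"))
  segs <- segment_runs(traj, hysteresis_cm, smooth_s)
  want <- if (direction == "outbound") 1L else -1L
  tt <- traj$times_s
  pp <- traj$position_cm
  span <- abs(pp[segs$end] - pp[segs$start])
  segs <- segs[segs$dir == want & span >= min_frac * track_cm, , drop = FALSE]
  if (nrow(segs) == 0L) return(list())
  lapply(seq_len(nrow(segs)), function(i) {
    t0 <- tt[segs$start[i]]; t1 <- tt[segs$end[i]]
    st <- spikes$times_s[spikes$times_s >= t0 & spikes$times_s < t1]
    if (!length(st)) return(numeric(0))
    stats::approx(tt, pp, xout = st)$y
  })
}
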