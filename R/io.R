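# Plain-text readers and writers for all session artifacts. Every writer
# round-trips through its reader; numbers are printed with 17 significant
# digits so round-trips are bit-exact.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write spike trains as delimited text
#'
#' Tab-separated columns `unit_id`, `region`, `time_s`, one spike per line.
#'
#' @param trains list of [spike_train()]s (or a single train).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  rows <- unlist(lapply(trains, function(tr) {
    if (!length(tr$times_s)) return(character(0))
    sprintf("%s\t%s\t%s", tr$unit_id, tr$region, fmt17(tr$times_s))
  }))
  writeLines(c("unit_id\tregion\ttime_s", rows), path)
  invisible(path)
}

#' Read spike trains written by [write_spike_trains()]
#'
#' @param path file path.
#' @return A named list of [spike_train()]s, in first-appearance order.
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(df$unit_id)
  out <- lapply(ids, function(id) {
    sel <- df$unit_id == id
    spike_train(df$time_s[sel], unit_id = id, region = df$region[sel][1L])
  })
  names(out) <- ids
  out
}

#' Write an LFP trace as single-channel text with a sidecar header
#'
#' Header comments carry the sampling rate and start time; one sample per line.
#'
#' @param trace an [lfp_trace()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(trace, path) {
  stopifnot(inherits(trace, "lfp_trace"))
  writeLines(
    c(
      sprintf("# rate_hz=%s", fmt17(trace$rate_hz)),
      sprintf("# t0_s=%s", fmt17(trace$t0_s)),
      fmt17(trace$samples)
    ),
    path
  )
  invisible(path)
}

#' Read an LFP trace written by [write_lfp()]
#'
#' @param path file path.
#' @return An [lfp_trace()].
#' @export
read_lfp <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_hdr <- function(key) {
    as.numeric(sub(sprintf("^# %s=", key), "",
                   grep(sprintf("^# %s=", key), hdr, value = TRUE)[1L]))
  }
  lfp_trace(as.numeric(body), rate_hz = get_hdr("rate_hz"), t0_s = get_hdr("t0_s"))
}

#' Write ripple events as delimited text
#'
#' Tab-separated `onset_s`, `offset_s`, `peak_sd`; detection parameters (if
#' attached by [detect_ripples()]) are echoed into the comment header for
#' provenance.
#'
#' @param events a [ripple_events()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ripples <- function(events, path) {
  stopifnot(inherits(events, "ripple_events"))
  cfg <- attr(events, "config")
  hdr <- "# swrtools ripple events"
  if (!is.null(cfg)) {
    hdr <- c(hdr, sprintf(
      "# band_hz=%g-%g detect_sd=%g bound_sd=%g smooth_ms=%g merge_ms=%g min_dur_ms=%g sd_estimate=%s",
      cfg$band_hz[1], cfg$band_hz[2], cfg$detect_sd, cfg$bound_sd,
      cfg$smooth_ms, cfg$merge_ms, cfg$min_dur_ms, cfg$sd_estimate
    ))
  }
  writeLines(
    c(
      hdr, "onset_s\toffset_s\tpeak_sd",
      sprintf("%s\t%s\t%s", fmt17(events$onset_s), fmt17(events$offset_s),
              fmt17(events$peak_sd))
    ),
    path
  )
  invisible(path)
}

#' Read ripple events written by [write_ripples()]
#'
#' @param path file path.
#' @return A [ripple_events()] table.
#' @export
read_ripples <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ripple_events(df$onset_s, df$offset_s, df$peak_sd)
}

#' Write a ground-truth manifest as JSON
#'
#' Structured text manifest of a synthetic session's ground truth (ripple
#' intervals and planted causal pairs).
#'
#' @param truth the `truth` element of a [gen_rest_session()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    ripples = truth$ripples,
    planted_pairs = data.frame(
      unit_id = truth$planted_pairs$unit_id,
      ca3_time_s = truth$planted_pairs$ca3_time_s,
      ca1_time_s = truth$planted_pairs$ca1_time_s,
      ripple_index = truth$planted_pairs$ripple_index
    ),
    ca1_member_times_s = truth$planted_pairs$ca1_member_times_s
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a ground-truth manifest written by [write_ground_truth()]
#'
#' @param path file path.
#' @return A list with `ripples` and `planted_pairs` (including the
#'   `ca1_member_times_s` list column), as produced by [gen_rest_session()].
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ripples <- as.data.frame(obj$ripples)
  pairs <- as.data.frame(obj$planted_pairs)
  members <- lapply(obj$ca1_member_times_s, as.numeric)
  if (nrow(pairs)) pairs$ca1_member_times_s <- I(members) else {
    pairs$ca1_member_times_s <- I(list())
  }
  list(ripples = ripples, planted_pairs = pairs)
}

#' Write an EPSC series as delimited text
#'
#' Tab-separated `sweep_time_s`, `amplitude_pa` (and `series_resistance_mohm`
#' when present), with pathway and induction marker in the comment header.
#'
#' @param series an [epsc_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_epsc <- function(series, path) {
  stopifnot(inherits(series, "epsc_series"))
  has_rs <- !is.null(series$series_resistance_mohm)
  hdr <- c(
    sprintf("# pathway=%s", series$pathway),
    sprintf("# induction_time_s=%s",
            if (is.na(series$induction_time_s)) "NA" else fmt17(series$induction_time_s))
  )
  cols <- c("sweep_time_s", "amplitude_pa", if (has_rs) "series_resistance_mohm")
  rows <- if (has_rs) {
    sprintf("%s\t%s\t%s", fmt17(series$sweep_times_s),
            fmt17(series$amplitudes_pa), fmt17(series$series_resistance_mohm))
  } else {
    sprintf("%s\t%s", fmt17(series$sweep_times_s), fmt17(series$amplitudes_pa))
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read an EPSC series written by [write_epsc()]
#'
#' @param path file path.
#' @return An [epsc_series()].
#' @export
read_epsc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(key) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    sub(sprintf("^# %s=", key), "", m[1L])
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  ind <- get_hdr("induction_time_s")
  epsc_series(
    df$sweep_time_s, df$amplitude_pa,
    pathway = get_hdr("pathway"),
    induction_time_s = if (is.na(ind) || ind == "NA") NA_real_ else as.numeric(ind),
    series_resistance_mohm = df$series_resistance_mohm
  )
}

#' Write classified causal pair events as delimited text
#'
#' Tab-separated `ca3_time_s`, `ca1_time_s`, `lag_ms`, `ripple_index`, `phase`,
#' `is_burst`, plus a comma-joined `ca1_member_times_s` column.
#'
#' @param found a `causal_pair_events` table from [classify_pairs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pair_events <- function(found, path) {
  stopifnot(inherits(found, "causal_pair_events"))
  members <- vapply(
    found$ca1_member_times_s,
    function(m) paste(fmt17(m), collapse = ","), character(1)
  )
  if (nrow(found) == 0L) members <- character(0)
  writeLines(
    c(
      "ca3_time_s\tca1_time_s\tlag_ms\tripple_index\tphase\tis_burst\tca1_member_times_s",
      sprintf("%s\t%s\t%s\t%d\t%s\t%s\t%s",
              fmt17(found$ca3_time_s), fmt17(found$ca1_time_s),
              fmt17(found$lag_ms), found$ripple_index, fmt17(found$phase),
              found$is_burst, members)
    ),
    path
  )
  invisible(path)
}
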