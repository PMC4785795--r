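test_that("rest-session generator is deterministic and honors degenerate configs", {
  cfg <- synth_config(seed = 7, duration_s = 30, ripple_rate_hz = 0.3,
                      planted_pairs_per_train = rep(1L, 4))
  a <- gen_rest_session(cfg)
  b <- gen_rest_session(cfg)
  expect_identical(a$lfp$samples, b$lfp$samples)
  expect_identical(
    lapply(a$trains, `[[`, "times_s"),
    lapply(b$trains, `[[`, "times_s")
  )
  expect_identical(a$truth$ripples, b$truth$ripples)

  silent <- gen_rest_session(synth_config(
    seed = 1, duration_s = 10, ripple_rate_hz = 0, baseline_rate_hz = 0,
    planted_pairs_per_train = rep(0L, 4)
  ))
  expect_equal(nrow(silent$truth$ripples), 0)
  expect_true(all(vapply(silent$trains, function(tr) length(tr$times_s), numeric(1)) == 0))
})

test_that("over-constrained pair requests are rejected", {
  cfg <- synth_config(seed = 3, duration_s = 15, ripple_rate_hz = 0.19,
                      planted_pairs_per_train = rep(10L, 4))
  expect_error(gen_rest_session(cfg), "over-constrained")
})

test_that("planted pairs are recovered exactly by the classifier when background is silent", {
  cfg <- synth_config(seed = 21, duration_s = 120, ripple_rate_hz = 0.4,
                      baseline_rate_hz = 0,
                      planted_pairs_per_train = c(5L, 0L, 3L, 2L))
  ses <- gen_rest_session(cfg)
  ev <- ripple_events(ses$truth$ripples$onset_s, ses$truth$ripples$offset_s)
  for (u in seq_len(4)) {
    ca1 <- ses$trains[[1 + u]]
    found <- classify_pairs(ses$trains[[1]], ca1, ev)
    mine <- ses$truth$planted_pairs[ses$truth$planted_pairs$unit_id == ca1$unit_id, ]
    expect_equal(nrow(found), nrow(mine))
    expect_equal(sort(found$ca3_time_s), sort(mine$ca3_time_s))
    expect_equal(sort(found$ca1_time_s), sort(mine$ca1_time_s))
  }
})

test_that("planted ripples carry excess ripple-band envelope power", {
  cfg <- synth_config(seed = 5, duration_s = 200, ripple_rate_hz = 0.2,
                      ripple_snr = 8)
  ses <- gen_rest_session(cfg)
  env <- lfp_envelope(bandpass_lfp(ses$lfp, c(120, 250)), 12)$samples
  tt <- ses$lfp$t0_s + (seq_along(env) - 1) / ses$lfp$rate_hz
  gt <- ses$truth$ripples
  inside <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(gt))) {
    inside <- inside | (tt >= gt$onset_s[i] & tt <= gt$offset_s[i])
  }
  excess <- (mean(env[inside]) - mean(env[!inside])) / sd(env[!inside])
  expect_gte(excess, cfg$ripple_snr / 2)
})

test_that("track sessions recover the planted place field and differ across seeds", {
  base <- list(duration_s = 600, n_ca3 = 1L, n_ca1 = 1L,
               planted_pairs_per_train = 0L,
               field_centers_cm = c(100, 100), field_sigma_cm = 10)
  s1 <- gen_track_session(do.call(synth_config, c(list(seed = 1), base)))
  s2 <- gen_track_session(do.call(synth_config, c(list(seed = 2), base)))
  for (s in list(s1, s2)) {
    rm_ <- rate_map(s$trains[[1]], s$trajectory)
    peak_bin <- which.max(rm_$rate_hz)
    # argmax bin contains (or abuts) the planted 100 cm center
    expect_true(rm_$bin_edges_cm[peak_bin] %in% c(90, 100))
  }
  expect_false(length(s1$trains[[1]]$times_s) == length(s2$trains[[1]]$times_s))

  quiet <- gen_track_session(do.call(
    synth_config, c(list(seed = 1), modifyList(base, list(field_peak_hz = 0, field_baseline_hz = 0)))
  ))
  expect_length(quiet$trains[[1]]$times_s, 0)
})

test_that("EPSC generator hits the planted potentiation factor", {
  flat <- gen_epsc_series(true_factor = 1, noise_cv = 0, seed = 1)
  expect_true(all(abs(flat$amplitudes_pa - flat$amplitudes_pa[1]) < 1e-12))

  clean <- gen_epsc_series(true_factor = 2, noise_cv = 0, seed = 1)
  norm <- normalize_to_baseline(minute_average(clean))
  final <- window_mean_of(norm, c(25, 30))
  expect_lt(abs(final - 2), 0.02)   # sigmoid saturation tolerance < 1 %

  est <- vapply(1:50, function(s) {
    ser <- gen_epsc_series(true_factor = 2, noise_cv = 0.2, seed = s)
    window_mean_of(normalize_to_baseline(minute_average(ser)), c(25, 30))
  }, numeric(1))
  expect_lt(abs(mean(est) - 2), 0.05)
})
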