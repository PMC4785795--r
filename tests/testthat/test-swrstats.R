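test_that("spikes per SWR summarizes per-event counts", {
  ev <- ripple_events(c(1, 2, 3, 4), c(1.1, 2.1, 3.1, 4.1))
  none <- spikes_per_swr(spike_train(numeric(0), "u", "CA1"), ev)
  expect_equal(none$median, 0)
  expect_true(all(none$counts == 0))

  one_each <- spikes_per_swr(spike_train(c(1.05, 2.05, 3.05, 4.05), "u", "CA1"), ev)
  expect_equal(one_each$mean, 1)

  expect_error(spikes_per_swr(spike_train(1, "u", "CA1"), ripple_events()),
               "no events")

  # planted 0.45 spikes/event mean recovered within 10 % over 500 events
  set.seed(1)
  onsets <- seq(1, by = 0.5, length.out = 500)
  ev500 <- ripple_events(onsets, onsets + 0.1)
  counts <- rpois(500, 0.45)
  spikes <- unlist(lapply(seq_len(500), function(i) {
    if (counts[i] == 0) return(numeric(0))
    onsets[i] + sort(runif(counts[i], 0, 0.1))
  }))
  got <- spikes_per_swr(spike_train(spikes, "u", "CA3"), ev500)
  expect_lt(abs(got$mean - 0.45) / 0.45, 0.1)
})

test_that("peri-SWR histograms recover planted timing structure", {
  onsets <- seq(1, by = 1, length.out = 200)
  ev <- ripple_events(onsets, onsets + 0.08)

  # CA3 fires at onset, CA1 12 ms later: CA3 peak precedes CA1 peak by 10-20 ms
  ca3 <- spike_train(onsets, "CA3a", "CA3")
  ca1 <- spike_train(onsets + 0.012, "CA1b", "CA1")
  ps <- peri_swr_psth(list(ca3, ca1), ev, window_s = c(-0.05, 0.1), bin_s = 0.005)
  ctr <- function(p) {
    e <- p$bin_edges_s
    (e[which.max(p$rate_hz)] + e[which.max(p$rate_hz) + 1]) / 2
  }
  lead <- (ctr(ps$CA1) - ctr(ps$CA3)) * 1000
  expect_gte(lead, 10 - 1e-6)
  expect_lte(lead, 20 + 1e-6)

  # homogeneous Poisson -> flat PSTH at the Poisson rate (+/- 3 SE per bin)
  set.seed(3)
  rate <- 5
  pois <- spike_train(sort(runif(rate * 220, 0, 220)), "u", "CA1")
  psf <- peri_swr_psth(list(pois), ev, window_s = c(-0.2, 0.2), bin_s = 0.02)$CA1
  se <- sqrt(rate / (200 * 0.02))
  expect_true(all(abs(psf$rate_hz - rate) <= 3 * se))

  # conservation: integral of PSTH over the window = mean spikes/event/unit
  total <- sum(psf$rate_hz) * 0.02
  direct <- mean(vapply(onsets, function(o) {
    sum(pois$times_s >= o - 0.2 & pois$times_s < o + 0.2)
  }, numeric(1)))
  expect_equal(total, direct, tolerance = 1e-10)

  silent <- peri_swr_psth(list(spike_train(numeric(0), "u", "CA1")), ev)$CA1
  expect_true(all(silent$rate_hz == 0))
})

test_that("coactivity counts active units per bin", {
  quiet <- coactivity(list(spike_train(numeric(0), "a", "CA1"),
                           spike_train(numeric(0), "b", "CA1")),
                      t_range = c(0, 5))
  expect_true(all(quiet$n_active == 0))

  # five units firing in every 1 s bin -> constant 5
  busy <- lapply(1:5, function(i) {
    spike_train(seq(0.1, 9.9, by = 0.5) + i * 0.01, paste0("u", i), "CA1")
  })
  expect_true(all(coactivity(busy, t_range = c(0, 9))$n_active == 5))

  # staggered schedule: unit i fires only in bin i
  stag <- lapply(1:3, function(i) {
    spike_train(i - 0.5, paste0("u", i), "CA1")
  })
  cc <- coactivity(stag, t_range = c(0, 2))
  expect_equal(cc$n_active[1:3], c(1, 1, 1))
})

test_that("SWR-restricted cross-correlogram matches construction and the brute-force oracle", {
  onsets <- seq(1, by = 1, length.out = 50)
  ev <- ripple_events(onsets, onsets + 0.1)

  # CA1 = CA3 shifted +5 ms, all inside events -> all mass in the [0,10) bin
  ca3 <- spike_train(onsets + 0.02, "CA3a", "CA3")
  ca1 <- spike_train(onsets + 0.025, "CA1b", "CA1")
  cc <- swr_crosscorr(ca3, ca1, ev)
  hot <- which(cc$counts > 0)
  expect_length(hot, 1)
  expect_equal(cc$lag_bin_edges_ms[hot], 0)  # bin [0, 10) holds lag +5 ms
  expect_equal(cc$n_ca1_in_swr, 50)
  expect_equal(sum(cc$normalized_counts), 50 / 50)

  # unnormalized bin sums equal the O(n^2) oracle on random trains
  for (seed in 1:5) {
    s <- random_session(seed, max_spikes = 60)
    got <- swr_crosscorr(s$ca3, s$ca1, s$ev, restrict_s = c(-1e6, 1e6),
                         normalizer = "restrict_window")
    expect_equal(got$counts,
                 oracle_crosscorr_counts(s$ca3$times_s, s$ca1$times_s))
    # antisymmetry of construction before normalization
    rev <- swr_crosscorr(s$ca1, s$ca3, s$ev, restrict_s = c(-1e6, 1e6),
                         normalizer = "restrict_window")
    expect_equal(got$counts, base::rev(rev$counts))
  }

  # independent Poisson trains -> flat correlogram (+/- 3 SE)
  set.seed(8)
  p3 <- spike_train(sort(runif(2000, 0, 200)), "CA3a", "CA3")
  p1 <- spike_train(sort(runif(2000, 0, 200)), "CA1b", "CA1")
  evl <- ripple_events(seq(1, 199), seq(1, 199) + 0.5)
  flat <- swr_crosscorr(p3, p1, evl, restrict_s = c(-0.25, 0.25))
  m <- mean(flat$counts)
  expect_true(all(abs(flat$counts - m) <= 3 * sqrt(m)))
})
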