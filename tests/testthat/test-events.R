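test_that("burst detection follows the ISI rule and matches the run-length oracle", {
  t_ms <- function(x) x / 1000
  b <- detect_bursts(spike_train(t_ms(c(0, 5, 8)), "u", "CA1"), 10)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 3)
  expect_equal(b$onset_s, 0)

  none <- detect_bursts(spike_train(t_ms(c(0, 50, 100)), "u", "CA1"), 10)
  expect_equal(nrow(none), 0)

  for (seed in 1:20) {
    set.seed(seed)
    tr <- spike_train(cumsum(rexp(80, 1 / 0.012)), "u", "CA1")
    got <- detect_bursts(tr, 10)
    ora <- oracle_bursts(tr$times_s, 10)
    expect_equal(nrow(got), length(ora))
    expect_equal(got$member_times_s, I(ora))
  }
})

test_that("the causal-pair rule is applied with strict boundaries", {
  ev <- ripple_events(0, 0.1)
  cfg <- event_rule_config()

  # CA3 at onset, CA1 10 ms later -> one event, lag 10 ms, phase 0
  f <- classify_pairs(spike_train(0, "a", "CA3"), spike_train(0.01, "b", "CA1"),
                      ev, cfg)
  expect_equal(nrow(f), 1)
  expect_equal(f$lag_ms, 10)
  expect_equal(f$phase, 0)
  expect_false(f$is_burst)

  # anti-causal: CA1 10 ms before CA3 -> nothing
  f2 <- classify_pairs(spike_train(0.02, "a", "CA3"),
                       spike_train(0.01, "b", "CA1"), ev, cfg)
  expect_equal(nrow(f2), 0)

  # lag exactly 30 ms is excluded (strictly less than 30 ms)
  f3 <- classify_pairs(spike_train(0, "a", "CA3"),
                       spike_train(0.03, "b", "CA1"), ev, cfg)
  expect_equal(nrow(f3), 0)

  # CA3 anchor outside the fractional window -> nothing
  f4 <- classify_pairs(spike_train(0.09, "a", "CA3"),
                       spike_train(0.095, "b", "CA1"), ev, cfg)
  expect_equal(nrow(f4), 0)

  # overlapping events are rejected
  bad <- structure(
    data.frame(onset_s = c(0, 0.05), offset_s = c(0.1, 0.15),
               peak_sd = c(6, 6), duration_s = c(0.1, 0.1)),
    class = c("ripple_events", "data.frame")
  )
  expect_error(
    classify_pairs(spike_train(0, "a", "CA3"), spike_train(0.01, "b", "CA1"),
                   bad, cfg),
    "overlap"
  )
})

test_that("greedy pairing consumes each CA1 spike/burst at most once", {
  ev <- ripple_events(0, 0.1)
  # two CA3 spikes, one CA1 spike: only the first CA3 spike pairs
  f <- classify_pairs(spike_train(c(0, 0.005), "a", "CA3"),
                      spike_train(0.02, "b", "CA1"), ev)
  expect_equal(nrow(f), 1)
  expect_equal(f$ca3_time_s, 0)

  # burst partner: both members belong to the event, anchored at burst onset
  fb <- classify_pairs(spike_train(0, "a", "CA3"),
                       spike_train(c(0.012, 0.018, 0.2), "b", "CA1"), ev)
  expect_equal(nrow(fb), 1)
  expect_true(fb$is_burst)
  expect_equal(fb$ca1_member_times_s[[1]], c(0.012, 0.018))

  # a burst straddling the lag boundary qualifies via its onset
  fs <- classify_pairs(spike_train(0, "a", "CA3"),
                       spike_train(c(0.028, 0.034), "b", "CA1"), ev)
  expect_equal(nrow(fs), 1)
  expect_equal(fs$lag_ms, 28)
})

test_that("classifier agrees exactly with the exhaustive oracle on random sessions", {
  cfg <- event_rule_config()
  for (seed in 1:100) {
    s <- random_session(seed)
    got <- classify_pairs(s$ca3, s$ca1, s$ev, cfg)
    ora <- oracle_classify(s$ca3$times_s, s$ca1$times_s, s$ev)
    expect_equal(got$ca3_time_s, ora$ca3, info = paste("seed", seed))
    expect_equal(got$ca1_time_s, ora$ca1, info = paste("seed", seed))
  }
})

test_that("event count grows monotonically with lag and window fractions", {
  s <- random_session(424242, max_spikes = 150)
  n_lag <- vapply(c(5, 10, 20, 30, 50), function(l) {
    nrow(classify_pairs(s$ca3, s$ca1, s$ev, event_rule_config(max_lag_ms = l)))
  }, numeric(1))
  expect_true(all(diff(n_lag) >= 0))
  n_win <- vapply(c(0, 0.2, 0.4, 0.6, 1), function(w) {
    nrow(classify_pairs(s$ca3, s$ca1, s$ev,
                        event_rule_config(pre_frac = w / 2, post_frac = w)))
  }, numeric(1))
  expect_true(all(diff(n_win) >= 0))
})

test_that("predictor counts separate pairs, burst pairs and total CA1 spikes", {
  ev <- ripple_events(c(1, 2, 3), c(1.1, 2.1, 3.1))
  none <- count_predictors(spike_train(numeric(0), "a", "CA3"),
                           spike_train(numeric(0), "b", "CA1"), ev)
  expect_equal(none$n_pairs, 0)
  expect_equal(none$n_ca3_burst_pairs, 0)
  expect_equal(none$n_ca1_spikes, 0)

  # single-spike partners: burst-pair count stays zero
  ca3 <- spike_train(c(1.01, 2.01, 3.01), "a", "CA3")
  ca1 <- spike_train(c(1.02, 2.02, 3.02, 5), "b", "CA1")
  got <- count_predictors(ca3, ca1, ev)
  expect_equal(got$n_pairs, 3)
  expect_equal(got$n_ca3_burst_pairs, 0)
  expect_equal(got$n_ca1_spikes, 4)

  # burst partners: every pair is a burst pair
  ca1b <- spike_train(c(1.02, 1.026, 2.02, 2.026), "b", "CA1")
  gotb <- count_predictors(ca3, ca1b, ev)
  expect_equal(gotb$n_pairs, 2)
  expect_equal(gotb$n_ca3_burst_pairs, 2)
  # unrestricted variant sees the same bursts regardless of SWR windows
  expect_gte(gotb$n_ca3_burst_pairs_unrestricted, 2)
})

test_that("event-spike removal and isolation mirror the editing experiments", {
  fx <- make_editing_fixture()
  found <- classify_pairs(fx$ca3, fx$ca1, fx$ev)
  expect_equal(nrow(found), fx$n_events)
  expect_equal(length(unlist(found$ca1_member_times_s)), fx$n_member_spikes)

  # necessity: removing the member spikes leaves nothing to classify
  pruned <- remove_event_spikes(fx$ca1, found)
  expect_equal(length(pruned$times_s),
               length(fx$ca1$times_s) - fx$n_member_spikes)
  expect_equal(nrow(classify_pairs(fx$ca3, pruned, fx$ev)), 0)

  # identity on an empty event list
  same <- remove_event_spikes(fx$ca1, classify_pairs(
    fx$ca3, spike_train(numeric(0), "b", "CA1"), fx$ev
  ))
  expect_equal(same$times_s, fx$ca1$times_s)

  # sufficiency: isolation retains exactly the event spikes and re-classifies
  iso <- isolate_events(fx$ca3, fx$ca1, found)
  expect_equal(length(iso$ca3$times_s) + length(iso$ca1$times_s),
               sum(1 + vapply(found$ca1_member_times_s, length, numeric(1))))
  again <- classify_pairs(iso$ca3, iso$ca1, fx$ev)
  expect_equal(nrow(again), fx$n_events)
  expect_equal(sort(again$ca3_time_s), sort(found$ca3_time_s))

  # stale event lists are rejected
  expect_error(remove_event_spikes(spike_train(99, "b", "CA1"), found), "stale")
})

test_that("classification is idempotent under isolation on random sessions", {
  n_nonempty <- 0L
  for (seed in 1:20) {
    s <- random_session(seed)
    found <- classify_pairs(s$ca3, s$ca1, s$ev)
    if (nrow(found) == 0) next
    n_nonempty <- n_nonempty + 1L
    iso <- isolate_events(s$ca3, s$ca1, found)
    again <- classify_pairs(iso$ca3, iso$ca1, s$ev)
    expect_equal(again$ca3_time_s, found$ca3_time_s)
    expect_equal(again$ca1_time_s, found$ca1_time_s)
  }
  expect_gt(n_nonempty, 0)
})
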