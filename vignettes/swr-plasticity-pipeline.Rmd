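---
title: "From sharp-wave ripples to synaptic plasticity: the swrtools pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sharp-wave ripples to synaptic plasticity: the swrtools pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swrtools)
```

## The scientific problem

During quiet rest and sleep, hippocampal place cells re-express ("replay")
firing sequences from recent behavior inside sharp-wave ripples (SWRs) —
transient 120–250 Hz oscillations of the CA1 local field potential. Replayed
CA3→CA1 spike patterns are temporally compressed enough to engage
spike-timing-dependent plasticity (STDP) at Schaffer-collateral synapses, and
experiments that replay recorded spike trains onto hippocampal slices show
that such patterns can induce long-term potentiation (LTP) — but only when
accompanied by SWR-associated synaptic input, and only when causal CA3→CA1
spike pairs fall near ripple onset. The unit of timing that predicts LTP is a
*causal pair*: a CA3 spike followed by a CA1 spike or burst less than 30 ms
later, occurring in a window from 30% of the SWR's duration before onset to
60% of its duration after onset. The number of such pairs in an induction
protocol correlates strongly with the synaptic change it produces, while
plausible alternatives (CA3→CA1-burst counts, total CA1 spikes) do not.

`swrtools` implements the full analysis chain behind that result: ripple
detection, place-field mapping, SWR-conditioned spike statistics, the
causal-pair classifier with its spike-train editing operations, stimulation
protocol construction, and plasticity quantification — plus a synthetic-data
generator that produces ground-truth-labeled sessions with the statistical
structure the analysis assumes, so every stage is testable without recorded
data.

## Ripple detection

The detector follows the standard offline procedure: band-pass the LFP at
120–250 Hz (4th-order Butterworth, applied forward–backward so event times are
not biased by filter delay), take the analytic-signal magnitude as the
instantaneous ripple-power envelope, smooth it with a Gaussian kernel, and
z-score it. Excursions above `detect_sd = 5` SDs become events; each event's
onset and offset are the nearest surrounding crossings of `bound_sd = 2` SDs,
located with sub-sample linear interpolation. Events closer than 20 ms are
merged and events shorter than 20 ms dropped (both configurable; neither value
is standardized in the field, so both are echoed into output headers).

Three numerical choices deserve explanation:

* **Baseline statistics** (`sd_estimate`). The envelope mean and SD should
  describe the ripple-free background. With ripples occupying even ~2% of a
  trace at 8 SDs, trace-wide statistics inflate the SD by ~20%, deflating
  every z-score and costing substantial recall at a 5 SD criterion. The
  default is therefore an iterative estimate: a first global pass flags
  samples above `bound_sd`, and the statistics are re-estimated from the
  remaining ripple-free segments. A single-pass `"global"` option is kept for
  comparison.
* **Envelope smoothing** (`smooth_ms`, Gaussian SD, default 12 ms). Smoothing
  prevents intra-ripple envelope troughs from splitting one physiological
  event into several. The specific width was calibrated on synthetic sessions
  with known onsets: at light smoothing the 2 SD crossing lands systematically
  *inside* the ripple (at a peak z of 8 the envelope near the true onset sits
  around z ≈ 1, below the bound), while heavy smoothing widens the envelope
  and pulls the crossing early, losing recall on short events. 12 ms zeroes
  the median onset bias at realistic ripple durations (40–80 ms); the residual
  error is a duration-dependent ±3–5 ms that is inherent to a fixed-threshold
  boundary rule.
* **Envelope vs squared power.** Whether the SD criterion applies to the
  envelope or its square is a free choice in the procedure's usual
  description; the envelope is used here (the squared statistic compresses
  low amplitudes and changes nothing qualitatively), and the detection
  statistic is exposed by `lfp_envelope()` so either convention can be built.

`offset_ripples()` shifts detected events rigidly in time (e.g. −100 ms), the
manipulation used to probe how tightly causal pairs are yoked to ripple onset.

## The causal-pair classifier

`classify_pairs()` applies the event rule with explicit conventions where the
verbal rule is silent:

* **Anchor.** The CA3 (presynaptic) spike time is tested against the
  fractional window `[onset − 0.3·dur, onset + 0.6·dur]` (closed on both
  ends); the window anchor is configurable to the CA1 side since the rule's
  wording does not name it.
* **Bursts.** A CA1 burst is a maximal run of ≥ 2 spikes with inter-spike
  intervals ≤ 10 ms (`detect_bursts()`); CA1 complex-spike bursts have 3–10 ms
  ISIs, and the threshold is configurable. A burst acts as a single pairing
  unit anchored at its onset, so a burst straddling the 30 ms lag boundary
  still qualifies if its onset is inside.
* **Tie-breaking.** Pairing is greedy left-to-right: CA3 spikes are processed
  in time order and each takes the earliest unconsumed CA1 spike/burst
  strictly within (0, 30) ms. Each CA1 unit is consumed by at most one event
  and each CA3 spike produces at most one event, which prevents one CA1 spike
  from being counted against several CA3 spikes. The test suite validates the
  scanning implementation against an exhaustive O(n²) oracle implementing the
  same policy on hundreds of random sessions.
* **Boundaries.** The lag inequality is strict on both sides (a lag of
  exactly 30 ms does not qualify, nor does a simultaneous pair), matching the
  "less than 30 ms later" phrasing.

`remove_event_spikes()` and `isolate_events()` reproduce the two editing
manipulations used to test necessity and sufficiency: deleting exactly the CA1
spikes that constitute the classified events, or retaining only the CA3
anchors and CA1 members. Classification is idempotent under isolation.

`count_predictors()` returns the three candidate predictors of plasticity
(causal pairs, CA3→CA1-burst pairs, total CA1 spikes). Whether the burst-pair
count should be restricted to SWR windows is ambiguous, so both variants are
reported (`n_ca3_burst_pairs` and `n_ca3_burst_pairs_unrestricted`).

## Place maps and SWR spike statistics

`rate_map()` divides the 200 cm track into 10 cm bins (the 10 cm lateral
dimension of the track collapses), interpolates position at spike times, and
reports occupancy-normalized rates — the field-standard normalization; bins the
animal never visited are `NA`, not zero. Trajectory gaps > 0.5 s are excluded
from occupancy. `trial_raster()` segments the trajectory into monotone
traversals covering ≥ 80% of the track (turning points found with a 5 cm
displacement hysteresis on a lightly smoothed copy of the position, so
per-sample tracking jitter cannot fake a turn) and reports per-trial spike
positions, including spike-free trials.

`swr_crosscorr()` computes the SWR-restricted CA3×CA1 cross-correlogram: only
spikes from 50 ms before to 150 ms after a ripple onset enter (both trains by
default, configurable to CA1 only); CA1−CA3 lags are histogrammed at 10 ms
pitch over ±100 ms with half-open bins `[lo, hi)`; and counts are normalized
by the number of CA1 spikes inside SWR event intervals (configurable to the
restriction window instead, since per-cell normalizers from the original
recordings cannot be reproduced). Positive lag always means CA1 after CA3.
`peri_swr_psth()`, `coactivity()` and `spikes_per_swr()` follow the obvious
definitions; all histogram operations are checked against brute-force
double-loop oracles.

## Stimulation protocols

`build_replay_protocol()` turns a rest epoch (default 300 s, the first 5 min
of post-run rest) into a three-channel schedule: test-pathway EPSP stimulation
at CA3 spike times, 2 ms / 2 nA somatic pulses at CA1 spike times, and
five-pulse 100 Hz trains on an independent ripple pathway at SWR onset times.
Modes `"without"` and `"offset_100ms_early"` drop or shift the ripple channel
only. `build_pairing_protocol()` builds the artificial timed-pairing variants:
300 repetitions at 5 Hz of one EPSP followed 10 ms later by one AP, delivered
alone, 13 ms after an SWR-train onset, 53 ms after it, or as EPSP-only.
`sine_wave_command()` renders the somatic SWR surrogate: one full sine cycle
per event, frequency scaled to the event's duration, peak and valley at
±100 pA ("one full cycle" is the reading of a sine whose peak *and* valley
both occur within the event; the cycle count is configurable). Schedules are
event lists written as plain text with 17 significant digits, so files
round-trip bit-exactly; waveforms are sampled at 10 kHz by default. The
constant −60 mV holding variant is a protocol metadata flag, not a waveform.
Whether the in vitro replay compressed the 300 s epoch is unstated in the
procedure being modeled; protocols preserve absolute in vivo times.

## Plasticity quantification

EPSC sweep series (0.1 Hz per pathway) pass series-resistance QC (> 20% change
from the initial value discards the cell; the boundary itself passes), are
averaged six sweeps to one point per minute (partial trailing groups dropped),
and normalized to the mean of the 5 min baseline before the induction marker —
which is explicit series metadata, never inferred from the data.
`compare_pathways()` computes each experiment's mean normalized response in
the 25–30 min post-induction window, runs a paired two-tailed t-test across
experiments (biological replicates, matching the "n =" usage per condition),
and reports the relative change in synaptic strength: mean test minus mean
control over the final 5 min. The "final 5 min" and the 25–30 min comparison
window are treated as the same (configurable) window. When all paired
differences are exactly zero the t statistic is undefined and p is reported
as 1. `correlate_predictor()` is an ordinary least-squares fit of relative
change on a predictor count, reporting r²; it fits whatever (change, count)
pairs it is given and reports n alongside.

## The synthetic-data generator

`gen_rest_session()` emulates a rest epoch: pink (1/f) background noise — the
default, because SD-threshold detection behavior depends on the background
spectrum and 1/f is closer to hippocampal LFP than white noise (a config
switch) — plus Gaussian-windowed `ripple_freq_hz` oscillations at known times.
The Gaussian envelope SD is duration/4, so the nominal onset/offset sit at the
window's 2σ points; nominal times are stored as ground truth. Ripple intervals
are non-overlapping with a 100 ms minimum gap, drawn either as a thinned
Poisson process (default) or on a jittered grid when a deterministic event
count is needed. `ripple_snr` is defined as the peak of the *smoothed*
detection-statistic envelope in SDs above the background envelope mean
(reference kernel `snr_ref_smooth_ms`, matching the detector default), i.e.
the peak detection z-score of a planted ripple; the injected amplitude
compensates the duration-dependent smoothing attenuation so an SNR-8 ripple
detects at z ≈ 8 whether it lasts 40 or 80 ms.

Spike trains are Poisson at `baseline_rate_hz` outside ripples and
`baseline_rate_hz · (1 + swr_gain)` inside (the multiplicative reactivation
gain means a silent-background configuration is silent everywhere, which keeps
the plant-and-recover contract exact). Causal pairs are planted by inserting a
CA3 spike at a configured phase of a ripple and its CA1 partner (spike or
short burst) at a configured lag strictly inside (0, 30) ms; each pair
occupies its own ripple, and configurations requesting more pairs than there
are ripples are rejected as over-constrained. With `baseline_rate_hz = 0` the
classifier provably returns exactly the planted set. All generators derive
per-stream sub-seeds deterministically from one master seed, so identical
configs give bit-identical sessions.

Default conditions were chosen once as a realistic rest session: 2 kHz LFP,
0.19 ripples/s (a 300 s epoch then contains ~57 SWRs), 150 Hz ripple
frequency, 40–80 ms durations, SNR 8, one CA3 and four CA1 units, 0.5 Hz
baseline with a 10× in-ripple gain, two planted pairs per CA1 train. These put
mean spikes/SWR in the 0.2–0.5 range typical of place cells during rest;
matching any particular recording's medians exactly is not a goal.

`gen_track_session()` produces a constant-speed back-and-forth trajectory on
the 200 cm track (sampled at 50 Hz with 1 cm tracking jitter) and place-cell
trains as inhomogeneous Poisson processes with Gaussian place fields
(configurable centers, σ = 15 cm, 10 Hz peak over a 0.1 Hz floor). The field
and trajectory parameters are generator additions — the rest-session
configuration does not constrain them — with defaults spreading fields evenly
along the track. `gen_epsc_series()` produces sweep series whose post-induction
mean rises sigmoidally (logistic midpoint 10 min, time constant 2 min —
saturating to within 0.1% by 25 min, consistent with LTP that develops slowly
and lacks a short-term facilitatory component) toward `true_factor` × baseline,
with multiplicative Gaussian sweep noise of a given coefficient of variation.

**What the generator does not emulate** — and therefore what passing tests do
not show about real data: no replay sequence content (only pair timing), no
spike-sorting errors or unit contamination, no non-stationary ripple rates or
amplitudes, no sharp-wave (stratum radiatum) component, no theta or movement
epochs, no biophysics (membrane potentials, short-term plasticity, failures).
Detector and classifier performance on these sessions bound what the
*algorithms* do under the stated statistical assumptions, not what any
recording system delivers.

## Verification problem sizes

The test suite validates the detector on 200 s sessions at 0.4 events/s and
SNR 8 (recall and precision ≥ 0.9, median onset error ≤ 5 ms); the classifier
against the exhaustive oracle on 500 random sessions; the editing operations
on a constructed 8-event/10-spike train; the −100 ms offset manipulation on
early-phase pairs (≥ 80% event loss); and the end-to-end count→plasticity
recovery on 100 repeats of 8 protocols (40 s sessions, planted counts 0–8,
outcome 0.25·count + N(0, 0.2²), giving an analytic R² of
`b²Sxx / (b²Sxx + (n−1)σ²) ≈ 0.93`). `scripts/acceptance.R` recomputes the
same quantities from scratch at a caller-supplied seed.

## Known limitations

* The 2 SD boundary rule has an irreducible duration-dependent onset error of
  a few ms at moderate SNR (analysis above); studies needing sharper onsets
  use the ripple-band trough nearest the crossing, which is out of scope here.
* The classifier assumes non-overlapping ripples (enforced upstream by
  merging) and errors otherwise rather than guessing a phase.
* `compare_pathways()` requires equal numbers of test and control experiments
  (paired design); unpaired designs are out of scope.
* Rate maps are one-dimensional; open-field (2-D) mapping is not implemented.
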