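---
title: "Methods: timing metrics, signal parsing and the corruption-impact simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing metrics, signal parsing and the corruption-impact simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventqa)
```

## Scope and model of the problem

An event-based experiment presents stimuli at prespecified times and
records responses. Three clocks are involved: the plan, the physical
realization of each event (what actually appeared on the screen or was
pressed), and the log written by the experimental software. `eventqa`
treats the physical record -- a photodiode taped to a test square on the
screen, a contact microphone next to the response keys, a peripheral
trigger stream -- as ground truth, and quantifies how the log and the
triggers deviate from it. Two failure modes are distinguished throughout:

* **delay** -- a constant shift between a physical event and its
  timestamp. Correctable after the fact, but it must be measured.
* **jitter** -- a trial-varying shift. Not correctable by shifting, so
  its spread is the quantity to report.

All computation is carried in seconds; reports print milliseconds. The
single conversion point (`format_ms()`) is deliberate: mixed second/
millisecond arithmetic is the most common class of bug in timing code.

## Signal parsing

Photodiode traces are parsed with the classic threshold pipeline:
binarize (sample >= threshold becomes 1), discrete difference, and a
transition is stamped at the first sample of the new state, at
`start_time + n/fs`. The automatic threshold is the midpoint of the 1st
and 99th trace percentiles: a robust mid-range that ignores occasional
outlier samples. Two numerical choices deserve a note:

* **Refractory handling.** `detect_transitions()` keeps every transition
  by default; the photodiode wrapper `parse_photodiode()` discards
  transitions closer than 2 samples to the previous accepted one, which
  suppresses threshold chatter without touching real flashes (the
  shortest flash a display can produce is one frame, ~16.7 ms, orders of
  magnitude above 2 samples at any reasonable sampling rate). Accepted
  transitions must alternate polarity, so chatter inside a pulse cannot
  fabricate events.
* **Audio envelopes are sparse.** Key presses occupy well under 1% of a
  recording, so a 99th-percentile threshold would sit in the noise
  floor. `extract_audio_onsets()` instead thresholds a short (2 ms)
  trailing moving-average envelope at the midpoint between its 1st
  percentile and its maximum, and applies the refractory (default 50 ms)
  to press onsets only -- a multi-peak burst is one press. The trailing
  window biases detected onsets late by under a millisecond at the
  default settings, which is inside every tolerance used here.

Under the recommended flash scheme the test square flashes at each event
onset *and* offset, so n logged events must yield exactly 2n pulses.
Count mismatches are hard errors, not repairs: they indicate signal
quality problems that need intervention, and the error message localizes
the first interval at which the detected and expected pulse trains
diverge.

## Timing metrics and sign conventions

For event streams recorded on different clocks the package compares
*intervals*: with physical onsets `t_phys` and logged onsets `t_log`,
the per-event discrepancy is

    delta_i = (t_phys[i+1] - t_phys[i]) - (t_log[i+1] - t_log[i])

This cancels any constant clock offset exactly (a property the test
suite asserts to sub-nanosecond precision), isolating jitter; it is
blind to delays by construction. Delays are measured only when the two
streams share a clock, as the direct difference `t_phys[i] - t_trig[i]`.
A positive delay therefore means the physical event lags its timestamp,
which is the usual display-latency situation; fixture generators use the
same convention, so recovery round-trips are positive. A linear fit of
the timestamp differences against time is attached to delay series as a
drift diagnostic; no detrending is ever applied, since the interval
method is already robust to slow drift over the short spans between
successive events.

If per-event timing noise has standard deviation s on one stream, the
interval differences have standard deviation `s * sqrt(2)` (differences
of independent errors). The parameter-recovery tests use this law: a
fixture with 5 ms Gaussian logging jitter must yield an interval-series
SD of 7.07 ms within Monte-Carlo tolerance. Summaries report the mean,
the n-1 sample SD (0 with an explicit low-n flag when only one value
exists), and the maximum absolute deviation; a configurable threshold
(default 5 ms SD) separates "pass" from "warn", reflecting the
expectation that a well-calibrated setup shows means near zero and SDs
of a few milliseconds.

## Geometry

Stimulus size and eccentricity are converted to degrees of visual angle
with `theta = 2 * atan(size / 2 / distance)`; at 57.3 cm one centimeter
subtends one degree, which doubles as a test oracle. Pixel sizes are
converted through the screen's cm/px factor, computed independently from
the height and the width; disagreement beyond 2% warns, since on square
pixels the two must agree and inequality indicates a measurement error.
Off-center stimuli are treated with the small-tilt approximation (the
offset enters the same formula); no tilt correction is attempted, and
reports should label far-off-center measurements accordingly.

## Content and design validation

Content checks are exact: an annotation table (manual transcript or
fixture ground truth) keyed by `event_index` is compared field by field,
and every mismatch is localized to a row and field. Coverage is
reported per realized condition -- the full cross of the declared
factors -- with unrealized or untested combinations listed, since each
condition should be verified at least once. Response plans are compared
positionally; planned repeats that the log collapsed are flagged as
"missing repeat", extra log entries as "unexpected". Design rules are
declarative (balanced counts per combination, maximum run length,
per-block counts) and every deviation is a violation: the realized
sequence either implements the intended design or it does not.

## The corruption-impact simulator

The simulator answers a planning question: how much content or timing
corruption does it take to destroy a true effect of a given size? Two
single-trial measures are modeled, a P1 ERP amplitude and a reaction
time, each with a two-condition difference of standardized size theta
(Cohen's d of the uncorrupted measured variable). Corruption is either
*label shuffle* (a random subset of trials, 2-40% on the grid, has its
condition labels permuted within the subset, preserving the label
multiset) or *onset jitter* (a random subset gets a fixed-magnitude,
random-sign onset-logging error of 2-40 ms). Each grid cell is
summarized by the mean Welch t statistic across trials over many
replicates, and the *boundary* of a sweep column is the smallest grid
proportion at which that mean falls below t = 1.96.

### Trial models

A P1 trial is a waveform: Gaussian-bump components plus white sensor
noise at 1000 Hz on a -200..500 ms epoch, epoch-locked to the *logged*
onset. The measured amplitude is the mean over the 90-110 ms window
minus the mean over the -100..0 ms baseline. An onset logged late by
`e` samples the template at `t + e`: the P1 bump slides out of the
window and the adjacent negative component slides in, so jitter both
attenuates the condition difference and inflates the within-condition
variance. The condition difference rides on the P1 bump amplitude,
scaled so the measured amplitudes have Cohen's d exactly theta.

Because the measured amplitude is a linear functional of the epoch, its
distribution is known exactly: the template's discrete window mean plus
Gaussian noise with SD `noise_sd * sqrt(1/n_window + 1/n_baseline)`.
`run_sweep()` samples from that distribution directly instead of
materializing every epoch sample -- a distributional identity, not an
approximation, and the test suite checks the literal waveform route
against it (exact equality of the deterministic part at zero noise,
matching spread otherwise). This is what makes tens of thousands of
replicates per cell affordable on one CPU.

RT trials are normal with a standardized difference theta; a jittered
trial's measured RT inherits the onset-logging error, which adds
`proportion * magnitude^2` to the variance and leaves the mean
untouched. Real reaction times are right-skewed; normality is a
deliberate simplification -- the t statistic across hundreds of trials
is insensitive to it, and no claim rests on RT distribution shape.

### Calibration, frozen defaults, and what they mean

The corruption grid and threshold are fixed by design; the free
parameters -- trials per condition, the RT noise SD, and the ERP
template -- were tuned once, by `scripts/calibrate_simulation.R`, so the
simulator reproduces a reference sensitivity pattern at theta = 0.2:
shuffle abolishes the P1 effect at 20% of trials and the RT effect at
5%; a one-frame (16 ms) jitter abolishes both at 15%; a two-frame
(32 ms) jitter abolishes the P1 effect at 5%. The tuning is analytic
(closed-form mean-t under each corruption, including the small-sample
inflation of E[t]) followed by Monte-Carlo verification with the
package's own sweep engine, and the results are frozen in
`sim_config()`: 281 (P1) and 206 (RT) trials per condition, 20.4 ms RT
noise, and a template with a small P1 bump (1.65 uV, 6 ms width) next
to a large negative component (-18.2 uV at 160 ms, 27 ms width) under
10 uV per-sample noise.

Two structural facts about this calibration are worth understanding.
First, the uncorrupted mean t is `theta * sqrt(n/2)`, so the shuffle
boundary pins the trial count into a narrow window (for the RT boundary
at 5% the window is about +-1.5%); the jitter boundary then pins the
noise SD. The margins separating adjacent grid cells from the threshold
are correspondingly tight for the RT boundaries (~0.015 t units), which
is why boundary computations use large replicate counts (30-40k for RT,
8-12k for P1; Monte-Carlo SE of a mean t is about `1/sqrt(reps)`).
Second, the jitter-magnitude response of the P1 boundary is governed by
how fast the template's window mean falls off with shift, which is why
the negative component's position and width are calibration parameters
rather than aesthetic choices. A consequence the user should know: with
a variance-inflation RT model, a 32 ms jitter on 5% of trials cannot
abolish a theta = 0.5 RT effect under any noise SD compatible with the
16 ms boundary at theta = 0.2 -- larger effects survive small jittered
fractions; only content errors or much larger jittered fractions
destroy them.

What the simulator does *not* model: trial-to-trial amplitude
variability beyond sensor noise, autocorrelated EEG background, skewed
RTs, response omissions. Passing sweeps therefore demonstrate the
sensitivity of the *t statistic* to the modeled corruptions, not a
full electrophysiological forward model.

### Null behavior

At theta = 0 the replicate distribution of t has mean ~0 and SD ~1 for
every corruption level -- corruptions must never manufacture an effect.
The suite asserts this, along with the monotone attenuation of the mean
t in the shuffle proportion (expected attenuation exactly `1 - p`) and
the analytic baseline `theta * sqrt(n/2)` within 5%.

## Synthetic fixtures and what passing tests show

Every metric in the package is validated by parameter recovery on
synthetic experiments: `generate_experiment()` builds the physical
timeline and the log with known injected corruption (constant delay,
Gaussian jitter, fixed-magnitude jitter on a subset, dropped events,
mislabeled rows), and returns the realized draws so tests can compare
estimates against the exact injected values. The synthetic photodiode
is an ideal rectangular pulse train plus Gaussian noise; the synthetic
keypress audio is a white-noise burst on a noise floor. Real signals
add ramps, bleed, mains hum and keyboard acoustics that these fixtures
do not emulate, so passing recovery tests certify the *pipeline
mathematics* (thresholding, localization, interval algebra, statistics),
not robustness to every pathological recording. The auto-threshold is
the component most sensitive to that gap; it can always be overridden
with an explicit threshold.

Problem sizes in the shipped tests are chosen for precision per unit
time: 500-1000 events for jitter-SD recovery (the sqrt(2) law is then
testable within 15%), 8000-40000 replicates per simulator boundary
(sized to each boundary's margin), and desk-scale fixtures (10-60
events) everywhere else.

## Reporting

`build_report()` assembles the computed artifacts into the standardized
report: geometry in degrees of visual angle, content and response
mismatch counts over totals, timing means/SDs/max-absolute in
milliseconds, per-rule design compliance, and trigger content/jitter/
delay. Sections not computed are printed as "not performed" rather than
dropped -- an absent test and a passing test must never be
confused. The JSON rendering is a lossless twin of the report object
(render, parse, render is the identity), and the markdown rendering is
meant to be pasted into a methods section or lab notebook. The CLI
(`inst/cli/eventqa.R`) wraps the same functions for shell use; each
check writes a JSON fragment and the `report` subcommand merges
fragments into the final document, with exit codes reflecting overall
status.
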