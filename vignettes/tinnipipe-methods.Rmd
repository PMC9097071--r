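---
title: "Methods: startle suppression, ABR thresholds and unit tuning in tinnipipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: startle suppression, ABR thresholds and unit tuning in tinnipipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinnipipe)
```

tinnipipe quantifies three kinds of auditory-electrophysiology recordings
used in rodent noise-induced-tinnitus studies, and ships a seeded
synthetic-recording generator with known ground truth so every stage of
the chain can be verified at desk scale. This vignette explains the
models, the tunable parameters and their defaults, the numerical choices
made where the procedures left freedom, and what the synthetic tests do
and do not establish about real recordings.

## 1. Gap-prepulse inhibition of acoustic startle (GPIAS)

A mouse startles at a loud noise pulse (105 dBSPL, 50 ms). If a brief
silent gap (40 ms) interrupts the background noise 100 ms before the
pulse, a hearing animal startles less; an animal with tinnitus at the
band of the background noise fails to detect the gap and startles almost
fully. Sessions present, per frequency band, 9 *Startle* trials (no gap)
and 9 *Gap-startle* trials in pseudo-random order, with 12-22 s of
background noise (integer seconds, uniform) between trials. Only the
loud-pulse onset carries a timestamp mark; gap timing is derived from the
schedule.

The quantification chain per band:

1. **Filtering** — piezoelectric traces: zero-phase 4th-order Butterworth
   bandpass 70-400 Hz; accelerometer traces: zero-phase lowpass below
   50 Hz per axis, then the per-sample mean of the absolute values of the
   three axes. Zero-phase (forward-backward) filtering is used because
   the response amplitude is read from a window keyed to the pulse mark:
   a causal filter's group delay would shift burst energy across the
   window boundary. Rectifying and axis-averaging commute with slicing,
   so the order "filter, slice, rectify-average, trial-average" used here
   matches either reading of the procedure.
2. **Slicing** — 200 ms around each pulse onset, fixed here as the
   half-open window [-100, +100) ms with the onset as the first sample of
   the post half.
3. **Averaging** — the 9 slices of a (band, type) pair are averaged
   point-wise *before* envelope extraction, for both trial types.
   (Averaging first suppresses incoherent noise by a factor of 3; the
   envelope of an average is not the average of envelopes, and the
   average-then-envelope order is the one that makes the noise-free
   identity below exact.)
4. **Envelope** — the instantaneous amplitude is the magnitude of the
   discrete analytic signal (Hilbert transform) of the full 200-ms
   averaged segment, computed by one-sided spectrum doubling on the FFT.
5. **Response amplitude** — mean envelope over [0, +100) ms minus mean
   envelope over [-100, 0) ms. The subtraction removes baseline offsets;
   on pure noise the result can be negative or zero, in which case the
   suppression index below is undefined and the band is flagged unusable
   rather than given an unbounded value.
6. **Index** — `(1 - GapStartle/Startle) * 100`, where *Startle* and
   *GapStartle* are the response amplitudes of the two averaged trial
   types. 100 means complete gap-induced suppression, 0 none, negative
   values facilitation.

Because every step from trace to amplitude is linear or
positively homogeneous, scaling a recording by k > 0 scales both
amplitudes by k and leaves the index unchanged, and a noise-free
synthetic session with programmed suppression s yields an index of
exactly 100 s (the gap-trial waveform is the startle-trial waveform
scaled by 1 - s).

**Screening and summary.** A band passes screening when its index is at
least 30%; animals failing bands are re-tested on the failed bands only,
and an animal is included when at least two bands pass after the retest.
Across sessions, the *most affected frequency* is the band with the
greatest index drop from before to after noise exposure; ties are broken
toward the lowest band center so reporting is deterministic.

## 2. Auditory brainstem responses (ABR)

Stimuli are 3-ms narrow-band noise pulses at 10 Hz, 529 repetitions per
condition, at 80 down to 35 dBSPL in 5-dB steps, for five bands. Epochs
of [-3, +9) ms around each pulse are averaged per intensity and
band-limited to 600-1500 Hz (zero-phase 4th-order Butterworth; for a
linear zero-phase filter, filtering the average equals averaging filtered
epochs, and the package exploits this for speed).

**Peak rule.** A sample of the averaged trace is a peak when it exceeds
the trace mean by one standard deviation, is strictly larger than the
previous sample and not smaller than the next (left plateau edges count).
The mean and SD are taken over the full 12-ms trace — the statistic's
support is a package choice; the trace's own statistics keep the rule
self-contained per intensity.

**Validity tracking.** Peaks at 80 dBSPL seed the tracks. At each lower
intensity a candidate peak is *valid* when it passes the peak rule on its
own trace, its latency exceeds that of a predecessor peak one step above
by at most `latency_tolerance` (default 0.5 ms), and its height (above
the trace mean) retains at least `min_height_ratio` (default 0.5) of that
predecessor's height. The hearing threshold is the lowest intensity
holding a valid peak; a valid peak at 35 dBSPL is reported as "<= 35"
via the `at_floor` flag, so group statistics can use the numeric value
while the censoring is preserved.

The two validity bounds deserve justification, because an unbounded
"latency must increase" rule is not usable in practice. The 1-SD peak
rule is *scale-invariant*: a sub-threshold average contains only residual
noise, and noise crossed by a relative threshold produces local maxima at
a rate that does not depend on the noise amplitude (about 0.6 spurious
peaks per millisecond of 600-1500 Hz noise). With a wide latency window,
each live track therefore extends into pure noise with high probability
per 5-dB step, and estimated thresholds collapse far below truth — at
any signal-to-noise ratio. The defaults are derived from the generator's
physics rather than tuned: wave latencies shift by at most 0.3 ms per
step (so 0.5 ms of tolerance covers every legitimate continuation), and
the amplitude growth law below makes the worst legitimate step-to-step
height ratio sqrt(0.5) = 0.71 (so a 0.5 floor passes real waves with
margin while rejecting noise maxima, which near threshold are several
times smaller than the last true peak). In a 300-run design simulation
this tracker recovers the programmed threshold exactly in 99.7% of runs.

**Wave 1.** The earliest-latency valid peak per intensity. Its amplitude
is the peak height minus the trace mean — consistent with the detection
statistic; peak-to-trough is a common alternative and the helper exposes
heights so either can be derived. The growth function divides each
intensity's wave-1 amplitude by the 80-dBSPL value, so it is 1 at
80 dBSPL by construction.

## 3. Synthetic generators

The generators define the study conditions the tests run under; their
defaults are fixed once and are not tuned per test.

* **Startle bursts** — a damped sinusoid (decay constant 30 ms) with
  carrier 150 Hz for the piezo sensor and 20 Hz for the accelerometer,
  keeping burst energy inside the respective analysis passbands; the
  accelerometer splits the burst across three axes (weights 0.5, 0.35,
  0.15). Burst onset coincides with pulse onset: reflex latency is not
  modeled, and only the analysis window, not the index, would change if
  it were. Noise is white Gaussian per sample; the default SD is 0.1 of
  the unit burst amplitude ("10% noise").
* **ABR templates** — five Gabor-like deflections (Gaussian envelope,
  sigma 0.4 ms, 1-kHz carrier) at 1.5, 2.4, 3.3, 4.2 and 5.1 ms with
  relative amplitudes 1.0, 0.6, 0.7, 0.5, 0.4 (wave 1 dominant), so the
  600-1500 Hz filter passes the waveform essentially unchanged. Peak
  amplitudes follow `g(I) = sqrt((I - thr + 5)/(85 - thr))` above the
  threshold `thr` and vanish below it; each 5-dB step down shifts all
  latencies by 0.1 ms (configurable up to 0.3 ms). The square-root law
  is a deliberate choice: with a linear-in-dB law, the response at the
  threshold intensity can be an order of magnitude below the 80-dB
  response and indistinguishable from averaged noise at any noise
  setting, making "the lowest intensity with a detectable peak" an
  ill-posed recovery target. Per-epoch noise SD defaults to 0.5 relative
  to the unit wave-1 amplitude — about 6 dB SNR per single epoch, 33 dB
  per 529-epoch average at 80 dBSPL, and at least 13 dB at the threshold
  intensity.
* **Spike trains** — inhomogeneous Poisson: a homogeneous baseline plus,
  in the 50 ms after each pulse, an evoked rate
  `max(0, peak_rate + slope (I - 80)) * exp(-(center - bf)^2 / (2 sigma^2))`,
  multiplied by `cno_gain` under CNO. The evoked window matches the PSTH
  post-half. Stimulation cells are laid out sequentially with 10 s of
  silence between intensities, as in the recording protocol.

What the generators do *not* emulate: startle habituation across trials,
movement artifacts, anesthesia-depth drift, electrode drift, overlapping
units on one channel, non-Gaussian sensor noise, and acoustic
calibration (all dB values are metadata labels). Passing recovery tests
therefore shows the *analysis chain* is correct and robust at realistic
noise levels — not that the chain is robust to every artifact of real
recordings.

## 4. Unit analysis

Spike events come either from an external sorter's event lists or from
[detect_events()], a documented single-unit surrogate: band-limit
500-14250 Hz, then take local minima below -k SD (k in 2..4.5, default
4.5) with a 1-ms refractory lockout. PSTHs count spikes in 100 1-ms bins
over [-50, +50) ms around each TTL. The frequency-response area (FRA)
holds, per (band, intensity) cell, the rate in the 50-ms evoked window
pooled over the cell's 529 pulses. The evoked-window statistic is a
package choice (the procedure names no window); 50 ms matches the PSTH
post-half and the generator's evoked window.

Tuning width is the mean of the max-normalized rates across the five
bands at 80 dBSPL (1 = flat/broad; 0.2 = one-hot/sharp), and best
frequency is the center of the argmax band, ties toward the lowest
center. Both are computed on the raw 5 x 10 grid; the 3x bilinear
upsampling ([upsample_fra()], pixel-centered so original nodes reappear
at aligned positions and values stay within the input range) is retained
for pseudocolor export only. Treatment effects are classified per feature
by the sign of CNO minus NaCl, with exact ties (possible for best
frequency on the discrete grid) reported as no change. Feature pairs are
correlated with Pearson's r and the non-correlation p-value,
Bonferroni-corrected; the family size defaults to the comparisons made in
the call and is configurable, since reported tables correct over
different family conventions. Best frequencies are reported in kHz
throughout.

## 5. Group statistics and power

Repeated-measures ANOVA (1-3 within factors) runs through `stats::aov`
with `Error(subject/...)` strata on complete balanced tables; constant
responses return F = NA with p = 1 rather than a spurious ratio.
Kruskal-Wallis (tie-corrected) with pairwise Wilcoxon follow-ups,
Shapiro normality screening, and two-tailed paired t tests use the base
R implementations; effect-size conventions are eta-squared
`(H - k + 1)/(n - k)` for Kruskal-Wallis and `r = Z/sqrt(n)` for
Wilcoxon. "Medium effect size" maps to Cohen's d = 0.5 (t test) and
f = 0.25 (ANOVA). Paired-t power uses the noncentral t distribution with
noncentrality `d sqrt(n)`; at d = 0.5 and n in {122, 102, 85, 91} the
minimum power is 99.5%. RM-ANOVA power uses the common design-software
convention `ncp = f^2 n m / (1 - rho)` with rho defaulting to 0.5 and
sphericity assumed; published power figures computed under unstated
conventions cannot be pinned to one formula, so only the convention used
here is documented and asserted.

## 6. Numerical notes and problem sizes

* Filters: `signal::butter(4, ...)` with `signal::filtfilt`; all three
  bands (70-400, 600-1500, 500-14250 Hz) are numerically stable at the
  default rates (2-30 kHz).
* The analytic signal uses the even/odd-length one-sided doubling
  construction; tests compare it against an explicit O(n^2) DFT oracle
  to 1e-9.
* Pulse onsets are generated sample-aligned (the TTL time is the exact
  sample time), so slicing is reproducible to the sample.
* Containers store traces as little-endian float32 (quantizing doubles
  on first write; bit-stable from the second write onward) and event
  times as float64; JSON sidecars are written at full precision.
* Test-suite problem sizes: 50 startle sessions of one band (the
  per-band chain is identical for any band count), 25 ABR stacks at
  529 epochs, 100 + 40 synthetic units on the full 5 x 10 grid; the
  orchestrated end-to-end run uses a 2-animal, 2-band cohort. These
  sizes give binomial resolution well inside the asserted recovery
  margins while keeping a full run under a minute.

## 7. Known limitations

* Single-trial startle analysis is out of scope (the averaged-trial
  envelope is the unit of analysis).
* The threshold tracker assumes the 80-dBSPL trace contains detectable
  response peaks; a non-responding band raises an explicit error rather
  than guessing.
* `detect_events` is a surrogate for template-matching spike sorting and
  is only meaningful on channels dominated by one unit.
* Best-frequency recovery is undefined when the true tuning center falls
  exactly between two tested band centers; analyses report the discrete
  argmax band only.
* The responder-unit criterion (post-window rate exceeding pre-window
  rate) replaces an external classification method and is labeled as
  such in the API.
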