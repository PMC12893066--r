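---
title: "Methods: evoked multi-unit activity and behavioral episode statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked multi-unit activity and behavioral episode statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evokedmua)
```

# The analysis

This package implements a complete analysis chain for stimulus-evoked
extracellular multi-unit activity (MUA) recorded from thalamic slices with a
linear 16-channel array, together with the behavioral episode statistics
(grooming bouts, three-chamber sociability) used alongside such recordings
in studies of thalamocortical hyperexcitability. Electrical stimuli
(100 us, 50 V) are delivered to the internal capsule every 30 s for 10-20
trials; the first three seconds after each stimulus are analyzed. Evoked
spiking splits into an **early response** on \[0, 1.5) s — a high-frequency
component that decays — and a **delayed response** on \[1.5, 3) s, whose
elevation is the hyperexcitability readout.

The chain is:

1. **Preprocessing** — blank a 2-ms window after each stimulus (replacing it
   with the channel's baseline mean), then apply a zero-phase 100 Hz - 6 kHz
   band-pass (2nd-order Butterworth, forward + reverse).
2. **Spike detection** — threshold the first derivative of each channel at
   `threshold_multiplier` (default 4) times the channel's baseline
   derivative RMS (pre-stimulus 0.5 s of every trial, concatenated); merge
   crossings closer than 1 ms; timestamp each event at its extremal
   derivative sample; measure the waveform duration by the 20%-of-peak rule
   and discard events wider than 2 ms.
3. **Response curves** — align spikes to the most recent stimulus (half-open
   \[0, 3) s window), pool counts into 1-ms bins, form the instantaneous
   frequency `counts / (n_channels * n_trials * bin_width)` and the relative
   spiking probability (per-bin fraction of all pooled spikes), split at
   1.5 s, and downsample 10-fold (probabilities summed, frequencies
   averaged).
4. **Group statistics** — slices are the unit of independence. Group-mean
   downsampled probability curves are compared pairwise with two-sample
   Kolmogorov-Smirnov tests, Bonferroni-corrected over the k(k-1)/2
   contrasts per window; absolute instantaneous frequencies are compared
   with a Kruskal-Wallis omnibus test and Dunn's tie-corrected post hoc.
5. **Behavior** — grooming episodes (subject, onset, duration) are
   summarized per mouse and per group; the cumulative probability of
   episode duration is fitted with the exponential-plateau model
   `Y(t) = ym - (ym - y0) exp(-k t)`, and groups are compared with an
   extra-sum-of-squares F test of one shared fit against per-group fits.
   Sociability preference is the per-mouse ratio of mouse-cup to object-cup
   approach time (right/left cups during habituation), compared across
   groups with a Shapiro-Wilk-gated pooled-variance t-test.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `bin_ms` | 1 | ms | PSTH bin width |
| `analysis_window_s` | 3.0 | s | post-stimulus span analyzed |
| `early_window_s` | \[0, 1.5) | s | early response |
| `delayed_window_s` | \[1.5, 3) | s | delayed response |
| `downsample_factor` | 10 | – | curve coarsening before KS |
| `threshold_multiplier` | 4.0 | x baseline RMS | detection threshold |
| `duration_cutoff_ms` | 2 | ms | waveform-width exclusion |
| `dead_time_ms` | 1 | ms | crossing-merge lockout |
| `baseline_window_s` | 0.5 | s | pre-stimulus RMS span |
| `artifact_blank_ms` | 2 | ms | post-stimulus blanking |
| `alpha` | 0.05 | – | significance level |

The threshold multiplier, baseline definition, dead time and blanking span
are not dictated by the recording protocol itself; they are exposed in
`analysis_config()` and default to conventional MUA practice. The threshold
is applied to the absolute derivative because electrode polarity is
arbitrary (`polarity` switches to one-sided thresholding). Relative
probability is normalized per slice over the full 3-s window by default —
the normalization that makes the early/delayed comparison scale-free across
slices with different firing rates — with per-window normalization
available via `prob_normalization = "window"`. The Kruskal-Wallis sample
unit is per-slice downsampled window bins pooled per group
(`kw_sample = "bins"`); per-slice means are available as `"slices"`.

# The synthetic-data generator

No public raw recordings accompany this kind of slice experiment, so the
package ships a seeded generator (`simulate_recording()`) that emulates the
statistical structure the analysis assumes, with full ground truth:

* **Spiking.** Per channel and trial, spike times are drawn from an
  inhomogeneous Poisson process: early rate `r0 exp(-t / tau)` (defaults
  `r0` = 60 Hz, `tau` = 3 s) and a delayed rate of 18 Hz for the
  normal-like conditions (`"WT-like"`, `"WTxMG-like"`) or 54 Hz — a 3x
  contrast, sinusoidally modulated at 3 Hz to mimic burst firing — for the
  hyperexcitable `"KOxMG-like"` condition. The figures of merit these rates
  produce (tens of Hz of sustained multi-unit firing per electrode during
  the evoked response) are realistic for pooled MUA, and dense enough that
  detection statistics are stable; no quantitative rates are claimed for
  any real preparation.
* **Waveforms.** Each spike is a biphasic template: a fast quarter-sine
  downstroke (10% of the negative lobe), a slower repolarization, and a
  positive overshoot at 15% of peak — below the 20% duration level, so the
  duration rule measures the negative lobe. The lobe length is calibrated
  so the 20%-of-peak width equals `spike_width_ms` exactly; widths other
  than the 0.6-ms default (e.g. 3 ms) exercise the exclusion rule.
* **Noise.** Gaussian background noise band-limited to 100 Hz - 6 kHz with
  power ~ 1/f inside the band, scaled to `noise_rms` (default 5 uV).
  The 1/f weighting reflects biological background in the MUA band
  (distant spiking and residual low-frequency activity dominate electrode
  thermal noise); it is also what makes derivative thresholding effective:
  against spectrally flat in-band noise the derivative of a band-limited
  spike cannot rise far above the derivative noise floor, whereas against
  low-frequency-weighted noise the fast downstroke stands out. The
  default spike amplitude (40 uV) is 8x the noise RMS.
* **Artifacts.** A 1-ms saturating square transient at each stimulus
  exercises blanking without modelling electrode physics.
* **Behavior.** Grooming episodes per mouse are Poisson in number with
  i.i.d. exponential durations and uniform onsets (resampled, then evenly
  respaced if needed, to keep episodes non-overlapping); sociability
  approach times are truncated-at-zero Gaussians, with equal means for the
  two empty cups during habituation.

`simulate_psth_counts()` draws the pooled per-bin Poisson counts of the
same generative model directly, skipping waveform rendering; group-level
power studies use it because the detector itself is validated separately.

**What passing tests do not show.** The generator produces stationary
noise, identical spike templates within a recording, rate profiles shared
by all channels, and no spontaneous (pre-stimulus) spiking. Real slices
have electrode-to-electrode amplitude variation, overlapping units,
nonstationary excitability and baseline activity. Detector fidelity
numbers obtained here therefore bound the method's behavior under its own
assumptions; they do not certify performance on any particular real
recording.

# Numerical choices

* **Filtering.** The zero-phase band-pass is a 2nd-order Butterworth run
  forward and backward (effective order 4, zero phase) with reflection
  padding, implemented with direct-form IIR passes. Artifact blanking runs
  *before* filtering so the acausal filter cannot smear artifact energy
  backwards into the baseline windows.
* **Duration metric.** The 20%-of-peak width is measured as the contiguous
  region around the waveform peak at or above 20% of the peak amplitude.
  For noise robustness the extent is delimited on a 3-point moving-average
  envelope and then refined inward to the nearest raw crossing; on clean
  waveforms this reduces exactly to the contiguous 20% width. Without this,
  a single noisy sample can truncate the width of a slowly decaying
  artifact and defeat the 2-ms exclusion.
* **Detection edge cases.** A channel whose baseline RMS is zero is skipped
  with a warning; events inside blanked spans are never reported; a
  degenerate flat segment raises an error from `measure_duration()`.
* **Relative probability of an empty PSTH** is an all-zero curve flagged
  `degenerate` rather than NaN.
* **Downsampling** requires the curve length to be divisible by the factor
  and drops the remainder with a warning otherwise; probabilities are
  summed (mass conserved to machine precision), frequencies averaged (rate
  units preserved).
* **Plateau fitting** minimizes least squares by Levenberg-Marquardt
  (`minpack.lm::nls.lm`) from five deterministic starts (`k` spanning
  0.03-30 times the reciprocal time range; `y0`, `ym` from the data
  extremes), keeping the best converged start by residual sum of squares.
  `k` is bounded positive. Flat input collapses to `ym = y0` with `k`
  flagged unidentifiable. The fit achieves the global minimum on
  model-generated data (verified against a dense grid search in the test
  suite).
* **Extra-sum-of-squares F.** The shared fit uses the union of the
  per-group curve points, so shared and separate fits partition identical
  points; the numerator df equals the extra parameters, `3 (k_groups - 1)`
  for the free model. Degrees of freedom are reported transparently from
  the points actually fitted. Note that when the fitted points are ECDF
  values their errors are serially correlated, so the nominal F reference
  distribution is approximate there; the test is calibrated (size about
  0.05) when the curve points carry independent errors.
* **Ties.** Kruskal-Wallis and Dunn statistics use the standard tie
  corrections; KS p-values use the asymptotic distribution by default
  (curves contain ties, and samples of 150 downsampled bins are well into
  the asymptotic regime).

# Validation problem sizes

The acceptance layer validates, at sizes chosen to exercise the defaults:
detector recall/precision on a full 16-channel, 10-trial, 30-s-ISI
recording at spike-peak/noise-RMS = 8 (about 16,000 true spikes);
exclusion of each template width in {0.6, 1, 1.8, 2.4, 3} ms; 50-Hz rate
recovery over 16 x 20 channel-trials; 50-replicate power and type-I
studies of the three-group comparison at 8 slices per group; 50-replicate
plateau recovery (noise sd 0.02 at 50 points) and F-test size/power under
a 3-fold rate-constant contrast; and byte-identical CLI reruns.

# Known limitations

* No spike sorting: the pipeline quantifies multi-unit activity only.
* Slices are treated as independent observations; mouse/slice nesting is
  not modelled (no mixed-effects layer).
* The simulator does not render local field potentials, spectral structure
  beyond rate modulation, electrode drift, or video-derived behavior.
* Boundary template widths (within a filter-ringing margin of the 2-ms
  cutoff) can classify differently after band-passing than in their clean
  rendered form; the cutoff is intended for clearly wide artifacts.
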