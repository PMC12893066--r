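# evokedmua

Analysis of stimulus-evoked extracellular multi-unit activity (MUA) in
thalamic slice recordings, and of the behavioral episode statistics that
accompany such recordings in studies of thalamocortical hyperexcitability
(excessive grooming, reduced sociability). It is written for
electrophysiologists and behavioral neuroscientists who need a tested,
scriptable version of this analysis chain, and it ships a seeded
synthetic-data generator with ground truth, so every stage can be validated
without access to raw recordings.

## What it computes

**Evoked MUA.** Voltage traces from a 16-channel array (band 100 Hz-6 kHz,
stimuli every 30 s for 10-20 trials) are artifact-blanked and band-passed;
spikes are detected per channel by thresholding the first derivative
dV/dt at *m* x RMS(dV/dt) over the pre-stimulus baseline (default
*m* = 4), merging crossings within 1 ms, and excluding waveforms wider
than 2 ms (20%-of-peak width). Aligned spikes form a peri-stimulus time
histogram with 1-ms bins over [0, 3) s; the instantaneous frequency is

    f_b = c_b / (n_channels * n_trials * Δ),    Δ = 1 ms,

and the relative spiking probability is p_b = c_b / Σ c_b. Curves split
into the early [0, 1.5) s and delayed [1.5, 3) s response windows and are
downsampled 10-fold. Groups (slices as independent observations) are
compared per window by two-sample Kolmogorov-Smirnov tests on the
probability curves with Bonferroni correction over the k(k-1)/2 contrasts,
and by a Kruskal-Wallis omnibus test with Dunn's tie-corrected post hoc on
the absolute instantaneous frequencies.

**Behavior.** Grooming episodes (subject, onset, duration) are summarized
per mouse; the cumulative probability of episode duration is fitted with
the exponential-plateau model

    Y(t) = ym − (ym − y0) · exp(−k t)

by Levenberg-Marquardt least squares with deterministic multistarts, and
groups are compared with an extra-sum-of-squares F test
(F = [(SS_shared − SS_sep)/(df_shared − df_sep)] / [SS_sep/df_sep]).
Per-mouse totals, episode counts and pooled episode durations use
Student's pooled-variance t-tests; three-chamber sociability preference
ratios (mouse/object approach time) use a Shapiro-Wilk-gated t-test.

## Worked example

```r
library(evokedmua)

# a hyperexcitable-condition slice: 16 channels, 10 trials, 30-s ISI
res <- simulate_recording(sim_config(condition = "KOxMG-like", seed = 42))
cfg <- analysis_config()
pre <- preprocess_recording(res$recording, cfg)
spikes <- detect_spikes(pre, cfg)
spikes
#> # A tibble: 30,209 × 4
#>   channel time_s duration_ms threshold_vps
#> 1       1  0.105        1.48         0.215
#> 2       1  0.239        0.84         0.215
#> ...

aligned <- align_to_stimulus(spikes, res$recording$stim_times)
psth <- compute_psth(aligned, cfg, 16, 10, group = "KOxMG-like")
glance(psth)
#> n_spikes = 23761, mean_rate_hz = 49.5, early_rate_hz = 45.7 ...

match_spike_trains(spikes, res$truth$spikes, tol_ms = 0.5,
                   stim_times = res$recording$stim_times)
#> n_true = 24788, recall = 0.931, precision = 0.971
```

The detected spike count, the ~50 Hz mean evoked rate and the
recall/precision against the generator's ground truth summarize one slice
of the hyperexcitable condition (its delayed firing runs at 3x the
normal-like rate, so per-channel collisions cost a little recall relative
to the ~0.96/0.96 obtained under the default condition).

Behavioral endpoints for a simulated two-group study (8 vs 11 mice):

```r
groom <- simulate_grooming(
  tibble::tibble(group = c("KOxMG-like", "WTxMG-like"),
                 n_mice = c(8L, 11L),
                 episode_rate = c(5.1, 4.9),
                 mean_duration_s = c(12, 7)),
  seed = 7)
grooming_report(groom)
#> total_time       t(17) = 2.84,  p = 0.011
#> n_episodes       t(17) = 2.60,  p = 0.019
#> episode_duration t(109) = 1.92, p = 0.058
#> duration_curve   extra-SS F(3, 105) = 86.8, p < 1e-27
```

The t statistics use df = n1 + n2 − 2 (17 for the 8-vs-11 per-mouse
endpoints; pooled episodes for the duration endpoint), and the F test
compares one shared plateau fit against per-group fits of the two groups'
cumulative duration curves. `autoplot()` methods display PSTHs and plateau
fits; `plot_group_curves()` shows group mean ± SEM response curves.

A thin command-line interface (`exec/mua`) wraps the same functions:
`simulate-ephys`, `simulate-behavior`, `detect`, `analyze`, `aggregate`,
`compare`, `behavior-groom`, `behavior-social`. Identical configuration
and seed give byte-identical output files.

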