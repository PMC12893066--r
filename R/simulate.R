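# Synthetic-data generators: seeded recordings with ground truth, plus
# grooming and sociability tables with known generating parameters.

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration
#'
#' Parameters of the synthetic slice-recording generator. The stimulation
#' protocol defaults (100-us, 50-V stimuli every 30 s, 10-20 trials,
#' 16-channel array, 100 Hz - 6 kHz band) mirror a standard evoked
#' thalamic-oscillation protocol. Firing-rate defaults are generator choices:
#' an early high-frequency component decaying from `early_rate_hz` with time
#' constant `early_tau_s` over \[0, 1.5) s, and a condition-dependent delayed
#' component over \[1.5, 3) s. Conditions model the study groups: `"WT-like"`
#' and `"WTxMG-like"` share a low delayed rate; `"KOxMG-like"` is
#' hyperexcitable, with a 3x delayed rate and slow (3 Hz) sinusoidal burst
#' modulation of delayed firing.
#'
#' @param fs Sampling rate, Hz. Must be at least twice the band high edge.
#' @param channel_count Number of electrode channels.
#' @param n_trials Number of stimuli (10-20 in the standard protocol).
#' @param isi_s Inter-stimulus interval, seconds.
#' @param pre_s Trace time before the first stimulus, seconds (must cover the
#'   baseline window).
#' @param stim_amp_v,stim_width_us Stimulation pulse amplitude (V) and width
#'   (us); recorded as metadata.
#' @param artifact_amp_v Rendered amplitude of the 1-ms saturating square
#'   stimulus artifact, volts at the electrode.
#' @param noise_rms Background noise RMS, volts.
#' @param noise_exponent Spectral exponent of the band-limited background
#'   noise (power ~ 1/f^exponent within the band). The default 1 models
#'   low-frequency-weighted biological noise.
#' @param spike_amplitude Absolute peak of the negative spike lobe, volts.
#' @param spike_width_ms Spike waveform width as measured by the 20%-of-peak
#'   duration rule, ms.
#' @param early_rate_hz,early_tau_s Early-window rate profile
#'   `r(t) = early_rate_hz * exp(-t / early_tau_s)` per channel.
#' @param delayed_rate_hz Delayed-window mean rate per channel; `NULL` takes
#'   the condition preset (18 Hz, or 54 Hz for `"KOxMG-like"`).
#' @param burst_freq_hz Delayed-window burst-modulation frequency, Hz.
#' @param burst_depth Relative depth of sinusoidal delayed-rate modulation
#'   (applied for `"KOxMG-like"`; the mean rate is unchanged).
#' @param condition Group condition label.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   output.
#' @return An object of class `mua_sim_config`.
#' @export
sim_config <- function(fs = 25000, channel_count = 16, n_trials = 10,
                       isi_s = 30, pre_s = 1,
                       stim_amp_v = 50, stim_width_us = 100,
                       artifact_amp_v = 5e-4,
                       noise_rms = 5e-6, noise_exponent = 1,
                       spike_amplitude = 4e-5, spike_width_ms = 0.6,
                       early_rate_hz = 60, early_tau_s = 3,
                       delayed_rate_hz = NULL,
                       burst_freq_hz = 3, burst_depth = 0.8,
                       condition = c("WT-like", "KOxMG-like", "WTxMG-like"),
                       seed = 1) {
  condition <- match.arg(condition)
  if (is.null(delayed_rate_hz)) {
    delayed_rate_hz <- if (condition == "KOxMG-like") 54 else 18
  }
  sim <- structure(list(
    fs = fs, channel_count = as.integer(channel_count),
    n_trials = as.integer(n_trials), isi_s = isi_s, pre_s = pre_s,
    stim_amp_v = stim_amp_v, stim_width_us = stim_width_us,
    artifact_amp_v = artifact_amp_v,
    noise_rms = noise_rms, noise_exponent = noise_exponent,
    spike_amplitude = spike_amplitude, spike_width_ms = spike_width_ms,
    early_rate_hz = early_rate_hz, early_tau_s = early_tau_s,
    delayed_rate_hz = delayed_rate_hz,
    burst_freq_hz = burst_freq_hz,
    burst_depth = if (condition == "KOxMG-like") burst_depth else 0,
    condition = condition, seed = as.integer(seed),
    band = c(100, 6000)
  ), class = "mua_sim_config")
  validate_sim_config(sim)
}

validate_sim_config <- function(sim) {
  if (sim$noise_rms <= 0) abort("noise_rms must be > 0")
  if (sim$n_trials < 1) abort("n_trials must be >= 1")
  if (sim$early_rate_hz < 0 || sim$delayed_rate_hz < 0) {
    abort("rates must be >= 0")
  }
  if (sim$fs < 2 * sim$band[2]) {
    abort(sprintf("aliasing error: fs = %g below twice the band high edge %g",
                  sim$fs, sim$band[2]))
  }
  if (sim$pre_s < 0 || sim$isi_s <= sim$fs * 0) NULL
  if (sim$isi_s <= 3) abort("isi_s must exceed the 3-s analysis window")
  sim
}

# --- spike template -------------------------------------------------------

# Biphasic extracellular template: a fast quarter-sine downstroke (fraction
# `frac` of the negative lobe), a slower quarter-cosine repolarization, and a
# low positive overshoot (15% of peak, below the 20% duration level). The
# negative-lobe length is calibrated so the 20%-of-peak width equals the
# requested width: width20 = (2/pi) * acos(0.2) * lobe length, independent of
# `frac`.
TEMPLATE_FRAC <- 0.10
TEMPLATE_WIDTH20_FACTOR <- (2 / pi) * acos(0.2)

template_value <- function(t_rel, width_ms, amp) {
  wl <- (width_ms / 1000) / TEMPLATE_WIDTH20_FACTOR
  td <- TEMPLATE_FRAC * wl
  tu <- (1 - TEMPLATE_FRAC) * wl
  tp <- 0.5 * wl
  v <- numeric(length(t_rel))
  a <- t_rel >= 0 & t_rel < td
  v[a] <- -amp * sin(pi * t_rel[a] / (2 * td))
  b <- t_rel >= td & t_rel < td + tu
  v[b] <- -amp * cos(pi * (t_rel[b] - td) / (2 * tu))
  p <- t_rel >= td + tu & t_rel < td + tu + tp
  v[p] <- 0.15 * amp * sin(pi * (t_rel[p] - td - tu) / tp)
  v
}

template_extent_s <- function(width_ms) {
  1.5 * (width_ms / 1000) / TEMPLATE_WIDTH20_FACTOR
}

# sample indices (1-based) and values of a spike rendered at continuous time
# t0 (s), sub-sample accurate: the template is evaluated at the sample clock
spike_samples <- function(t0, width_ms, amp, fs, n) {
  ext <- template_extent_s(width_ms)
  i0 <- max(0L, floor(t0 * fs))
  i1 <- min(n - 1L, ceiling((t0 + ext) * fs))
  if (i1 < i0) return(list(idx = integer(), v = numeric()))
  ii <- i0:i1
  list(idx = ii + 1L, v = template_value(ii / fs - t0, width_ms, amp))
}

# add a spike into channel vector x (convenience for tests and fixtures;
# within simulate_recording the rendering is done in-frame to avoid copies)
render_spike <- function(x, t0, width_ms, amp, fs) {
  s <- spike_samples(t0, width_ms, amp, fs, length(x))
  x[s$idx] <- x[s$idx] + s$v
  x
}

# --- noise ----------------------------------------------------------------

# Gaussian noise band-limited to [low, high] Hz with power ~ 1/f^exponent
# inside the band, scaled to the requested RMS. Built in the Fourier domain
# with random phases, so it is stationary and seeded-deterministic.
bandlimited_noise <- function(n, fs, rms, band = c(100, 6000), exponent = 1) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  mag <- ifelse(f >= band[1] & f <= band[2], f^(-exponent / 2), 0)
  ph <- runif(nf, 0, 2 * pi)
  sp <- complex(modulus = mag, argument = ph)
  full <- c(complex(real = 0), sp,
            if (n %% 2 == 0) Conj(rev(sp[-nf])) else Conj(rev(sp)))
  x <- Re(fft(full, inverse = TRUE))[1:n]
  x / sqrt(mean(x^2)) * rms
}

# --- rate profiles --------------------------------------------------------

# per-channel instantaneous rate (Hz) at stimulus-relative time t in [0, 3)
rate_at <- function(t, sim) {
  r <- numeric(length(t))
  e <- t >= 0 & t < 1.5
  r[e] <- sim$early_rate_hz * exp(-t[e] / sim$early_tau_s)
  d <- t >= 1.5 & t < 3
  r[d] <- sim$delayed_rate_hz *
    (1 + sim$burst_depth * sin(2 * pi * sim$burst_freq_hz * (t[d] - 1.5)))
  pmax(r, 0)
}

# draw one trial's stimulus-relative spike times by thinning
draw_trial_spikes <- function(sim) {
  bound_e <- sim$early_rate_hz
  te <- if (bound_e > 0) {
    ne <- rpois(1, bound_e * 1.5)
    cand <- runif(ne, 0, 1.5)
    cand[runif(ne) < exp(-cand / sim$early_tau_s)]
  } else numeric()
  bound_d <- sim$delayed_rate_hz * (1 + sim$burst_depth)
  td <- if (bound_d > 0) {
    nd <- rpois(1, bound_d * 1.5)
    cand <- runif(nd, 1.5, 3)
    cand[runif(nd) < rate_at(cand, sim) / bound_d]
  } else numeric()
  sort(c(te, td))
}

#' Simulate a stimulus-evoked multichannel recording with ground truth
#'
#' Per channel, spike times are drawn from an inhomogeneous Poisson process
#' (early decaying component on \[0, 1.5) s, condition-dependent delayed
#' component on \[1.5, 3) s after each stimulus), rendered as biphasic
#' templates of the configured width and amplitude, and superposed on
#' band-limited Gaussian background noise. A 1-ms saturating square artifact
#' is rendered at each stimulus time on every channel. The returned payload
#' is quantized to float32, so writing and re-reading the default trace file
#' is bit-exact. Identical `sim` (including its seed) gives bit-identical
#' output.
#'
#' @param sim An [sim_config()] object.
#' @param meta Optional metadata overrides (`slice_id`, `animal_id`, `group`;
#'   `group` defaults to the condition label).
#' @return A list with elements `recording` (an `mua_recording`) and `truth`
#'   (class `mua_truth`): `truth$spikes` is a tibble of every inserted spike
#'   (`channel`, `trial`, `time_s` on the trace clock, `t_rel`
#'   stimulus-relative, `width_ms`), and `truth$rates` records the generating
#'   rate functions.
#' @export
simulate_recording <- function(sim = sim_config(), meta = list()) {
  validate_sim_config(sim)
  with_seed(sim$seed, {
    fs <- sim$fs
    n <- round((sim$pre_s + sim$n_trials * sim$isi_s) * fs)
    stim <- sim$pre_s + (seq_len(sim$n_trials) - 1) * sim$isi_s
    data <- matrix(0, nrow = sim$channel_count, ncol = n)
    truth <- vector("list", sim$channel_count)
    art_idx <- unlist(lapply(stim, function(s) {
      (floor(s * fs)):(floor(s * fs) + round(0.001 * fs) - 1)
    })) + 1L
    for (ch in seq_len(sim$channel_count)) {
      x <- bandlimited_noise(n, fs, sim$noise_rms, sim$band,
                             sim$noise_exponent)
      ch_rel <- vector("list", sim$n_trials)
      for (tr in seq_len(sim$n_trials)) {
        t_rel <- draw_trial_spikes(sim)
        ch_rel[[tr]] <- t_rel
        for (t0 in t_rel) {
          s <- spike_samples(stim[tr] + t0, sim$spike_width_ms,
                             sim$spike_amplitude, fs, n)
          x[s$idx] <- x[s$idx] + s$v
        }
      }
      x[art_idx] <- sim$artifact_amp_v
      data[ch, ] <- quantize_float32(x)
      truth[[ch]] <- tibble(
        channel = ch,
        trial = rep(seq_len(sim$n_trials), lengths(ch_rel)),
        t_rel = unlist(ch_rel) %||% numeric()
      )
    }
    spikes <- dplyr::bind_rows(truth)
    spikes$time_s <- stim[spikes$trial] + spikes$t_rel
    spikes$width_ms <- rep(sim$spike_width_ms, nrow(spikes))
    spikes <- spikes[c("channel", "trial", "time_s", "t_rel", "width_ms")]
    meta_full <- modifyList(
      list(slice_id = "sim_slice", animal_id = "sim_animal",
           group = sim$condition, gain = 10000, band = sim$band,
           precision = "float32",
           stim_amp_v = sim$stim_amp_v, stim_width_us = sim$stim_width_us),
      meta)
    rec <- new_recording(data, fs, stim_times = stim, meta = meta_full)
    truth_obj <- structure(
      list(spikes = spikes,
           rates = list(early_rate_hz = sim$early_rate_hz,
                        early_tau_s = sim$early_tau_s,
                        delayed_rate_hz = sim$delayed_rate_hz,
                        burst_freq_hz = sim$burst_freq_hz,
                        burst_depth = sim$burst_depth),
           sim = sim),
      class = "mua_truth")
    list(recording = rec, truth = truth_obj)
  })
}

#' Simulate pooled PSTH spike counts for a set of slices
#'
#' Spike-count-level counterpart of [simulate_recording()]: for each slice it
#' draws the pooled per-bin spike counts of the same generative model
#' directly (per 1-ms bin, `counts ~ Poisson(n_channels * n_trials *
#' rate(t) * bin width)`), skipping waveform rendering and detection. Used
#' for group-level power studies where the detector itself is not under
#' test.
#'
#' @param groups Either a named integer vector mapping a condition label
#'   (`"WT-like"`, `"KOxMG-like"`, `"WTxMG-like"`) to a number of slices,
#'   e.g. `c("WT-like" = 8, "KOxMG-like" = 8)`, or a data frame with
#'   columns `group` (label), `condition` and `n_slices` (so several groups
#'   can share one generating condition, as in null studies).
#' @param seed Integer seed.
#' @param cfg An [analysis_config()].
#' @param n_channels,n_trials Channels and trials per slice.
#' @param sim_overrides Named list of [sim_config()] overrides applied to
#'   every condition (e.g. a custom `delayed_rate_hz`).
#' @return A list of `mua_psth` objects (one per slice) with `slice_id` and
#'   `group` metadata.
#' @export
simulate_psth_counts <- function(groups, seed, cfg = analysis_config(),
                                 n_channels = 16, n_trials = 10,
                                 sim_overrides = list()) {
  if (is.data.frame(groups)) {
    spec <- as_tibble(groups)
    if (!all(c("group", "condition", "n_slices") %in% names(spec))) {
      abort("groups data frame needs columns group, condition, n_slices")
    }
  } else {
    if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
      abort("groups must be a named vector: condition label -> n slices")
    }
    spec <- tibble(group = names(groups), condition = names(groups),
                   n_slices = as.integer(groups))
  }
  with_seed(seed, {
    binw <- cfg$bin_ms / 1000
    nb <- round(cfg$analysis_window_s / binw)
    edges <- seq(0, cfg$analysis_window_s, length.out = nb + 1)
    mid <- (edges[-1] + edges[-(nb + 1)]) / 2
    out <- list()
    k <- 0
    for (gi in seq_len(nrow(spec))) {
      sim <- do.call(sim_config,
                     modifyList(list(condition = spec$condition[gi],
                                     seed = 1L), sim_overrides))
      lam <- n_channels * n_trials * rate_at(mid, sim) * binw
      for (s in seq_len(spec$n_slices[gi])) {
        k <- k + 1
        counts <- rpois(nb, lam)
        out[[k]] <- new_psth(edges, counts, n_channels, n_trials,
                             slice_id = sprintf("%s_s%02d", spec$group[gi],
                                                s),
                             group = spec$group[gi])
      }
    }
    out
  })
}

#' Measure per-channel RMS of a recording over a quiet window
#'
#' Simulator self-check: computes the per-channel root mean square of the
#' voltage over a window known (from ground truth) to contain no spikes or
#' artifacts, to verify the rendered noise level.
#'
#' @param rec An `mua_recording`.
#' @param quiet_window Length-2 numeric, half-open interval in seconds.
#' @return A tibble with columns `channel`, `rms`.
#' @export
measure_trace_noise <- function(rec, quiet_window) {
  i0 <- floor(quiet_window[1] * rec$fs) + 1L
  i1 <- ceiling(quiet_window[2] * rec$fs)
  i1 <- min(i1, ncol(rec$data))
  if (i1 < i0) abort("empty quiet window")
  tibble(channel = seq_len(rec$channel_count),
         rms = apply(rec$data[, i0:i1, drop = FALSE], 1,
                     function(v) sqrt(mean(v^2))))
}

#' Simulate a grooming episode table
#'
#' Per mouse, the episode count is Poisson with the group's rate, durations
#' are i.i.d. exponential with the group's mean, and onsets are uniform over
#' the session (resampled, then evenly respaced if needed, so that episodes
#' do not overlap).
#'
#' @param groups A data frame (or tibble) with columns `group`, `n_mice`,
#'   `episode_rate` (expected episodes per mouse per session) and
#'   `mean_duration_s`.
#' @param seed Integer seed.
#' @param session_length_s Session length, seconds (default 1200).
#' @return An [episode_table()] tibble.
#' @export
simulate_grooming <- function(groups, seed, session_length_s = 1200) {
  groups <- as_tibble(groups)
  need <- c("group", "n_mice", "episode_rate", "mean_duration_s")
  if (!all(need %in% names(groups))) {
    abort(paste0("groups must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(groups$mean_duration_s <= 0)) abort("mean duration must be > 0")
  if (any(groups$episode_rate <= 0)) abort("episode rate must be > 0")
  with_seed(seed, {
    rows <- list()
    for (gi in seq_len(nrow(groups))) {
      g <- groups[gi, ]
      for (m in seq_len(g$n_mice)) {
        subj <- sprintf("%s_m%02d", g$group, m)
        n_ep <- rpois(1, g$episode_rate)
        if (n_ep == 0) next
        dur <- rexp(n_ep, rate = 1 / g$mean_duration_s)
        dur <- pmin(dur, session_length_s / 4)
        if (sum(dur) >= 0.9 * session_length_s) {
          abort("episodes cannot fit in the session; lower the rate or mean")
        }
        onset <- place_episodes(n_ep, dur, session_length_s)
        rows[[length(rows) + 1]] <- tibble(
          subject = subj, group = g$group, onset_s = onset, duration_s = dur)
      }
    }
    tbl <- dplyr::bind_rows(rows)
    if (nrow(tbl) == 0) {
      return(episode_table(session_length_s = session_length_s))
    }
    episode_table(tbl$subject, tbl$group, tbl$onset_s, tbl$duration_s,
                  session_length_s = session_length_s)
  })
}

# uniform onsets conditioned on non-overlap: rejection sample, fall back to
# even spacing of the inter-episode gaps
place_episodes <- function(n_ep, dur, session_length_s) {
  ord <- seq_len(n_ep)
  for (try in 1:200) {
    onset <- sort(runif(n_ep, 0, session_length_s - max(dur)))
    if (n_ep == 1 || all(onset[-1] >= (onset + dur)[-n_ep])) return(onset)
  }
  free <- session_length_s - sum(dur)
  gap <- free / (n_ep + 1)
  cumsum(c(gap, head(dur, -1) + gap))
}

#' Simulate a three-chamber sociability interaction table
#'
#' Per mouse, approach times are truncated-at-zero Gaussian draws: during
#' habituation both empty cups share the same mean (no side preference);
#' during the test phase the mouse-containing and object-containing cups use
#' the group's respective means.
#'
#' @param groups A data frame with columns `group`, `n_mice`,
#'   `mouse_time_mean_s`, `object_time_mean_s`, `sd_s`.
#' @param seed Integer seed.
#' @return An [interaction_table()] tibble.
#' @export
simulate_sociability <- function(groups, seed) {
  groups <- as_tibble(groups)
  need <- c("group", "n_mice", "mouse_time_mean_s", "object_time_mean_s",
            "sd_s")
  if (!all(need %in% names(groups))) {
    abort(paste0("groups must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(groups$sd_s <= 0)) abort("sd must be > 0")
  if (any(groups$mouse_time_mean_s < 0 | groups$object_time_mean_s < 0)) {
    abort("means must be >= 0")
  }
  rtruncnorm0 <- function(n, mean, sd) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  with_seed(seed, {
    rows <- list()
    for (gi in seq_len(nrow(groups))) {
      g <- groups[gi, ]
      hab_mean <- (g$mouse_time_mean_s + g$object_time_mean_s) / 2
      for (m in seq_len(g$n_mice)) {
        subj <- sprintf("%s_m%02d", g$group, m)
        rows[[length(rows) + 1]] <- tibble(
          subject = subj, group = g$group,
          side_or_content = c("left", "right", "mouse", "object"),
          phase = c("habituation", "habituation", "test", "test"),
          approach_time_s = c(rtruncnorm0(2, hab_mean, g$sd_s),
                              rtruncnorm0(1, g$mouse_time_mean_s, g$sd_s),
                              rtruncnorm0(1, g$object_time_mean_s, g$sd_s)))
      }
    }
    tbl <- dplyr::bind_rows(rows)
    interaction_table(tbl$subject, tbl$group, tbl$side_or_content, tbl$phase,
                      tbl$approach_time_s)
  })
}
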