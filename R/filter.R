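# Preprocessing: software band-pass (matching the acquisition band),
# stimulus-artifact blanking, and the baseline derivative-RMS used as the
# detection threshold unit.

# direct-form IIR pass (numerator by convolution, denominator recursively)
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(numeric(nb - 1), x)
  z <- as.numeric(stats::filter(xp, b, method = "convolution",
                                sides = 1))[nb:length(xp)]
  as.numeric(stats::filter(z, -a[-1], method = "recursive"))
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a 2nd-order Butterworth band-pass forward and backward
#' (zero-phase, effective order 4) to every channel. Synthetic traces are
#' filtered through the same 100 Hz - 6 kHz band that acquisition hardware
#' applies to real recordings, so detection operates on the analyzed band in
#' either case.
#'
#' @param rec An `mua_recording`.
#' @param low_hz,high_hz Band edges, Hz. `fs` must exceed `2 * high_hz`.
#' @return A band-limited copy of `rec` with `meta$band` updated; length
#'   preserved.
#' @export
bandpass_filter <- function(rec, low_hz = 100, high_hz = 6000) {
  if (rec$fs <= 2 * high_hz) {
    abort(sprintf("fs = %g too low for a %g Hz band edge", rec$fs, high_hz))
  }
  bf <- signal::butter(2, c(low_hz, high_hz) / (rec$fs / 2), type = "pass")
  # zero-phase: forward + reversed pass, with reflection padding so edge
  # transients stay out of the trace
  pad <- min(ncol(rec$data) - 1, round(3 * rec$fs / low_hz))
  out <- rec
  for (ch in seq_len(rec$channel_count)) {
    x <- rec$data[ch, ]
    n <- length(x)
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    y <- iir_filter(bf$b, bf$a, xp)
    y <- rev(iir_filter(bf$b, bf$a, rev(y)))
    out$data[ch, ] <- y[(pad + 1):(pad + n)]
  }
  out$meta$band <- c(low_hz, high_hz)
  out$meta$precision <- "float64"
  out
}

#' Blank the stimulus artifact
#'
#' Replaces samples in `[stim, stim + artifact_blank_ms)` after every
#' stimulus with the channel's baseline mean (mean over the pre-stimulus
#' baseline windows), so detection can never fire inside the blanked spans.
#' Blank before filtering to keep the acausal filter from smearing the
#' artifact outside the blanked span.
#'
#' @param rec An `mua_recording`.
#' @param stim_times Stimulus onsets, seconds; defaults to the recording's.
#' @param artifact_blank_ms Blanking span, ms; 0 returns the trace unchanged.
#' @param baseline_window_s Pre-stimulus span used for the channel mean.
#' @return A blanked copy of `rec`.
#' @export
blank_artifact <- function(rec, stim_times = rec$stim_times,
                           artifact_blank_ms = 2, baseline_window_s = 0.5) {
  if (artifact_blank_ms == 0 || length(stim_times) == 0) return(rec)
  n <- ncol(rec$data)
  blank_idx <- unlist(lapply(stim_times, function(s) {
    i0 <- floor(s * rec$fs)
    i1 <- min(ceiling((s + artifact_blank_ms / 1000) * rec$fs) - 1, n - 1)
    if (i1 < i0) integer() else i0:i1
  })) + 1L
  if (length(blank_idx) == 0) return(rec)
  base_idx <- baseline_indices(rec, stim_times, baseline_window_s,
                               warn_skip = FALSE)
  out <- rec
  for (ch in seq_len(rec$channel_count)) {
    mu <- if (length(base_idx)) mean(rec$data[ch, base_idx]) else 0
    out$data[ch, blank_idx] <- mu
  }
  out
}

# sample indices (1-based) of the concatenated pre-stimulus baseline windows;
# windows that precede the trace start are skipped (with a warning if asked)
baseline_indices <- function(rec, stim_times, baseline_window_s,
                             warn_skip = TRUE) {
  idx <- integer()
  skipped <- 0
  for (s in stim_times) {
    i0 <- floor((s - baseline_window_s) * rec$fs)
    i1 <- floor(s * rec$fs) - 1
    if (i0 < 0) {
      skipped <- skipped + 1
      next
    }
    idx <- c(idx, i0:i1)
  }
  if (skipped > 0 && warn_skip) {
    warn(sprintf("%d baseline window(s) precede trace start; skipped",
                 skipped))
  }
  idx + 1L
}

#' Baseline RMS of the first derivative
#'
#' Per channel, the root mean square of the first derivative of the voltage
#' over the concatenated pre-stimulus baseline windows of all trials. This is
#' the unit in which the detection threshold is expressed.
#'
#' @param rec A band-limited `mua_recording`.
#' @param stim_times Stimulus onsets, seconds; defaults to the recording's.
#' @param baseline_window_s Span before each stimulus, seconds.
#' @return A tibble with columns `channel`, `rms_vps` (volts/second).
#' @export
baseline_rms <- function(rec, stim_times = rec$stim_times,
                         baseline_window_s = 0.5) {
  if (length(stim_times) == 0) abort("no stimuli; baseline undefined")
  idx <- baseline_indices(rec, stim_times, baseline_window_s)
  if (length(idx) == 0) abort("all baseline windows precede trace start")
  tibble(
    channel = seq_len(rec$channel_count),
    rms_vps = apply(rec$data[, idx, drop = FALSE], 1, function(v) {
      d <- diff(v) * rec$fs
      sqrt(mean(d^2))
    }))
}

#' Preprocess a recording for spike detection
#'
#' Standard order: blank the stimulus artifact on the raw trace, then apply
#' the zero-phase band-pass. Blanking first prevents the acausal filter from
#' spreading artifact energy backwards into the pre-stimulus baseline.
#'
#' @param rec An `mua_recording`.
#' @param cfg An [analysis_config()].
#' @return A band-limited, artifact-blanked `mua_recording`.
#' @export
preprocess_recording <- function(rec, cfg = analysis_config()) {
  blanked <- blank_artifact(rec, rec$stim_times, cfg$artifact_blank_ms,
                            cfg$baseline_window_s)
  bandpass_filter(blanked, rec$meta$band[1], rec$meta$band[2])
}
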