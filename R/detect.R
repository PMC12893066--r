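# Spike detection: first-derivative thresholding relative to baseline RMS,
# dead-time merging, 20%-of-peak waveform-duration measurement, and
# exclusion of waveforms wider than the duration cutoff.

#' Measure a waveform's duration by the 20%-of-peak rule
#'
#' The duration is the width of the contiguous region around the waveform's
#' absolute peak in which the rectified voltage stays at or above 20% of the
#' peak amplitude, in milliseconds. This is the rule used to exclude events
#' wider than the duration cutoff (the conventional marker of non-spike
#' transients).
#'
#' The extent of the waveform is first delimited on a three-point
#' moving-average envelope (so a single noisy sample cannot truncate a
#' slowly decaying waveform), then each boundary is refined inward to the
#' nearest raw sample at or above the 20% level. On clean waveforms this
#' reduces exactly to the contiguous 20%-of-peak width.
#'
#' @param segment Numeric voltage segment containing one event peak.
#' @param fs Sampling rate, Hz.
#' @param peak_at Optional index of the peak sample; defaults to the maximum
#'   of `abs(segment)`.
#' @return Duration in ms.
#' @export
measure_duration <- function(segment, fs, peak_at = NULL) {
  if (length(segment) < 2 || all(segment == segment[1])) {
    abort("undefined duration: flat segment")
  }
  a <- abs(segment)
  n <- length(a)
  p <- if (is.null(peak_at)) which.max(a) else peak_at
  lev <- 0.2 * a[p]
  sm <- a
  if (n >= 3) {
    sm[2:(n - 1)] <- (a[1:(n - 2)] + a[2:(n - 1)] + a[3:n]) / 3
  }
  l <- p
  while (l > 1 && sm[l - 1] >= lev) l <- l - 1
  r <- p
  while (r < n && sm[r + 1] >= lev) r <- r + 1
  while (l < p && a[l] < lev) l <- l + 1
  while (r > p && a[r] < lev) r <- r - 1
  (r - l + 1) / fs * 1000
}

#' Detect extracellular spikes on every channel
#'
#' Per channel: the first difference of the voltage (scaled by `fs`) is
#' thresholded at `threshold_multiplier` times the channel's baseline
#' derivative RMS; threshold crossings closer than `dead_time_ms` are merged
#' into one event timestamped at the extremal derivative sample; each event's
#' waveform duration is measured by the 20%-of-peak rule and events wider
#' than `duration_cutoff_ms` are discarded. Events inside artifact-blanked
#' spans are never reported. Channels with zero baseline RMS are skipped
#' with a warning.
#'
#' @param rec A band-limited, artifact-blanked `mua_recording` (see
#'   [preprocess_recording()]).
#' @param cfg An [analysis_config()].
#' @return A tibble of class `mua_spikes` with columns `channel`, `time_s`,
#'   `duration_ms`, `threshold_vps`, sorted by channel then time; the
#'   configuration used is attached as attribute `config`.
#' @export
detect_spikes <- function(rec, cfg = analysis_config()) {
  base <- baseline_rms(rec, rec$stim_times, cfg$baseline_window_s)
  dead_n <- max(1L, round(cfg$dead_time_ms / 1000 * rec$fs))
  seg_half <- max(3L, ceiling(cfg$duration_cutoff_ms * 2 / 1000 * rec$fs))
  n <- ncol(rec$data)
  blank_spans <- if (length(rec$stim_times)) {
    cbind(rec$stim_times, rec$stim_times + cfg$artifact_blank_ms / 1000)
  } else matrix(numeric(), ncol = 2)
  out <- vector("list", rec$channel_count)
  for (ch in seq_len(rec$channel_count)) {
    rms <- base$rms_vps[ch]
    if (rms == 0) {
      warn(sprintf("channel %d: zero baseline RMS; skipped", ch))
      out[[ch]] <- tibble(channel = integer(), time_s = numeric(),
                          duration_ms = numeric(), threshold_vps = numeric())
      next
    }
    thr <- cfg$threshold_multiplier * rms
    d <- diff(rec$data[ch, ]) * rec$fs
    cross <- switch(cfg$polarity,
                    abs = which(abs(d) > thr),
                    neg = which(d < -thr),
                    pos = which(d > thr))
    if (length(cross) == 0) {
      out[[ch]] <- tibble(channel = integer(), time_s = numeric(),
                          duration_ms = numeric(), threshold_vps = numeric())
      next
    }
    grp <- cumsum(c(1L, as.integer(diff(cross) >= dead_n)))
    ev_idx <- vapply(split(cross, grp),
                     function(ix) ix[which.max(abs(d[ix]))], integer(1))
    ev_idx <- unname(ev_idx)
    # waveform duration around each event's voltage peak
    dur <- vapply(ev_idx, function(i) {
      lo <- max(1L, i - seg_half)
      hi <- min(n, i + seg_half)
      seg <- rec$data[ch, lo:hi]
      if (all(seg == seg[1])) return(NA_real_)
      # peak = extremal voltage near the derivative extremum
      center <- i - lo + 1L
      win <- max(1L, center - dead_n):min(hi - lo + 1L, center + dead_n)
      p <- win[which.max(abs(seg[win]))]
      measure_duration(seg, rec$fs, peak_at = p)
    }, numeric(1))
    keep <- !is.na(dur) & dur <= cfg$duration_cutoff_ms
    ev_idx <- ev_idx[keep]
    dur <- dur[keep]
    t_ev <- ev_idx / rec$fs
    if (nrow(blank_spans)) {
      in_blank <- vapply(t_ev, function(t0) {
        any(t0 >= blank_spans[, 1] & t0 < blank_spans[, 2])
      }, logical(1))
      t_ev <- t_ev[!in_blank]
      dur <- dur[!in_blank]
    }
    out[[ch]] <- tibble(channel = ch, time_s = t_ev, duration_ms = dur,
                        threshold_vps = thr)
  }
  spikes <- dplyr::bind_rows(out)
  structure(spikes, config = cfg,
            class = c("mua_spikes", class(spikes)))
}

#' Write detected spikes to CSV
#' @param spikes An `mua_spikes` tibble.
#' @param path Output path; columns `channel,time_s,duration_ms`.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  readr::write_csv(spikes[c("channel", "time_s", "duration_ms")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a spike table written by [write_spikes()]
#' @param path CSV path.
#' @return An `mua_spikes` tibble (without a threshold column).
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("channel", "time_s", "duration_ms")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("format error: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  structure(as_tibble(tbl[need]), class = c("mua_spikes", class(tbl)))
}
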