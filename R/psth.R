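# Trial-aligned PSTHs, instantaneous-frequency and relative-probability
# curves, early/delayed windowing, downsampling, and slice -> group
# aggregation.

new_psth <- function(bin_edges, counts, n_channels, n_trials,
                     slice_id = "slice1", group = "unknown") {
  binw <- bin_edges[2] - bin_edges[1]
  structure(list(
    bin_edges_s = bin_edges,
    counts = as.numeric(counts),
    rate_hz = as.numeric(counts) / (n_channels * n_trials * binw),
    n_channels = n_channels,
    n_trials = n_trials,
    slice_id = slice_id,
    group = group
  ), class = "mua_psth")
}

#' @export
print.mua_psth <- function(x, ...) {
  cat(sprintf(
    "<mua_psth> %d bins of %g ms over [0, %g) s; %d spikes; %d ch x %d trials (%s / %s)\n",
    length(x$counts), diff(x$bin_edges_s[1:2]) * 1000,
    max(x$bin_edges_s), sum(x$counts), x$n_channels, x$n_trials,
    x$slice_id, x$group))
  invisible(x)
}

#' Align detected spikes to stimulus onsets
#'
#' Assigns each spike to the most recent stimulus and keeps it iff its
#' stimulus-relative time falls in the half-open analysis window
#' `[0, analysis_window_s)`. A spike at exactly the stimulus time is
#' retained at `t_rel = 0`.
#'
#' @param spikes An `mua_spikes` tibble (or any tibble with `channel`,
#'   `time_s`).
#' @param stim_times Stimulus onsets, seconds, strictly increasing.
#' @param analysis_window_s Post-stimulus span retained, seconds.
#' @return A tibble with columns `channel`, `trial`, `t_rel`.
#' @export
align_to_stimulus <- function(spikes, stim_times, analysis_window_s = 3.0) {
  if (length(stim_times) == 0) abort("no stimuli to align to")
  trial <- findInterval(spikes$time_s, stim_times)
  t_rel <- spikes$time_s - c(-Inf, stim_times)[trial + 1]
  keep <- trial >= 1 & t_rel >= 0 & t_rel < analysis_window_s
  tibble(channel = spikes$channel[keep], trial = trial[keep],
         t_rel = t_rel[keep])
}

#' Compute a peri-stimulus time histogram
#'
#' Pools aligned spikes over `bin_ms` bins covering
#' `[0, analysis_window_s)`. The instantaneous frequency of a bin is the
#' mean spike count per channel per trial divided by the bin width:
#' `rate_hz = counts / (n_channels * n_trials * bin_width)`.
#'
#' @param aligned Output of [align_to_stimulus()] (may contain zero spikes).
#' @param cfg An [analysis_config()].
#' @param n_channels,n_trials Averaging denominators (channels on the array,
#'   stimuli delivered); they cannot be inferred from `aligned` when some
#'   channels or trials are silent.
#' @param slice_id,group Metadata carried into downstream aggregation.
#' @return An object of class `mua_psth`.
#' @export
compute_psth <- function(aligned, cfg = analysis_config(),
                         n_channels, n_trials,
                         slice_id = "slice1", group = "unknown") {
  binw <- cfg$bin_ms / 1000
  nb <- round(cfg$analysis_window_s / binw)
  edges <- seq(0, by = binw, length.out = nb + 1)
  idx <- floor(aligned$t_rel / binw) + 1L
  idx <- idx[idx >= 1 & idx <= nb]
  counts <- tabulate(idx, nbins = nb)
  new_psth(edges, counts, n_channels, n_trials, slice_id, group)
}

#' Relative spiking probability curve
#'
#' Per-bin probability of eliciting a spike: the bin's pooled count divided
#' by the total pooled count over the full analysis window. A zero-total
#' PSTH yields an all-zero curve flagged degenerate (attribute
#' `degenerate`).
#'
#' @param psth An `mua_psth`.
#' @return Numeric vector of per-bin probabilities summing to 1 (or all zero
#'   if degenerate).
#' @export
relative_probability <- function(psth) {
  tot <- sum(psth$counts)
  if (tot == 0) {
    return(structure(rep(0, length(psth$counts)), degenerate = TRUE))
  }
  structure(psth$counts / tot, degenerate = FALSE)
}

#' Downsample a curve by an integer factor
#'
#' Aggregates non-overlapping groups of `factor` bins, summing for
#' probability-like curves (mass conserved) or averaging for frequency-like
#' curves (rate units preserved). If the curve length is not divisible by
#' `factor` the remainder bins are dropped with a warning.
#'
#' @param curve Numeric vector.
#' @param factor Integer >= 1; 1 is the identity.
#' @param mode `"sum"` (probabilities) or `"mean"` (frequencies).
#' @return The coarser numeric vector.
#' @export
downsample_curve <- function(curve, factor = 10L, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (factor < 1) abort("downsample factor must be >= 1")
  if (factor == 1) return(as.numeric(curve))
  n <- length(curve)
  rem <- n %% factor
  if (rem != 0) {
    warn(sprintf("curve length %d not divisible by %d; dropping %d bins",
                 n, factor, rem))
    curve <- curve[seq_len(n - rem)]
  }
  m <- matrix(curve, nrow = factor)
  if (mode == "sum") colSums(m) else colMeans(m)
}

#' Split a PSTH into early and delayed response windows
#'
#' Splits the instantaneous-frequency and relative-probability curves at the
#' configured window boundary (default 1.5 s; windows are half-open, so a
#' spike at exactly 1.5 s belongs to the delayed window), then downsamples
#' each window's curves by `cfg$downsample_factor` (probabilities summed,
#' frequencies averaged). Relative probability is normalized per slice over
#' the full analysis window by default (`cfg$prob_normalization`), or within
#' each window with `"window"`.
#'
#' @param psth An `mua_psth` covering the full analysis window.
#' @param cfg An [analysis_config()].
#' @return A tibble with one row per downsampled bin: `slice_id`, `group`,
#'   `window` (`"early"`/`"delayed"`), `bin`, `t_mid` (s), `freq_hz`,
#'   `prob`.
#' @export
window_response <- function(psth, cfg = analysis_config()) {
  binw <- diff(psth$bin_edges_s[1:2])
  span <- max(psth$bin_edges_s)
  if (abs(span - cfg$analysis_window_s) > binw / 2) {
    abort("config windows do not cover the PSTH span")
  }
  prob <- relative_probability(psth)
  windows <- list(early = cfg$early_window_s, delayed = cfg$delayed_window_s)
  mids <- psth$bin_edges_s[-length(psth$bin_edges_s)] + binw / 2
  purrr::map_dfr(names(windows), function(w) {
    iv <- windows[[w]]
    sel <- mids >= iv[1] & mids < iv[2]
    p <- prob[sel]
    if (cfg$prob_normalization == "window") {
      tot <- sum(p)
      if (tot > 0) p <- p / tot
    }
    f_ds <- downsample_curve(psth$rate_hz[sel], cfg$downsample_factor,
                             mode = "mean")
    p_ds <- downsample_curve(p, cfg$downsample_factor, mode = "sum")
    t_ds <- downsample_curve(mids[sel], cfg$downsample_factor, mode = "mean")
    tibble(slice_id = psth$slice_id, group = psth$group, window = w,
           bin = seq_along(p_ds), t_mid = t_ds, freq_hz = f_ds, prob = p_ds)
  })
}

#' Aggregate windowed slice responses to group-level curves
#'
#' Bin-wise mean and standard error across slices per group; slices are the
#' unit of independence (each slice is a distinct preparation).
#'
#' @param responses A tibble of stacked [window_response()] rows from one or
#'   more slices.
#' @return A tibble with columns `group`, `window`, `bin`, `t_mid`,
#'   `mean_freq_hz`, `sem_freq_hz`, `mean_prob`, `sem_prob`, `n_slices`.
#' @export
aggregate_slices <- function(responses) {
  if (nrow(responses) == 0) abort("no responses to aggregate")
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  responses |>
    dplyr::group_by(.data$group, .data$window, .data$bin) |>
    dplyr::summarise(
      t_mid = mean(.data$t_mid),
      mean_freq_hz = mean(.data$freq_hz),
      sem_freq_hz = sem(.data$freq_hz),
      mean_prob = mean(.data$prob),
      sem_prob = sem(.data$prob),
      n_slices = dplyr::n_distinct(.data$slice_id),
      .groups = "drop")
}

#' Full per-slice response from a preprocessed recording
#'
#' Convenience wrapper: detect spikes, align to stimuli, bin, window and
#' downsample in one call.
#'
#' @param rec A band-limited, artifact-blanked `mua_recording`.
#' @param cfg An [analysis_config()].
#' @param spikes Optional precomputed `mua_spikes` (skips detection).
#' @return A [window_response()] tibble for the slice.
#' @export
slice_response <- function(rec, cfg = analysis_config(), spikes = NULL) {
  if (is.null(spikes)) spikes <- detect_spikes(rec, cfg)
  aligned <- align_to_stimulus(spikes, rec$stim_times, cfg$analysis_window_s)
  psth <- compute_psth(aligned, cfg, rec$channel_count,
                       length(rec$stim_times),
                       slice_id = rec$meta$slice_id, group = rec$meta$group)
  window_response(psth, cfg)
}
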