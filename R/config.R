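#' Analysis configuration
#'
#' Bundles every tunable parameter of the evoked-MUA pipeline. Defaults follow
#' the standard protocol for evoked thalamic multi-unit analysis: 1-ms PSTH
#' bins over the first 3 s of each trial, an early response window of
#' \[0, 1.5) s and a delayed window of \[1.5, 3) s post-stimulus, 10-fold
#' downsampling of relative-probability curves before distributional
#' comparison, and exclusion of detected waveforms wider than 2 ms. All
#' windows are half-open \[a, b); times are seconds.
#'
#' @param bin_ms PSTH bin width in milliseconds.
#' @param analysis_window_s Post-stimulus span analyzed, seconds.
#' @param early_window_s Length-2 numeric, the half-open early-response window.
#' @param delayed_window_s Length-2 numeric, the half-open delayed-response
#'   window. Together with `early_window_s` it must partition
#'   `[0, analysis_window_s)`.
#' @param downsample_factor Integer fold for curve downsampling.
#' @param duration_cutoff_ms Maximum admissible spike waveform duration (ms);
#'   wider events are excluded.
#' @param threshold_multiplier Detection threshold in units of the baseline
#'   RMS of the first derivative.
#' @param dead_time_ms Refractory lockout: threshold crossings closer than
#'   this are merged into one event.
#' @param baseline_window_s Pre-stimulus span used for baseline RMS, seconds.
#' @param artifact_blank_ms Post-stimulus blanking span, milliseconds.
#' @param alpha Significance level used by the statistical layer.
#' @param polarity `"abs"` thresholds the absolute derivative (default);
#'   `"neg"`/`"pos"` threshold one polarity only.
#' @param prob_normalization `"slice"` (default) normalizes relative spiking
#'   probability over the full analysis window per slice; `"window"`
#'   normalizes within each response window.
#' @param kw_sample Sample unit fed to the Kruskal-Wallis omnibus test:
#'   `"bins"` pools per-slice downsampled window bins (default) or
#'   `"slices"` uses per-slice mean frequencies.
#'
#' @return An object of class `mua_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$bin_ms
#' @export
analysis_config <- function(bin_ms = 1,
                            analysis_window_s = 3.0,
                            early_window_s = c(0, 1.5),
                            delayed_window_s = c(1.5, 3.0),
                            downsample_factor = 10L,
                            duration_cutoff_ms = 2,
                            threshold_multiplier = 4.0,
                            dead_time_ms = 1,
                            baseline_window_s = 0.5,
                            artifact_blank_ms = 2,
                            alpha = 0.05,
                            polarity = c("abs", "neg", "pos"),
                            prob_normalization = c("slice", "window"),
                            kw_sample = c("bins", "slices")) {
  cfg <- list(
    bin_ms = bin_ms,
    analysis_window_s = analysis_window_s,
    early_window_s = as.numeric(early_window_s),
    delayed_window_s = as.numeric(delayed_window_s),
    downsample_factor = as.integer(downsample_factor),
    duration_cutoff_ms = duration_cutoff_ms,
    threshold_multiplier = threshold_multiplier,
    dead_time_ms = dead_time_ms,
    baseline_window_s = baseline_window_s,
    artifact_blank_ms = artifact_blank_ms,
    alpha = alpha,
    polarity = match.arg(polarity),
    prob_normalization = match.arg(prob_normalization),
    kw_sample = match.arg(kw_sample)
  )
  validate_config(cfg)
  structure(cfg, class = "mua_config")
}

validate_config <- function(cfg) {
  for (f in c("bin_ms", "analysis_window_s", "duration_cutoff_ms",
              "threshold_multiplier", "dead_time_ms", "baseline_window_s")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      abort(paste0(f, " must be a positive scalar"))
    }
  }
  if (cfg$artifact_blank_ms < 0) abort("artifact_blank_ms must be >= 0")
  if (cfg$downsample_factor < 1) abort("downsample_factor must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must be in (0, 1)")
  e <- cfg$early_window_s
  d <- cfg$delayed_window_s
  if (length(e) != 2 || length(d) != 2 || e[1] >= e[2] || d[1] >= d[2]) {
    abort("early/delayed windows must be increasing length-2 intervals")
  }
  if (e[2] > d[1] && d[2] > e[1] && !(e[2] <= d[1] || d[2] <= e[1])) {
    abort("windows overlap")
  }
  if (!(isTRUE(all.equal(e[1], 0)) &&
        isTRUE(all.equal(e[2], d[1])) &&
        isTRUE(all.equal(d[2], cfg$analysis_window_s)))) {
    abort("early and delayed windows must partition [0, analysis_window_s)")
  }
  invisible(cfg)
}

#' Load an analysis configuration from a structured-text file
#'
#' Reads a YAML key/value file and merges it over [analysis_config()]
#' defaults. Absent keys keep their defaults; unknown keys are ignored with a
#' warning; invariant violations (e.g. overlapping windows) are rejected.
#'
#' @param path Path to a YAML file. An empty file yields all defaults.
#' @return An `mua_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- analysis_config()
  known <- names(unclass(defaults))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warn(paste0("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(analysis_config, modifyList(list(), raw))
}

#' @export
print.mua_config <- function(x, ...) {
  cat("<mua_config>\n")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}
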