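# broom-style tidiers for the package's fitted/derived objects.

#' Tidy a PSTH into a per-bin tibble
#' @param x An `mua_psth`.
#' @param ... Unused.
#' @return A tibble with `t_mid`, `count`, `rate_hz`, `prob`.
#' @export
tidy.mua_psth <- function(x, ...) {
  binw <- diff(x$bin_edges_s[1:2])
  mids <- x$bin_edges_s[-length(x$bin_edges_s)] + binw / 2
  tibble(t_mid = mids, count = x$counts, rate_hz = x$rate_hz,
         prob = as.numeric(relative_probability(x)))
}

#' One-row PSTH summary
#' @param x An `mua_psth`.
#' @param ... Unused.
#' @return A tibble with slice metadata, totals and window means.
#' @export
glance.mua_psth <- function(x, ...) {
  binw <- diff(x$bin_edges_s[1:2])
  mids <- x$bin_edges_s[-length(x$bin_edges_s)] + binw / 2
  tibble(slice_id = x$slice_id, group = x$group,
         n_spikes = sum(x$counts),
         n_channels = x$n_channels, n_trials = x$n_trials,
         mean_rate_hz = mean(x$rate_hz),
         early_rate_hz = mean(x$rate_hz[mids < 1.5]),
         delayed_rate_hz = mean(x$rate_hz[mids >= 1.5]))
}

#' Tidy a plateau fit's coefficients
#' @param x A `plateau_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.plateau_fit <- function(x, ...) {
  tibble(term = c("y0", "ym", "k"), estimate = c(x$y0, x$ym, x$k))
}

#' One-row plateau-fit summary
#' @param x A `plateau_fit`.
#' @param ... Unused.
#' @return A tibble with fit statistics.
#' @export
glance.plateau_fit <- function(x, ...) {
  tibble(ss_resid = x$ss_resid, df_resid = x$df_resid,
         n_points = x$n_points, converged = x$converged)
}
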