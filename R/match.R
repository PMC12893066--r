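# Ground-truth validation: one-to-one matching of detected and true spike
# trains within a time tolerance.

#' Match detected spikes against ground truth
#'
#' One-to-one, per-channel matching of detected spike times to true spike
#' times within `tol_ms` (sorted two-pointer sweep). Recall is the matched
#' fraction of true spikes, precision the matched fraction of detections.
#' Optionally restricts both trains to the post-stimulus analysis windows
#' before matching, which is the span the pipeline analyzes.
#'
#' @param detected A tibble with `channel`, `time_s` (e.g. [detect_spikes()]
#'   output).
#' @param truth A tibble with `channel`, `time_s` (e.g. `truth$spikes` from
#'   [simulate_recording()]).
#' @param tol_ms Matching tolerance, ms.
#' @param stim_times,analysis_window_s If `stim_times` is non-NULL, only
#'   events within `[stim, stim + analysis_window_s)` of some stimulus are
#'   considered.
#' @return A one-row tibble: `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`.
#' @export
match_spike_trains <- function(detected, truth, tol_ms = 0.5,
                               stim_times = NULL, analysis_window_s = 3.0) {
  restrict <- function(tv) {
    if (is.null(stim_times)) return(rep(TRUE, length(tv)))
    out <- logical(length(tv))
    for (s in stim_times) {
      out <- out | (tv >= s & tv < s + analysis_window_s)
    }
    out
  }
  det <- detected[restrict(detected$time_s), c("channel", "time_s")]
  tru <- truth[restrict(truth$time_s), c("channel", "time_s")]
  tol <- tol_ms / 1000
  matched <- 0L
  for (ch in unique(tru$channel)) {
    td <- sort(det$time_s[det$channel == ch])
    tt <- sort(tru$time_s[tru$channel == ch])
    i <- 1L
    j <- 1L
    while (i <= length(td) && j <= length(tt)) {
      if (abs(td[i] - tt[j]) <= tol) {
        matched <- matched + 1L
        i <- i + 1L
        j <- j + 1L
      } else if (td[i] < tt[j]) {
        i <- i + 1L
      } else {
        j <- j + 1L
      }
    }
  }
  tibble(n_true = nrow(tru), n_detected = nrow(det), n_matched = matched,
         recall = if (nrow(tru)) matched / nrow(tru) else NA_real_,
         precision = if (nrow(det)) matched / nrow(det) else NA_real_)
}
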