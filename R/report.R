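# High-level behavioral reports combining the summary and test layers.

#' Grooming comparison report for two groups
#'
#' Student's t-tests on per-mouse total grooming time and episode counts,
#' a t-test on pooled per-episode durations (episodes as the unit), and the
#' extra-sum-of-squares F test of shared vs per-group exponential-plateau
#' fits to the cumulative duration-probability curves. Per-group plateau
#' rate constants are appended as `plateau-fit` rows.
#'
#' @param tbl An [episode_table()] with exactly two groups.
#' @param alpha Significance level.
#' @param all_subjects Optional subject roster (see [episode_summaries()]).
#' @return A tibble of test rows with an `endpoint` column.
#' @export
grooming_report <- function(tbl, alpha = 0.05, all_subjects = NULL) {
  grps <- unique(tbl$group)
  if (length(grps) != 2) abort("grooming report expects exactly two groups")
  s <- episode_summaries(tbl, all_subjects)
  ps <- s$per_subject
  row_of <- function(col, endpoint) {
    a <- ps[[col]][ps$group == grps[1]]
    b <- ps[[col]][ps$group == grps[2]]
    out <- t_test_independent(a, b, alpha = alpha,
                              comparison = paste(grps[1], "vs", grps[2]))
    out$endpoint <- endpoint
    out
  }
  dur_a <- s$durations$duration_s[s$durations$group == grps[1]]
  dur_b <- s$durations$duration_s[s$durations$group == grps[2]]
  dur_row <- t_test_independent(dur_a, dur_b, alpha = alpha,
                                comparison = paste(grps[1], "vs", grps[2]))
  dur_row$endpoint <- "episode_duration"
  cmp <- compare_duration_curves(tbl, alpha = alpha)
  f_row <- cmp$test
  f_row$endpoint <- "duration_curve"
  k_rows <- purrr::map_dfr(names(cmp$per_group), function(g) {
    f <- cmp$per_group[[g]]
    out <- test_row("plateau-fit", g, f$k, p_raw = NA_real_, alpha = alpha,
                    note = sprintf("y0=%.4g ym=%.4g", f$y0, f$ym))
    out$endpoint <- "duration_curve"
    out
  })
  dplyr::bind_rows(row_of("total_time_s", "total_time"),
                   row_of("n_episodes", "n_episodes"),
                   dur_row, f_row, k_rows)
}
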