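# Independent brute-force / closed-form oracles used to check the
# statistical layer, plus small fixture builders.

# KS D by exhaustive ECDF evaluation at all pooled points
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  Fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(Fa - Fb))
}

# tie-corrected Kruskal-Wallis H from the definition
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  g <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn z for one pair from the definition
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  g <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  (rbar[[i]] - rbar[[j]]) /
    sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
}

# pooled-variance t from the closed form
oracle_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# small, fast simulation config for pipeline tests
tiny_sim <- function(...) {
  args <- utils::modifyList(
    list(channel_count = 4, n_trials = 3, isi_s = 4, pre_s = 1), list(...))
  do.call(sim_config, args)
}

# render a clean spike template into a zero trace at time t0 (s)
clean_template_trace <- function(width_ms, amp, fs = 25000, dur_s = 0.2,
                                 t0 = 0.05) {
  x <- numeric(round(dur_s * fs))
  evokedmua:::render_spike(x, t0, width_ms, amp, fs)
}

# draw aligned homogeneous-Poisson spikes directly (PSTH-level fixture)
poisson_aligned <- function(rate_hz, n_channels, n_trials, window_s = 3) {
  rows <- list()
  for (ch in seq_len(n_channels)) {
    for (tr in seq_len(n_trials)) {
      n <- rpois(1, rate_hz * window_s)
      if (n > 0) {
        rows[[length(rows) + 1]] <-
          tibble::tibble(channel = ch, trial = tr,
                         t_rel = sort(runif(n, 0, window_s)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) tibble::tibble(channel = integer(), trial = integer(),
                                     t_rel = numeric()) else out
}
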