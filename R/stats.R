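# Group-comparison layer: two-sample KS with Bonferroni over pairwise
# contrasts, Kruskal-Wallis omnibus with Dunn's post hoc, pooled-variance
# t-test with a Shapiro-Wilk normality gate.

test_row <- function(test, comparison, statistic, df1 = NA_real_,
                     df2 = NA_real_, p_raw, p_adjusted = p_raw,
                     correction = "none", alpha = 0.05,
                     note = NA_character_) {
  tibble(test = test, comparison = comparison, statistic = statistic,
         df1 = df1, df2 = df2, p_raw = p_raw, p_adjusted = p_adjusted,
         correction = correction, alpha = alpha, note = note)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with a two-sided p-value; the asymptotic
#' approximation is used by default, the exact distribution optionally for
#' small tie-free samples.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param exact Use the exact p for small samples (passed to
#'   [stats::ks.test()]); default asymptotic.
#' @param alpha Significance level recorded in the result.
#' @param comparison Label for the contrast.
#' @return A one-row test tibble (`test`, `comparison`, `statistic` = D,
#'   `p_raw`, `p_adjusted`, ...).
#' @export
ks_two_sample <- function(a, b, exact = FALSE, alpha = 0.05,
                          comparison = "a vs b") {
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample must have n >= 2")
  }
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  test_row("ks", comparison, unname(res$statistic), p_raw = res$p.value,
           alpha = alpha)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`, order preserved; `m` defaults to the family
#' size `length(p_values)`.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param m Family size.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  pmin(1, m * p_values)
}

#' Kruskal-Wallis omnibus rank test
#'
#' Tie-corrected H with a chi-square p on k - 1 degrees of freedom. If all
#' values are identical across groups the test is degenerate: H = 0, p = 1,
#' flagged in `note`.
#'
#' @param groups A list of numeric samples (>= 2 groups, total n >= 3).
#' @param alpha Significance level recorded in the result.
#' @return A one-row test tibble with `statistic` = H, `df1` = k - 1.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) abort("need >= 2 groups")
  if (any(lengths(groups) < 1) || sum(lengths(groups)) < 3) {
    abort("each group needs n >= 1 and total n >= 3")
  }
  x <- unlist(groups)
  if (length(unique(x)) == 1) {
    return(test_row("kruskal-wallis", "omnibus", 0,
                    df1 = length(groups) - 1, p_raw = 1, alpha = alpha,
                    note = "degenerate: all values identical"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::kruskal.test(x, g)
  test_row("kruskal-wallis", "omnibus", unname(res$statistic),
           df1 = unname(res$parameter), p_raw = res$p.value, alpha = alpha)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on pooled mean ranks with tie correction,
#' following a Kruskal-Wallis omnibus test:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values are
#' adjusted with Bonferroni over the `k(k-1)/2` contrasts.
#'
#' @param groups A named list of >= 3 numeric samples.
#' @param alpha Significance level recorded in the results.
#' @return A tibble with one row per pairwise contrast.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 3) {
    abort("Dunn's test needs >= 3 groups; use a two-sample test instead")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    test_row("dunn", paste(i, "vs", j), z, p_raw = p, alpha = alpha)
  })
  rows$p_adjusted <- bonferroni(rows$p_raw, m = length(pairs))
  rows$correction <- "bonferroni"
  rows
}

#' Student's (pooled-variance) independent-samples t-test
#'
#' Two-sided pooled-variance t with `df = n_a + n_b - 2`. Degenerate input
#' (zero pooled variance with equal means) gives t = 0, p = 1, flagged.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param alpha Significance level recorded in the result.
#' @param comparison Label for the contrast.
#' @return A one-row test tibble with `statistic` = t, `df1` = df.
#' @export
t_test_independent <- function(a, b, alpha = 0.05, comparison = "a vs b") {
  if (length(a) < 2 || length(b) < 2) abort("each sample must have n >= 2")
  df <- length(a) + length(b) - 2
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(test_row("t", comparison, 0, df1 = df, p_raw = 1, alpha = alpha,
                      note = "degenerate: zero pooled variance"))
    }
    return(test_row("t", comparison, Inf * sign(mean(a) - mean(b)), df1 = df,
                    p_raw = 0, alpha = alpha,
                    note = "degenerate: zero variance, distinct means"))
  }
  res <- stats::t.test(a, b, var.equal = TRUE)
  test_row("t", comparison, unname(res$statistic),
           df1 = unname(res$parameter), p_raw = res$p.value, alpha = alpha)
}

#' Shapiro-Wilk normality check
#'
#' Gate used before Student's t-tests; a p below `alpha` produces a warning
#' (the pipeline does not abort, matching the practice of reporting the
#' parametric test alongside the gate).
#'
#' @param sample Numeric, 3 <= n <= 5000.
#' @param alpha Warning threshold.
#' @param label Sample label used in the warning.
#' @return A one-row test tibble with `statistic` = W.
#' @export
normality_check <- function(sample, alpha = 0.05, label = "sample") {
  if (length(sample) < 3 || length(sample) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (length(unique(sample)) == 1) {
    abort("degenerate sample: all values identical")
  }
  res <- stats::shapiro.test(sample)
  if (res$p.value < alpha) {
    warn(sprintf("normality rejected for %s (Shapiro-Wilk p = %.3g)",
                 label, res$p.value))
  }
  test_row("shapiro-wilk", label, unname(res$statistic),
           p_raw = res$p.value, alpha = alpha)
}

#' Compare groups on evoked-response curves
#'
#' The full statistical layer for windowed slice responses. Per response
#' window (early, delayed): (1) pairwise two-sample KS tests on the
#' group-mean downsampled relative-probability curves, Bonferroni-corrected
#' over the `k(k-1)/2` contrasts; (2) a Kruskal-Wallis omnibus test on
#' absolute instantaneous frequencies (per-slice downsampled window bins
#' pooled per group by default, per-slice means with
#' `cfg$kw_sample = "slices"`), followed by Dunn's post hoc when k >= 3.
#' With two groups the Kruskal-Wallis/Dunn step is skipped in favor of the
#' KS contrast (noted in the result).
#'
#' @param responses A tibble of stacked [window_response()] rows across
#'   slices and groups.
#' @param cfg An [analysis_config()].
#' @return A tibble of test rows with a `window` column.
#' @export
compare_groups_ephys <- function(responses, cfg = analysis_config()) {
  grps <- unique(responses$group)
  k <- length(grps)
  if (k < 2) abort("need >= 2 groups")
  m <- k * (k - 1) / 2
  purrr::map_dfr(unique(responses$window), function(w) {
    sub <- responses[responses$window == w, ]
    agg <- aggregate_slices(sub)
    # (1) pairwise KS on group-mean downsampled probability curves
    ks_rows <- purrr::map_dfr(utils::combn(grps, 2, simplify = FALSE),
                              function(pr) {
      a <- agg$mean_prob[agg$group == pr[1]]
      b <- agg$mean_prob[agg$group == pr[2]]
      ks_two_sample(a, b, alpha = cfg$alpha,
                    comparison = paste(pr[1], "vs", pr[2]))
    })
    ks_rows$p_adjusted <- bonferroni(ks_rows$p_raw, m = m)
    ks_rows$correction <- if (m > 1) "bonferroni" else "none"
    # (2) omnibus KW + Dunn on frequency samples
    freq_samples <- lapply(grps, function(g) {
      gs <- sub[sub$group == g, ]
      if (cfg$kw_sample == "bins") {
        gs$freq_hz
      } else {
        tapply(gs$freq_hz, gs$slice_id, mean)
      }
    })
    names(freq_samples) <- grps
    rank_rows <- if (k >= 3) {
      dplyr::bind_rows(kruskal_wallis(freq_samples, alpha = cfg$alpha),
                       dunn_posthoc(freq_samples, alpha = cfg$alpha))
    } else {
      test_row("kruskal-wallis", "omnibus", NA_real_, p_raw = NA_real_,
               alpha = cfg$alpha,
               note = "skipped: two groups, see KS contrast")
    }
    out <- dplyr::bind_rows(ks_rows, rank_rows)
    out$window <- w
    out[, c("window", setdiff(names(out), "window"))]
  })
}
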