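# The statistical layer against brute-force / closed-form oracles, plus its
# structural behavior (correction families, degenerate input, gating).

test_that("KS statistic matches the exhaustive ECDF oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p_raw, 1)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  set.seed(101)
  for (i in 1:5) {
    a <- runif(150)
    b <- runif(150) + 0.15
    r <- ks_two_sample(a, b)
    expect_equal(r$statistic, oracle_ks_D(a, b), tolerance = 1e-12)
    expect_true(r$p_raw >= 0 && r$p_raw <= 1)
  }
  expect_error(ks_two_sample(1, 1:5), "n >= 2")
})

test_that("Bonferroni adjustment is the clamped product", {
  expect_equal(bonferroni(c(0.01, 0.02, 0.5), m = 3), c(0.03, 0.06, 1.0))
  expect_equal(bonferroni(c(0.2, 0.7), m = 1), c(0.2, 0.7))
  set.seed(103)
  p <- runif(20)
  adj <- bonferroni(p, m = 7)
  expect_true(all(adj >= p & adj <= 1))
  expect_equal(order(adj), order(pmin(1, 7 * p)))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Kruskal-Wallis H matches the tie-corrected rank oracle", {
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_lt(kruskal_wallis(same)$statistic, 1e-10)

  g <- list(c(1, 2, 3), c(101, 102, 103), c(201, 202, 203))
  r <- kruskal_wallis(g)
  expect_equal(r$statistic, oracle_kw_H(g), tolerance = 1e-12)
  expect_equal(r$df1, 2)

  ties <- list(c(1, 1, 2, 2), c(2, 2, 3), c(1, 3, 3, 3))
  expect_equal(kruskal_wallis(ties)$statistic, oracle_kw_H(ties),
               tolerance = 1e-12)

  degen <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_raw, 1)
  expect_match(degen$note, "degenerate")
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
})

test_that("Dunn z matches the closed form and controls its family", {
  g <- list(a = c(1, 5, 8), b = c(2, 2, 9, 4), c = c(7, 7, 7))
  r <- dunn_posthoc(g)
  expect_equal(nrow(r), 3)  # k(k-1)/2
  expect_equal(r$statistic[r$comparison == "a vs b"],
               oracle_dunn_z(g, 1, 2), tolerance = 1e-12)
  expect_equal(r$statistic[r$comparison == "b vs c"],
               oracle_dunn_z(g, 2, 3), tolerance = 1e-12)
  expect_equal(r$p_adjusted, pmin(1, 3 * r$p_raw))

  same <- list(x = c(1, 2, 3), y = c(1, 2, 3), z = c(1, 2, 3))
  rs <- dunn_posthoc(same)
  expect_true(all(abs(rs$statistic) < 1e-10))
  expect_true(all(rs$p_adjusted == 1))
  expect_error(dunn_posthoc(list(1:3, 4:6)), ">= 3 groups")
})

test_that("a clearly shifted group is flagged by Dunn, the third is not", {
  set.seed(107)
  hits <- c(ab = 0, ac = 0, bc = 0)
  reps <- 20
  for (i in 1:reps) {
    g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, mean = 1.5))
    r <- dunn_posthoc(g)
    sig <- r$p_adjusted < 0.05
    hits["ac"] <- hits["ac"] + sig[r$comparison == "a vs c"]
    hits["bc"] <- hits["bc"] + sig[r$comparison == "b vs c"]
    hits["ab"] <- hits["ab"] + sig[r$comparison == "a vs b"]
  }
  expect_gte(hits[["ac"]] / reps, 0.95)
  expect_gte(hits[["bc"]] / reps, 0.95)
  expect_lte(hits[["ab"]] / reps, 0.2)
})

test_that("pooled t matches the closed form and is antisymmetric", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  r <- t_test_independent(a, b)
  expect_equal(r$statistic, oracle_pooled_t(a, b), tolerance = 1e-12)
  expect_equal(r$df1, 4)
  r2 <- t_test_independent(b, a)
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_raw, r$p_raw)

  same <- t_test_independent(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)
  set.seed(109)
  x <- rnorm(8); y <- rnorm(11, 0.3)
  expect_equal(t_test_independent(x, y)$statistic, oracle_pooled_t(x, y),
               tolerance = 1e-12)
  expect_equal(t_test_independent(x, y)$df1, 17)
})

test_that("the Shapiro-Wilk gate separates Gaussian from exponential", {
  set.seed(113)
  reps <- 20
  gauss_pass <- exp_fail <- 0
  for (i in 1:reps) {
    g <- rnorm(300)
    r <- normality_check(g)
    gauss_pass <- gauss_pass + (r$p_raw > 0.05)
    e <- rexp(300)
    expect_warning(re <- normality_check(e), "normality rejected")
    exp_fail <- exp_fail + (re$p_raw < 0.05)
  }
  expect_gte(gauss_pass / reps, 0.9)
  expect_gte(exp_fail / reps, 0.9)
  expect_error(normality_check(rep(1, 10)), "degenerate")
  expect_error(normality_check(c(1, 2)), "3 <= n")
})

test_that("the ephys comparison layer assembles the right families", {
  psths <- simulate_psth_counts(c("WT-like" = 3, "KOxMG-like" = 3,
                                  "WTxMG-like" = 3), seed = 127)
  cfg <- analysis_config()
  wr <- purrr::map_dfr(psths, window_response, cfg = cfg)
  res <- compare_groups_ephys(wr, cfg)
  for (w in c("early", "delayed")) {
    sub <- res[res$window == w, ]
    expect_equal(sum(sub$test == "ks"), 3)           # k(k-1)/2 contrasts
    expect_equal(sum(sub$test == "kruskal-wallis"), 1)
    expect_equal(sum(sub$test == "dunn"), 3)
    ks <- sub[sub$test == "ks", ]
    expect_equal(ks$p_adjusted, pmin(1, 3 * ks$p_raw))
  }
  # two groups: KS only, m = 1, rank tests skipped with a note
  wr2 <- wr[wr$group != "WTxMG-like", ]
  res2 <- compare_groups_ephys(wr2, cfg)
  ks2 <- res2[res2$test == "ks", ]
  expect_equal(ks2$p_adjusted, ks2$p_raw)
  expect_true(all(res2$correction[res2$test == "ks"] == "none"))
  kw2 <- res2[res2$test == "kruskal-wallis", ]
  expect_match(kw2$note, "skipped")
  expect_false("dunn" %in% res2$test)
})
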