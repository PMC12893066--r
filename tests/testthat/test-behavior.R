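# Grooming summaries, duration-probability curves, plateau fitting, the
# extra-sum-of-squares F test and sociability ratios.

test_that("episode summaries total correctly and keep silent subjects", {
  tbl <- episode_table(subject = c("m1", "m1", "m1", "m2"),
                       group = c("KO", "KO", "KO", "WT"),
                       onset_s = c(10, 100, 200, 50),
                       duration_s = c(2, 3, 5, 4))
  s <- episode_summaries(tbl)
  m1 <- s$per_subject[s$per_subject$subject == "m1", ]
  expect_equal(m1$total_time_s, 10)
  expect_equal(m1$n_episodes, 3L)
  expect_equal(nrow(s$durations), 4)

  roster <- tibble::tibble(subject = c("m1", "m2", "m3"),
                           group = c("KO", "WT", "WT"))
  s2 <- episode_summaries(tbl, all_subjects = roster)
  m3 <- s2$per_subject[s2$per_subject$subject == "m3", ]
  expect_equal(m3$total_time_s, 0)
  expect_equal(m3$n_episodes, 0L)

  empty <- episode_table()
  s3 <- episode_summaries(empty)
  expect_equal(nrow(s3$per_subject), 0)
})

test_that("the duration-probability curve is a proper ECDF", {
  cv <- duration_probability_curve(c(1, 2, 3))
  expect_equal(cv$t, c(1, 2, 3))
  expect_equal(cv$p, c(1, 2, 3) / 3)

  cv2 <- duration_probability_curve(c(4, 4, 4))
  expect_equal(nrow(cv2), 1)
  expect_equal(cv2$p, 1)

  set.seed(131)
  d <- rexp(500, rate = 1 / 8)
  cv3 <- duration_probability_curve(d)
  expect_true(all(diff(cv3$p) > 0))
  expect_equal(cv3$p[nrow(cv3)], 1)
  # Glivenko-Cantelli: close to the generating exponential CDF in sup norm
  expect_lt(max(abs(cv3$p - (1 - exp(-cv3$t / 8)))), 0.05)
  expect_error(duration_probability_curve(c(1, 2)), ">= 3")
})

test_that("plateau fitting recovers noiseless parameters to 1e-6", {
  t <- seq(0, 60, length.out = 50)
  y <- 1 - (1 - 0) * exp(-0.1 * t)
  fit <- fit_exponential_plateau(tibble::tibble(t = t, y = y))
  expect_true(fit$converged)
  expect_lt(abs(fit$y0 - 0), 1e-6)
  expect_lt(abs(fit$ym - 1) / 1, 1e-6)
  expect_lt(abs(fit$k - 0.1) / 0.1, 1e-6)
  expect_equal(fit$df_resid, 47)
  expect_lt(fit$ss_resid, 1e-12)
})

test_that("plateau fitting reaches the grid-search global minimum", {
  t <- seq(0, 20, length.out = 40)
  y <- plateau_y <- 0.9 - (0.9 - 0.2) * exp(-0.5 * t)
  fit <- fit_exponential_plateau(tibble::tibble(t = t, y = y))
  grid <- expand.grid(y0 = seq(0, 0.5, by = 0.05),
                      ym = seq(0.5, 1.2, by = 0.05),
                      k = exp(seq(log(0.01), log(5), length.out = 40)))
  ss_grid <- apply(grid, 1, function(p) {
    sum((y - (p[2] - (p[2] - p[1]) * exp(-p[3] * t)))^2)
  })
  expect_lte(fit$ss_resid, min(ss_grid) + 1e-12)
})

test_that("flat data is flagged as unidentifiable, not mis-fit", {
  t <- seq(0, 10, length.out = 20)
  fit <- fit_exponential_plateau(tibble::tibble(t = t, y = rep(0.7, 20)))
  # ym collapses to the constant; residuals vanish
  expect_lt(abs(fit$ym - 0.7), 1e-6)
  expect_lt(fit$ss_resid, 1e-12)
  expect_false(fit$k_identifiable)
  expect_error(fit_exponential_plateau(tibble::tibble(t = 1:3, y = 1:3)),
               ">= 4")
})

test_that("fixing y0 reduces the parameter count and df bookkeeping", {
  t <- seq(0, 30, length.out = 30)
  y <- 1 - exp(-0.2 * t)
  fit <- fit_exponential_plateau(tibble::tibble(t = t, y = y), y0_fixed = 0)
  expect_equal(fit$y0, 0)
  expect_equal(fit$df_resid, 28)
  expect_lt(abs(fit$k - 0.2) / 0.2, 1e-6)
})

test_that("extra-SS F has 3(k-1) numerator df and F = 0 when fits tie", {
  set.seed(137)
  mk_fit <- function(k, n = 30, noise = 0.02) {
    t <- seq(0, 40, length.out = n)
    y <- 1 - exp(-k * t) + rnorm(n, sd = noise)
    fit_exponential_plateau(tibble::tibble(t = t, y = y))
  }
  f1 <- mk_fit(0.1)
  f2 <- mk_fit(0.3)
  pooled <- dplyr::bind_rows(f1$data, f2$data)
  shared <- fit_exponential_plateau(pooled)
  res <- extra_ss_f_test(shared, list(f1, f2))
  expect_equal(res$df1, 3)  # 3 (k_groups - 1)
  expect_equal(res$df2, f1$df_resid + f2$df_resid)
  expect_true(res$statistic >= 0)

  # identical shared and separate SS -> F = 0 exactly
  fake <- function(ss, df, n) {
    structure(list(y0 = 0, ym = 1, k = 1, ss_resid = ss, df_resid = df,
                   n_points = n, converged = TRUE,
                   data = tibble::tibble(t = numeric(n), y = numeric(n))),
              class = "plateau_fit")
  }
  r0 <- extra_ss_f_test(fake(2, 57, 60), list(fake(1, 27, 30),
                                              fake(1, 27, 30)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_raw, 1)
})

test_that("the duration-curve comparison separates 3-fold rate constants", {
  set.seed(139)
  reps <- 15
  f_null <- f_alt <- numeric(reps)
  alt_rej <- 0
  subj <- rep(c("a1", "a2", "b1", "b2"), each = 25)
  grp <- rep(c("A", "B"), each = 50)
  ons <- rep(seq(1, 1100, length.out = 25), 4)
  clamp <- function(d) pmax(pmin(d, 40), 0.05)
  for (i in 1:reps) {
    d_null <- episode_table(subject = subj, group = grp, onset_s = ons,
                            duration_s = clamp(rexp(100, 1 / 8)))
    f_null[i] <- compare_duration_curves(d_null)$test$statistic
    d_alt <- episode_table(subject = subj, group = grp, onset_s = ons,
                           duration_s = clamp(c(rexp(50, 1 / 4),
                                                rexp(50, 1 / 12))))
    r2 <- compare_duration_curves(d_alt)
    f_alt[i] <- r2$test$statistic
    alt_rej <- alt_rej + (r2$test$p_raw < 0.05)
  }
  # ECDF points are serially correlated, so the F reference distribution is
  # only an ordering device here; a genuine rate-constant contrast must
  # still dominate the null clearly and be flagged essentially always
  expect_gte(alt_rej / reps, 0.9)
  expect_gt(median(f_alt), 5 * median(f_null))
})

test_that("sociability ratios compute, exclude zero denominators, and test", {
  tbl <- interaction_table(
    subject = rep(c("m1", "m2"), each = 4),
    group = rep(c("KO", "WT"), each = 4),
    side_or_content = rep(c("left", "right", "mouse", "object"), 2),
    phase = rep(c("habituation", "habituation", "test", "test"), 2),
    approach_time_s = c(30, 30, 120, 60, 20, 25, 0.0, 50))
  r <- sociability_ratios(tbl)
  expect_equal(r$ratios$ratio[r$ratios$subject == "m1" &
                              r$ratios$phase == "habituation"], 1)
  expect_equal(r$ratios$ratio[r$ratios$subject == "m1" &
                              r$ratios$phase == "test"], 2)

  tbl0 <- interaction_table(
    subject = rep("m3", 4), group = rep("KO", 4),
    side_or_content = c("left", "right", "mouse", "object"),
    phase = c("habituation", "habituation", "test", "test"),
    approach_time_s = c(0, 10, 50, 60))
  expect_warning(r0 <- sociability_ratios(tbl0), "zero left")
  expect_false("habituation" %in% r0$ratios$phase)
})

test_that("a preference contrast is detected across groups", {
  set.seed(149)
  reps <- 20
  hits <- 0
  groups <- tibble::tibble(group = c("A", "B"), n_mice = c(9L, 8L),
                           mouse_time_mean_s = c(90, 60),
                           object_time_mean_s = c(60, 90), sd_s = 15)
  for (i in 1:reps) {
    tbl <- simulate_sociability(groups, seed = 1000 + i)
    r <- suppressWarnings(sociability_ratios(tbl))
    tt <- r$tests[r$tests$test == "t" & r$tests$phase == "test", ]
    hits <- hits + (tt$p_raw < 0.05)
  }
  expect_gte(hits / reps, 0.8)
})
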