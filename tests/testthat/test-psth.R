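# Alignment, PSTH binning and averaging, relative probability,
# downsampling, windowing and slice aggregation.

test_that("alignment uses half-open windows and drops late spikes", {
  stim <- c(1, 5)
  sp <- tibble::tibble(channel = rep(1L, 5),
                       time_s = c(1.0, 2.0, 4.2, 5.0 + 1.5, 9.0))
  al <- align_to_stimulus(sp, stim, 3)
  # stim+0 retained at 0; stim+3.2 dropped; 1.5 lands in trial 2
  expect_equal(nrow(al), 3)
  expect_equal(al$t_rel, c(0, 1, 1.5))
  expect_equal(al$trial, c(1L, 1L, 2L))
  expect_error(align_to_stimulus(sp, numeric()), "no stimuli")
  # a spike before the first stimulus is dropped
  expect_equal(nrow(align_to_stimulus(
    tibble::tibble(channel = 1L, time_s = 0.5), stim, 3)), 0)
})

test_that("PSTH counts are conserved and the averaging rule is exact", {
  cfg <- analysis_config()
  # zero spikes -> all-zero curve
  empty <- tibble::tibble(channel = integer(), trial = integer(),
                          t_rel = numeric())
  p0 <- compute_psth(empty, cfg, 16, 10)
  expect_true(all(p0$counts == 0))
  expect_true(all(p0$rate_hz == 0))

  # one spike at 10 ms in one channel/trial of a 16-ch, 10-trial session
  one <- tibble::tibble(channel = 3L, trial = 2L, t_rel = 0.0104)
  p1 <- compute_psth(one, cfg, 16, 10)
  expect_equal(sum(p1$counts), 1)
  expect_equal(p1$rate_hz[11], 1 / (16 * 10 * 0.001))
  expect_equal(sum(p1$rate_hz > 0), 1)

  # conservation on a random aligned set
  set.seed(61)
  al <- poisson_aligned(20, 4, 5)
  p <- compute_psth(al, cfg, 4, 5)
  expect_identical(sum(p$counts), as.numeric(nrow(al)))
})

test_that("homogeneous Poisson input recovers its rate", {
  set.seed(67)
  al <- poisson_aligned(50, 16, 20)
  p <- compute_psth(al, analysis_config(), 16, 20)
  expect_lt(abs(mean(p$rate_hz) - 50) / 50, 0.1)
})

test_that("relative probability normalizes and flags degenerate input", {
  cfg <- analysis_config()
  one <- compute_psth(tibble::tibble(channel = 1L, trial = 1L, t_rel = 0.5),
                      cfg, 1, 1)
  pr <- relative_probability(one)
  expect_equal(max(pr), 1)
  expect_equal(sum(pr), 1)

  set.seed(71)
  al <- poisson_aligned(30, 4, 5)
  pr2 <- relative_probability(compute_psth(al, cfg, 4, 5))
  expect_equal(sum(pr2), 1)
  expect_false(attr(pr2, "degenerate"))

  empty <- compute_psth(tibble::tibble(channel = integer(),
                                       trial = integer(),
                                       t_rel = numeric()), cfg, 4, 5)
  pr3 <- relative_probability(empty)
  expect_true(all(pr3 == 0))
  expect_true(attr(pr3, "degenerate"))
})

test_that("downsampling conserves mass, preserves constants, validates", {
  x <- runif(1500)
  expect_identical(downsample_curve(x, 1), x)
  d <- downsample_curve(x, 10, mode = "sum")
  expect_length(d, 150)
  expect_equal(sum(d), sum(x))
  k <- downsample_curve(rep(3.5, 100), 10, mode = "mean")
  expect_true(all(k == 3.5))
  expect_error(downsample_curve(x, 0), "factor")
  expect_warning(downsample_curve(runif(105), 10), "dropping")
})

test_that("windowing partitions mass at the half-open 1.5-s boundary", {
  cfg <- analysis_config()
  al <- tibble::tibble(channel = c(1L, 1L), trial = c(1L, 1L),
                       t_rel = c(0.4, 1.5))
  p <- compute_psth(al, cfg, 2, 3, slice_id = "sx", group = "gx")
  wr <- window_response(p, cfg)
  expect_equal(sum(wr$prob), 1)
  expect_equal(sum(wr$prob[wr$window == "early"]), 0.5)
  expect_equal(sum(wr$prob[wr$window == "delayed"]), 0.5)
  expect_equal(nrow(wr), 300)  # 150 downsampled bins per window
  # the spike at exactly 1.5 s counts in the delayed window
  dl <- wr[wr$window == "delayed", ]
  expect_equal(sum(dl$freq_hz > 0), 1)
  # silent delayed window stays zero
  al2 <- tibble::tibble(channel = 1L, trial = 1L, t_rel = 0.2)
  wr2 <- window_response(compute_psth(al2, cfg, 2, 3), cfg)
  expect_true(all(wr2$freq_hz[wr2$window == "delayed"] == 0))
})

test_that("an early-only condition puts its probability mass early", {
  psths <- simulate_psth_counts(c("WT-like" = 1), seed = 73,
                                sim_overrides = list(delayed_rate_hz = 0))
  wr <- window_response(psths[[1]], analysis_config())
  expect_gte(sum(wr$prob[wr$window == "early"]), 0.99)
})

test_that("the pipeline is invariant to channel and trial order", {
  set.seed(79)
  al <- poisson_aligned(25, 4, 4)
  cfg <- analysis_config()
  p <- compute_psth(al, cfg, 4, 4)
  perm <- al[sample(nrow(al)), ]
  perm$channel <- c(3L, 1L, 4L, 2L)[perm$channel]
  perm$trial <- c(2L, 4L, 1L, 3L)[perm$trial]
  p2 <- compute_psth(perm, cfg, 4, 4)
  expect_identical(p$counts, p2$counts)
  expect_identical(p$rate_hz, p2$rate_hz)
})

test_that("slice aggregation averages with SEM across slices", {
  cfg <- analysis_config()
  set.seed(83)
  mk <- function(id) {
    al <- poisson_aligned(20, 4, 4)
    window_response(compute_psth(al, cfg, 4, 4, slice_id = id,
                                 group = "g1"), cfg)
  }
  one <- mk("s1")
  agg1 <- aggregate_slices(one)
  j <- dplyr::inner_join(agg1, one, by = c("window", "bin"))
  expect_equal(j$mean_prob, j$prob, tolerance = 1e-12)
  expect_equal(j$mean_freq_hz, j$freq_hz, tolerance = 1e-12)
  expect_true(all(agg1$sem_prob == 0))
  expect_true(all(agg1$n_slices == 1))

  two <- dplyr::bind_rows(one, dplyr::mutate(one, slice_id = "s2"))
  agg2 <- aggregate_slices(two)
  expect_true(all(agg2$sem_prob == 0))  # identical slices
  expect_true(all(agg2$n_slices == 2))
  expect_error(aggregate_slices(one[0, ]), "no responses")
})
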