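# Behavioral quantification: grooming episode summaries, cumulative
# duration-probability curves, exponential-plateau fitting with the
# extra-sum-of-squares F test, and sociability preference ratios.

#' Per-subject and per-group grooming episode summaries
#'
#' Totals grooming time and episode counts per subject and aggregates them
#' per group (mean +/- SEM). Per-episode durations are pooled per group for
#' the duration comparison, with episodes (not mice) as the unit.
#' Subjects listed in `all_subjects` but absent from the table are included
#' with zero episodes.
#'
#' @param tbl An [episode_table()] tibble.
#' @param all_subjects Optional tibble with columns `subject`, `group`
#'   enumerating subjects that may have no episodes.
#' @return A list with elements `per_subject` (tibble: `subject`, `group`,
#'   `total_time_s`, `n_episodes`), `per_group` (tibble of group means and
#'   SEMs) and `durations` (tibble: `group`, `duration_s`, pooled episodes).
#' @export
episode_summaries <- function(tbl, all_subjects = NULL) {
  per_subject <- tbl |>
    dplyr::group_by(.data$subject, .data$group) |>
    dplyr::summarise(total_time_s = sum(.data$duration_s),
                     n_episodes = dplyr::n(), .groups = "drop")
  if (!is.null(all_subjects)) {
    missing <- dplyr::anti_join(as_tibble(all_subjects), per_subject,
                                by = "subject")
    if (nrow(missing)) {
      per_subject <- dplyr::bind_rows(
        per_subject,
        tibble(subject = missing$subject, group = missing$group,
               total_time_s = 0, n_episodes = 0L))
    }
  }
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  per_group <- per_subject |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_mice = dplyr::n(),
                     mean_total_time_s = mean(.data$total_time_s),
                     sem_total_time_s = sem(.data$total_time_s),
                     mean_n_episodes = mean(.data$n_episodes),
                     sem_n_episodes = sem(.data$n_episodes),
                     .groups = "drop")
  durations <- tibble(group = tbl$group, duration_s = tbl$duration_s)
  list(per_subject = per_subject, per_group = per_group,
       durations = durations)
}

#' Cumulative probability curve of episode durations
#'
#' Empirical cumulative proportion `P(duration <= t)` evaluated at each
#' distinct observed duration: monotone nondecreasing, terminating at 1.
#' This is the curve to which the exponential-plateau model is fitted.
#'
#' @param durations Numeric vector of episode durations (n >= 3).
#' @return A tibble with columns `t` (distinct durations, ascending) and
#'   `p` (cumulative proportion).
#' @export
duration_probability_curve <- function(durations) {
  if (length(durations) < 3) abort("need >= 3 durations")
  t <- sort(unique(durations))
  n <- length(durations)
  p <- vapply(t, function(ti) sum(durations <= ti) / n, numeric(1))
  tibble(t = t, p = p)
}

plateau_model <- function(t, y0, ym, k) ym - (ym - y0) * exp(-k * t)

#' Fit an exponential-plateau model
#'
#' Least-squares fit of `Y(t) = ym - (ym - y0) * exp(-k t)` by damped
#' (Levenberg-Marquardt) least squares with five deterministic multistarts
#' (`k` spanning 0.03-30 times the reciprocal time range; `y0`, `ym`
#' initialized from the data extremes). The best converged start by residual
#' sum of squares wins. With `y0_fixed` supplied, `y0` is held and two
#' parameters are fitted.
#'
#' @param curve A data frame with columns `t` (>= 0) and `y`, n >= 4 points.
#' @param y0_fixed Optional fixed value of `y0`.
#' @return An object of class `plateau_fit` with fields `y0`, `ym`, `k`,
#'   `ss_resid`, `df_resid` (`n - 3` for a free fit), `n_points`,
#'   `converged`, `data`.
#' @export
fit_exponential_plateau <- function(curve, y0_fixed = NULL) {
  curve <- as_tibble(curve)
  if (!all(c("t", "y") %in% names(curve))) {
    abort("curve must have columns t and y")
  }
  if (nrow(curve) < 4) abort("need >= 4 points")
  if (any(curve$t < 0)) abort("t must be >= 0")
  tspan <- diff(range(curve$t))
  if (tspan == 0) abort("degenerate curve: single t value")
  k_starts <- c(0.03, 0.3, 1, 3, 30) / tspan
  y0_0 <- curve$y[which.min(curve$t)]
  ym_0 <- curve$y[which.max(curve$t)]
  free_y0 <- is.null(y0_fixed)
  n_par <- if (free_y0) 3L else 2L
  residual_fn <- function(p) {
    if (free_y0) {
      curve$y - plateau_model(curve$t, p[1], p[2], p[3])
    } else {
      curve$y - plateau_model(curve$t, y0_fixed, p[1], p[2])
    }
  }
  best <- NULL
  for (k0 in k_starts) {
    par0 <- if (free_y0) c(y0_0, ym_0, k0) else c(ym_0, k0)
    lower <- if (free_y0) c(-Inf, -Inf, 1e-12) else c(-Inf, 1e-12)
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, fn = residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    ss <- sum(res$fvec^2)
    ok <- res$info %in% 1:4
    if (is.null(best) || (ok && !best$ok) ||
        (ok == best$ok && ss < best$ss)) {
      best <- list(par = res$par, ss = ss, ok = ok)
    }
  }
  if (is.null(best)) {
    return(structure(list(y0 = y0_fixed %||% y0_0, ym = ym_0,
                          k = NA_real_, ss_resid = NA_real_,
                          df_resid = nrow(curve) - n_par,
                          n_points = nrow(curve), converged = FALSE,
                          k_identifiable = FALSE, data = curve),
                     class = "plateau_fit"))
  }
  y0_hat <- if (free_y0) best$par[1] else y0_fixed
  ym_hat <- if (free_y0) best$par[2] else best$par[1]
  k_hat <- if (free_y0) best$par[3] else best$par[2]
  structure(list(
    y0 = y0_hat,
    ym = ym_hat,
    k = k_hat,
    ss_resid = best$ss,
    df_resid = nrow(curve) - n_par,
    n_points = nrow(curve),
    converged = best$ok,
    k_identifiable = abs(ym_hat - y0_hat) >
      1e-8 * max(1, abs(ym_hat), abs(y0_hat)),
    data = curve
  ), class = "plateau_fit")
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat(sprintf(
    "<plateau_fit> y0 = %.4g, ym = %.4g, k = %.4g /s; SS = %.4g on %d df%s\n",
    x$y0, x$ym, x$k, x$ss_resid, x$df_resid,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Predict from a plateau fit
#' @param object A `plateau_fit`.
#' @param newdata Optional data frame with column `t`.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.plateau_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata$t
  plateau_model(t, object$y0, object$ym, object$k)
}

#' Extra-sum-of-squares F test for nested plateau fits
#'
#' Compares one shared fit on the pooled points of all groups against
#' separate per-group fits of the same model:
#' `F = ((SS_shared - SS_sep) / (df_shared - df_sep)) / (SS_sep / df_sep)`
#' with `SS_sep` and `df_sep` summed over groups. The numerator degrees of
#' freedom equal the extra parameters, `3 (k_groups - 1)` for the free
#' 3-parameter model.
#'
#' @param shared A `plateau_fit` on the pooled data.
#' @param separate A list of `plateau_fit`s, one per group, partitioning the
#'   same points.
#' @param alpha Significance level recorded in the result.
#' @return A one-row test tibble with `statistic` = F, `df1`, `df2`.
#' @export
extra_ss_f_test <- function(shared, separate, alpha = 0.05) {
  ss_sep <- sum(vapply(separate, function(f) f$ss_resid, numeric(1)))
  df_sep <- sum(vapply(separate, function(f) f$df_resid, numeric(1)))
  n_sep <- sum(vapply(separate, function(f) f$n_points, numeric(1)))
  if (n_sep != shared$n_points) {
    abort("separate fits must partition the shared fit's points")
  }
  df1 <- shared$df_resid - df_sep
  if (df1 <= 0) abort("shared fit must have more residual df than separate")
  if (ss_sep == 0) {
    return(test_row("extra-ss F", "shared vs separate", Inf, df1 = df1,
                    df2 = df_sep, p_raw = 0, alpha = alpha,
                    note = "flagged: zero separate residual SS"))
  }
  if (shared$ss_resid < ss_sep - 1e-8 * max(1, ss_sep)) {
    abort("fitting inconsistency: shared SS below separate SS")
  }
  f <- max(0, (shared$ss_resid - ss_sep) / df1) / (ss_sep / df_sep)
  test_row("extra-ss F", "shared vs separate", f, df1 = df1, df2 = df_sep,
           p_raw = stats::pf(f, df1, df_sep, lower.tail = FALSE),
           alpha = alpha)
}

#' Grooming duration-curve comparison across groups
#'
#' Builds the pooled and per-group cumulative duration-probability curves,
#' fits the exponential-plateau model to each, and runs the
#' extra-sum-of-squares F test of one shared curve against per-group
#' curves.
#'
#' @param tbl An [episode_table()] tibble with >= 2 groups.
#' @param alpha Significance level.
#' @return A list with `shared` (plateau fit), `per_group` (named list of
#'   fits) and `test` (one-row tibble).
#' @export
compare_duration_curves <- function(tbl, alpha = 0.05) {
  grps <- unique(tbl$group)
  if (length(grps) < 2) abort("need >= 2 groups")
  curve_of <- function(d) {
    cv <- duration_probability_curve(d)
    tibble(t = cv$t, y = cv$p)
  }
  per_group <- lapply(grps, function(g) {
    fit_exponential_plateau(curve_of(tbl$duration_s[tbl$group == g]))
  })
  names(per_group) <- grps
  # one shared parameter set fitted to the union of the per-group curve
  # points, so shared and separate fits partition the same points
  pooled_pts <- dplyr::bind_rows(lapply(per_group, function(f) f$data))
  shared <- fit_exponential_plateau(pooled_pts)
  list(shared = shared, per_group = per_group,
       test = extra_ss_f_test(shared, per_group, alpha = alpha))
}

#' Sociability preference ratios and group comparison
#'
#' Per subject: the habituation ratio (right/left empty-cup approach time)
#' and the test ratio (mouse/object approach time). Subjects with a zero
#' denominator are excluded with a warning. For two groups, each phase's
#' ratios are compared with a Shapiro-Wilk-gated Student's t-test.
#'
#' @param tbl An [interaction_table()] tibble.
#' @param alpha Significance level.
#' @return A list with `ratios` (tibble: `subject`, `group`, `phase`,
#'   `ratio`) and `tests` (tibble of test rows, including the normality
#'   checks).
#' @export
sociability_ratios <- function(tbl, alpha = 0.05) {
  wide <- tbl |>
    tidyr::pivot_wider(id_cols = c("subject", "group"),
                       names_from = "side_or_content",
                       values_from = "approach_time_s")
  ratios <- list()
  if (all(c("left", "right") %in% names(wide))) {
    zero <- wide$left == 0
    if (any(zero)) {
      warn(sprintf("excluding %d subject(s) with zero left-cup time",
                   sum(zero)))
    }
    ok <- wide[!zero, ]
    ratios$habituation <- tibble(subject = ok$subject, group = ok$group,
                                 phase = "habituation",
                                 ratio = ok$right / ok$left)
  }
  if (all(c("mouse", "object") %in% names(wide))) {
    zero <- wide$object == 0
    if (any(zero)) {
      warn(sprintf("excluding %d subject(s) with zero object-cup time",
                   sum(zero)))
    }
    ok <- wide[!zero, ]
    ratios$test <- tibble(subject = ok$subject, group = ok$group,
                          phase = "test", ratio = ok$mouse / ok$object)
  }
  ratios <- dplyr::bind_rows(ratios)
  grps <- unique(ratios$group)
  tests <- if (length(grps) == 2) {
    purrr::map_dfr(unique(ratios$phase), function(ph) {
      r <- ratios[ratios$phase == ph, ]
      a <- r$ratio[r$group == grps[1]]
      b <- r$ratio[r$group == grps[2]]
      if (length(a) < 3 || length(b) < 3) {
        out <- test_row("t", paste(grps[1], "vs", grps[2]), NA_real_,
                        p_raw = NA_real_, alpha = alpha,
                        note = "skipped: fewer than 3 subjects per group")
        out$phase <- ph
        return(out)
      }
      gate <- dplyr::bind_rows(
        normality_check(a, alpha, label = paste0(ph, ":", grps[1])),
        normality_check(b, alpha, label = paste0(ph, ":", grps[2])))
      tt <- t_test_independent(a, b, alpha = alpha,
                               comparison = paste(grps[1], "vs", grps[2]))
      out <- dplyr::bind_rows(gate, tt)
      out$phase <- ph
      out
    })
  } else {
    tibble()
  }
  list(ratios = ratios, tests = tests)
}
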