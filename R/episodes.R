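#' Construct a behavioral episode table
#'
#' Episode tables record one grooming bout per row: subject, group label,
#' onset (seconds from session start) and duration (seconds). Episodes of a
#' subject may not overlap, and onsets must lie within the session.
#'
#' @param subject Character/factor subject identifiers.
#' @param group Character/factor group labels.
#' @param onset_s Numeric onsets in seconds.
#' @param duration_s Numeric durations in seconds, strictly positive.
#' @param session_length_s Session length in seconds (default 1200, a 20-min
#'   video session).
#' @return A tibble of class `episode_table` with columns `subject`, `group`,
#'   `onset_s`, `duration_s` and a `session_length_s` attribute.
#' @export
episode_table <- function(subject = character(), group = character(),
                          onset_s = numeric(), duration_s = numeric(),
                          session_length_s = 1200) {
  tbl <- tibble(subject = as.character(subject),
                group = as.character(group),
                onset_s = as.numeric(onset_s),
                duration_s = as.numeric(duration_s))
  validate_episode_table(tbl, session_length_s)
  structure(tbl, session_length_s = session_length_s,
            class = c("episode_table", class(tbl)))
}

validate_episode_table <- function(tbl, session_length_s) {
  need <- c("subject", "group", "onset_s", "duration_s")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("format error: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.finite(tbl$duration_s) | tbl$duration_s <= 0)
  if (length(bad)) {
    abort(paste0("validation error: duration_s must be > 0 (row ",
                 bad[1], ")"))
  }
  bad <- which(tbl$onset_s < 0 | tbl$onset_s >= session_length_s)
  if (length(bad)) {
    abort(paste0("validation error: onset_s outside [0, session) (row ",
                 bad[1], ")"))
  }
  # per-subject non-overlap
  for (s in unique(tbl$subject)) {
    rows <- which(tbl$subject == s)
    if (length(rows) < 2) next
    o <- tbl$onset_s[rows]
    d <- tbl$duration_s[rows]
    ord <- order(o)
    if (any(o[ord][-1] < (o[ord] + d[ord])[-length(rows)])) {
      abort(paste0("validation error: overlapping episodes for subject ", s))
    }
  }
  invisible(tbl)
}

#' Read a behavioral episode table from CSV
#'
#' Expects columns `subject,group,onset_s,duration_s` (comma-separated,
#' header row, '.' decimal separator, UTF-8). Rows are preserved in input
#' order; invariant violations are rejected with the offending row cited.
#'
#' @param path CSV path.
#' @param session_length_s Session length in seconds.
#' @return An `episode_table` tibble.
#' @export
read_episode_table <- function(path, session_length_s = 1200) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  extra <- setdiff(names(tbl), c("subject", "group", "onset_s", "duration_s"))
  if (length(extra)) {
    abort(paste0("format error: unknown column(s): ",
                 paste(extra, collapse = ", ")))
  }
  episode_table(tbl$subject, tbl$group, tbl$onset_s, tbl$duration_s,
                session_length_s = session_length_s)
}

#' Write an episode table to CSV
#' @param tbl An `episode_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_episode_table <- function(tbl, path) {
  readr::write_csv(tbl[c("subject", "group", "onset_s", "duration_s")], path,
                   progress = FALSE)
  invisible(path)
}

#' Construct a sociability interaction table
#'
#' One row per subject x cup x phase: approach time spent at the left/right
#' empty cup during habituation and at the mouse-/object-containing cup
#' during the test phase of a three-chamber sociability assay.
#'
#' @param subject,group Identifiers.
#' @param side_or_content One of `"left"`, `"right"`, `"mouse"`, `"object"`.
#' @param phase `"habituation"` or `"test"`.
#' @param approach_time_s Nonnegative approach time, seconds.
#' @return A tibble of class `interaction_table`.
#' @export
interaction_table <- function(subject = character(), group = character(),
                              side_or_content = character(),
                              phase = character(),
                              approach_time_s = numeric()) {
  soc <- as.character(side_or_content)
  ph <- as.character(phase)
  if (length(soc) && !all(soc %in% c("left", "right", "mouse", "object"))) {
    abort("side_or_content must be left/right/mouse/object")
  }
  if (length(ph) && !all(ph %in% c("habituation", "test"))) {
    abort("phase must be habituation or test")
  }
  at <- as.numeric(approach_time_s)
  if (any(!is.finite(at) | at < 0)) {
    abort("validation error: approach_time_s must be >= 0")
  }
  tbl <- tibble(subject = as.character(subject),
                group = as.character(group),
                side_or_content = soc, phase = ph, approach_time_s = at)
  structure(tbl, class = c("interaction_table", class(tbl)))
}

#' Read a sociability interaction table from CSV
#' @param path CSV with columns
#'   `subject,group,side_or_content,phase,approach_time_s`.
#' @return An `interaction_table` tibble.
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject", "group", "side_or_content", "phase", "approach_time_s")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("format error: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  interaction_table(tbl$subject, tbl$group, tbl$side_or_content, tbl$phase,
                    tbl$approach_time_s)
}

#' Write an interaction table to CSV
#' @param tbl An `interaction_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(tbl, path) {
  readr::write_csv(
    tbl[c("subject", "group", "side_or_content", "phase", "approach_time_s")],
    path, progress = FALSE)
  invisible(path)
}
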