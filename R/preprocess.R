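#' Clean a raw session table
#'
#' Standard hygiene ahead of any analysis: sessions containing a missing value
#' in any sensor channel are dropped whole (no imputation), exact duplicate
#' rows collapse to one, and user / sport labels are normalized to canonical
#' lower-case trimmed identifiers. The operation is idempotent.
#'
#' @param table A session table.
#' @return The cleaned table, with a `cleaning_report` attribute (a list with
#'   `n_sessions_in`, `n_sessions_dropped_missing`, `n_duplicate_rows_removed`,
#'   `n_sessions_out`) retrievable via [cleaning_report()].
#' @examples
#' tab <- generate_cohort(cohort_spec(n_users = 2, sessions_per_user = 3))
#' tab$heart_rate[1] <- NA
#' cleaned <- clean_sessions(tab)
#' cleaning_report(cleaned)
#' @export
clean_sessions <- function(table) {
  assert_session_table(table)
  n_in <- n_distinct(table$session_id)

  dup_removed <- sum(duplicated(table))
  out <- distinct(table)

  bad_sessions <- out |>
    filter(dplyr::if_any(all_of(SESSION_CHANNELS), is.na)) |>
    pull(.data$session_id) |>
    unique()
  out <- filter(out, !.data$session_id %in% bad_sessions)

  out <- out |>
    mutate(
      user_id = tolower(trimws(.data$user_id)),
      sport = tolower(trimws(.data$sport))
    ) |>
    arrange(.data$session_id, .data$timestamp)

  report <- list(
    n_sessions_in = n_in,
    n_sessions_dropped_missing = length(bad_sessions),
    n_duplicate_rows_removed = dup_removed,
    n_sessions_out = n_distinct(out$session_id)
  )
  attr(out, "cleaning_report") <- report
  out
}

#' @rdname clean_sessions
#' @param cleaned A table returned by `clean_sessions()`.
#' @export
cleaning_report <- function(cleaned) {
  attr(cleaned, "cleaning_report")
}

#' Derive per-session physiological and activity features
#'
#' Computes, for each session, the scalar features that summarize the bout:
#' duration (last minus first timestamp, seconds), total distance (trapezoidal
#' integral of the speed channel over time, meters), peak and mean heart rate,
#' recovery speed, and exercise intensity. Recovery speed is the rate of
#' heart-rate decline from the session peak to the final sample,
#' `(peak - final) / (t_final - t_peak)` in bpm/s, defined as 0 when the peak
#' falls on the last sample; it reflects post-exercise stabilization.
#' Exercise intensity is the session's mean heart rate as a fraction of the
#' cohort-wide maximum heart rate.
#'
#' @param table A cleaned session table.
#' @return A tibble with one row per session: `session_id`, `duration`,
#'   `total_distance`, `peak_heart_rate`, `mean_heart_rate`, `recovery_speed`,
#'   `exercise_intensity`.
#' @export
derive_session_features <- function(table) {
  assert_session_table(table)
  lens <- table |> count(.data$session_id)
  if (any(lens$n < 2)) {
    abort(
      sprintf("Sessions with a single timestep have undefined duration: %s",
              paste(lens$session_id[lens$n < 2], collapse = ", ")),
      class = "ddmr_validation_error"
    )
  }
  cohort_max_hr <- max(table$heart_rate)

  table |>
    group_by(.data$session_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    summarise(
      duration = as.numeric(difftime(max(.data$timestamp), min(.data$timestamp),
                                     units = "secs")),
      total_distance = trapezoid(as.numeric(.data$timestamp), .data$speed),
      peak_heart_rate = max(.data$heart_rate),
      mean_heart_rate = mean(.data$heart_rate),
      recovery_speed = recovery_rate(as.numeric(.data$timestamp), .data$heart_rate),
      .groups = "drop"
    ) |>
    mutate(exercise_intensity = .data$mean_heart_rate / cohort_max_hr)
}

trapezoid <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

recovery_rate <- function(t, hr) {
  peak_idx <- which.max(hr)
  n <- length(hr)
  if (peak_idx == n) return(0)
  (hr[peak_idx] - hr[n]) / (t[n] - t[peak_idx])
}
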