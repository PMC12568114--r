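#' Specify a synthetic wearable exercise cohort
#'
#' A cohort spec describes the shape of a simulated population of wearable
#' exercise logs: how many users, how many sessions each records, the sport
#' mix, session lengths, and how much planted redundancy (near-duplicate
#' sessions) the cohort carries. The generator is the test bed for the whole
#' pipeline: planted duplicates are flagged in a provenance column so that
#' reduction quality can be scored against ground truth.
#'
#' @param n_users Number of users (>= 1).
#' @param sessions_per_user Sessions recorded per user (>= 2 when
#'   `duplicate_rate > 0`, since a duplicate needs a same-user source).
#' @param sports Named numeric vector of sport mixing proportions,
#'   e.g. `c(run = 0.5, bike = 0.3, row = 0.2)`. Normalized to sum to 1.
#' @param session_length_range Integer vector `c(min, max)` of timesteps per
#'   session; `min >= 2`.
#' @param sampling_interval Seconds between consecutive timesteps.
#' @param duplicate_rate Fraction in \[0, 1\] of all sessions that are planted
#'   near-duplicates of another same-user session. The planted count is
#'   `round(duplicate_rate * n_users * sessions_per_user)`.
#' @param noise_scale Relative jitter magnitude applied to a duplicated
#'   session's channels: each channel gets Gaussian noise with standard
#'   deviation `noise_scale` times the channel's within-session spread.
#' @param timeline_days Length of the simulated calendar, in days. Sessions
#'   are scattered across it so chronological splits are meaningful.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#'
#' @return An object of class `ddm_cohort_spec`.
#' @seealso [generate_cohort()], [drift_spec()]
#' @export
cohort_spec <- function(n_users = 20,
                        sessions_per_user = 12,
                        sports = c(run = 0.5, bike = 0.3, row = 0.2),
                        session_length_range = c(30, 90),
                        sampling_interval = 10,
                        duplicate_rate = 0,
                        noise_scale = 0.02,
                        timeline_days = 180,
                        seed = 1) {
  check_number(n_users, "n_users", lower = 1, integerish = TRUE)
  check_number(sessions_per_user, "sessions_per_user", lower = 1, integerish = TRUE)
  if (!is.numeric(sports) || is.null(names(sports)) || any(!nzchar(names(sports)))) {
    validation_error("`sports` must be a named numeric vector of proportions.", "sports")
  }
  if (any(sports < 0) || sum(sports) <= 0) {
    validation_error("`sports` proportions must be non-negative and sum > 0.", "sports")
  }
  if (length(session_length_range) != 2L || session_length_range[1] < 2 ||
      session_length_range[2] < session_length_range[1]) {
    validation_error(
      "`session_length_range` must be c(min, max) with min >= 2 and max >= min.",
      "session_length_range"
    )
  }
  check_number(sampling_interval, "sampling_interval", lower = 1)
  check_number(duplicate_rate, "duplicate_rate", lower = 0, upper = 1)
  if (duplicate_rate > 0 && sessions_per_user < 2) {
    validation_error(
      "`duplicate_rate` > 0 requires `sessions_per_user` >= 2.", "duplicate_rate"
    )
  }
  check_number(noise_scale, "noise_scale", lower = 0)
  check_number(timeline_days, "timeline_days", lower = 1)
  check_number(seed, "seed", integerish = TRUE)

  structure(
    list(
      n_users = as.integer(n_users),
      sessions_per_user = as.integer(sessions_per_user),
      sports = sports / sum(sports),
      session_length_range = as.integer(session_length_range),
      sampling_interval = as.numeric(sampling_interval),
      duplicate_rate = duplicate_rate,
      noise_scale = noise_scale,
      timeline_days = as.numeric(timeline_days),
      seed = as.integer(seed)
    ),
    class = "ddm_cohort_spec"
  )
}

#' @export
print.ddm_cohort_spec <- function(x, ...) {
  cat("<ddm_cohort_spec>\n")
  cat(sprintf("  users: %d, sessions/user: %d (%d total)\n",
              x$n_users, x$sessions_per_user, x$n_users * x$sessions_per_user))
  cat(sprintf("  sports: %s\n",
              paste(sprintf("%s=%.2f", names(x$sports), x$sports), collapse = ", ")))
  cat(sprintf("  duplicate_rate: %.2f, noise_scale: %.3f, seed: %d\n",
              x$duplicate_rate, x$noise_scale, x$seed))
  invisible(x)
}

# Per-sport channel regimes, drawn once per cohort so that sports have
# distinct but stable speed/heart-rate envelopes.
sport_profiles <- function(sport_names) {
  base_speed <- runif(length(sport_names), 1.5, 8)
  hr_amp <- runif(length(sport_names), 40, 80)
  tibble(sport = sport_names, base_speed = base_speed, hr_amp = hr_amp)
}

# Simulate one session's multichannel series. Heart rate follows a baseline +
# exertion ramp + recovery tail; speed is piecewise-constant per ~60 s block;
# altitude is a slow random walk; GPS integrates speed along a wandering
# heading.
simulate_session_channels <- function(len, dt, hr_base, hr_amp, base_speed) {
  t_rel <- (seq_len(len) - 1) * dt
  total <- t_rel[len] + dt

  ramp <- pmin(t_rel / (0.25 * total + dt), 1)
  tail_start <- 0.8 * total
  recovery <- ifelse(t_rel > tail_start,
                     exp(-(t_rel - tail_start) / (0.15 * total + dt)), 1)
  heart_rate <- hr_base + hr_amp * ramp * recovery + rnorm(len, sd = 2)

  block <- pmax(1L, as.integer(ceiling(60 / dt)))
  n_blocks <- ceiling(len / block)
  block_speed <- base_speed * runif(n_blocks, 0.8, 1.2)
  speed <- rep(block_speed, each = block)[seq_len(len)]
  speed <- pmax(0, speed + rnorm(len, sd = 0.05 * base_speed))

  altitude <- 50 + cumsum(rnorm(len, sd = 0.3))

  heading <- cumsum(c(runif(1, 0, 2 * pi), rnorm(len - 1, sd = 0.1)))
  step <- speed * dt
  lat0 <- runif(1, 35, 45)
  lon0 <- runif(1, -5, 5)
  latitude <- lat0 + cumsum(c(0, (step * cos(heading))[-len])) / 111320
  longitude <- lon0 + cumsum(c(0, (step * sin(heading))[-len])) /
    (111320 * cos(lat0 * pi / 180))

  tibble(
    heart_rate = heart_rate, speed = speed, altitude = altitude,
    latitude = latitude, longitude = longitude
  )
}

#' Generate a synthetic wearable exercise cohort
#'
#' Produces a long-format session table: one row per timestep with session id,
#' user id, sport, UTC timestamp and the five sensor channels (heart rate,
#' speed, altitude, latitude, longitude). A fraction of sessions, controlled
#' by `duplicate_rate`, are planted near-duplicates: a same-user session is
#' copied in full, each channel jittered by `noise_scale` times its spread,
#' and the copy is given its own start time. The `planted_duplicate` column
#' records this provenance (synthetic data only; [write_sessions()] moves it
#' to a sidecar file so the main schema matches real-world logs).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `session_id`, `user_id`, `sport`,
#'   `timestamp`, `heart_rate`, `speed`, `altitude`, `latitude`, `longitude`,
#'   `planted_duplicate`, timestamp-sorted within each session.
#' @examples
#' tab <- generate_cohort(cohort_spec(n_users = 3, sessions_per_user = 4, seed = 42))
#' dplyr::n_distinct(tab$session_id)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "ddm_cohort_spec")) {
    validation_error("`spec` must be created by cohort_spec().", "spec")
  }
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n_total <- spec$n_users * spec$sessions_per_user
  n_dup <- round(spec$duplicate_rate * n_total)
  users <- sprintf("u%03d", seq_len(spec$n_users))

  # Spread planted duplicates across users as evenly as possible, capped at
  # sessions_per_user - 1 so each user keeps at least one original source.
  dup_per_user <- integer(spec$n_users)
  if (n_dup > 0) {
    idx <- rep(seq_len(spec$n_users), length.out = n_dup)
    for (i in idx) {
      if (dup_per_user[i] < spec$sessions_per_user - 1L) {
        dup_per_user[i] <- dup_per_user[i] + 1L
      } else {
        free <- which(dup_per_user < spec$sessions_per_user - 1L)
        if (length(free) == 0) break
        dup_per_user[free[1]] <- dup_per_user[free[1]] + 1L
      }
    }
  }

  profiles <- sport_profiles(names(spec$sports))
  t0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  timeline_secs <- spec$timeline_days * 86400
  dt <- spec$sampling_interval

  session_counter <- 0L
  out <- vector("list", spec$n_users)
  for (u in seq_len(spec$n_users)) {
    n_orig <- spec$sessions_per_user - dup_per_user[u]
    hr_base <- runif(1, 60, 80)
    starts <- sort(runif(spec$sessions_per_user, 0, timeline_secs))
    orig_slots <- sort(sample(spec$sessions_per_user, n_orig))

    originals <- vector("list", n_orig)
    for (j in seq_len(n_orig)) {
      sport <- sample(names(spec$sports), 1, prob = spec$sports)
      prof <- profiles[profiles$sport == sport, ]
      len <- sample(seq(spec$session_length_range[1],
                        spec$session_length_range[2]), 1)
      ch <- simulate_session_channels(len, dt, hr_base, prof$hr_amp, prof$base_speed)
      originals[[j]] <- list(sport = sport, channels = ch,
                             start = starts[orig_slots[j]])
    }

    dup_slots <- setdiff(seq_len(spec$sessions_per_user), orig_slots)
    dups <- vector("list", length(dup_slots))
    for (j in seq_along(dup_slots)) {
      src <- originals[[sample(n_orig, 1)]]
      ch <- src$channels
      jitter <- function(x) x + rnorm(length(x), sd = spec$noise_scale *
                                        max(sd(x), 1e-6))
      ch <- dplyr::mutate(ch, across(all_of(SESSION_CHANNELS), jitter))
      dups[[j]] <- list(sport = src$sport, channels = ch,
                        start = starts[dup_slots[j]])
    }

    sess <- c(originals, dups)
    flags <- c(rep(FALSE, n_orig), rep(TRUE, length(dup_slots)))
    # restore chronological order of this user's sessions
    ord <- order(vapply(sess, function(s) s$start, numeric(1)))
    sess <- sess[ord]
    flags <- flags[ord]

    rows <- vector("list", length(sess))
    for (j in seq_along(sess)) {
      session_counter <- session_counter + 1L
      s <- sess[[j]]
      len <- nrow(s$channels)
      rows[[j]] <- dplyr::bind_cols(
        tibble(
          session_id = sprintf("s%06d", session_counter),
          user_id = users[u],
          sport = s$sport,
          timestamp = t0 + s$start + (seq_len(len) - 1) * dt
        ),
        s$channels
      ) |> mutate(planted_duplicate = flags[j])
    }
    out[[u]] <- bind_rows(rows)
  }
  bind_rows(out)
}

#' Specify a distribution drift to apply to a cohort
#'
#' Drift is modelled as a change point on the cohort's calendar: sessions
#' starting after `onset` (as a fraction of the observed timeline) have their
#' channel means shifted additively, and optionally their sport labels
#' resampled toward a new preference mixture.
#'
#' @param onset Fraction of the timeline in \[0, 1\] after which drift applies.
#' @param channel_shifts Named numeric vector of additive mean shifts, names
#'   among `heart_rate`, `speed`, `altitude` (e.g. `c(heart_rate = 10)` for a
#'   +10 bpm shift).
#' @param preference_shift Optional named numeric vector of new sport mixing
#'   proportions; post-onset sessions have their sport label resampled from
#'   it (labels only; channels are left as generated).
#' @return An object of class `ddm_drift_spec`.
#' @export
drift_spec <- function(onset = 0.5, channel_shifts = c(heart_rate = 0),
                       preference_shift = NULL) {
  check_number(onset, "onset", lower = 0, upper = 1)
  allowed <- c("heart_rate", "speed", "altitude")
  if (!is.numeric(channel_shifts) || is.null(names(channel_shifts)) ||
      !all(names(channel_shifts) %in% allowed)) {
    validation_error(
      sprintf("`channel_shifts` must be a named numeric vector with names in {%s}.",
              paste(allowed, collapse = ", ")),
      "channel_shifts"
    )
  }
  if (!is.null(preference_shift)) {
    if (!is.numeric(preference_shift) || is.null(names(preference_shift)) ||
        any(preference_shift < 0) || sum(preference_shift) <= 0) {
      validation_error(
        "`preference_shift` must be a named non-negative numeric vector.",
        "preference_shift"
      )
    }
    preference_shift <- preference_shift / sum(preference_shift)
  }
  structure(
    list(onset = onset, channel_shifts = channel_shifts,
         preference_shift = preference_shift),
    class = "ddm_drift_spec"
  )
}

#' Inject distribution drift into a session table
#'
#' Applies the change-point drift described by a [drift_spec()]: every session
#' whose first timestamp falls after the onset fraction of the table's time
#' span gets its channels shifted by the specified amounts (and, if requested,
#' its sport label resampled). Session and user counts, session lengths and
#' the schema are unchanged.
#'
#' @param table A session table (see [generate_cohort()]).
#' @param drift A [drift_spec()].
#' @param seed Integer seed (only consumed when `preference_shift` is set).
#' @return The drifted session table.
#' @export
inject_drift <- function(table, drift, seed = 1) {
  assert_session_table(table)
  if (!inherits(drift, "ddm_drift_spec")) {
    validation_error("`drift` must be created by drift_spec().", "drift")
  }
  starts <- table |>
    group_by(.data$session_id) |>
    summarise(start = min(.data$timestamp), .groups = "drop")
  lo <- min(starts$start)
  hi <- max(starts$start)
  cutoff <- lo + drift$onset * as.numeric(difftime(hi, lo, units = "secs"))
  shifted_ids <- starts$session_id[as.numeric(starts$start) >= as.numeric(cutoff)]

  out <- table
  hit <- out$session_id %in% shifted_ids
  for (ch in names(drift$channel_shifts)) {
    out[[ch]][hit] <- out[[ch]][hit] + drift$channel_shifts[[ch]]
  }
  if (!is.null(drift$preference_shift)) {
    out <- withr::with_seed(seed, {
      new_sports <- setNames(
        sample(names(drift$preference_shift), length(shifted_ids),
               replace = TRUE, prob = drift$preference_shift),
        shifted_ids
      )
      mutate(out, sport = ifelse(hit, new_sports[.data$session_id], .data$sport))
    })
  }
  out
}
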