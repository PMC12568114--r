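# Fixture builders shared across test files. Everything is generated in code;
# no fixture files on disk.

# A hand-built session table from explicit channel vectors.
make_session <- function(session_id, user_id = "u1", sport = "run",
                         heart_rate, speed = NULL, altitude = NULL,
                         latitude = NULL, longitude = NULL,
                         start = "2024-01-01 10:00:00", dt = 60) {
  n <- length(heart_rate)
  tibble::tibble(
    session_id = session_id,
    user_id = user_id,
    sport = sport,
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * dt,
    heart_rate = heart_rate,
    speed = speed %||% rep(2, n),
    altitude = altitude %||% rep(50, n),
    latitude = latitude %||% rep(40, n),
    longitude = longitude %||% rep(0, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_cohort <- function(n_users = 5, sessions_per_user = 10,
                         duplicate_rate = 0.3, seed = 7, ...) {
  generate_cohort(cohort_spec(
    n_users = n_users, sessions_per_user = sessions_per_user,
    duplicate_rate = duplicate_rate, session_length_range = c(20, 40),
    seed = seed, ...
  ))
}

# Independent brute-force oracle for per-user session reduction: all-pairs
# exact cosine within (user, sport), union-find connected components, same
# representative rule (most timesteps, earliest start on ties). Shares no
# code path with the package implementation.
brute_force_reduce <- function(embedding, summary, tau) {
  ids <- rownames(embedding$scores)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  xn <- embedding$scores / sqrt(rowSums(embedding$scores^2))
  meta <- summary[match(ids, summary$session_id), ]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (meta$user_id[i] != meta$user_id[j]) next
      if (meta$sport[i] != meta$sport[j]) next
      sim <- sum(xn[i, ] * xn[j, ])
      if (sim >= tau - 1e-12) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  kept <- character(0)
  for (r in unique(roots)) {
    members <- which(roots == r)
    ord <- order(-meta$record_count[members],
                 as.numeric(meta$start_time[members]),
                 meta$session_id[members])
    kept <- c(kept, meta$session_id[members[ord[1]]])
  }
  sort(kept)
}

# Synthetic implicit-feedback interactions with per-user favourite items.
planted_interactions <- function(seed, n_users = 12, n_items = 8,
                                 n_per_user = 30) {
  set.seed(seed)
  users <- sprintf("u%02d", seq_len(n_users))
  items <- letters[seq_len(n_items)]
  fav <- lapply(users, function(u) sample(items, 2))
  pos <- dplyr::bind_rows(lapply(seq_along(users), function(i) {
    pick <- ifelse(runif(n_per_user) < 0.8,
                   sample(fav[[i]], n_per_user, replace = TRUE),
                   sample(items, n_per_user, replace = TRUE))
    tibble::tibble(
      user_id = users[i], item_id = pick,
      timestamp = as.POSIXct("2024-01-01", tz = "UTC") +
        runif(n_per_user, 0, 100 * 86400),
      context = rnorm(n_per_user, 120, 5), label = 1L
    )
  }))
  dplyr::arrange(pos, timestamp)
}
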