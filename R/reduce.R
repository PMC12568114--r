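#' Consolidate near-duplicate sessions per user
#'
#' The final stage of the data-reduction module. Within each (user, sport)
#' group, sessions whose embedded summaries have exact cosine similarity at or
#' above the threshold tau are linked into a graph (candidate pairs come from
#' the approximate index; similarities are recomputed exactly before
#' thresholding). Each connected component keeps exactly one representative —
#' the session with the most recorded timesteps, ties broken by earliest start
#' — and the rest are removed. Consolidation by connected components makes the
#' result order-independent. Every user present before reduction retains at
#' least one session.
#'
#' @param embedding A [project_pca()] embedding of the sessions to reduce.
#' @param summary The matching summary matrix (supplies `record_count` and
#'   `start_time`).
#' @param table The session table whose rows are to be subset.
#' @param config A [reduction_config()]; `similarity_threshold` is tau.
#' @return An object of class `ddm_user_pattern`: list with `sessions` (the
#'   surviving session-table rows), `kept_ids`, `removed` (tibble mapping each
#'   removed session to the representative that subsumed it), and `counts`
#'   (`n_before`, `n_after`, `n_removed`, `rate_percent`).
#' @export
reduce_user_sessions <- function(embedding, summary, table,
                                 config = reduction_config()) {
  tau <- config$similarity_threshold
  if (!is.numeric(tau) || tau <= 0) {
    validation_error("`similarity_threshold` must be > 0.", "similarity_threshold")
  }
  assert_session_table(table)
  ids <- rownames(embedding$scores)
  if (!setequal(ids, summary$session_id) ||
      !all(ids %in% unique(table$session_id))) {
    abort("`embedding`, `summary` and `table` must be aligned by session_id.",
          class = "ddmr_validation_error")
  }

  n <- length(ids)
  k_query <- min(n - 1L, config$ann_search_k)
  nb <- query_neighbors(embedding, config, n_neighbors = k_query,
                        include_self = FALSE)

  meta <- summary[, SUMMARY_INDEX_COLS]
  pairs <- nb |>
    left_join(rename(meta, user_a = "user_id", sport_a = "sport",
                     rc_a = "record_count", st_a = "start_time"),
              by = "session_id") |>
    left_join(rename(meta, neighbor_id = "session_id", user_b = "user_id",
                     sport_b = "sport", rc_b = "record_count", st_b = "start_time"),
              by = "neighbor_id") |>
    filter(.data$user_a == .data$user_b, .data$sport_a == .data$sport_b,
           .data$similarity >= tau - 1e-12)

  kept <- ids
  removed <- tibble(session_id = character(), representative_id = character(),
                    user_id = character(), sport = character())
  if (nrow(pairs) > 0) {
    g <- igraph::graph_from_data_frame(
      pairs[, c("session_id", "neighbor_id")],
      directed = FALSE,
      vertices = data.frame(name = ids)
    )
    comp <- igraph::components(g)$membership
    grp <- tibble(session_id = names(comp), component = unname(comp)) |>
      left_join(meta, by = "session_id")
    reps <- grp |>
      group_by(.data$component) |>
      arrange(dplyr::desc(.data$record_count), .data$start_time,
              .data$session_id, .by_group = TRUE) |>
      summarise(representative_id = first(.data$session_id), .groups = "drop")
    grp <- left_join(grp, reps, by = "component")
    removed <- grp |>
      filter(.data$session_id != .data$representative_id) |>
      select("session_id", "representative_id", "user_id", "sport")
    kept <- setdiff(ids, removed$session_id)

    # sanity: no examined edge at or above tau may survive between kept sessions
    leftover <- pairs$session_id %in% kept & pairs$neighbor_id %in% kept
    stopifnot(!any(leftover))
  }

  counts <- list(
    n_before = n,
    n_after = length(kept),
    n_removed = n - length(kept),
    rate_percent = reduction_rate(n, length(kept))
  )
  structure(
    list(
      sessions = filter(table, .data$session_id %in% kept),
      kept_ids = kept,
      removed = removed,
      counts = counts,
      config = config
    ),
    class = "ddm_user_pattern"
  )
}

#' @export
print.ddm_user_pattern <- function(x, ...) {
  cat("<ddm_user_pattern>\n")
  cat(sprintf("  sessions: %d kept of %d (%.1f%% reduction at tau = %.3f)\n",
              x$counts$n_after, x$counts$n_before, x$counts$rate_percent,
              x$config$similarity_threshold))
  invisible(x)
}

#' Percentage reduction between two record counts
#'
#' @param n_before Record count before reduction (> 0).
#' @param n_after Record count after reduction (`0 <= n_after <= n_before`).
#' @return `100 * (1 - n_after / n_before)`.
#' @examples
#' reduction_rate(139161, 118285) # ~15
#' @export
reduction_rate <- function(n_before, n_after) {
  check_number(n_before, "n_before", lower = 1)
  check_number(n_after, "n_after", lower = 0, upper = n_before)
  100 * (1 - n_after / n_before)
}

#' Run the full data-reduction module on a session table
#'
#' Convenience wrapper chaining [summarize_sessions()], [filter_by_sport()],
#' [project_pca()] and [reduce_user_sessions()]: the five-stage reduction of
#' raw time-series logs into consolidated per-user pattern data.
#'
#' @param table A cleaned session table.
#' @param config A [reduction_config()].
#' @return A `ddm_user_pattern` (see [reduce_user_sessions()]).
#' @export
reduce_sessions <- function(table, config = reduction_config()) {
  summary <- summarize_sessions(table)
  summary <- filter_by_sport(summary, config$min_sessions_per_sport)
  if (isTRUE(config$per_sport_pca)) {
    parts <- split(summary, summary$sport)
    patterns <- lapply(parts, function(part) {
      emb <- project_pca(part, config)
      reduce_user_sessions(emb, part, filter(table, .data$session_id %in%
                                               part$session_id), config)
    })
    kept <- unlist(lapply(patterns, function(p) p$kept_ids), use.names = FALSE)
    removed <- bind_rows(lapply(patterns, function(p) p$removed))
    n_before <- sum(vapply(patterns, function(p) p$counts$n_before, numeric(1)))
    counts <- list(
      n_before = n_before, n_after = length(kept),
      n_removed = n_before - length(kept),
      rate_percent = reduction_rate(n_before, length(kept))
    )
    return(structure(
      list(sessions = filter(table, .data$session_id %in% kept),
           kept_ids = kept, removed = removed, counts = counts, config = config),
      class = "ddm_user_pattern"
    ))
  }
  embedding <- project_pca(summary, config)
  reduce_user_sessions(embedding, summary, table, config)
}
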