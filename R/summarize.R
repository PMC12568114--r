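SUMMARY_INDEX_COLS <- c("session_id", "user_id", "sport", "record_count", "start_time")

#' Summarize variable-length sessions into fixed-length feature vectors
#'
#' Condenses each multichannel session into a fixed-width row: for each of the
#' heart-rate, speed and altitude channels the mean, standard deviation
#' (population form, divisor N), minimum and maximum, concatenated with the
#' per-session derived features of [derive_session_features()]. This is the
#' matrix the similarity machinery operates on, so width and alignment are
#' contractual: every row has the same columns and no missing entries.
#'
#' @param table A cleaned session table.
#' @param derived Optional precomputed [derive_session_features()] output;
#'   computed from `table` when omitted.
#' @return A tibble with index columns `session_id`, `user_id`, `sport`,
#'   `record_count`, `start_time` followed by the numeric feature columns.
#' @export
summarize_sessions <- function(table, derived = NULL) {
  assert_session_table(table)
  if (is.null(derived)) derived <- derive_session_features(table)

  stats <- table |>
    group_by(.data$session_id, .data$user_id, .data$sport) |>
    summarise(
      record_count = dplyr::n(),
      start_time = min(.data$timestamp),
      hr_mean = mean(.data$heart_rate), hr_sd = sd_pop(.data$heart_rate),
      hr_min = min(.data$heart_rate), hr_max = max(.data$heart_rate),
      speed_mean = mean(.data$speed), speed_sd = sd_pop(.data$speed),
      speed_min = min(.data$speed), speed_max = max(.data$speed),
      alt_mean = mean(.data$altitude), alt_sd = sd_pop(.data$altitude),
      alt_min = min(.data$altitude), alt_max = max(.data$altitude),
      .groups = "drop"
    )
  out <- inner_join(stats, derived, by = "session_id")
  if (any(out$record_count < 2)) {
    abort("All sessions must have record_count >= 2.", class = "ddmr_validation_error")
  }
  out
}

summary_feature_cols <- function(summary) {
  setdiff(names(summary), SUMMARY_INDEX_COLS)
}

#' Filter a summary matrix by sport support
#'
#' Retains only sports with enough sessions to support reliable similarity
#' analysis; sparsely observed sports add heterogeneity (e.g. atypical
#' heart-rate envelopes) without enough data to pattern-match against.
#'
#' @param summary A [summarize_sessions()] matrix.
#' @param min_sessions_per_sport Minimum session count a sport needs to be
#'   retained; `0` keeps everything.
#' @return The filtered summary, with a `filter_report` attribute listing the
#'   per-sport counts and which sports were dropped.
#' @export
filter_by_sport <- function(summary, min_sessions_per_sport = 0) {
  check_number(min_sessions_per_sport, "min_sessions_per_sport", lower = 0,
               integerish = TRUE)
  counts <- count(summary, .data$sport, name = "n_sessions")
  keep_sports <- counts$sport[counts$n_sessions >= min_sessions_per_sport]
  out <- filter(summary, .data$sport %in% keep_sports)
  if (nrow(out) == 0) {
    abort("All sports fall below `min_sessions_per_sport`; nothing retained.",
          class = "ddmr_empty_result")
  }
  attr(out, "filter_report") <- list(
    sport_counts = counts,
    dropped_sports = setdiff(counts$sport, keep_sports),
    n_removed = nrow(summary) - nrow(out)
  )
  out
}

#' Configure the data-reduction module
#'
#' Bundles the tunables of the reduction pipeline. Defaults follow the
#' operating point used throughout: cosine similarity threshold 0.99, five
#' principal components (or a cumulative explained-variance target when
#' `variance_target` is supplied), and an approximate-neighbour index with 10
#' random-projection trees searched over 100 nodes.
#'
#' @param similarity_threshold Cosine similarity threshold tau in (0, 1];
#'   same-user same-sport session pairs at or above it are considered
#'   redundant.
#' @param pca_components Number of principal components to keep (ignored when
#'   `variance_target` is given).
#' @param variance_target Optional cumulative explained-variance fraction in
#'   (0, 1]; the smallest component count reaching it is used.
#' @param min_sessions_per_sport Sport-support filter passed to
#'   [filter_by_sport()].
#' @param ann_trees Number of random-projection trees in the index.
#' @param ann_search_k Number of tree nodes inspected per query.
#' @param per_sport_pca Fit the PCA separately within each sport instead of on
#'   the pooled post-filter matrix.
#' @param seed Integer seed for index construction.
#' @return An object of class `ddm_reduction_config`.
#' @export
reduction_config <- function(similarity_threshold = 0.99,
                             pca_components = 5,
                             variance_target = NULL,
                             min_sessions_per_sport = 0,
                             ann_trees = 10,
                             ann_search_k = 100,
                             per_sport_pca = FALSE,
                             seed = 1) {
  if (!is.numeric(similarity_threshold) || length(similarity_threshold) != 1 ||
      similarity_threshold <= 0 || similarity_threshold > 1) {
    validation_error("`similarity_threshold` must be in (0, 1].",
                     "similarity_threshold")
  }
  check_number(pca_components, "pca_components", lower = 1, integerish = TRUE)
  if (!is.null(variance_target)) {
    check_number(variance_target, "variance_target", lower = 1e-6, upper = 1)
  }
  check_number(min_sessions_per_sport, "min_sessions_per_sport", lower = 0,
               integerish = TRUE)
  check_number(ann_trees, "ann_trees", lower = 1, integerish = TRUE)
  check_number(ann_search_k, "ann_search_k", lower = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(
      similarity_threshold = similarity_threshold,
      pca_components = as.integer(pca_components),
      variance_target = variance_target,
      min_sessions_per_sport = as.integer(min_sessions_per_sport),
      ann_trees = as.integer(ann_trees),
      ann_search_k = as.integer(ann_search_k),
      per_sport_pca = isTRUE(per_sport_pca),
      seed = as.integer(seed)
    ),
    class = "ddm_reduction_config"
  )
}

#' Project session summaries into a PCA embedding
#'
#' Standardizes the summary features (zero mean, unit variance; constant
#' columns are dropped with a message) and projects them onto the leading
#' principal components. When `variance_target` is set in the config, the
#' smallest number of components whose cumulative explained-variance ratio
#' reaches the target is retained.
#'
#' @param summary A (possibly sport-filtered) [summarize_sessions()] matrix
#'   with at least 2 rows.
#' @param config A [reduction_config()].
#' @return An object of class `ddm_embedding`: list with `scores` (sessions by
#'   components matrix, rownames = session ids), `rotation`, `center`,
#'   `scale`, `explained_variance_ratio`, and `index` (the summary's index
#'   columns).
#' @export
project_pca <- function(summary, config = reduction_config()) {
  feature_cols <- summary_feature_cols(summary)
  if (nrow(summary) < 2) {
    abort("PCA needs at least 2 sessions.", class = "ddmr_validation_error")
  }
  x <- as.matrix(summary[, feature_cols])
  rownames(x) <- summary$session_id

  sds <- apply(x, 2, sd)
  constant <- sds < 1e-12
  if (all(constant)) {
    abort("Summary matrix has zero variance in every column.",
          class = "ddmr_validation_error")
  }
  if (any(constant)) {
    inform(sprintf("Dropping %d constant column(s) before PCA: %s",
                   sum(constant), paste(feature_cols[constant], collapse = ", ")))
    x <- x[, !constant, drop = FALSE]
  }
  centers <- colMeans(x)
  scales <- apply(x, 2, sd)
  xs <- scale(x, center = centers, scale = scales)

  fit <- prcomp(xs, center = FALSE, scale. = FALSE)
  evr <- fit$sdev^2 / sum(fit$sdev^2)

  k <- if (!is.null(config$variance_target)) {
    which(cumsum(evr) >= config$variance_target - 1e-12)[1]
  } else {
    min(config$pca_components, ncol(fit$x))
  }
  structure(
    list(
      scores = fit$x[, seq_len(k), drop = FALSE],
      rotation = fit$rotation[, seq_len(k), drop = FALSE],
      center = centers,
      scale = scales,
      explained_variance_ratio = evr,
      n_components = k,
      index = summary[, SUMMARY_INDEX_COLS]
    ),
    class = "ddm_embedding"
  )
}

#' @export
print.ddm_embedding <- function(x, ...) {
  cat("<ddm_embedding>\n")
  cat(sprintf("  %d sessions x %d components (%.1f%% variance retained)\n",
              nrow(x$scores), x$n_components,
              100 * sum(x$explained_variance_ratio[seq_len(x$n_components)])))
  invisible(x)
}
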