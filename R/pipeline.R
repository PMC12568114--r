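#' Plan the chronological retraining stages
#'
#' Slices the cohort's sessions, ordered by start time, into consecutive
#' stages: by default an initial 55% for the first training, then three 15%
#' increments. Slice sizes are floored, with the remainder assigned to the
#' first slice; stage N's "old data" is the union of all earlier slices (data
#' accumulates raw between stages: `old[N+1] = old[N] + new[N]`).
#'
#' @param table A session table.
#' @param fractions Stage fractions, summing to 1.
#' @return A `ddm_stage_plan`: tibble with one row per session (`session_id`,
#'   `user_id`, `start_time`, `stage`), plus a `fractions` attribute.
#' @export
plan_stages <- function(table, fractions = c(0.55, 0.15, 0.15, 0.15)) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    validation_error("`fractions` must sum to 1.", "fractions")
  }
  assert_session_table(table)
  sessions <- table |>
    group_by(.data$session_id, .data$user_id) |>
    summarise(start_time = min(.data$timestamp), .groups = "drop") |>
    arrange(.data$start_time, .data$session_id)
  n <- nrow(sessions)
  sizes <- floor(fractions * n)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  sessions$stage <- rep(seq_along(fractions), times = sizes)
  attr(sessions, "fractions") <- fractions
  class(sessions) <- c("ddm_stage_plan", class(sessions))
  sessions
}

#' Configure a retraining strategy
#'
#' @param mode One of `"scratch"` (train on all accumulated raw data),
#'   `"simple_merge"` (old data uniformly subsampled to the size of the
#'   DDM-reduced set, then merged with new data) or `"ddm"` (the full
#'   reduce -> select -> package -> retrain path).
#' @param reduction A [reduction_config()].
#' @param controller A [controller_config()].
#' @param hr A [hr_config()].
#' @param rec A [rec_config()].
#' @param negatives_ratio Negatives per positive interaction.
#' @param k Ranking cutoff.
#' @param weight_floor Feature-weight floor used when packaging.
#' @param use_reduction,use_selection Ablation switches for the `ddm` mode.
#' @param warm_start Warm-start models from the previous stage (ignored for
#'   `"scratch"`).
#' @param seed Base seed; per-stage seeds are derived from it.
#' @return A list of class `ddm_strategy_config`.
#' @export
strategy_config <- function(mode = c("ddm", "scratch", "simple_merge"),
                            reduction = reduction_config(),
                            controller = controller_config(),
                            hr = hr_config(),
                            rec = rec_config(),
                            negatives_ratio = 4,
                            k = 10,
                            weight_floor = 0.1,
                            use_reduction = TRUE,
                            use_selection = TRUE,
                            warm_start = TRUE,
                            seed = 1) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode, reduction = reduction, controller = controller,
         hr = hr, rec = rec, negatives_ratio = negatives_ratio, k = k,
         weight_floor = weight_floor, use_reduction = use_reduction,
         use_selection = use_selection, warm_start = warm_start,
         seed = as.integer(seed)),
    class = "ddm_strategy_config"
  )
}

stage_ids <- function(plan, stage_id, old = FALSE) {
  if (old) plan$session_id[plan$stage < stage_id]
  else plan$session_id[plan$stage == stage_id]
}

#' Run one retraining stage under a strategy
#'
#' Assembles the stage's training set according to the strategy mode, fits
#' the heart-rate predictor and the recommender on it, and evaluates both on
#' the chronologically held-out test block. At stage 1 there is no old data,
#' so all modes train on the same initial slice.
#'
#' @param plan A [plan_stages()] plan.
#' @param table The full (cleaned) session table the plan was made from.
#' @param stage_id Stage number (1-based).
#' @param strategy A [strategy_config()].
#' @param state Carry-over from the previous stage (as returned in
#'   `$state`); `NULL` at stage 1. For `simple_merge`, `state$reduced_counts`
#'   must hold the paired DDM run's per-stage reduced-old counts (a
#'   configuration error otherwise).
#' @return A list with `report` (one-row tibble), `version`
#'   (`ddm_data_version`), `weights` (when fitted) and `state` to pass to the
#'   next stage.
#' @export
run_stage <- function(plan, table, stage_id, strategy, state = NULL) {
  t_start <- Sys.time()
  stage_seed <- strategy$seed + 1000L * stage_id
  old_ids <- stage_ids(plan, stage_id, old = TRUE)
  new_ids <- stage_ids(plan, stage_id)
  old_table <- filter(table, .data$session_id %in% old_ids)
  new_table <- filter(table, .data$session_id %in% new_ids)

  user_pattern <- NULL
  weights <- NULL
  n_old <- length(old_ids)
  n_reduced_old <- n_old

  if (stage_id > 1 && n_old > 0) {
    if (strategy$mode == "ddm") {
      if (isTRUE(strategy$use_reduction)) {
        red_cfg <- strategy$reduction
        red_cfg$seed <- stage_seed
        user_pattern <- reduce_sessions(old_table, red_cfg)
        n_reduced_old <- user_pattern$counts$n_after
      } else {
        user_pattern <- keep_all_pattern(old_table, strategy$reduction)
      }
      if (isTRUE(strategy$use_selection)) {
        weights <- fit_stage_weights(user_pattern$sessions, new_table, strategy,
                                     stage_seed)
      }
    } else if (strategy$mode == "simple_merge") {
      target_n <- state$reduced_counts[[as.character(stage_id)]]
      if (is.null(target_n)) {
        abort("simple_merge needs the paired DDM run's reduced-old count in `state$reduced_counts`.",
              class = "ddmr_configuration_error")
      }
      keep <- withr::with_seed(stage_seed,
                               sample(old_ids, min(target_n, n_old)))
      user_pattern <- subset_pattern(old_table, keep, strategy$reduction)
      n_reduced_old <- length(keep)
    } else {
      user_pattern <- keep_all_pattern(old_table, strategy$reduction)
    }
  }

  version <- package_data_version(
    user_pattern = user_pattern, new_data = new_table, weights = weights,
    version_id = stage_id, parent = if (stage_id > 1) stage_id - 1L else NULL,
    weight_floor = strategy$weight_floor
  )

  hr_cfg <- strategy$hr
  hr_cfg$seed <- stage_seed
  warm <- if (strategy$mode != "scratch" && isTRUE(strategy$warm_start)) {
    state$hr_model
  } else {
    NULL
  }
  hr_model <- train_hr_predictor(version, warm_from = warm, config = hr_cfg)

  # recommender protocol: positives from the version's sessions, context from
  # the heart-rate model, chronological 80/10/10, 4 negatives per positive
  ctx <- predict_session_context(hr_model, version$sessions)
  feats <- version$sessions |>
    group_by(.data$session_id, .data$user_id, .data$sport) |>
    summarise(start_time = min(.data$timestamp), .groups = "drop")
  positives <- interactions_from_sessions(feats, context = ctx)
  split <- chronological_split(positives)
  catalog <- sort(unique(plan_catalog(table)))
  negatives <- sample_negatives(split$train, ratio = strategy$negatives_ratio,
                                item_catalog = catalog, seed = stage_seed)
  rec_cfg <- strategy$rec
  rec_cfg$seed <- stage_seed
  rec_model <- train_recommender(bind_rows(split$train, negatives),
                                 item_catalog = catalog, config = rec_cfg)
  rec_eval <- evaluate_recommender(rec_model, split$test, k = strategy$k)

  hr_eval_table <- filter(version$sessions, .data$session_id %in%
                            feats$session_id[feats$start_time >=
                                               min(split$test$timestamp)])
  if (n_distinct(hr_eval_table$session_id) < 2) hr_eval_table <- version$sessions
  hr_pred <- predict_hr(hr_model, hr_eval_table)

  elapsed <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  report <- tibble(
    stage = stage_id,
    mode = strategy$mode,
    version_id = version$version_id,
    n_old = n_old,
    n_reduced_old = if (stage_id > 1) n_reduced_old else 0L,
    n_new = length(new_ids),
    n_total = version$metadata$n_total,
    reduction_rate = if (stage_id > 1 && n_old > 0) {
      reduction_rate(n_old, n_reduced_old)
    } else {
      0
    },
    mae = mae(hr_pred$observed, hr_pred$predicted),
    rmse = rmse(hr_pred$observed, hr_pred$predicted),
    precision = rec_eval$summary$precision,
    recall = rec_eval$summary$recall,
    f1 = rec_eval$summary$f1,
    ndcg = rec_eval$summary$ndcg,
    elapsed = elapsed
  )
  list(
    report = report,
    version = version,
    weights = weights,
    state = list(
      hr_model = hr_model,
      reduced_counts = state$reduced_counts,
      rec_model = rec_model
    )
  )
}

plan_catalog <- function(table) unique(table$sport)

keep_all_pattern <- function(old_table, config) {
  ids <- unique(old_table$session_id)
  structure(
    list(sessions = old_table, kept_ids = ids,
         removed = tibble(session_id = character(),
                          representative_id = character(),
                          user_id = character(), sport = character()),
         counts = list(n_before = length(ids), n_after = length(ids),
                       n_removed = 0L, rate_percent = 0),
         config = config),
    class = "ddm_user_pattern"
  )
}

subset_pattern <- function(old_table, keep_ids, config) {
  ids <- unique(old_table$session_id)
  structure(
    list(sessions = filter(old_table, .data$session_id %in% keep_ids),
         kept_ids = keep_ids,
         removed = tibble(session_id = setdiff(ids, keep_ids),
                          representative_id = NA_character_,
                          user_id = NA_character_, sport = NA_character_),
         counts = list(n_before = length(ids), n_after = length(keep_ids),
                       n_removed = length(ids) - length(keep_ids),
                       rate_percent = reduction_rate(length(ids),
                                                     length(keep_ids))),
         config = config),
    class = "ddm_user_pattern"
  )
}

fit_stage_weights <- function(old_sessions, new_table, strategy, stage_seed) {
  combined <- bind_rows(select(old_sessions, all_of(SESSION_COLUMNS)),
                        select(new_table, all_of(SESSION_COLUMNS)))
  feats <- summarize_sessions(combined) |> add_sequential_features()
  schema <- default_feature_schema()
  cols <- c("session_id", "user_id", "start_time", schema$feature)
  feats <- feats[, intersect(cols, names(feats))]
  feats <- arrange(feats, .data$start_time)
  n <- nrow(feats)
  n_train <- max(2L, floor(0.8 * n))
  ctl <- strategy$controller
  ctl$seed <- stage_seed
  fit_bilevel(feats[seq_len(n_train), ], feats[(n_train + 1):n, ],
              target = "mean_heart_rate", schema = schema, config = ctl)
}

#' Run the staged retraining experiment
#'
#' Executes the four-stage retraining protocol for each requested strategy
#' mode on one cohort, returning per-stage reports (counts, reduction rates,
#' heart-rate error, ranking metrics, wall-clock bookkeeping). When
#' `simple_merge` is requested the `ddm` mode runs first so the size-matched
#' baseline can mirror its reduced-old counts.
#'
#' @param table A session table (cleaned internally).
#' @param modes Strategy modes to run.
#' @param fractions Stage fractions (see [plan_stages()]).
#' @param strategy Base [strategy_config()]; its `mode` field is overridden
#'   per run.
#' @param seed Base seed.
#' @return An object of class `ddm_experiment`: list with `reports` (tibble,
#'   one row per stage x mode), `versions` (the `ddm` mode's data versions),
#'   `weights` (per-stage feature weights), `plan` and `config`.
#' @export
run_experiment <- function(table,
                           modes = c("ddm", "scratch", "simple_merge"),
                           fractions = c(0.55, 0.15, 0.15, 0.15),
                           strategy = strategy_config(),
                           seed = 1) {
  modes <- match.arg(modes, c("ddm", "scratch", "simple_merge"),
                     several.ok = TRUE)
  table <- clean_sessions(table)
  plan <- plan_stages(table, fractions)
  n_stages <- length(fractions)

  if ("simple_merge" %in% modes) {
    modes <- c("ddm", setdiff(modes, "ddm"))
    modes <- unique(c("ddm", modes))
    modes <- modes[order(match(modes, c("ddm", "scratch", "simple_merge")))]
  }

  reports <- list()
  versions <- list()
  weights <- list()
  reduced_counts <- list()
  for (mode in modes) {
    st <- strategy
    st$mode <- mode
    st$seed <- as.integer(seed)
    state <- list(reduced_counts = reduced_counts)
    for (stage in seq_len(n_stages)) {
      res <- run_stage(plan, table, stage, st, state)
      reports[[length(reports) + 1]] <- res$report
      state <- res$state
      state$reduced_counts <- reduced_counts
      if (mode == "ddm") {
        versions[[stage]] <- res$version
        if (!is.null(res$weights)) weights[[stage]] <- res$weights
        reduced_counts[[as.character(stage)]] <- res$report$n_reduced_old
        state$reduced_counts <- reduced_counts
      }
    }
  }

  structure(
    list(reports = bind_rows(reports), versions = versions, weights = weights,
         plan = plan, config = strategy, seed = seed),
    class = "ddm_experiment"
  )
}

#' @export
print.ddm_experiment <- function(x, ...) {
  cat("<ddm_experiment>\n")
  print(as.data.frame(x$reports[, c("stage", "mode", "n_old", "n_reduced_old",
                                    "n_new", "n_total", "reduction_rate",
                                    "mae", "rmse", "ndcg")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Data-version count table for an experiment
#'
#' Renders the `ddm` mode's per-stage counts in the standard shape: version,
#' old data, reduced old data (+ rate), new data, total.
#'
#' @param experiment A [run_experiment()] result.
#' @return A tibble.
#' @export
experiment_count_table <- function(experiment) {
  experiment$reports |>
    filter(.data$mode == "ddm") |>
    mutate(reduced_old = sprintf("%d (%.0f%%)", .data$n_reduced_old,
                                 .data$reduction_rate)) |>
    select(version = "stage", old = "n_old", reduced_old = "reduced_old",
           new = "n_new", total = "n_total")
}

#' Sweep the similarity threshold of the reduction module
#'
#' Re-runs only the reduction (summaries and PCA are shared across
#' thresholds) for each tau and reports the number of removed sessions and
#' the reduction rate — the accuracy/efficiency trade-off curve.
#'
#' @param table A cleaned session table.
#' @param thresholds Similarity thresholds to evaluate.
#' @param config Base [reduction_config()].
#' @return A tibble with `threshold`, `n_before`, `n_removed`,
#'   `reduction_rate`, sorted as given.
#' @export
run_threshold_sweep <- function(table,
                                thresholds = c(1.0, 0.995, 0.99, 0.975, 0.95, 0.90),
                                config = reduction_config()) {
  summary <- summarize_sessions(table)
  summary <- filter_by_sport(summary, config$min_sessions_per_sport)
  embedding <- project_pca(summary, config)
  rows <- lapply(thresholds, function(tau) {
    cfg <- config
    cfg$similarity_threshold <- tau
    up <- reduce_user_sessions(embedding, summary, table, cfg)
    tibble(threshold = tau, n_before = up$counts$n_before,
           n_removed = up$counts$n_removed,
           reduction_rate = up$counts$rate_percent)
  })
  bind_rows(rows)
}

#' Module-contribution ablation
#'
#' Runs the final retraining stage three ways — the full pipeline, without
#' the data-reduction module, and without the feature-selection module — and
#' reports the evaluation metrics for each.
#'
#' @param table A session table.
#' @param fractions Stage fractions.
#' @param strategy Base [strategy_config()].
#' @param seed Base seed.
#' @return A tibble with one row per variant (`ddm`, `no_reduction`,
#'   `no_selection`).
#' @export
run_ablation <- function(table, fractions = c(0.55, 0.15, 0.15, 0.15),
                         strategy = strategy_config(), seed = 1) {
  table <- clean_sessions(table)
  plan <- plan_stages(table, fractions)
  n_stages <- length(fractions)
  variants <- list(
    ddm = c(use_reduction = TRUE, use_selection = TRUE),
    no_reduction = c(use_reduction = FALSE, use_selection = TRUE),
    no_selection = c(use_reduction = TRUE, use_selection = FALSE)
  )
  rows <- lapply(names(variants), function(vn) {
    st <- strategy
    st$mode <- "ddm"
    st$seed <- as.integer(seed)
    st$use_reduction <- as.logical(variants[[vn]]["use_reduction"])
    st$use_selection <- as.logical(variants[[vn]]["use_selection"])
    state <- NULL
    res <- NULL
    for (stage in seq_len(n_stages)) {
      res <- run_stage(plan, table, stage, st, state)
      state <- res$state
    }
    mutate(res$report, variant = vn, .before = 1)
  })
  bind_rows(rows)
}
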