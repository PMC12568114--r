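#' Build an interaction set from session-level records
#'
#' One positive interaction per session: the user consumed an exercise item
#' (the sport) at the session's start time, with the model-predicted mean
#' heart rate attached as a contextual feature. Negatives are added separately
#' by [sample_negatives()].
#'
#' @param features Session-level tibble with `session_id`, `user_id`, `sport`,
#'   `start_time`.
#' @param context Optional named numeric vector (names = session ids) of
#'   contextual values, e.g. predicted mean heart rate; defaults to 0.
#' @return An interaction tibble: `user_id`, `item_id`, `timestamp`,
#'   `context`, `label` (= 1).
#' @export
interactions_from_sessions <- function(features, context = NULL) {
  ctx <- if (is.null(context)) {
    rep(0, nrow(features))
  } else {
    as.numeric(context[features$session_id])
  }
  tibble(
    user_id = features$user_id,
    item_id = features$sport,
    timestamp = features$start_time,
    context = ctx,
    label = 1L
  ) |>
    arrange(.data$timestamp)
}

#' Chronologically split interactions into train/validation/test
#'
#' The interactions are sorted by timestamp and cut into contiguous,
#' non-overlapping blocks: the oldest fraction for training, then validation,
#' then the most recent block for testing, so no test interaction predates a
#' training one. Block sizes are floored, with the remainder assigned to the
#' training block.
#'
#' @param interactions Interaction tibble with a `timestamp` column.
#' @param fractions Length-3 numeric vector summing to 1 (default 80/10/10).
#' @return A list with elements `train`, `val`, `test`.
#' @export
chronological_split <- function(interactions, fractions = c(0.8, 0.1, 0.1)) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    validation_error("`fractions` must be three numbers summing to 1.",
                     "fractions")
  }
  ordered <- arrange(interactions, .data$timestamp)
  n <- nrow(ordered)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  list(
    train = ordered[seq_len(n_train), ],
    val = ordered[seq_len(n_val) + n_train, ],
    test = ordered[seq_len(n_test) + n_train + n_val, ]
  )
}

#' Sample uniform negative interactions
#'
#' Pairs every positive interaction with `ratio` negatives drawn uniformly at
#' random from the whole item catalog (with replacement). Uniform sampling is
#' deliberately not positive-excluding: a sampled negative may coincide with
#' an item the user actually consumed, unless `exclude_positive = TRUE`.
#' Negatives inherit the positive's user, timestamp and context, with label 0.
#'
#' @param positives Interaction tibble (label 1 rows).
#' @param ratio Negatives per positive (>= 0).
#' @param item_catalog Character vector of all item ids (non-empty).
#' @param seed Integer seed.
#' @param exclude_positive Resample negatives that collide with the same
#'   user's positives.
#' @return The negative interactions (label 0), `ratio * nrow(positives)`
#'   rows.
#' @export
sample_negatives <- function(positives, ratio = 4, item_catalog, seed = 1,
                             exclude_positive = FALSE) {
  if (length(item_catalog) == 0) {
    validation_error("`item_catalog` must be non-empty.", "item_catalog")
  }
  check_number(ratio, "ratio", lower = 0, integerish = TRUE)
  if (ratio == 0 || nrow(positives) == 0) return(positives[0, ])
  withr::with_seed(seed, {
    idx <- rep(seq_len(nrow(positives)), each = ratio)
    items <- sample(item_catalog, length(idx), replace = TRUE)
    if (exclude_positive) {
      user_items <- split(positives$item_id, positives$user_id)
      for (i in seq_along(idx)) {
        u <- positives$user_id[idx[i]]
        tries <- 0
        while (items[i] %in% user_items[[u]] && tries < 50) {
          items[i] <- sample(item_catalog, 1)
          tries <- tries + 1
        }
      }
    }
    out <- positives[idx, ]
    out$item_id <- items
    out$label <- 0L
    out
  })
}
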