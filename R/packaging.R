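#' Package a versioned training dataset
#'
#' Combines the reduced historical sessions (user pattern data) with newly
#' collected, preprocessed sessions and applies the fitted feature weights to
#' produce an immutable, versioned training dataset: the unit the retraining
#' pipeline consumes. Feature columns whose weight falls below the policy
#' floor are dropped from the version's feature table (`mode = "drop"`), or
#' numeric features are scaled by their weight (`mode = "scale"`); all weights
#' are recorded in the metadata either way, so the decision is reversible
#' downstream.
#'
#' @param user_pattern A `ddm_user_pattern` from [reduce_user_sessions()], or
#'   `NULL` for an initial version with no historical data.
#' @param new_data Session table of new records (session ids disjoint from
#'   the kept old ones).
#' @param weights Optional `ddm_feature_weights`.
#' @param version_id Monotone integer version identifier.
#' @param parent Parent version id (`NULL` for the first version).
#' @param weight_floor Features with weight below this are dropped.
#' @param mode `"drop"` or `"scale"`.
#' @return An object of class `ddm_data_version`: list with `version_id`,
#'   `sessions` (timestep-level records), `features` (session-level feature
#'   table after weight filtering), `metadata`.
#' @export
package_data_version <- function(user_pattern = NULL, new_data, weights = NULL,
                            version_id = 1L, parent = NULL,
                            weight_floor = 0.1, mode = c("drop", "scale")) {
  mode <- match.arg(mode)
  assert_session_table(new_data, "new_data")
  old_sessions <- if (is.null(user_pattern)) {
    new_data[0, ]
  } else {
    user_pattern$sessions
  }
  old_ids <- unique(old_sessions$session_id)
  new_ids <- unique(new_data$session_id)
  collisions <- intersect(old_ids, new_ids)
  if (length(collisions) > 0) {
    abort(sprintf("session_id collision between old and new data: %s",
                  paste(collisions, collapse = ", ")),
          class = "ddmr_validation_error")
  }

  sessions <- bind_rows(
    select(old_sessions, all_of(SESSION_COLUMNS)),
    select(new_data, all_of(SESSION_COLUMNS))
  )
  attr(sessions, "cleaning_report") <- NULL
  features <- summarize_sessions(sessions) |> add_sequential_features()

  dropped_features <- character(0)
  if (!is.null(weights)) {
    present <- intersect(weights$feature, names(features))
    if (mode == "drop") {
      dropped_features <- weights$feature[weights$weight < weight_floor]
      features <- features[, setdiff(names(features),
                                     intersect(dropped_features, present))]
    } else {
      for (f in present) {
        w <- weights$weight[weights$feature == f]
        if (is.numeric(features[[f]])) features[[f]] <- features[[f]] * w
      }
    }
  }

  n_old <- length(old_ids)
  n_new <- length(new_ids)
  metadata <- list(
    version_id = as.integer(version_id),
    parent = if (is.null(parent)) NULL else as.integer(parent),
    n_old_kept = n_old,
    n_new = n_new,
    n_total = n_old + n_new,
    reduction = if (is.null(user_pattern)) NULL else c(
      user_pattern$counts,
      list(similarity_threshold = user_pattern$config$similarity_threshold)
    ),
    feature_weights = if (is.null(weights)) NULL else
      setNames(as.list(weights$weight), weights$feature),
    dropped_features = dropped_features,
    weight_floor = weight_floor,
    weight_mode = mode,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  structure(
    list(version_id = as.integer(version_id), sessions = sessions,
         features = features, metadata = metadata),
    class = "ddm_data_version"
  )
}

#' @export
print.ddm_data_version <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<ddm_data_version %d>\n", x$version_id))
  cat(sprintf("  sessions: %d old + %d new = %d total\n",
              m$n_old_kept, m$n_new, m$n_total))
  if (!is.null(m$reduction)) {
    cat(sprintf("  reduction: %.1f%% at tau = %.3f\n",
                m$reduction$rate_percent, m$reduction$similarity_threshold))
  }
  invisible(x)
}

version_dir <- function(root_dir, version_id) {
  file.path(root_dir, sprintf("version_%03d", as.integer(version_id)))
}

#' Write / read a data version on disk
#'
#' Each version occupies its own directory under `root_dir`
#' (`version_<id>/`): timestep records and session-level features as CSV,
#' metadata as a JSON sidecar. Reading verifies integrity (recorded counts
#' must match the records); the round trip is the identity.
#'
#' @param v A `ddm_data_version`.
#' @param root_dir Version store directory.
#' @return `write_version()` returns the version directory invisibly;
#'   `read_version()` returns the `ddm_data_version`.
#' @export
write_version <- function(v, root_dir) {
  dir.create(root_dir, showWarnings = FALSE, recursive = TRUE)
  d <- version_dir(root_dir, v$version_id)
  dir.create(d, showWarnings = FALSE)
  write_sessions(v$sessions, file.path(d, "sessions.csv"))
  feats <- mutate(v$features, start_time = format(.data$start_time,
                                                  "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  readr::write_csv(feats, file.path(d, "features.csv"))
  jsonlite::write_json(v$metadata, file.path(d, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(d)
}

#' @rdname write_version
#' @param version_id Version id to read.
#' @export
read_version <- function(root_dir, version_id) {
  d <- version_dir(root_dir, version_id)
  meta_path <- file.path(d, "metadata.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("No metadata for version %s under %s.", version_id, root_dir),
          class = "ddmr_integrity_error")
  }
  metadata <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  sessions <- read_sessions(file.path(d, "sessions.csv"))
  features <- readr::read_csv(file.path(d, "features.csv"),
                              col_types = readr::cols(), progress = FALSE) |>
    mutate(start_time = as.POSIXct(.data$start_time,
                                   format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  n_total <- n_distinct(sessions$session_id)
  if (!identical(as.integer(metadata$n_total), as.integer(n_total))) {
    abort(sprintf(
      "Version %s metadata records %s sessions but %d are present.",
      version_id, metadata$n_total, n_total),
      class = "ddmr_integrity_error")
  }
  if (!is.null(metadata$parent) && length(metadata$parent) == 0) {
    metadata$parent <- NULL
  }
  structure(
    list(version_id = as.integer(metadata$version_id), sessions = sessions,
         features = features, metadata = metadata),
    class = "ddm_data_version"
  )
}

#' Walk a version's lineage back to its root
#'
#' @param root_dir Version store directory.
#' @param version_id Version to start from.
#' @return Integer vector of version ids from the root ancestor to
#'   `version_id`.
#' @export
version_lineage <- function(root_dir, version_id) {
  chain <- integer(0)
  current <- as.integer(version_id)
  seen <- integer(0)
  while (!is.null(current)) {
    if (current %in% seen) {
      abort("Version lineage contains a cycle.", class = "ddmr_integrity_error")
    }
    seen <- c(seen, current)
    chain <- c(current, chain)
    v <- read_version(root_dir, current)
    current <- if (is.null(v$metadata$parent)) NULL else as.integer(v$metadata$parent)
  }
  chain
}
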