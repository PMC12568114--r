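#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy fitted feature weights
#'
#' @param x A `ddm_feature_weights` object.
#' @param ... Unused.
#' @return A tibble with `feature`, `group`, `weight`, `rank`.
#' @method tidy ddm_feature_weights
#' @export
tidy.ddm_feature_weights <- function(x, ...) {
  out <- as_tibble(x)
  out$rank <- rank(-out$weight, ties.method = "first")
  out
}

#' @rdname tidy.ddm_feature_weights
#' @method glance ddm_feature_weights
#' @export
glance.ddm_feature_weights <- function(x, ...) {
  prov <- attr(x, "provenance")
  tibble(
    n_features = nrow(x),
    n_outer = prov$n_outer,
    final_train_loss = if (length(prov$train_loss)) tail(prov$train_loss, 1) else NA_real_,
    final_val_loss = if (length(prov$val_loss)) tail(prov$val_loss, 1) else NA_real_,
    seed = prov$seed
  )
}

#' Tidy a user-pattern reduction result
#'
#' @param x A `ddm_user_pattern` object.
#' @param ... Unused.
#' @return The removed-session map: one row per removed session with the
#'   representative that subsumed it.
#' @method tidy ddm_user_pattern
#' @export
tidy.ddm_user_pattern <- function(x, ...) {
  as_tibble(x$removed)
}

#' @rdname tidy.ddm_user_pattern
#' @method glance ddm_user_pattern
#' @export
glance.ddm_user_pattern <- function(x, ...) {
  tibble(
    n_before = x$counts$n_before,
    n_after = x$counts$n_after,
    n_removed = x$counts$n_removed,
    reduction_rate = x$counts$rate_percent,
    similarity_threshold = x$config$similarity_threshold
  )
}

#' Tidy an experiment's stage reports
#'
#' @param x A `ddm_experiment` object.
#' @param ... Unused.
#' @return The per-stage, per-mode report tibble.
#' @method tidy ddm_experiment
#' @export
tidy.ddm_experiment <- function(x, ...) {
  as_tibble(x$reports)
}

#' Glance at a packaged data version
#'
#' @param x A `ddm_data_version` object.
#' @param ... Unused.
#' @return One-row tibble of the version's counts and reduction metadata.
#' @method glance ddm_data_version
#' @export
glance.ddm_data_version <- function(x, ...) {
  m <- x$metadata
  tibble(
    version_id = m$version_id,
    parent = m$parent %||% NA_integer_,
    n_old_kept = m$n_old_kept,
    n_new = m$n_new,
    n_total = m$n_total,
    reduction_rate = if (is.null(m$reduction)) NA_real_ else m$reduction$rate_percent,
    n_dropped_features = length(m$dropped_features)
  )
}
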