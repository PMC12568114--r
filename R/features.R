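FEATURE_GROUPS <- c("attribute", "contextual", "health_metric", "sequential")

#' Define a feature-group schema
#'
#' Every input feature is assigned to exactly one of four groups: `attribute`
#' (user/item attributes such as sport), `contextual` (exercise context such
#' as duration, distance, intensity), `health_metric` (physiological measures
#' such as heart rate and recovery speed) and `sequential` (temporally ordered
#' activity patterns such as per-user session order). The assignment must be
#' total and disjoint.
#'
#' @param attribute,contextual,health_metric,sequential Character vectors of
#'   feature names.
#' @return A tibble of class `ddm_feature_schema` with columns `feature`,
#'   `group`, in schema order (the tie-break order used when ranking).
#' @export
feature_group_schema <- function(attribute = character(),
                                 contextual = character(),
                                 health_metric = character(),
                                 sequential = character()) {
  groups <- list(attribute = attribute, contextual = contextual,
                 health_metric = health_metric, sequential = sequential)
  schema <- bind_rows(lapply(names(groups), function(g) {
    if (length(groups[[g]]) == 0) return(NULL)
    tibble(feature = groups[[g]], group = g)
  }))
  if (is.null(schema) || nrow(schema) == 0) {
    validation_error("Schema must contain at least one feature.", "schema")
  }
  dups <- schema$feature[duplicated(schema$feature)]
  if (length(dups) > 0) {
    validation_error(
      sprintf("Features assigned to more than one group: %s",
              paste(unique(dups), collapse = ", ")),
      "schema"
    )
  }
  class(schema) <- c("ddm_feature_schema", class(schema))
  schema
}

#' Default schema for the session-level features of this package
#'
#' Maps the features produced by [summarize_sessions()] /
#' [add_sequential_features()] onto the four groups.
#'
#' @return A `ddm_feature_schema`.
#' @export
default_feature_schema <- function() {
  feature_group_schema(
    attribute = "sport",
    contextual = c("duration", "total_distance", "exercise_intensity"),
    health_metric = c("mean_heart_rate", "peak_heart_rate", "recovery_speed",
                      "hr_sd"),
    sequential = c("session_index", "days_since_prev")
  )
}

#' Per-user session-order statistics
#'
#' Adds the sequential-group features to a session-level table: `session_index`
#' (1-based order of the session within its user's history) and
#' `days_since_prev` (days elapsed since the user's previous session, 0 for
#' the first).
#'
#' @param rows A session-level tibble with `user_id` and `start_time`.
#' @return `rows` with `session_index` and `days_since_prev` appended.
#' @export
add_sequential_features <- function(rows) {
  rows |>
    group_by(.data$user_id) |>
    arrange(.data$start_time, .by_group = TRUE) |>
    mutate(
      session_index = row_number(),
      days_since_prev = as.numeric(
        difftime(.data$start_time, dplyr::lag(.data$start_time,
                                              default = first(.data$start_time)),
                 units = "days"))
    ) |>
    ungroup()
}

#' Encode feature columns into grouped numeric blocks
#'
#' Turns a session-level feature table into the numeric design matrix the
#' controller weights. Numeric features pass through as single columns;
#' categorical features are one-hot encoded (levels fixed by `encoders` when
#' supplied, so train and validation encodings align). Identifier columns
#' (`session_id`, `user_id`, `start_time`) are carried, not encoded. Any other
#' column not named in the schema is an error, as is a schema feature missing
#' from the data.
#'
#' @param rows Feature tibble.
#' @param schema A [feature_group_schema()].
#' @param encoders Optional encoder list from a previous call (its `levels`
#'   are reused).
#' @return A list of class `ddm_feature_blocks`: `x` (numeric matrix), `map`
#'   (tibble column -> feature -> group), `encoders`.
#' @export
embed_features <- function(rows, schema, encoders = NULL) {
  id_cols <- c("session_id", "user_id", "start_time")
  data_cols <- setdiff(names(rows), id_cols)
  unknown <- setdiff(data_cols, schema$feature)
  if (length(unknown) > 0) {
    abort(sprintf("Columns not mapped by the schema: %s",
                  paste(unknown, collapse = ", ")),
          class = "ddmr_schema_error")
  }
  missing <- setdiff(schema$feature, data_cols)
  if (length(missing) > 0) {
    abort(sprintf("Schema features absent from the data: %s",
                  paste(missing, collapse = ", ")),
          class = "ddmr_schema_error")
  }

  levels_map <- if (is.null(encoders)) list() else encoders$levels
  cols <- list()
  map <- list()
  for (i in seq_len(nrow(schema))) {
    f <- schema$feature[i]
    g <- schema$group[i]
    v <- rows[[f]]
    if (is.numeric(v)) {
      cols[[f]] <- matrix(v, ncol = 1, dimnames = list(NULL, f))
      map[[f]] <- tibble(column = f, feature = f, group = g)
    } else {
      lv <- levels_map[[f]] %||% sort(unique(as.character(v)))
      levels_map[[f]] <- lv
      m <- vapply(lv, function(l) as.numeric(as.character(v) == l),
                  numeric(length(v)))
      if (length(v) == 1) m <- matrix(m, nrow = 1)
      colnames(m) <- paste0(f, "=", lv)
      cols[[f]] <- m
      map[[f]] <- tibble(column = colnames(m), feature = f, group = g)
    }
  }
  structure(
    list(x = do.call(cbind, cols), map = bind_rows(map),
         encoders = list(levels = levels_map)),
    class = "ddm_feature_blocks"
  )
}

#' Configure the feature-weight controller
#'
#' @param hidden Hidden-layer width of the two-layer MLP.
#' @param dropout Dropout rate on the hidden layer, active only while fitting.
#' @param n_outer Outer (controller) update steps.
#' @param n_inner Inner (downstream-model) gradient steps per outer step.
#' @param lr_inner,lr_outer Learning rates for the inner model and the
#'   controller.
#' @param ridge L2 penalty on the inner model's coefficients.
#' @param seed Integer seed.
#' @return A list of class `ddm_controller_config`.
#' @export
controller_config <- function(hidden = 32, dropout = 0.2, n_outer = 20,
                              n_inner = 10, lr_inner = 0.1, lr_outer = 0.2,
                              ridge = 1e-3, seed = 1) {
  check_number(hidden, "hidden", lower = 1, integerish = TRUE)
  check_number(dropout, "dropout", lower = 0, upper = 0.99)
  check_number(n_outer, "n_outer", lower = 0, integerish = TRUE)
  check_number(n_inner, "n_inner", lower = 1, integerish = TRUE)
  structure(
    list(hidden = as.integer(hidden), dropout = dropout,
         n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
         lr_inner = lr_inner, lr_outer = lr_outer, ridge = ridge,
         seed = as.integer(seed)),
    class = "ddm_controller_config"
  )
}

#' Initialize a feature-weight controller
#'
#' A two-layer perceptron with rectified-linear hidden activation, dropout on
#' the hidden layer (rate set in the config, active only during fitting) and
#' sigmoid-bounded outputs: one weight in \[0, 1\] per schema feature, driven
#' by a latent summary vector `z` of the current data batch.
#'
#' @param feature_names Character vector of schema features (output order).
#' @param input_dim Dimension of the latent vector `z`.
#' @param config A [controller_config()].
#' @return An object of class `ddm_controller`.
#' @export
new_feature_controller <- function(feature_names, input_dim,
                                   config = controller_config()) {
  m <- length(feature_names)
  withr::with_seed(config$seed, {
    state <- list(
      W1 = matrix(rnorm(config$hidden * input_dim, sd = 1 / sqrt(input_dim)),
                  config$hidden, input_dim),
      b1 = numeric(config$hidden),
      W2 = matrix(rnorm(m * config$hidden, sd = 1 / sqrt(config$hidden)),
                  m, config$hidden),
      b2 = numeric(m),
      feature_names = feature_names,
      dropout = config$dropout
    )
  })
  structure(state, class = "ddm_controller")
}

#' Forward pass of the controller
#'
#' In evaluation mode (`training = FALSE`, the default) the pass is
#' deterministic; dropout noise is injected only during fitting.
#'
#' @param state A [new_feature_controller()] object.
#' @param z Latent input vector.
#' @param training Apply dropout to the hidden layer.
#' @return A named numeric vector of feature weights in \[0, 1\].
#' @export
controller_forward <- function(state, z, training = FALSE) {
  fw <- controller_forward_cache(state, z, training)
  setNames(as.numeric(fw$a), state$feature_names)
}

controller_forward_cache <- function(state, z, training = FALSE) {
  if (length(z) != ncol(state$W1)) {
    abort(sprintf("`z` has dimension %d; controller expects %d.",
                  length(z), ncol(state$W1)),
          class = "ddmr_validation_error")
  }
  pre <- as.numeric(state$W1 %*% z + state$b1)
  h <- pmax(pre, 0)
  mask <- rep(1, length(h))
  if (training && state$dropout > 0) {
    mask <- stats::rbinom(length(h), 1, 1 - state$dropout) / (1 - state$dropout)
    h <- h * mask
  }
  s <- as.numeric(state$W2 %*% h + state$b2)
  a <- 1 / (1 + exp(-s))
  list(a = a, s = s, h = h, pre = pre, mask = mask, z = z)
}

#' Fit feature weights by bi-level optimization
#'
#' Alternates two nested optimizations: the inner loop fits a downstream
#' linear heart-rate model on the training split with the current weights
#' applied multiplicatively to the (standardized, encoded) features; the
#' outer loop updates the controller by the first-order gradient of the
#' validation loss with respect to the weights, holding the inner model's
#' coefficients fixed. The validation loss thus supervises which features the
#' controller should amplify. The latent vector `z` is the per-batch mean of
#' the encoded training features. Fully seeded; aborts on a non-finite loss.
#'
#' @param train,val Disjoint chronological feature tibbles, each containing
#'   the schema features plus the target column.
#' @param target Name of the numeric target column (default
#'   `"mean_heart_rate"`; the target is excluded from the weighted features).
#' @param schema A [feature_group_schema()]; defaults to the features present.
#' @param config A [controller_config()].
#' @return A `ddm_feature_weights` tibble (`feature`, `group`, `weight`) with
#'   provenance (`n_outer`, seed, loss trajectories) and the fitted controller
#'   attached as attributes.
#' @export
fit_bilevel <- function(train, val, target = "mean_heart_rate",
                        schema = NULL, config = controller_config()) {
  if (!target %in% names(train) || !target %in% names(val)) {
    abort(sprintf("Target column `%s` missing.", target),
          class = "ddmr_validation_error")
  }
  if (is.null(schema)) {
    feats <- setdiff(names(train), c("session_id", "user_id", "start_time", target))
    schema <- feature_group_schema(contextual = feats)
  }
  schema <- schema[schema$feature != target, ]
  strip <- function(d) d[, setdiff(names(d), target), drop = FALSE]
  blocks_tr <- embed_features(strip(train), schema)
  blocks_val <- embed_features(strip(val), schema, encoders = blocks_tr$encoders)

  x_tr <- blocks_tr$x
  x_val <- blocks_val$x
  mu <- colMeans(x_tr)
  sg <- pmax(apply(x_tr, 2, sd), 1e-8)
  x_tr <- sweep(sweep(x_tr, 2, mu), 2, sg, "/")
  x_val <- sweep(sweep(x_val, 2, mu), 2, sg, "/")

  y_mu <- mean(train[[target]])
  y_sg <- max(sd(train[[target]]), 1e-8)
  y_tr <- (train[[target]] - y_mu) / y_sg
  y_val <- (val[[target]] - y_mu) / y_sg

  z <- colMeans(x_tr)
  col_feature <- blocks_tr$map$feature
  feat_idx <- match(col_feature, schema$feature)

  state <- new_feature_controller(schema$feature, length(z), config)
  n_tr <- nrow(x_tr)
  n_val <- nrow(x_val)
  p <- ncol(x_tr)
  beta <- numeric(p)
  b0 <- 0
  train_loss <- numeric(0)
  val_loss <- numeric(0)

  withr::with_seed(config$seed + 1L, {
    for (step in seq_len(config$n_outer)) {
      fw <- controller_forward_cache(state, z, training = TRUE)
      acol <- fw$a[feat_idx]
      xw_tr <- sweep(x_tr, 2, acol, "*")
      xw_val <- sweep(x_val, 2, acol, "*")

      for (it in seq_len(config$n_inner)) {
        r <- as.numeric(xw_tr %*% beta) + b0 - y_tr
        g_beta <- as.numeric(crossprod(xw_tr, r)) * (2 / n_tr) +
          2 * config$ridge * beta
        beta <- beta - config$lr_inner * g_beta
        b0 <- b0 - config$lr_inner * 2 * mean(r)
      }
      r_tr <- as.numeric(xw_tr %*% beta) + b0 - y_tr
      r_val <- as.numeric(xw_val %*% beta) + b0 - y_val
      train_loss[step] <- mean(r_tr^2)
      val_loss[step] <- mean(r_val^2)
      if (!is.finite(val_loss[step]) || !is.finite(train_loss[step])) {
        abort(sprintf(
          "Non-finite loss at outer step %d (train %.3g, val %.3g); lower the learning rates.",
          step, train_loss[step], val_loss[step]),
          class = "ddmr_optimization_error")
      }

      # d(val loss)/d a_col, then aggregated to schema features
      d_acol <- as.numeric(crossprod(x_val, r_val) * beta) * (2 / n_val)
      d_a <- vapply(seq_len(nrow(schema)),
                    function(mi) sum(d_acol[feat_idx == mi]), numeric(1))

      ds <- d_a * fw$a * (1 - fw$a)
      dW2 <- tcrossprod(ds, fw$h)
      db2 <- ds
      dh <- as.numeric(crossprod(state$W2, ds)) * fw$mask
      dpre <- dh * (fw$pre > 0)
      dW1 <- tcrossprod(dpre, z)
      db1 <- dpre

      state$W1 <- state$W1 - config$lr_outer * dW1
      state$b1 <- state$b1 - config$lr_outer * db1
      state$W2 <- state$W2 - config$lr_outer * dW2
      state$b2 <- state$b2 - config$lr_outer * db2
    }
  })

  weights <- controller_forward(state, z, training = FALSE)
  out <- tibble(feature = schema$feature, group = schema$group,
                weight = as.numeric(weights))
  class(out) <- c("ddm_feature_weights", class(out))
  attr(out, "provenance") <- list(
    n_outer = config$n_outer, n_inner = config$n_inner, seed = config$seed,
    train_loss = train_loss, val_loss = val_loss, target = target
  )
  attr(out, "controller") <- state
  attr(out, "z") <- z
  out
}

#' Select the most important features from fitted weights
#'
#' Deterministic ranking by decreasing weight; ties are broken by schema
#' order. Exactly one of `top_m` or `weight_floor` selects the subset.
#'
#' @param weights A `ddm_feature_weights` tibble (see [fit_bilevel()]).
#' @param top_m Keep the `top_m` highest-weighted features.
#' @param weight_floor Keep features with `weight >= weight_floor`.
#' @return The selected rows of `weights`, with a `rank` column, in rank
#'   order.
#' @export
select_important_features <- function(weights, top_m = NULL, weight_floor = NULL) {
  if (is.null(top_m) && is.null(weight_floor)) {
    validation_error("Supply `top_m` or `weight_floor`.", "top_m")
  }
  ranked <- weights[order(-weights$weight, seq_len(nrow(weights))), ]
  ranked$rank <- seq_len(nrow(ranked))
  if (!is.null(top_m)) {
    check_number(top_m, "top_m", lower = 1, integerish = TRUE)
    if (top_m > nrow(weights)) {
      validation_error(
        sprintf("`top_m` (%d) exceeds the number of features (%d).",
                top_m, nrow(weights)), "top_m")
    }
    return(head(ranked, top_m))
  }
  filter(ranked, .data$weight >= weight_floor)
}

#' Serialize feature weights to JSON / schema to YAML
#'
#' @param weights A `ddm_feature_weights` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_weights <- function(weights, path) {
  payload <- list(
    weights = setNames(as.list(weights$weight), weights$feature),
    groups = setNames(as.list(weights$group), weights$feature),
    provenance = attr(weights, "provenance")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_weights
#' @param schema A `ddm_feature_schema`.
#' @export
write_feature_schema <- function(schema, path) {
  groups <- split(schema$feature, schema$group)
  yaml::write_yaml(groups, path)
  invisible(path)
}
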