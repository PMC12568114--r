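#' Configure the exercise recommender
#'
#' @param embedding_dim User/item embedding size.
#' @param hidden Width of the perceptron head's hidden layer.
#' @param epochs Full-batch gradient epochs.
#' @param lr Learning rate.
#' @param seed Integer seed.
#' @return A list of class `ddm_rec_config`.
#' @export
rec_config <- function(embedding_dim = 16, hidden = 16, epochs = 400, lr = 1,
                       seed = 1) {
  structure(
    list(embedding_dim = as.integer(embedding_dim), hidden = as.integer(hidden),
         epochs = as.integer(epochs), lr = lr, seed = as.integer(seed)),
    class = "ddm_rec_config"
  )
}

#' Train a neural collaborative-filtering recommender
#'
#' Learned user and item embedding tables feed, together with a scalar
#' contextual feature (the predicted mean heart rate), a one-hidden-layer
#' perceptron head with a sigmoid output, trained with binary cross-entropy
#' on positives plus sampled negatives. Training is full-batch gradient
#' descent, fully seeded.
#'
#' @param interactions Interaction tibble (positives and negatives) with
#'   `user_id`, `item_id`, `context`, `label`.
#' @param item_catalog Character vector of all item ids scored at inference;
#'   defaults to the items observed in `interactions`.
#' @param config A [rec_config()].
#' @return An object of class `ddm_recommender` with `$losses` (BCE per
#'   epoch, entry 1 pre-update).
#' @export
train_recommender <- function(interactions, item_catalog = NULL,
                              config = rec_config()) {
  if (nrow(interactions) == 0) {
    abort("No interactions to train on.", class = "ddmr_validation_error")
  }
  users <- sort(unique(interactions$user_id))
  items <- sort(unique(c(interactions$item_id, item_catalog)))
  ui <- match(interactions$user_id, users)
  ii <- match(interactions$item_id, items)
  y <- as.numeric(interactions$label)

  ctx_mu <- mean(interactions$context)
  ctx_sg <- max(sd(interactions$context), 1e-8)
  ctx <- (interactions$context - ctx_mu) / ctx_sg

  d <- config$embedding_dim
  h_size <- config$hidden
  withr::with_seed(config$seed, {
    params <- list(
      U = matrix(rnorm(length(users) * d, sd = 0.1), length(users), d),
      V = matrix(rnorm(length(items) * d, sd = 0.1), length(items), d),
      W1 = matrix(rnorm((2 * d + 1) * h_size, sd = 1 / sqrt(2 * d + 1)),
                  2 * d + 1, h_size),
      b1 = numeric(h_size),
      w2 = rnorm(h_size, sd = 0.3),
      b2 = 0
    )
  })

  n <- length(y)
  forward <- function(params) {
    x <- cbind(params$U[ui, , drop = FALSE], params$V[ii, , drop = FALSE], ctx)
    z1 <- x %*% params$W1 + matrix(params$b1, n, h_size, byrow = TRUE)
    hh <- pmax(z1, 0)
    s <- as.numeric(hh %*% params$w2) + params$b2
    p <- 1 / (1 + exp(-s))
    list(x = x, z1 = z1, h = hh, p = p)
  }
  bce <- function(p) {
    eps <- 1e-12
    -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  }

  losses <- numeric(config$epochs + 1)
  fw <- forward(params)
  losses[1] <- bce(fw$p)
  for (ep in seq_len(config$epochs)) {
    ds <- (fw$p - y) / n
    dw2 <- as.numeric(crossprod(fw$h, ds))
    db2 <- sum(ds)
    dh <- outer(ds, params$w2)
    dz1 <- dh * (fw$z1 > 0)
    dW1 <- crossprod(fw$x, dz1)
    db1 <- colSums(dz1)
    dx <- dz1 %*% t(params$W1)
    dU <- rowsum(dx[, seq_len(d), drop = FALSE], ui)
    dV <- rowsum(dx[, d + seq_len(d), drop = FALSE], ii)

    params$w2 <- params$w2 - config$lr * dw2
    params$b2 <- params$b2 - config$lr * db2
    params$W1 <- params$W1 - config$lr * dW1
    params$b1 <- params$b1 - config$lr * db1
    uidx <- as.integer(rownames(dU))
    vidx <- as.integer(rownames(dV))
    params$U[uidx, ] <- params$U[uidx, ] - config$lr * dU
    params$V[vidx, ] <- params$V[vidx, ] - config$lr * dV

    fw <- forward(params)
    losses[ep + 1] <- bce(fw$p)
    if (!is.finite(losses[ep + 1])) {
      abort(sprintf("Non-finite recommender loss at epoch %d.", ep),
            class = "ddmr_optimization_error")
    }
  }

  structure(
    list(params = params, users = users, items = items,
         ctx_mu = ctx_mu, ctx_sg = ctx_sg, losses = losses, config = config),
    class = "ddm_recommender"
  )
}

#' Top-K exercise recommendations for a user
#'
#' Scores every catalog item for the user under the given context and returns
#' the `k` best, deterministically (score ties broken by catalog order). A
#' user unseen at training time raises a cold-start error rather than backing
#' off silently.
#'
#' @param model A `ddm_recommender`.
#' @param user User id.
#' @param k List length (all items when `k` exceeds the catalog).
#' @param context Contextual value (raw scale, e.g. predicted bpm); defaults
#'   to the training mean.
#' @return Character vector of item ids, best first.
#' @export
recommend_top_k <- function(model, user, k = 10, context = NULL) {
  uix <- match(user, model$users)
  if (is.na(uix)) {
    abort(sprintf("User `%s` was not seen during training (cold start).", user),
          class = "ddmr_cold_start_error")
  }
  ctx <- if (is.null(context)) 0 else (context - model$ctx_mu) / model$ctx_sg
  n_items <- length(model$items)
  d <- model$config$embedding_dim
  x <- cbind(
    matrix(model$params$U[uix, ], n_items, d, byrow = TRUE),
    model$params$V,
    rep(ctx, n_items)
  )
  z1 <- x %*% model$params$W1 +
    matrix(model$params$b1, n_items, length(model$params$b1), byrow = TRUE)
  s <- as.numeric(pmax(z1, 0) %*% model$params$w2) + model$params$b2
  ord <- order(-s, seq_len(n_items))
  model$items[head(ord, min(k, n_items))]
}

#' Evaluate a recommender on held-out test interactions
#'
#' Ground truth for each user is the set of items actually consumed in the
#' test block. Users without test positives (or unknown to the model) are
#' skipped, matching per-user evaluation over users with test items.
#'
#' @param model A `ddm_recommender`.
#' @param test_positives Test-block positive interactions.
#' @param k Cutoff (default 10).
#' @return A list with `per_user` (tibble of per-user metrics) and `summary`
#'   (one-row tibble of means).
#' @export
evaluate_recommender <- function(model, test_positives, k = 10) {
  test_positives <- filter(test_positives, .data$label == 1)
  per_user <- list()
  for (u in unique(test_positives$user_id)) {
    if (!u %in% model$users) next
    rows <- filter(test_positives, .data$user_id == u)
    relevant <- unique(rows$item_id)
    ranked <- recommend_top_k(model, u, k = k, context = mean(rows$context))
    prf <- precision_recall_f1_at_k(ranked, relevant, k = k)
    per_user[[u]] <- mutate(prf, ndcg = ndcg_at_k(ranked, relevant, k = k),
                            user_id = u)
  }
  if (length(per_user) == 0) {
    abort("No evaluable users in the test block.", class = "ddmr_validation_error")
  }
  per_user <- bind_rows(per_user)
  list(
    per_user = per_user,
    summary = summarise(per_user,
                        precision = mean(.data$precision),
                        recall = mean(.data$recall),
                        f1 = mean(.data$f1),
                        ndcg = mean(.data$ndcg))
  )
}
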