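#' Configure the recurrent heart-rate predictor
#'
#' @param hidden Hidden-state size of the recurrent cell.
#' @param window Input window length (timesteps) used to predict the next
#'   heart-rate sample.
#' @param epochs Full-batch gradient epochs.
#' @param lr Learning rate.
#' @param max_windows Cap on training windows (subsampled deterministically
#'   when exceeded).
#' @param seed Integer seed.
#' @return A list of class `ddm_hr_config`.
#' @export
hr_config <- function(hidden = 8, window = 12, epochs = 40, lr = 0.05,
                      max_windows = 400, seed = 1) {
  structure(
    list(hidden = as.integer(hidden), window = as.integer(window),
         epochs = as.integer(epochs), lr = lr,
         max_windows = as.integer(max_windows), seed = as.integer(seed)),
    class = "ddm_hr_config"
  )
}

HR_INPUT_CHANNELS <- c("heart_rate", "speed", "altitude")

# Slice sessions into (window -> next heart-rate sample) training examples.
# Returns an array x [n, window, channels] and target vector y (raw bpm).
hr_windows <- function(table, window, stride = NULL) {
  stride <- stride %||% max(1L, window %/% 2L)
  xs <- list()
  ys <- numeric(0)
  sess <- character(0)
  for (sid in unique(table$session_id)) {
    rows <- table[table$session_id == sid, ]
    rows <- rows[order(rows$timestamp), ]
    len <- nrow(rows)
    if (len < window + 1) next
    starts <- seq(1, len - window, by = stride)
    mat <- as.matrix(rows[, HR_INPUT_CHANNELS])
    for (s in starts) {
      xs[[length(xs) + 1]] <- mat[s:(s + window - 1), , drop = FALSE]
      ys <- c(ys, rows$heart_rate[s + window])
      sess <- c(sess, sid)
    }
  }
  if (length(xs) == 0) {
    abort(sprintf("No session is long enough for window length %d.", window),
          class = "ddmr_validation_error")
  }
  x <- array(NA_real_, dim = c(length(xs), window, length(HR_INPUT_CHANNELS)))
  for (i in seq_along(xs)) x[i, , ] <- xs[[i]]
  list(x = x, y = ys, session_id = sess)
}

rnn_forward <- function(x, params) {
  n <- dim(x)[1]
  w <- dim(x)[2]
  h_size <- ncol(params$Wx)
  hs <- vector("list", w)
  h <- matrix(0, n, h_size)
  for (t in seq_len(w)) {
    a <- x[, t, , drop = TRUE]
    if (is.null(dim(a))) a <- matrix(a, nrow = n)
    h <- tanh(a %*% params$Wx + h %*% params$Wh +
                matrix(params$b, n, h_size, byrow = TRUE))
    hs[[t]] <- h
  }
  yhat <- as.numeric(h %*% params$v) + params$c
  list(yhat = yhat, hs = hs)
}

rnn_gradients <- function(x, y, params, fw) {
  n <- dim(x)[1]
  w <- dim(x)[2]
  h_size <- ncol(params$Wx)
  dyhat <- 2 * (fw$yhat - y) / n
  h_last <- fw$hs[[w]]
  g <- list(
    Wx = matrix(0, nrow(params$Wx), h_size),
    Wh = matrix(0, h_size, h_size),
    b = numeric(h_size),
    v = as.numeric(crossprod(h_last, dyhat)),
    c = sum(dyhat)
  )
  dh <- outer(dyhat, params$v)  # n x h
  for (t in rev(seq_len(w))) {
    h_t <- fw$hs[[t]]
    da <- dh * (1 - h_t^2)
    a <- x[, t, , drop = TRUE]
    if (is.null(dim(a))) a <- matrix(a, nrow = n)
    g$Wx <- g$Wx + crossprod(a, da)
    h_prev <- if (t == 1) matrix(0, n, h_size) else fw$hs[[t - 1]]
    g$Wh <- g$Wh + crossprod(h_prev, da)
    g$b <- g$b + colSums(da)
    dh <- da %*% t(params$Wh)
  }
  g
}

#' Train the recurrent heart-rate predictor
#'
#' A compact single-layer recurrent regressor with a linear head: the hidden
#' state is updated over a sliding window of standardized channel inputs
#' (heart rate, speed, altitude) and the final state predicts the next
#' heart-rate sample. Trained by full-batch gradient descent through time.
#' When `warm_from` is supplied the parameters (and input scaler) initialize
#' from the donor model — the retraining path — so the first recorded loss
#' equals the donor's final loss on identical data.
#'
#' @param version A `ddm_data_version`, or a plain session table.
#' @param warm_from Optional donor `ddm_hr_model`.
#' @param config A [hr_config()].
#' @return An object of class `ddm_hr_model` with the loss history in
#'   `$losses` (entry 1 is the pre-update loss).
#' @export
train_hr_predictor <- function(version, warm_from = NULL, config = hr_config()) {
  table <- if (inherits(version, "ddm_data_version")) version$sessions else version
  assert_session_table(table)
  wins <- hr_windows(table, config$window)

  withr::with_seed(config$seed, {
    n_all <- length(wins$y)
    if (n_all > config$max_windows) {
      pick <- sort(sample(n_all, config$max_windows))
      wins$x <- wins$x[pick, , , drop = FALSE]
      wins$y <- wins$y[pick]
      wins$session_id <- wins$session_id[pick]
    }

    if (is.null(warm_from)) {
      scaler <- list(
        mu = apply(wins$x, 3, mean),
        sg = pmax(apply(wins$x, 3, sd), 1e-8),
        y_mu = mean(wins$y),
        y_sg = max(sd(wins$y), 1e-8)
      )
      n_ch <- length(HR_INPUT_CHANNELS)
      params <- list(
        Wx = matrix(rnorm(n_ch * config$hidden, sd = 0.3), n_ch, config$hidden),
        Wh = matrix(rnorm(config$hidden^2, sd = 0.1), config$hidden, config$hidden),
        b = numeric(config$hidden),
        v = rnorm(config$hidden, sd = 0.3),
        c = 0
      )
    } else {
      scaler <- warm_from$scaler
      params <- warm_from$params
    }

    x <- wins$x
    for (ch in seq_along(scaler$mu)) {
      x[, , ch] <- (x[, , ch] - scaler$mu[ch]) / scaler$sg[ch]
    }
    y <- (wins$y - scaler$y_mu) / scaler$y_sg

    losses <- numeric(config$epochs + 1)
    fw <- rnn_forward(x, params)
    losses[1] <- mean((fw$yhat - y)^2)
    for (ep in seq_len(config$epochs)) {
      g <- rnn_gradients(x, y, params, fw)
      params$Wx <- params$Wx - config$lr * g$Wx
      params$Wh <- params$Wh - config$lr * g$Wh
      params$b <- params$b - config$lr * g$b
      params$v <- params$v - config$lr * g$v
      params$c <- params$c - config$lr * g$c
      fw <- rnn_forward(x, params)
      losses[ep + 1] <- mean((fw$yhat - y)^2)
      if (!is.finite(losses[ep + 1])) {
        abort(sprintf("Non-finite training loss at epoch %d.", ep),
              class = "ddmr_optimization_error")
      }
    }

    structure(
      list(params = params, scaler = scaler, losses = losses, config = config),
      class = "ddm_hr_model"
    )
  })
}

#' Predict next-step heart rate over session windows
#'
#' @param model A `ddm_hr_model`.
#' @param table Session table to evaluate on.
#' @return A tibble with `session_id`, `observed`, `predicted` (bpm), one row
#'   per window.
#' @export
predict_hr <- function(model, table) {
  assert_session_table(table)
  wins <- hr_windows(table, model$config$window)
  x <- wins$x
  for (ch in seq_along(model$scaler$mu)) {
    x[, , ch] <- (x[, , ch] - model$scaler$mu[ch]) / model$scaler$sg[ch]
  }
  fw <- rnn_forward(x, model$params)
  tibble(
    session_id = wins$session_id,
    observed = wins$y,
    predicted = fw$yhat * model$scaler$y_sg + model$scaler$y_mu
  )
}

#' Per-session predicted mean heart rate (contextual feature)
#'
#' @inheritParams predict_hr
#' @return Named numeric vector: session id -> predicted mean heart rate.
#'   Sessions too short for the model's window fall back to the session's
#'   observed mean.
#' @export
predict_session_context <- function(model, table) {
  preds <- tryCatch(predict_hr(model, table), error = function(e) NULL)
  obs_mean <- table |>
    group_by(.data$session_id) |>
    summarise(m = mean(.data$heart_rate), .groups = "drop")
  ctx <- setNames(obs_mean$m, obs_mean$session_id)
  if (!is.null(preds)) {
    pm <- preds |>
      group_by(.data$session_id) |>
      summarise(m = mean(.data$predicted), .groups = "drop")
    ctx[pm$session_id] <- pm$m
  }
  ctx
}
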