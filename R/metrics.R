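#' Heart-rate prediction error metrics
#'
#' Mean absolute error and root mean squared error over paired observed and
#' predicted values: `MAE = mean(|y - yhat|)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`. RMSE amplifies large deviations, which
#' makes it the more sensitive of the two to instability under drift; it is
#' never smaller than MAE.
#'
#' @param observed,predicted Equal-length numeric vectors (bpm).
#' @return A single number, in the units of the inputs.
#' @examples
#' mae(c(0, 0), c(3, 4))  # 3.5
#' rmse(c(0, 0), c(3, 4)) # sqrt(12.5)
#' @export
mae <- function(observed, predicted) {
  check_prediction_pairs(observed, predicted)
  mean(abs(observed - predicted))
}

#' @rdname mae
#' @export
rmse <- function(observed, predicted) {
  check_prediction_pairs(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

check_prediction_pairs <- function(observed, predicted) {
  if (length(observed) == 0) {
    abort("Prediction set is empty.", class = "ddmr_validation_error")
  }
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.",
          class = "ddmr_validation_error")
  }
  invisible(TRUE)
}

#' Top-K precision, recall and F1
#'
#' Evaluates a ranked recommendation list against the set of items the user
#' actually consumed. With `TP` the number of relevant items among the first
#' `k` returned: precision is `TP` over the number of returned items (`k`, or
#' fewer when the catalog is smaller), recall is `TP / |relevant|`, and F1 is
#' the harmonic mean `2 * P * R / (P + R)`, defined as 0 when `P + R = 0`.
#' An empty ground-truth set makes recall undefined and raises an error;
#' per-user evaluation is intended to run over users with test-set items.
#'
#' @param ranked Character/integer vector of item ids in rank order (no
#'   duplicates).
#' @param relevant Ground-truth set of relevant item ids (non-empty).
#' @param k Cutoff, default 10.
#' @return A tibble with columns `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1_at_k(c("a", "b", "c"), relevant = c("a", "z"), k = 3)
#' @export
precision_recall_f1_at_k <- function(ranked, relevant, k = 10) {
  check_ranked(ranked, relevant)
  returned <- head(ranked, k)
  tp <- sum(returned %in% relevant)
  precision <- tp / length(returned)
  recall <- tp / length(relevant)
  tibble(precision = precision, recall = recall,
         f1 = f1_score(precision, recall))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Values in \[0, 1\].
#' @return `2 * precision * recall / (precision + recall)`, or 0 when both
#'   are 0.
#' @examples
#' f1_score(0.11, 0.25) # ~0.153
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Normalized discounted cumulative gain at K
#'
#' `DCG = sum_i (2^rel_i - 1) / log2(i + 1)` over positions `i = 1..k`, with
#' binary relevance `rel_i` indicating whether the item at position `i` is in
#' the ground-truth set. `IDCG` is the DCG of the ideal reordering (all
#' relevant items first) and `NDCG = DCG / IDCG`, defined as 0 when
#' `IDCG = 0`. Higher scores reward placing relevant items nearer the top.
#'
#' @inheritParams precision_recall_f1_at_k
#' @return A number in \[0, 1\].
#' @examples
#' ndcg_at_k(c("x", "a"), relevant = "a", k = 10) # 1 / log2(3)
#' @export
ndcg_at_k <- function(ranked, relevant, k = 10) {
  check_ranked(ranked, relevant, allow_empty_relevant = TRUE)
  returned <- head(ranked, k)
  rel <- as.numeric(returned %in% relevant)
  pos <- seq_along(rel)
  dcg <- sum((2^rel - 1) / log2(pos + 1))
  n_ideal <- min(length(relevant), k)
  if (n_ideal == 0) return(0)
  idcg <- sum(1 / log2(seq_len(n_ideal) + 1))
  if (idcg == 0) return(0)
  dcg / idcg
}

check_ranked <- function(ranked, relevant, allow_empty_relevant = FALSE) {
  if (anyDuplicated(ranked)) {
    abort("`ranked` must not contain duplicate items.",
          class = "ddmr_validation_error")
  }
  if (!allow_empty_relevant && length(relevant) == 0) {
    abort("Ground-truth set is empty: recall is undefined.",
          class = "ddmr_validation_error")
  }
  invisible(TRUE)
}

#' Bundle evaluation metrics for one retraining stage
#'
#' @param mae,rmse Heart-rate prediction errors (bpm).
#' @param precision,recall,f1,ndcg Mean top-K ranking metrics.
#' @param reduction_rate Percent of old records removed by reduction.
#' @param n_records Training record count.
#' @param elapsed Wall-clock seconds spent retraining (bookkeeping only).
#' @return A one-row tibble of class `ddm_eval_report`.
#' @export
eval_report <- function(mae = NA_real_, rmse = NA_real_, precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_, ndcg = NA_real_,
                        reduction_rate = NA_real_, n_records = NA_integer_,
                        elapsed = NA_real_) {
  out <- tibble(
    mae = mae, rmse = rmse, precision = precision, recall = recall, f1 = f1,
    ndcg = ndcg, reduction_rate = reduction_rate,
    n_records = as.integer(n_records), elapsed = elapsed
  )
  class(out) <- c("ddm_eval_report", class(out))
  out
}
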