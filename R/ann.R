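#' Build an approximate nearest-neighbour index over session embeddings
#'
#' A forest of random-projection trees over the angular (cosine) metric, in
#' the style of the Annoy family of indexes. Vectors are L2-normalized; each
#' tree recursively splits the data by the hyperplane spanned by the
#' difference of two randomly chosen member points, thresholded at the median
#' projection so trees stay balanced. Queries walk the forest with a priority
#' queue ordered by hyperplane margin, inspecting nodes until `search_k`
#' candidates have been gathered, then score every candidate with the exact
#' cosine similarity. Zero vectors (cosine undefined) are excluded from the
#' index with a warning.
#'
#' @param x Numeric matrix, one row per item; rownames are used as item ids.
#' @param n_trees Number of trees; more trees, better recall, more memory.
#' @param seed Integer seed controlling the random hyperplanes.
#' @param leaf_size Maximum number of items in a leaf node.
#' @return An object of class `ddm_ann_index`.
#' @seealso [ann_query()], [query_neighbors()]
#' @export
ann_index <- function(x, n_trees = 10, seed = 1, leaf_size = 10) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  norms <- sqrt(rowSums(x^2))
  zero <- norms < 1e-12
  if (any(zero)) {
    warn(sprintf(
      "Excluding %d zero vector(s) from the index (cosine undefined): %s",
      sum(zero), paste(rownames(x)[zero], collapse = ", ")
    ))
    x <- x[!zero, , drop = FALSE]
    norms <- norms[!zero]
  }
  if (nrow(x) < 1) abort("No nonzero vectors to index.", class = "ddmr_validation_error")
  xn <- x / norms

  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_trees), function(i) build_rp_tree(xn, seq_len(nrow(xn)), leaf_size))
  })
  structure(
    list(vectors = xn, ids = rownames(x), trees = trees, leaf_size = leaf_size,
         n_trees = n_trees, excluded = names(zero)[zero]),
    class = "ddm_ann_index"
  )
}

build_rp_tree <- function(xn, items, leaf_size) {
  if (length(items) <= leaf_size) {
    return(list(leaf = TRUE, items = items))
  }
  # split hyperplane from a short two-means refinement of a random point
  # pair, on a bounded sample of the node's items
  smp <- if (length(items) > 128) sample(items, 128) else items
  pair <- sample(smp, 2)
  c1 <- xn[pair[1], ]
  c2 <- xn[pair[2], ]
  xs <- xn[smp, , drop = FALSE]
  for (iter in 1:5) {
    d1 <- xs %*% c1
    d2 <- xs %*% c2
    side <- d1 >= d2
    if (all(side) || !any(side)) break
    c1n <- colMeans(xs[side, , drop = FALSE])
    c2n <- colMeans(xs[!side, , drop = FALSE])
    if (sqrt(sum(c1n^2)) > 1e-12) c1 <- c1n / sqrt(sum(c1n^2))
    if (sqrt(sum(c2n^2)) > 1e-12) c2 <- c2n / sqrt(sum(c2n^2))
  }
  w <- c1 - c2
  if (sqrt(sum(w^2)) < 1e-12) w <- rnorm(ncol(xn))
  w <- w / sqrt(sum(w^2))
  proj <- as.numeric(xn[items, , drop = FALSE] %*% w)
  m <- median(proj)
  left <- items[proj < m]
  right <- items[proj >= m]
  if (length(left) == 0 || length(right) == 0) {
    # all projections tied: split arbitrarily but deterministically in half
    half <- length(items) %/% 2
    left <- items[seq_len(half)]
    right <- items[-seq_len(half)]
  }
  list(leaf = FALSE, w = w, m = m,
       left = build_rp_tree(xn, left, leaf_size),
       right = build_rp_tree(xn, right, leaf_size))
}

#' Query an approximate nearest-neighbour index
#'
#' @param index A [ann_index()].
#' @param q Query vector (same dimension as the indexed vectors).
#' @param n_neighbors Number of neighbours to return.
#' @param search_k Number of candidate items to gather before exact cosine
#'   rescoring; larger values trade speed for recall.
#' @return A tibble with columns `id`, `similarity` (exact cosine), `rank`,
#'   ordered by decreasing similarity.
#' @export
ann_query <- function(index, q, n_neighbors = 10, search_k = 100) {
  if (length(q) != ncol(index$vectors)) {
    abort(sprintf("Query has dimension %d; index expects %d.",
                  length(q), ncol(index$vectors)),
          class = "ddmr_validation_error")
  }
  qnorm <- sqrt(sum(q^2))
  if (qnorm < 1e-12) {
    abort("Cosine similarity is undefined for a zero query vector.",
          class = "ddmr_validation_error")
  }
  qn <- q / qnorm

  # Priority-queue traversal over all trees at once: each entry is a node with
  # the smallest margin seen on the path to it; pop the most promising first.
  nodes <- lapply(index$trees, identity)
  prios <- rep(Inf, length(nodes))
  seen <- logical(nrow(index$vectors))
  n_cand <- 0L
  while (length(nodes) > 0 && n_cand < search_k) {
    i <- which.max(prios)
    node <- nodes[[i]]
    p <- prios[i]
    nodes[[i]] <- NULL
    prios <- prios[-i]
    if (isTRUE(node$leaf)) {
      fresh <- node$items[!seen[node$items]]
      seen[fresh] <- TRUE
      n_cand <- n_cand + length(fresh)
    } else {
      margin <- sum(qn * node$w) - node$m
      nodes <- c(nodes, list(node$right, node$left))
      prios <- c(prios, min(p, margin), min(p, -margin))
    }
  }
  cand <- which(seen)
  sims <- as.numeric(index$vectors[cand, , drop = FALSE] %*% qn)
  ord <- order(-sims, cand)
  keep <- head(ord, n_neighbors)
  tibble(
    id = index$ids[cand[keep]],
    similarity = sims[keep],
    rank = seq_along(keep)
  )
}

#' Neighbour lists for every session in an embedding
#'
#' Runs the approximate index over all embedded sessions and returns, for each
#' one, its nearest neighbours by cosine similarity. Candidates come from the
#' random-projection forest; similarities are always recomputed exactly on the
#' embedding vectors, so reported values carry no approximation.
#'
#' @param embedding A [project_pca()] result.
#' @param config A [reduction_config()] (supplies `ann_trees`, `ann_search_k`,
#'   `seed`).
#' @param n_neighbors Neighbours to return per session.
#' @param include_self Keep the query session itself in its neighbour list
#'   (similarity 1).
#' @return A tibble with columns `session_id`, `neighbor_id`, `similarity`,
#'   `rank`.
#' @export
query_neighbors <- function(embedding, config = reduction_config(),
                            n_neighbors = 10, include_self = FALSE) {
  scores <- embedding$scores
  if (nrow(scores) < 2) {
    abort("Need at least 2 embedded sessions.", class = "ddmr_validation_error")
  }
  idx <- ann_index(scores, n_trees = config$ann_trees, seed = config$seed)
  ask <- n_neighbors + if (include_self) 0L else 1L
  res <- lapply(seq_len(nrow(scores)), function(i) {
    id <- rownames(scores)[i]
    nb <- ann_query(idx, scores[i, ], n_neighbors = ask,
                    search_k = config$ann_search_k)
    if (!include_self) nb <- filter(nb, .data$id != !!id)
    nb <- head(nb, n_neighbors)
    if (nrow(nb) == 0) return(NULL)
    tibble(session_id = id, neighbor_id = nb$id,
           similarity = nb$similarity, rank = seq_len(nrow(nb)))
  })
  bind_rows(res)
}
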