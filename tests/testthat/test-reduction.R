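test_that("session summaries use population standard deviation and fixed width", {
  s1 <- make_session("s1", heart_rate = rep(120, 3))
  s2 <- make_session("s2", heart_rate = c(1, 2, 3))
  summ <- summarize_sessions(dplyr::bind_rows(s1, s2))

  r1 <- summ[summ$session_id == "s1", ]
  expect_equal(r1$hr_mean, 120)
  expect_equal(r1$hr_sd, 0)
  expect_equal(r1$hr_min, 120)
  expect_equal(r1$hr_max, 120)

  r2 <- summ[summ$session_id == "s2", ]
  expect_equal(r2$hr_mean, 2)
  expect_equal(r2$hr_sd, sqrt(2 / 3)) # population form
  expect_equal(c(r2$hr_min, r2$hr_max), c(1, 3))

  # 4 stats x 3 channels + 6 derived scalars beyond the index columns
  n_features <- ncol(summ) - 5
  expect_equal(n_features, 4 * 3 + 6)
  expect_true(all(!is.na(as.matrix(summ[, -(1:5)]))))
})

test_that("sport filtering removes under-supported sports and reports", {
  tab <- dplyr::bind_rows(
    lapply(1:12, function(i) make_session(sprintf("r%d", i), sport = "run",
                                          heart_rate = c(100, 110, 105))),
    lapply(1:3, function(i) make_session(sprintf("w%d", i), sport = "row",
                                         heart_rate = c(90, 95, 92)))
  )
  summ <- summarize_sessions(tab)
  kept <- filter_by_sport(summ, min_sessions_per_sport = 10)
  expect_equal(nrow(kept), 12)
  expect_equal(unique(kept$sport), "run")
  expect_equal(attr(kept, "filter_report")$dropped_sports, "row")

  expect_equal(nrow(filter_by_sport(summ, 0)), nrow(summ))
  expect_error(filter_by_sport(summ, 100), class = "ddmr_empty_result")
})

test_that("PCA explained-variance ratios match an independent eigendecomposition", {
  set.seed(31)
  x <- matrix(rnorm(10 * 8), 10, 8)
  summ <- tibble::tibble(
    session_id = sprintf("s%d", 1:10), user_id = "u1", sport = "run",
    record_count = 5L,
    start_time = as.POSIXct("2024-01-01", tz = "UTC") + 1:10
  )
  summ <- dplyr::bind_cols(summ, as.data.frame(x))
  emb <- project_pca(summ, reduction_config(pca_components = 8))

  xs <- scale(x)
  ev <- eigen(stats::cov(xs) * (nrow(xs) - 1) / (nrow(xs) - 1),
              symmetric = TRUE)$values
  expect_equal(emb$explained_variance_ratio, ev / sum(ev), tolerance = 1e-8)

  # orthonormal directions, nonincreasing ratios summing to <= 1
  expect_equal(crossprod(emb$rotation), diag(ncol(emb$rotation)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(emb$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(emb$explained_variance_ratio), 1 + 1e-8)
})

test_that("PCA handles rank-1 data, full rank reconstruction and variance targets", {
  base <- rnorm(8)
  x <- outer(seq(1, 2, length.out = 12), base) # rank 1
  summ <- tibble::tibble(
    session_id = sprintf("s%d", 1:12), user_id = "u1", sport = "run",
    record_count = 5L,
    start_time = as.POSIXct("2024-01-01", tz = "UTC") + 1:12
  )
  summ <- dplyr::bind_cols(summ, as.data.frame(x))
  emb <- project_pca(summ, reduction_config(pca_components = 3))
  expect_gt(emb$explained_variance_ratio[1], 0.999)

  # variance target picks the smallest sufficient component count
  set.seed(5)
  x2 <- matrix(rnorm(20 * 6), 20, 6)
  summ2 <- tibble::tibble(
    session_id = sprintf("t%d", 1:20), user_id = "u1", sport = "run",
    record_count = 5L,
    start_time = as.POSIXct("2024-01-01", tz = "UTC") + 1:20
  )
  summ2 <- dplyr::bind_cols(summ2, as.data.frame(x2))
  emb2 <- project_pca(summ2, reduction_config(variance_target = 0.9))
  evr <- emb2$explained_variance_ratio
  expect_gte(sum(evr[seq_len(emb2$n_components)]), 0.9)
  if (emb2$n_components > 1) {
    expect_lt(sum(evr[seq_len(emb2$n_components - 1)]), 0.9)
  }

  # full-rank projection reconstructs the standardized matrix
  emb3 <- project_pca(summ2, reduction_config(pca_components = 6))
  xs <- scale(x2)
  recon <- emb3$scores %*% t(emb3$rotation)
  expect_equal(unname(recon), unname(xs[, ]), tolerance = 1e-8)

  # all-constant input is an error
  summ_const <- summ2
  for (j in 6:11) summ_const[[j]] <- 1
  expect_error(project_pca(summ_const, reduction_config()),
               class = "ddmr_validation_error")
})

test_that("ann queries return exact self-similarity and handle zero vectors", {
  set.seed(17)
  x <- matrix(rnorm(50 * 4), 50, 4)
  rownames(x) <- sprintf("v%02d", 1:50)
  idx <- ann_index(x, n_trees = 10, seed = 1)
  nb <- ann_query(idx, x[7, ], n_neighbors = 5, search_k = 100)
  expect_equal(nb$id[1], "v07")
  expect_equal(nb$similarity[1], 1, tolerance = 1e-12)

  # identical vectors are mutual neighbours at similarity 1
  x2 <- rbind(x, v99 = x[7, ])
  idx2 <- ann_index(x2, n_trees = 10, seed = 1)
  nb2 <- ann_query(idx2, x2["v99", ], n_neighbors = 2, search_k = 200)
  expect_setequal(nb2$id[1:2], c("v07", "v99"))
  expect_equal(nb2$similarity, c(1, 1), tolerance = 1e-12)

  x3 <- rbind(x, zero = 0)
  expect_warning(ann_index(x3, n_trees = 2, seed = 1), "zero")
  expect_error(ann_query(idx, rep(0, 4)), class = "ddmr_validation_error")
})

test_that("approximate neighbour recall is high against brute force", {
  set.seed(23)
  x <- matrix(rnorm(400 * 5), 400, 5)
  rownames(x) <- sprintf("p%03d", 1:400)
  idx <- ann_index(x, n_trees = 10, seed = 2)
  xn <- x / sqrt(rowSums(x^2))
  sims <- xn %*% t(xn)
  rec <- vapply(1:100, function(i) {
    nb <- ann_query(idx, x[i, ], n_neighbors = 11, search_k = 100)
    approx <- setdiff(nb$id, rownames(x)[i])[1:10]
    exact <- rownames(x)[setdiff(order(-sims[i, ], seq_len(400)), i)[1:10]]
    length(intersect(approx, exact)) / 10
  }, numeric(1))
  expect_gte(mean(rec), 0.9)
})

test_that("the session with more recorded timesteps represents its duplicates", {
  # two sessions with identical summary vectors but different record counts,
  # embedded among unrelated filler sessions
  set.seed(12)
  filler <- matrix(rnorm(10 * 6), 10, 6)
  feats <- rbind(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6), filler)
  summ <- tibble::tibble(
    session_id = c("long", "short", sprintf("f%02d", 1:10)),
    user_id = c("u1", "u1", rep("u2", 10)),
    sport = "run",
    record_count = c(100L, 50L, rep(30L, 10)),
    start_time = as.POSIXct("2024-01-02", tz = "UTC") + c(86400, 0, 1:10)
  )
  summ <- dplyr::bind_cols(summ, as.data.frame(feats))
  tab <- dplyr::bind_rows(lapply(summ$session_id, function(id) {
    make_session(id, user_id = summ$user_id[summ$session_id == id],
                 heart_rate = c(100, 110, 120))
  }))
  emb <- project_pca(summ, reduction_config(pca_components = 4))
  up <- reduce_user_sessions(emb, summ, tab,
                             reduction_config(similarity_threshold = 0.99,
                                              seed = 1))
  expect_true("long" %in% up$kept_ids)
  expect_false("short" %in% up$kept_ids)
  expect_equal(tidy(up)$representative_id[tidy(up)$session_id == "short"],
               "long")
  # ties in record count fall back to the earliest start
  summ2 <- summ
  summ2$record_count[1] <- 50L # tie; "short" starts a day earlier
  emb2 <- project_pca(summ2, reduction_config(pca_components = 4))
  up2 <- reduce_user_sessions(emb2, summ2, tab,
                              reduction_config(similarity_threshold = 0.99,
                                               seed = 1))
  expect_true("short" %in% up2$kept_ids)
  expect_false("long" %in% up2$kept_ids)
})

test_that("unreachable threshold removes nothing; kept + removed partition input", {
  tab <- clean_sessions(small_cohort(seed = 14))
  summ <- summarize_sessions(tab)
  emb <- project_pca(summ, reduction_config())

  up_all <- reduce_user_sessions(emb, summ, tab,
                                 reduction_config(similarity_threshold = 1))
  # tau = 1 keeps everything except exact duplicates in embedding space
  up <- reduce_user_sessions(emb, summ, tab, reduction_config())
  expect_setequal(c(up$kept_ids, up$removed$session_id), summ$session_id)
  expect_gte(up_all$counts$n_after, up$counts$n_after)

  # every user retains at least one session
  kept_users <- unique(summ$user_id[summ$session_id %in% up$kept_ids])
  expect_setequal(kept_users, unique(summ$user_id))

  expect_error(
    reduce_user_sessions(emb, summ, tab,
                         reduction_config(similarity_threshold = -1)),
    "similarity_threshold"
  )
})

test_that("ann-backed reduction equals the brute-force all-pairs oracle", {
  tab <- clean_sessions(small_cohort(n_users = 5, sessions_per_user = 6,
                                     duplicate_rate = 0.3, seed = 18))
  summ <- summarize_sessions(tab)
  emb <- project_pca(summ, reduction_config())
  for (tau in c(0.995, 0.95)) {
    cfg <- reduction_config(similarity_threshold = tau, seed = 2)
    up <- reduce_user_sessions(emb, summ, tab, cfg)
    expect_equal(sort(up$kept_ids), brute_force_reduce(emb, summ, tau),
                 info = sprintf("tau = %s", tau))
  }
})

test_that("reduction rate follows its closed form", {
  expect_equal(round(reduction_rate(139161, 118285)), 15)
  expect_equal(round(reduction_rate(215067, 176339)), 18)
  expect_equal(reduction_rate(100, 100), 0)
  expect_error(reduction_rate(0, 0), "n_before")
  expect_error(reduction_rate(10, 11), "n_after")
})
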