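test_that("cohort has the requested shape and exact planted-duplicate count", {
  spec <- cohort_spec(n_users = 10, sessions_per_user = 20,
                      duplicate_rate = 0.3, seed = 7)
  tab <- generate_cohort(spec)

  expect_equal(dplyr::n_distinct(tab$session_id), 200)
  expect_equal(dplyr::n_distinct(tab$user_id), 10)
  prov <- dplyr::distinct(tab, session_id, planted_duplicate)
  expect_equal(sum(prov$planted_duplicate), 60) # round(0.3 * 200)

  none <- generate_cohort(cohort_spec(n_users = 3, sessions_per_user = 4,
                                      duplicate_rate = 0, seed = 1))
  expect_equal(sum(none$planted_duplicate), 0)
})

test_that("generation is deterministic given spec and seed", {
  spec <- cohort_spec(n_users = 4, sessions_per_user = 5,
                      duplicate_rate = 0.2, seed = 42)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  other <- cohort_spec(n_users = 4, sessions_per_user = 5,
                       duplicate_rate = 0.2, seed = 43)
  expect_false(identical(generate_cohort(spec), generate_cohort(other)))
})

test_that("session tables satisfy their schema invariants", {
  tab <- small_cohort(seed = 3)
  per_sess <- tab |>
    dplyr::group_by(session_id) |>
    dplyr::summarise(
      one_user = dplyr::n_distinct(user_id) == 1,
      one_sport = dplyr::n_distinct(sport) == 1,
      increasing = all(diff(as.numeric(timestamp)) > 0)
    )
  expect_true(all(per_sess$one_user))
  expect_true(all(per_sess$one_sport))
  expect_true(all(per_sess$increasing))
})

test_that("planted duplicates are near-identical to a same-user session", {
  tab <- small_cohort(n_users = 4, duplicate_rate = 0.25, seed = 9)
  summ <- summarize_sessions(clean_sessions(tab))
  emb <- project_pca(summ, reduction_config())
  xn <- emb$scores / sqrt(rowSums(emb$scores^2))
  prov <- dplyr::distinct(tab, session_id, planted_duplicate, user_id)
  dup_ids <- prov$session_id[prov$planted_duplicate]
  best <- vapply(dup_ids, function(id) {
    u <- prov$user_id[prov$session_id == id]
    mates <- summ$session_id[summ$user_id == u & summ$session_id != id]
    max(as.numeric(xn[mates, , drop = FALSE] %*% xn[id, ]))
  }, numeric(1))
  # jitter leaves almost every copy at cosine ~1; the occasional dip comes
  # from peak-position-sensitive derived features (recovery speed)
  expect_true(all(best > 0.9))
  expect_gte(mean(best > 0.99), 0.8)
})

test_that("invalid cohort specs fail naming the offending field", {
  expect_error(cohort_spec(duplicate_rate = 1.5), "duplicate_rate")
  expect_error(cohort_spec(n_users = 0), "n_users")
  expect_error(cohort_spec(session_length_range = c(1, 5)),
               "session_length_range")
  expect_error(cohort_spec(sports = c(0.5, 0.5)), "sports")
})

test_that("drift shifts post-onset channel means by the requested amount", {
  tab <- small_cohort(n_users = 10, sessions_per_user = 12,
                      duplicate_rate = 0, seed = 5)
  drift <- drift_spec(onset = 0.5, channel_shifts = c(heart_rate = 10))
  out <- inject_drift(tab, drift)

  expect_equal(nrow(out), nrow(tab))
  expect_equal(dplyr::n_distinct(out$session_id),
               dplyr::n_distinct(tab$session_id))

  starts <- tab |>
    dplyr::group_by(session_id) |>
    dplyr::summarise(start = min(timestamp))
  cutoff <- min(starts$start) +
    0.5 * as.numeric(difftime(max(starts$start), min(starts$start),
                              units = "secs"))
  post <- starts$session_id[as.numeric(starts$start) >= as.numeric(cutoff)]
  delta <- mean(out$heart_rate[out$session_id %in% post]) -
    mean(tab$heart_rate[tab$session_id %in% post])
  expect_equal(delta, 10, tolerance = 1e-10)
  # pre-onset untouched
  expect_identical(out$heart_rate[!out$session_id %in% post],
                   tab$heart_rate[!tab$session_id %in% post])
})

test_that("zero drift is the identity and drift is reproducible", {
  tab <- small_cohort(n_users = 3, seed = 8)
  expect_identical(inject_drift(tab, drift_spec(onset = 0.5)), tab)

  drift <- drift_spec(onset = 0.3, channel_shifts = c(speed = 1),
                      preference_shift = c(run = 0.9, bike = 0.1))
  expect_identical(inject_drift(tab, drift, seed = 4),
                   inject_drift(tab, drift, seed = 4))
  expect_error(drift_spec(onset = 1.2), "onset")
})

test_that("session tables round-trip through CSV with provenance sidecar", {
  tab <- small_cohort(n_users = 2, sessions_per_user = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(tab, path)
  expect_true(file.exists(paste0(path, ".provenance.csv")))
  back <- read_sessions(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-6)
})
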