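make_pattern <- function(table, keep_ids = NULL) {
  keep_ids <- keep_ids %||% unique(table$session_id)
  kept <- dplyr::filter(table, session_id %in% keep_ids)
  structure(
    list(sessions = kept, kept_ids = keep_ids,
         removed = tibble::tibble(session_id = setdiff(unique(table$session_id),
                                                       keep_ids),
                                  representative_id = NA_character_,
                                  user_id = NA_character_,
                                  sport = NA_character_),
         counts = list(n_before = dplyr::n_distinct(table$session_id),
                       n_after = length(keep_ids),
                       n_removed = dplyr::n_distinct(table$session_id) -
                         length(keep_ids),
                       rate_percent = 0),
         config = reduction_config()),
    class = "ddm_user_pattern"
  )
}

test_that("packaged versions conserve counts and reject id collisions", {
  old <- clean_sessions(small_cohort(n_users = 3, sessions_per_user = 4,
                                     duplicate_rate = 0, seed = 1))
  new <- clean_sessions(small_cohort(n_users = 3, sessions_per_user = 2,
                                     duplicate_rate = 0, seed = 2))
  new$session_id <- paste0("new_", new$session_id)
  up <- make_pattern(old)

  v <- package_data_version(up, new, version_id = 2, parent = 1)
  expect_equal(v$metadata$n_total, v$metadata$n_old_kept + v$metadata$n_new)
  expect_equal(v$metadata$n_total, dplyr::n_distinct(v$sessions$session_id))
  expect_equal(nrow(v$features), v$metadata$n_total)

  # empty new data: version equals the user-pattern records
  v0 <- package_data_version(up, new[0, ], version_id = 3, parent = 2)
  expect_equal(sort(unique(v0$sessions$session_id)),
               sort(unique(old$session_id)))

  expect_error(package_data_version(up, old, version_id = 2),
               class = "ddmr_validation_error")
})

test_that("weight policy drops or scales feature columns and records metadata", {
  old <- clean_sessions(small_cohort(n_users = 3, sessions_per_user = 4,
                                     duplicate_rate = 0, seed = 3))
  new <- clean_sessions(small_cohort(n_users = 2, sessions_per_user = 2,
                                     duplicate_rate = 0, seed = 4))
  new$session_id <- paste0("n_", new$session_id)
  up <- make_pattern(old)
  w <- tibble::tibble(
    feature = c("recovery_speed", "total_distance"),
    group = c("health_metric", "contextual"),
    weight = c(0.05, 0.9)
  )
  class(w) <- c("ddm_feature_weights", class(w))

  v <- package_data_version(up, new, weights = w, version_id = 2, parent = 1,
                       weight_floor = 0.1)
  expect_false("recovery_speed" %in% names(v$features))
  expect_true("total_distance" %in% names(v$features))
  expect_equal(v$metadata$dropped_features, "recovery_speed")
  expect_equal(v$metadata$feature_weights$recovery_speed, 0.05)

  # floor 0 drops nothing
  v2 <- package_data_version(up, new, weights = w, version_id = 2, parent = 1,
                        weight_floor = 0)
  expect_true("recovery_speed" %in% names(v2$features))

  # scale mode multiplies instead of dropping
  v3 <- package_data_version(up, new, weights = w, version_id = 2, parent = 1,
                        mode = "scale")
  expect_equal(v3$features$total_distance, v$features$total_distance * 0.9)
})

test_that("versions round-trip through disk and tampering is detected", {
  root <- withr::local_tempdir()
  old <- clean_sessions(small_cohort(n_users = 2, sessions_per_user = 3,
                                     duplicate_rate = 0, seed = 5))
  v1 <- package_data_version(NULL, old, version_id = 1)
  write_version(v1, root)
  back <- read_version(root, 1)
  expect_equal(back$metadata$n_total, v1$metadata$n_total)
  expect_equal(as.data.frame(back$sessions), as.data.frame(v1$sessions),
               tolerance = 1e-6)
  expect_equal(as.data.frame(back$features), as.data.frame(v1$features),
               tolerance = 1e-6)

  # corrupt the recorded count
  meta_path <- file.path(root, "version_001", "metadata.json")
  meta <- jsonlite::read_json(meta_path)
  meta$n_total <- meta$n_total + 1
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  expect_error(read_version(root, 1), class = "ddmr_integrity_error")
  expect_error(read_version(root, 99), class = "ddmr_integrity_error")
})

test_that("lineage walks chained versions back to the root", {
  root <- withr::local_tempdir()
  base <- clean_sessions(small_cohort(n_users = 2, sessions_per_user = 3,
                                      duplicate_rate = 0, seed = 6))
  v1 <- package_data_version(NULL, base, version_id = 1)
  write_version(v1, root)
  for (i in 2:3) {
    nd <- clean_sessions(small_cohort(n_users = 2, sessions_per_user = 2,
                                      duplicate_rate = 0, seed = 6 + i))
    nd$session_id <- sprintf("v%d_%s", i, nd$session_id)
    prev <- read_version(root, i - 1)
    v <- package_data_version(make_pattern(prev$sessions), nd, version_id = i,
                         parent = i - 1)
    write_version(v, root)
  }
  expect_equal(version_lineage(root, 3), c(1, 2, 3))
  expect_equal(version_lineage(root, 1), 1)
})
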