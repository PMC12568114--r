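test_that("schemas are total, disjoint partitions of the features", {
  schema <- feature_group_schema(attribute = c("a1", "a2"),
                                 contextual = "c1",
                                 health_metric = c("h1", "h2", "h3"),
                                 sequential = "s1")
  expect_equal(nrow(schema), 7)
  expect_error(feature_group_schema(attribute = "x", contextual = "x"),
               "more than one group")
  expect_error(feature_group_schema(), "at least one")
})

test_that("embedding partitions features into grouped blocks", {
  rows <- tibble::tibble(
    session_id = sprintf("s%d", 1:6),
    a1 = rnorm(6), a2 = rnorm(6),
    c1 = c("x", "y", "x", "z", "y", "x"),
    h1 = rnorm(6),
    s1 = 1:6
  )
  schema <- feature_group_schema(attribute = c("a1", "a2"), contextual = "c1",
                                 health_metric = "h1", sequential = "s1")
  blocks <- embed_features(rows, schema)
  # every feature appears in exactly one block
  expect_setequal(unique(blocks$map$feature), schema$feature)
  expect_equal(anyDuplicated(blocks$map$column), 0)
  # one-hot expansion for the categorical feature
  expect_equal(sum(blocks$map$feature == "c1"), 3)
  expect_equal(ncol(blocks$x), 4 + 3)
  # block widths by group before encoding expansion
  widths <- table(schema$group)
  expect_equal(unname(widths[c("attribute", "contextual", "health_metric",
                               "sequential")]),
               c(2L, 1L, 1L, 1L), ignore_attr = TRUE)

  rows$foo <- 1
  expect_error(embed_features(rows, schema), "foo")
  expect_error(embed_features(rows[, 1:3], schema), class = "ddmr_schema_error")
})

test_that("controller forward pass is bounded, deterministic in eval mode", {
  ctl <- new_feature_controller(c("f1", "f2", "f3"), input_dim = 4,
                                controller_config(seed = 3))
  z <- rnorm(4)
  w1 <- controller_forward(ctl, z)
  w2 <- controller_forward(ctl, z)
  expect_identical(w1, w2)
  expect_named(w1, c("f1", "f2", "f3"))

  # all-zero parameters give sigmoid(0) = 0.5
  ctl0 <- ctl
  ctl0$W1[] <- 0; ctl0$b1[] <- 0; ctl0$W2[] <- 0; ctl0$b2[] <- 0
  expect_equal(unname(controller_forward(ctl0, z)), rep(0.5, 3))

  # bounds over many random controllers and inputs
  set.seed(11)
  for (i in 1:100) {
    ctl_i <- new_feature_controller(c("f1", "f2"), input_dim = 3,
                                    controller_config(seed = i))
    w <- controller_forward(ctl_i, rnorm(3, sd = 5))
    expect_true(all(w >= 0 & w <= 1))
  }

  expect_error(controller_forward(ctl, rnorm(7)), class = "ddmr_validation_error")
})

test_that("zero outer steps return the initialization forward pass", {
  set.seed(2)
  d <- tibble::tibble(x1 = rnorm(40), x2 = rnorm(40))
  d$mean_heart_rate <- d$x1 + rnorm(40, sd = 0.1)
  schema <- feature_group_schema(contextual = c("x1", "x2"))
  cfg <- controller_config(n_outer = 0, seed = 5)
  w <- fit_bilevel(d[1:30, ], d[31:40, ], schema = schema, config = cfg)

  # rebuild the same initialization and latent vector independently
  blocks <- embed_features(d[1:30, c("x1", "x2")], schema)
  xs <- scale(blocks$x)
  z <- colMeans(xs)
  ctl <- new_feature_controller(schema$feature, length(z), cfg)
  expect_equal(w$weight, unname(controller_forward(ctl, z)), tolerance = 1e-12)
})

test_that("bi-level fitting upweights a planted informative feature", {
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    x <- matrix(rnorm(n * 4), n, 4)
    colnames(x) <- c("signal", "noise1", "noise2", "noise3")
    d <- tibble::as_tibble(x)
    d$mean_heart_rate <- 2 * x[, 1] + rnorm(n, sd = 0.3)
    schema <- feature_group_schema(contextual = colnames(x))
    w <- fit_bilevel(d[1:150, ], d[151:200, ], schema = schema,
                     config = controller_config(seed = seed))
    if (w$weight[1] > mean(w$weight[2:4])) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("validation loss tends to decrease over outer steps", {
  improved <- 0
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- 150
    x <- matrix(rnorm(n * 3), n, 3)
    colnames(x) <- c("a", "b", "c")
    d <- tibble::as_tibble(x)
    d$mean_heart_rate <- x[, 1] - x[, 2] + rnorm(n, sd = 0.2)
    schema <- feature_group_schema(contextual = colnames(x))
    w <- fit_bilevel(d[1:100, ], d[101:150, ], schema = schema,
                     config = controller_config(seed = seed))
    traj <- attr(w, "provenance")$val_loss
    if (utils::tail(traj, 1) <= traj[1]) improved <- improved + 1
  }
  expect_gte(improved, 6)
})

test_that("bi-level fitting is reproducible end to end", {
  set.seed(77)
  d <- tibble::tibble(x1 = rnorm(60), x2 = rnorm(60))
  d$mean_heart_rate <- d$x1 + rnorm(60, sd = 0.2)
  schema <- feature_group_schema(contextual = c("x1", "x2"))
  w1 <- fit_bilevel(d[1:45, ], d[46:60, ], schema = schema,
                    config = controller_config(seed = 9))
  w2 <- fit_bilevel(d[1:45, ], d[46:60, ], schema = schema,
                    config = controller_config(seed = 9))
  expect_equal(w1$weight, w2$weight, tolerance = 1e-15)
  expect_equal(attr(w1, "provenance")$val_loss, attr(w2, "provenance")$val_loss)
})

test_that("feature selection ranks deterministically with schema-order ties", {
  w <- tibble::tibble(
    feature = c("f1", "f2", "f3", "f4"),
    group = "contextual",
    weight = c(0.4, 0.9, 0.4, 0.1)
  )
  class(w) <- c("ddm_feature_weights", class(w))
  top <- select_important_features(w, top_m = 3)
  expect_equal(top$feature, c("f2", "f1", "f3")) # f1 before f3 on tie
  expect_equal(top$rank, 1:3)

  # independent sort oracle
  ord <- order(-w$weight, seq_len(nrow(w)))
  expect_equal(select_important_features(w, top_m = 4)$feature, w$feature[ord])

  floor_sel <- select_important_features(w, weight_floor = 0.4)
  expect_setequal(floor_sel$feature, c("f1", "f2", "f3"))
  expect_error(select_important_features(w, top_m = 5), "top_m")
  expect_error(select_important_features(w), "top_m")

  # equal weights fall back to schema order entirely
  w2 <- w
  w2$weight <- rep(0.5, 4)
  expect_equal(select_important_features(w2, top_m = 4)$feature, w2$feature)
})

test_that("weights and schema serialize to JSON and YAML", {
  skip_if_not_installed("yaml")
  w <- tibble::tibble(feature = c("f1", "f2"), group = c("contextual", "sequential"),
                      weight = c(0.25, 0.75))
  class(w) <- c("ddm_feature_weights", class(w))
  attr(w, "provenance") <- list(n_outer = 5L, seed = 1L)
  jw <- withr::local_tempfile(fileext = ".json")
  write_feature_weights(w, jw)
  back <- jsonlite::read_json(jw, simplifyVector = TRUE)
  expect_equal(back$weights$f2, 0.75)
  expect_equal(back$provenance$n_outer, 5)

  sy <- withr::local_tempfile(fileext = ".yaml")
  schema <- feature_group_schema(contextual = "f1", sequential = "f2")
  write_feature_schema(schema, sy)
  expect_equal(yaml::read_yaml(sy)$contextual, "f1")
})
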