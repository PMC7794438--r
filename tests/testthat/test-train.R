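test_that("weighted cross-entropy matches the formula and weights positives", {
  expect_lt(weighted_cross_entropy(1, 0.999999, 100), 2e-4)
  expect_equal(weighted_cross_entropy(0, 0.5, 100), log(2))
  expect_equal(weighted_cross_entropy(1, 0.5, 100), 100 * log(2))
  # batch loss is the mean of per-sample losses
  expect_equal(
    weighted_cross_entropy(c(1, 0), c(0.5, 0.5), 100),
    (100 * log(2) + log(2)) / 2
  )
  expect_error(weighted_cross_entropy(1, 0.5, 0), "positive")
  expect_error(weighted_cross_entropy(1, 0.5, -3), "positive")
})

test_that("a positive sample's gradient is exactly w_pos times its weight-1 gradient", {
  sc <- feature_schema(
    list(feature_spec("A", "continuous"), feature_spec("F", "binary")), "y"
  )
  base <- gamnn_config(layer_size = 4, dropout_p = 0, l2_lambda = 0, seed = 6)
  m <- build_model(sc, base)
  X <- matrix(c(0.7, 1), 1, 2, dimnames = list(NULL, c("A", "F")))
  fp <- gamnn:::forward_pass(m, X, training = TRUE)
  g100 <- {
    m$config$positive_class_weight <- 100
    gamnn:::backward_pass(m, X, 1L, fp)
  }
  g1 <- {
    m$config$positive_class_weight <- 1
    gamnn:::backward_pass(m, X, 1L, fp)
  }
  for (nm in names(g1)) {
    expect_equal(g100[[nm]], 100 * g1[[nm]], tolerance = 1e-12)
  }
})

test_that("training separates an easily separable toy problem", {
  sc <- feature_schema(
    list(feature_spec("A", "continuous"), feature_spec("B", "continuous")), "y"
  )
  ds <- withr::with_seed(31, {
    a <- rnorm(400)
    b <- rnorm(400)
    y <- as.integer(a > 0)  # one informative feature, fully separable
    new_dataset(cbind(A = a, B = b), y)
  })
  cfg <- gamnn_config(layer_size = 10, max_epochs = 100, seed = 31)
  fit <- train_gamnn(build_model(sc, cfg), ds, cfg)
  expect_gte(roc_auc(ds$labels, predict_proba(fit$model, ds)), 0.95)
  expect_equal(nrow(fit$log), 100)  # no early stopping by default
})

test_that("the learning rate drops by the reduce factor after a patience-length plateau", {
  sc <- feature_schema(list(feature_spec("A", "continuous")), "y")
  ds <- tiny_dataset(n = 40, seed = 2)
  ds <- new_dataset(ds$values[, "AGE", drop = FALSE], ds$labels, "A")
  # a vanishing learning rate freezes the weights, so the monitored
  # validation loss never improves after epoch 1
  cfg <- gamnn_config(
    layer_size = 4, dropout_p = 0, learning_rate = 1e-300, min_lr = 0,
    max_epochs = 14, lr_patience_epochs = 5, lr_reduce_factor = 10, seed = 2
  )
  fit <- train_gamnn(build_model(sc, cfg), ds, cfg, val_ds = ds)
  lr <- fit$log$lr
  expect_equal(lr[1:6], rep(1e-300, 6))       # epoch 1 sets best; 5 stale epochs
  expect_equal(lr[7], 1e-300 / 10)            # reduction applies to the next epoch
  ratios <- lr[-1] / lr[-length(lr)]
  expect_true(all(vapply(ratios, function(r) {
    isTRUE(all.equal(r, 1)) || isTRUE(all.equal(r, 1 / 10))
  }, logical(1))))
  expect_true(all(diff(fit$log$lr) <= 0))     # never increases
})

test_that("training is reproducible under a fixed seed", {
  sc <- tiny_schema()
  ds <- tiny_dataset(n = 60, seed = 13)
  cfg <- gamnn_config(layer_size = 6, max_epochs = 5, seed = 99)
  f1 <- train_gamnn(build_model(sc, cfg), ds, cfg)
  f2 <- train_gamnn(build_model(sc, cfg), ds, cfg)
  expect_equal(f1$log$train_loss, f2$log$train_loss, tolerance = 1e-6)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("training rejects empty or single-class data", {
  sc <- feature_schema(list(feature_spec("A", "continuous")), "y")
  cfg <- gamnn_config(seed = 1)
  ds0 <- new_dataset(matrix(numeric(0), 0, 1, dimnames = list(NULL, "A")), integer(0))
  expect_error(train_gamnn(build_model(sc, cfg), ds0, cfg), "empty")
  ds1 <- new_dataset(cbind(A = rnorm(10)), rep(1L, 10))
  expect_error(train_gamnn(build_model(sc, cfg), ds1, cfg), "single class")
})

test_that("stratified folds balance positives and partition all rows", {
  labels <- c(rep(1L, 5), rep(0L, 5))
  folds <- kfold_indices(10, 5, labels, seed = 4)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), 1:10)
  expect_equal(sum(lengths(folds)), 10)
  pos_per_fold <- vapply(folds, function(f) sum(labels[f]), integer(1))
  expect_equal(pos_per_fold, rep(1L, 5))
  expect_identical(folds, kfold_indices(10, 5, labels, seed = 4))
  expect_error(kfold_indices(10, 5, c(rep(0L, 8), 1L, 1L), seed = 1), "fewer folds")

  # positive counts never differ by more than one, any n
  labels2 <- withr::with_seed(5, rbinom(83, 1, 0.3))
  folds2 <- kfold_indices(83, 5, labels2, seed = 5)
  pos2 <- vapply(folds2, function(f) sum(labels2[f]), integer(1))
  expect_lte(max(pos2) - min(pos2), 1)
})

test_that("U-shaped solutions are representable and stable, but not found from random init", {
  # The single-unit tanh bottleneck admits non-monotone shape functions and
  # gradient training preserves them, yet Adam from random initialization
  # converges to the U's monotone component (a higher-loss local minimum):
  # the fitted curve tracks only one arm. This documents a known failure
  # mode of the architecture for strongly non-monotone effects.
  set.seed(3)
  n <- 6000
  z <- rnorm(n)
  f <- 0.6 * (z^2 - 1)  # symmetric U on the standardized scale
  y <- rbinom(n, 1, plogis(-2.2 + f))
  scm <- feature_schema(list(feature_spec("Z", "continuous")), "y")
  ds <- new_dataset(cbind(Z = z), y)
  cfg <- gamnn_config(seed = 1, dropout_p = 0, positive_class_weight = 1,
                      max_epochs = 40)
  cold <- train_gamnn(build_model(scm, cfg), ds, cfg)
  rho_cold <- cor(feature_contribution(cold$model, ds, "Z"), f,
                  method = "spearman")
  expect_lt(abs(rho_cold), 0.5)  # monotone collapse: no rank agreement with the U

  # warm start from a hand-constructed U (two opposing shifted tanh units)
  m <- build_model(scm, cfg)
  k <- 1.5; ctr <- 1.2
  W1 <- matrix(0, 1, 50); b1 <- numeric(50)
  W1[1, 1] <- k; b1[1] <- k * ctr
  W1[1, 2] <- k; b1[2] <- -k * ctr
  W2 <- matrix(0, 50, 1); W2[1, 1] <- -1; W2[2, 1] <- 1
  m$params[["Z.W1"]] <- W1; m$params[["Z.b1"]] <- b1
  m$params[["Z.W2"]] <- W2; m$params[["Z.b2"]] <- 0
  m$params[["logistic.w"]] <- 2.0; m$params[["logistic.b0"]] <- -1.2
  warm <- train_gamnn(m, ds, cfg)
  rho_warm <- cor(feature_contribution(warm$model, ds, "Z"), f,
                  method = "spearman")
  expect_gt(rho_warm, 0.95)  # training preserves and refines the U
  expect_lt(gamnn:::dataset_loss(warm$model, ds),
            gamnn:::dataset_loss(cold$model, ds))  # the U is the better optimum
})

test_that("class weighting raises recall at threshold 0.5 on imbalanced data", {
  sim <- generate_cohort(linear_cohort_spec(2500, seed = 10, prevalence = 0.04))
  pp <- split_prep(sim, seed = 10)
  recall_at <- function(w) {
    cfg <- gamnn_config(layer_size = 10, max_epochs = 25,
                        positive_class_weight = w, seed = 10)
    fit <- train_gamnn(build_model(sim$schema, cfg), pp$train, cfg)
    pred <- predict_proba(fit$model, pp$test) >= 0.5
    sum(pred & pp$test$labels == 1) / sum(pp$test$labels == 1)
  }
  expect_gt(recall_at(100), recall_at(1))
})

test_that("a singleton grid is selected with mean AUC equal to its fold mean", {
  sim <- generate_cohort(linear_cohort_spec(1200, seed = 3, prevalence = 0.1))
  pp <- split_prep(sim, seed = 3)
  grid <- list(gamnn_config(layer_size = 6, max_epochs = 8, seed = 3))
  gs <- grid_search_cv(pp$train, sim$schema, grid, k = 5, seed = 3)
  expect_equal(nrow(gs$results), 1)
  expect_true(gs$results$selected[1])
  expect_equal(gs$results$mean_auc[1], mean(gs$results$fold_aucs[[1]]),
               tolerance = 1e-12)
  expect_length(gs$results$fold_aucs[[1]], 5)
  # the returned model is retrained on all training rows
  expect_s3_class(gs$model, "gamnn_fit")
  expect_length(predict_proba(gs$model$model, pp$test), nrow(pp$test$values))
})

test_that("grid-search ties break by grid order", {
  sim <- generate_cohort(linear_cohort_spec(1200, seed = 3, prevalence = 0.1))
  pp <- split_prep(sim, seed = 3)
  cfg <- gamnn_config(layer_size = 6, max_epochs = 8, seed = 3)
  gs <- grid_search_cv(pp$train, sim$schema, list(cfg, cfg), k = 5, seed = 3)
  expect_equal(gs$results$mean_auc[1], gs$results$mean_auc[2])
  expect_equal(which(gs$results$selected), 1L)
})

test_that("the canonical grid has the documented axes", {
  g <- gamnn_grid()
  expect_length(g, 4 * 5 * 2 * 3 * 2)
  sizes <- sort(unique(vapply(g, function(c) c$layer_size, integer(1))))
  expect_equal(sizes, c(10L, 40L, 50L, 90L, 100L))
  expect_setequal(unique(vapply(g, function(c) c$dropout_p, double(1))),
                  c(0.25, 0.5, 0.9))
  expect_setequal(unique(vapply(g, function(c) c$l2_lambda, double(1))),
                  c(0.001, 0.0001))

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_hidden_layers: [1]",
    "layer_size: [10, 50]",
    "hidden_activation: [tanh]",
    "dropout_p: [0.5]",
    "l2_lambda: [0.0001]"
  ), path)
  g2 <- read_grid(path, max_epochs = 7)
  expect_length(g2, 2)
  expect_equal(g2[[1]]$max_epochs, 7L)
})

test_that("train logs export to CSV with the documented columns", {
  sc <- feature_schema(list(feature_spec("A", "continuous")), "y")
  ds <- new_dataset(cbind(A = rnorm(40)), rep(c(0L, 1L), 20))
  cfg <- gamnn_config(layer_size = 4, max_epochs = 3, seed = 1)
  fit <- train_gamnn(build_model(sc, cfg), ds, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_train_log(fit, path)
  log <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(log), c("epoch", "train_loss", "val_loss", "lr"))
  expect_equal(nrow(log), 3)
})
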