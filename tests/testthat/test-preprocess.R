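test_that("train/test split has round(f*n) training rows and is seed-determined", {
  sp <- train_test_split(10, 0.8, seed = 1)
  expect_length(sp$train_idx, 8)
  expect_length(sp$test_idx, 2)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:10)
  expect_identical(train_test_split(10, 0.8, seed = 7),
                   train_test_split(10, 0.8, seed = 7))
  expect_false(identical(sp$train_idx, train_test_split(10, 0.8, seed = 2)$train_idx))
  expect_error(train_test_split(1, 0.8, 1), "n >= 2")
})

test_that("imputation follows each policy and never uses the test set's own mean", {
  sc <- tiny_schema()
  train <- new_dataset(
    cbind(AGE = c(40, 60, NA), ASA_SCORE = c(2, NA, 3),
          MAX_GLUCOSE = c(100, 110, 120),
          ART_LINE_YN = c(1, NA, 0), CVC_ANES_YN = c(0, 0, 1)),
    c(0L, 1L, 0L)
  )
  stats <- impute_stats(train, sc)
  expect_equal(stats[["AGE"]], 50)  # mean of observed {40, 60}
  imp <- impute(train, sc, stats)
  expect_false(anyNA(imp$values))
  expect_equal(imp$values[3, "AGE"], c(AGE = 50))
  expect_equal(imp$values[2, "ASA_SCORE"], c(ASA_SCORE = 3))  # constant policy
  expect_equal(imp$values[2, "ART_LINE_YN"], c(ART_LINE_YN = 0))  # zero policy
  # observed cells unchanged
  obs <- !is.na(train$values)
  expect_identical(imp$values[obs], train$values[obs])

  # test rows take the TRAINING mean, not their own
  test <- new_dataset(
    cbind(AGE = c(100, NA), ASA_SCORE = c(4, 4), MAX_GLUCOSE = c(90, 95),
          ART_LINE_YN = c(1, 1), CVC_ANES_YN = c(0, 0)),
    c(0L, 1L)
  )
  expect_equal(impute(test, sc, stats)$values[2, "AGE"], c(AGE = 50))
})

test_that("imputation errors on absent stats and all-missing training features", {
  sc <- feature_schema(list(feature_spec("AGE", "continuous")), "y")
  ds <- new_dataset(cbind(AGE = c(NA_real_, NA_real_)), c(0L, 1L))
  expect_error(impute_stats(ds, sc), "entirely missing")
  expect_error(
    impute(ds, sc, setNames(numeric(0), character(0))),
    "no mean for feature 'AGE'"
  )
})

test_that("clipping replaces out-of-bound values and only those", {
  sc <- tiny_schema()  # MAX_GLUCOSE has clip_max = 300
  ds <- new_dataset(
    cbind(AGE = c(30, 55), ASA_SCORE = c(2, 3),
          MAX_GLUCOSE = c(9999, 300),
          ART_LINE_YN = c(0, 1), CVC_ANES_YN = c(0, 0)),
    c(0L, 1L)
  )
  cl <- clip_values(ds, sc)
  expect_equal(cl$values[1, "MAX_GLUCOSE"], c(MAX_GLUCOSE = 300))
  expect_equal(cl$values[2, "MAX_GLUCOSE"], c(MAX_GLUCOSE = 300))  # boundary untouched
  expect_identical(cl$values[, "AGE"], ds$values[, "AGE"])  # no bounds: identity

  sc_min <- feature_schema(list(feature_spec("T", "continuous", clip_min = 0)), "y")
  ds_min <- new_dataset(cbind(T = c(-5, 2)), c(0L, 1L))
  expect_equal(clip_values(ds_min, sc_min)$values[, "T"], c(0, 2))
})

test_that("standardization uses population sd of training rows only", {
  sc <- feature_schema(
    list(feature_spec("A", "continuous"), feature_spec("B", "continuous")),
    "y"
  )
  train <- new_dataset(cbind(A = c(1, 3), B = c(0, 10)), c(0L, 1L))
  st <- standardize_fit(train, sc)
  expect_equal(st$stats$mean[st$stats$feature == "A"], 2)
  expect_equal(st$stats$sd[st$stats$feature == "A"], 1)  # population sd of {1,3}
  expect_equal(sum(!is.na(st$stats$sd)), 2)

  applied <- standardize_apply(new_dataset(cbind(A = 3, B = 5), 0L), st)
  expect_equal(applied$values[1, "A"], c(A = 1))

  # applying train-fitted stats back to the training set: mean 0, sd 1
  back <- standardize_apply(train, st)
  expect_lt(max(abs(colMeans(back$values))), 1e-10)
  expect_equal(unname(apply(back$values, 2, function(v) sqrt(mean((v - mean(v))^2)))),
               c(1, 1), tolerance = 1e-10)

  const <- new_dataset(cbind(A = c(5, 5, 5), B = 1:3), c(0L, 1L, 0L))
  expect_error(standardize_fit(const, sc), "'A'")

  expect_error(
    standardize_apply(new_dataset(cbind(A = 1, C = 2), 0L), st),
    "C"
  )
})

test_that("binary features stay on their 0/1 scale unless asked otherwise", {
  sc <- tiny_schema()
  ds <- tiny_dataset()
  prep <- preprocess_fit(ds, sc)
  out <- preprocess_apply(ds, prep)
  expect_setequal(unique(out$values[, "ART_LINE_YN"]), c(0, 1))

  prep2 <- preprocess_fit(ds, sc, standardize_binary = TRUE)
  out2 <- preprocess_apply(ds, prep2)
  expect_lt(max(abs(mean(out2$values[, "ART_LINE_YN"]))), 1e-10)
})

test_that("no test-set statistic influences preprocessing (leakage check)", {
  sc <- tiny_schema()
  sim <- tiny_dataset(n = 100, seed = 11)
  split <- train_test_split(100, 0.8, seed = 3)
  train <- gamnn:::subset_dataset(sim, split$train_idx)
  prep1 <- preprocess_fit(train, sc)
  # perturb the test rows heavily; training-fitted stats must be bit-identical
  sim2 <- sim
  sim2$values[split$test_idx, "AGE"] <- sim2$values[split$test_idx, "AGE"] * 1000
  train2 <- gamnn:::subset_dataset(sim2, split$train_idx)
  prep2 <- preprocess_fit(train2, sc)
  expect_identical(prep1$std_stats$stats, prep2$std_stats$stats)
  expect_identical(prep1$impute_means, prep2$impute_means)
})

test_that("the composed impute -> clip -> standardize pipeline is deterministic", {
  sc <- tiny_schema()
  ds <- tiny_dataset(n = 80, seed = 5)
  ds$values[c(2, 9), "AGE"] <- NA
  ds$values[4, "MAX_GLUCOSE"] <- 5000
  run <- function() {
    prep <- preprocess_fit(ds, sc)
    preprocess_apply(ds, prep)$values
  }
  expect_identical(run(), run())
})

test_that("standardization stats and preprocessors survive JSON round-trips", {
  sc <- tiny_schema()
  ds <- tiny_dataset()
  prep <- preprocess_fit(ds, sc)
  p1 <- withr::local_tempfile(fileext = ".json")
  write_standardization(prep$std_stats, p1)
  st2 <- read_standardization(p1)
  expect_equal(st2$stats, prep$std_stats$stats)

  p2 <- withr::local_tempfile(fileext = ".json")
  write_preprocessor(prep, p2)
  prep2 <- read_preprocessor(p2, sc)
  expect_equal(prep2$impute_means, prep$impute_means)
  expect_equal(preprocess_apply(ds, prep2)$values,
               preprocess_apply(ds, prep)$values, tolerance = 1e-12)
})
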