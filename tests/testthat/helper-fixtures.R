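# Shared fixtures and independent oracles, all built in code.

# Tiny mixed schema: 3 continuous (one with constant-policy imputation and
# clipping) + 2 binary features.
tiny_schema <- function() {
  feature_schema(
    list(
      feature_spec("AGE", "continuous"),
      feature_spec("ASA_SCORE", "continuous",
                   impute_policy = "constant", constant_value = 3),
      feature_spec("MAX_GLUCOSE", "continuous", clip_max = 300),
      feature_spec("ART_LINE_YN", "binary"),
      feature_spec("CVC_ANES_YN", "binary")
    ),
    outcome = "label"
  )
}

# Small complete dataset matching tiny_schema, with a signal in AGE.
tiny_dataset <- function(n = 60, seed = 42) {
  withr::with_seed(seed, {
    age <- rnorm(n, 56, 17)
    asa <- sample(1:4, n, replace = TRUE)
    glu <- rnorm(n, 140, 30)
    art <- rbinom(n, 1, 0.2)
    cvc <- rbinom(n, 1, 0.1)
    logit <- -1 + 0.06 * (age - 56) + 0.8 * art
    y <- rbinom(n, 1, plogis(logit))
    if (all(y == y[1])) y[1] <- 1 - y[1]
    new_dataset(
      cbind(AGE = age, ASA_SCORE = asa, MAX_GLUCOSE = glu,
            ART_LINE_YN = art, CVC_ANES_YN = cvc),
      y
    )
  })
}

# O(n^2) all-pairs AUC oracle: wins + half-ties over positive-negative pairs.
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Ranking-walk AP oracle: walk the score-descending list (stable ties),
# accumulate precision at each positive.
brute_force_ap <- function(labels, scores) {
  ord <- order(-scores)
  y <- labels[ord]
  tp <- 0
  acc <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      tp <- tp + 1
      acc <- acc + tp / i
    }
  }
  acc / sum(labels == 1)
}

# A GAM-NN with every parameter drawn N(0, sd); independent of build_model's
# initialization path.
random_small_model <- function(schema, seed, n_hidden_layers = 1L,
                               layer_size = 4L) {
  cfg <- gamnn_config(
    n_hidden_layers = n_hidden_layers, layer_size = layer_size,
    dropout_p = 0, seed = seed
  )
  m <- build_model(schema, cfg)
  withr::with_seed(seed + 1000, {
    m$params <- lapply(m$params, function(p) {
      if (is.matrix(p)) matrix(rnorm(length(p)), nrow(p), ncol(p))
      else rnorm(length(p))
    })
  })
  m
}

# All-linear-logit cohort for the linear-limit checks.
linear_cohort_spec <- function(n, seed, prevalence = 0.05) {
  cohort_spec(
    n_samples = n,
    continuous = list(
      cont_effect("AGE", "linear", scale = 0.9, mean = 56, sd = 17,
                  lower = 18, upper = 89),
      cont_effect("MIN_DBP", "linear", scale = -0.7, mean = 45, sd = 12,
                  lower = 10, upper = 90),
      cont_effect("EBL", "linear", scale = 0.5, mean = 100, sd = 80,
                  lower = 0, upper = 2000)
    ),
    binary = list(bin_effect("ART_LINE_YN", prevalence = 0.2, weight = 0.8)),
    target_prevalence = prevalence,
    seed = seed
  )
}

split_prep <- function(sim, seed = 1) {
  split <- train_test_split(nrow(sim$dataset$values), 0.8, seed)
  train_raw <- gamnn:::subset_dataset(sim$dataset, split$train_idx)
  test_raw <- gamnn:::subset_dataset(sim$dataset, split$test_idx)
  prep <- preprocess_fit(train_raw, sim$schema)
  list(
    split = split, prep = prep,
    train_raw = train_raw, test_raw = test_raw,
    train = preprocess_apply(train_raw, prep),
    test = preprocess_apply(test_raw, prep)
  )
}
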