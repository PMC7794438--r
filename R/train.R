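#' Class-weighted cross-entropy
#'
#' Positive samples cost `w_pos` times the loss of the matching negative:
#' `y = 1` contributes `w_pos * (-log p)` and `y = 0` contributes
#' `-log(1 - p)`. Over a batch the loss is the mean of per-sample losses.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities.
#' @param w_pos Positive-class weight (default 100, reflecting a <1%
#'   outcome prevalence).
#' @return Mean weighted cross-entropy (a single nonnegative number).
#' @export
weighted_cross_entropy <- function(y, p, w_pos = 100) {
  if (!is.numeric(w_pos) || length(w_pos) != 1L || w_pos <= 0) {
    abort("`w_pos` must be a positive number.")
  }
  y <- assert_binary_labels(y)
  p <- clamp_prob(p)
  per <- ifelse(y == 1, w_pos * (-log(p)), -log(1 - p))
  mean(per)
}

# Sum of squared entries of every weight matrix/vector (biases excluded).
l2_penalty <- function(params) {
  nm <- names(params)
  wnames <- nm[grepl("\\.W[0-9]+$", nm) | nm == "logistic.w"]
  sum(vapply(params[wnames], function(p) sum(p^2), double(1)))
}

# Gradients of mean weighted CE + L2 w.r.t. every parameter, for one batch.
backward_pass <- function(model, X, y, fp) {
  cfg <- model$config
  L <- cfg$n_hidden_layers
  lambda <- cfg$l2_lambda
  keep <- 1 - cfg$dropout_p
  p <- model$params
  n <- nrow(X)
  prob <- sigmoid(fp$logit)
  wts <- ifelse(y == 1, cfg$positive_class_weight, 1)
  dlogit <- matrix(wts * (prob - y) / n, ncol = 1L)
  grads <- list()
  w_log <- p[["logistic.w"]]
  grads[["logistic.w"]] <- as.numeric(crossprod(fp$units, dlogit)) + 2 * lambda * w_log
  grads[["logistic.b0"]] <- sum(dlogit)
  agrad <- activation_grad(cfg$hidden_activation)
  for (f in model$cont_features) {
    j <- match(f, model$feature_names)
    cache <- fp$caches[[f]]
    dZb <- dlogit * w_log[j] * (1 - cache$Tb^2)
    Wb <- p[[paste0(f, ".W", L + 1L)]]
    grads[[paste0(f, ".W", L + 1L)]] <- crossprod(cache$As[[L + 1L]], dZb) + 2 * lambda * Wb
    grads[[paste0(f, ".b", L + 1L)]] <- sum(dZb)
    dA <- dZb %*% t(Wb)
    for (l in rev(seq_len(L))) {
      if (cfg$dropout_p > 0 && !is.null(cache$masks[[l]])) {
        dA <- dA * cache$masks[[l]] / keep
      }
      dZ <- dA * agrad(cache$Zs[[l]], cache$Hs[[l]])
      Wl <- p[[paste0(f, ".W", l)]]
      grads[[paste0(f, ".W", l)]] <- crossprod(cache$As[[l]], dZ) + 2 * lambda * Wl
      grads[[paste0(f, ".b", l)]] <- colSums(dZ)
      if (l > 1L) dA <- dZ %*% t(Wl)
    }
  }
  grads
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

dataset_loss <- function(model, ds) {
  fp <- forward_pass(model, ds$values, training = FALSE)
  weighted_cross_entropy(ds$labels, sigmoid(fp$logit),
                         model$config$positive_class_weight) +
    model$config$l2_lambda * l2_penalty(model$params)
}

#' Train a GAM-NN
#'
#' Mini-batch training with Adam, class-weighted cross-entropy, dropout on
#' subnetwork hidden layers, and an L2 penalty on weight matrices. The
#' learning rate is divided by `lr_reduce_factor` whenever the monitored
#' loss (validation loss when `val_ds` is given, otherwise training loss)
#' fails to improve for `lr_patience_epochs` consecutive epochs, down to
#' `min_lr`. Training runs to `max_epochs` unless `early_stop` is enabled.
#' All randomness (shuffling, dropout) derives from `config$seed`, so a
#' fixed seed reproduces the final weights.
#'
#' @param model A `gamnn_model` from [build_model()].
#' @param train_ds Preprocessed training `gamnn_dataset`.
#' @param config A [gamnn_config()]; defaults to the model's own.
#' @param val_ds Optional held-out `gamnn_dataset` monitored for the
#'   learning-rate schedule.
#' @return A `gamnn_fit`: list with the trained `model` and a `log` tibble
#'   (`epoch`, `train_loss`, `val_loss`, `lr`).
#' @export
train_gamnn <- function(model, train_ds, config = model$config, val_ds = NULL) {
  n <- nrow(train_ds$values)
  if (n == 0L) abort("Training set is empty.")
  if (length(unique(train_ds$labels)) < 2L) {
    abort("Training labels contain a single class; cannot train a classifier.")
  }
  model$config <- config
  state <- adam_init(model$params)
  lr <- config$learning_rate
  best <- Inf
  wait <- 0L
  log_rows <- vector("list", config$max_epochs)
  n_epochs <- 0L
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        Xb <- train_ds$values[idx, , drop = FALSE]
        yb <- train_ds$labels[idx]
        fp <- forward_pass(model, Xb, training = TRUE)
        batch_losses[bi] <- weighted_cross_entropy(
          yb, sigmoid(fp$logit), config$positive_class_weight
        ) + config$l2_lambda * l2_penalty(model$params)
        grads <- backward_pass(model, Xb, yb, fp)
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
      }
      train_loss <- mean(batch_losses)
      val_loss <- if (!is.null(val_ds)) dataset_loss(model, val_ds) else NA_real_
      monitored <- if (is.na(val_loss)) train_loss else val_loss
      log_rows[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                             val_loss = val_loss, lr = lr)
      n_epochs <- epoch
      if (monitored < best) {
        best <- monitored
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$lr_patience_epochs) {
          at_floor <- lr <= config$min_lr
          if (at_floor && config$early_stop) break
          lr <- max(lr / config$lr_reduce_factor, config$min_lr)
          wait <- 0L
        }
      }
    }
  })
  log <- tibble::as_tibble(do.call(rbind, log_rows[seq_len(n_epochs)]))
  structure(list(model = model, log = log), class = "gamnn_fit")
}

#' @export
print.gamnn_fit <- function(x, ...) {
  cat(sprintf(
    "<gamnn_fit> %d epochs, final train loss %.4f, final lr %g\n",
    nrow(x$log), x$log$train_loss[nrow(x$log)], x$log$lr[nrow(x$log)]
  ))
  invisible(x)
}

#' Training log of a fit
#'
#' @param x A `gamnn_fit`.
#' @param ... Unused.
#' @return The per-epoch log tibble.
#' @export
tidy.gamnn_fit <- function(x, ...) x$log

#' One-row fit summary
#'
#' @param x A `gamnn_fit`.
#' @param ... Unused.
#' @return One-row tibble with epoch count and final losses.
#' @export
glance.gamnn_fit <- function(x, ...) {
  n <- nrow(x$log)
  tibble::tibble(
    n_epochs = n,
    final_train_loss = x$log$train_loss[n],
    final_val_loss = x$log$val_loss[n],
    final_lr = x$log$lr[n]
  )
}

#' Export a training log to CSV
#'
#' @param fit A `gamnn_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(fit, path) {
  readr::write_csv(fit$log, path, progress = FALSE)
  invisible(path)
}

#' Stratified k-fold validation indices
#'
#' Partitions `1:n` into `k` disjoint validation folds, stratified by
#' outcome so each fold's positive count differs by at most one — at a
#' sub-1% prevalence, unstratified folds can easily contain no positives,
#' leaving the fold AUC undefined.
#'
#' @param n Number of rows.
#' @param k Number of folds (>= 2).
#' @param labels 0/1 outcome vector of length `n`.
#' @param seed Integer seed.
#' @return List of `k` integer vectors (validation indices) partitioning
#'   `1:n`.
#' @export
kfold_indices <- function(n, k = 5L, labels, seed = 1L) {
  if (k < 2L) abort("Need k >= 2 folds.")
  labels <- assert_binary_labels(labels)
  if (length(labels) != n) abort("`labels` must have length n.")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < k)) {
    abort(sprintf(
      "Class %s has only %d member(s) but k = %d; use fewer folds.",
      names(counts)[which.min(counts)], min(counts), k
    ))
  }
  folds <- vector("list", k)
  with_seed(derive_seed(seed, "kfold"), {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      assign_f <- rep_len(seq_len(k), length(idx))
      for (i in seq_len(k)) {
        folds[[i]] <- c(folds[[i]], idx[assign_f == i])
      }
    }
  })
  lapply(folds, sort)
}

#' Define a hyperparameter grid
#'
#' Builds the Cartesian product of the supplied hyperparameter values as a
#' list of [gamnn_config()]s. Defaults reproduce the canonical search
#' space: 1-4 hidden layers, sizes {10, 40, 50, 90, 100}, relu/tanh,
#' dropout {0.25, 0.5, 0.9}, L2 {0.001, 0.0001}.
#'
#' @param n_hidden_layers,layer_size,hidden_activation,dropout_p,l2_lambda
#'   Vectors of candidate values.
#' @param ... Further fixed arguments passed to every [gamnn_config()]
#'   (e.g. `max_epochs`, `seed`).
#' @return List of `gamnn_config` objects.
#' @export
gamnn_grid <- function(n_hidden_layers = 1:4,
                       layer_size = c(10L, 40L, 50L, 90L, 100L),
                       hidden_activation = c("relu", "tanh"),
                       dropout_p = c(0.25, 0.5, 0.9),
                       l2_lambda = c(0.001, 0.0001),
                       ...) {
  combos <- expand.grid(
    n_hidden_layers = n_hidden_layers,
    layer_size = layer_size,
    hidden_activation = hidden_activation,
    dropout_p = dropout_p,
    l2_lambda = l2_lambda,
    stringsAsFactors = FALSE
  )
  fixed <- list(...)
  lapply(seq_len(nrow(combos)), function(i) {
    do.call(gamnn_config, c(as.list(combos[i, ]), fixed))
  })
}

#' Read a hyperparameter grid from YAML/JSON
#'
#' The document lists candidate values per hyperparameter; their Cartesian
#' product defines the grid. Unlisted hyperparameters keep
#' [gamnn_config()] defaults.
#'
#' @param path Config file path.
#' @param ... Fixed arguments forwarded to [gamnn_grid()].
#' @return List of `gamnn_config` objects.
#' @export
read_grid <- function(path, ...) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- c(doc, list(...))
  do.call(gamnn_grid, args)
}

#' Cross-validated grid search
#'
#' For every candidate configuration, trains `k` models on stratified
#' folds of the training data (each fold's model never sees its own
#' validation rows) and scores each held-out fold by ROC AUC. The
#' configuration with the highest mean fold AUC wins (ties broken by grid
#' order), and is then retrained on all training rows before being
#' returned.
#'
#' @param train_ds Preprocessed training `gamnn_dataset`.
#' @param schema The [feature_schema()].
#' @param grid List of [gamnn_config()]s (see [gamnn_grid()]).
#' @param k Number of folds.
#' @param seed Integer seed for folds and per-combination training seeds.
#' @return A `gamnn_grid_search`: `results` tibble (one row per
#'   combination with `fold_aucs` list-column, `mean_auc`, `selected`),
#'   the retrained winning `model` (a `gamnn_fit`), and `best_config`.
#' @export
grid_search_cv <- function(train_ds, schema, grid, k = 5L, seed = 1L) {
  if (length(grid) == 0L) abort("The hyperparameter grid is empty.")
  n <- nrow(train_ds$values)
  folds <- kfold_indices(n, k, train_ds$labels, seed)
  fold_aucs <- matrix(NA_real_, length(grid), k)
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    for (fi in seq_len(k)) {
      val_idx <- folds[[fi]]
      tr_idx <- setdiff(seq_len(n), val_idx)
      stopifnot(length(intersect(tr_idx, val_idx)) == 0L)
      # fold seed depends on the config's own seed and the fold, not the
      # grid position: identical configurations tie exactly, and ties then
      # break by grid order
      cfg_fold <- cfg
      cfg_fold$seed <- derive_seed(seed, sprintf("fold%d_%d", fi, cfg$seed))
      fit <- tryCatch(
        {
          m0 <- build_model(schema, cfg_fold)
          train_gamnn(m0, subset_dataset(train_ds, tr_idx), cfg_fold,
                      val_ds = subset_dataset(train_ds, val_idx))
        },
        error = function(e) {
          abort(sprintf(
            "Training failed for grid combination %d, fold %d: %s",
            ci, fi, conditionMessage(e)
          ))
        }
      )
      scores <- predict_proba(fit$model, subset_dataset(train_ds, val_idx))
      fold_aucs[ci, fi] <- roc_auc(train_ds$labels[val_idx], scores)
    }
  }
  mean_aucs <- rowMeans(fold_aucs)
  best_i <- which.max(mean_aucs)  # which.max returns the first maximum
  best_cfg <- grid[[best_i]]
  best_cfg$seed <- derive_seed(seed, sprintf("retrain_%d", best_cfg$seed))
  final_fit <- train_gamnn(build_model(schema, best_cfg), train_ds, best_cfg)
  results <- tibble::tibble(
    combination = seq_along(grid),
    config = grid,
    fold_aucs = lapply(seq_along(grid), function(i) fold_aucs[i, ]),
    mean_auc = mean_aucs,
    selected = seq_along(grid) == best_i
  )
  structure(
    list(results = results, model = final_fit, best_config = best_cfg,
         k = k, seed = as.integer(seed)),
    class = "gamnn_grid_search"
  )
}

#' @export
print.gamnn_grid_search <- function(x, ...) {
  cat(sprintf(
    "<gamnn_grid_search> %d combinations x %d folds; best mean AUC %.4f (combination %d)\n",
    nrow(x$results), x$k, max(x$results$mean_auc), which(x$results$selected)
  ))
  invisible(x)
}

#' Grid-search results table
#'
#' @param x A `gamnn_grid_search`.
#' @param ... Unused.
#' @return The per-combination results tibble.
#' @export
tidy.gamnn_grid_search <- function(x, ...) x$results
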