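#' GAM-NN configuration
#'
#' Hyperparameters of the generalized additive neural network and its
#' training loop. Defaults reproduce the reference configuration for the
#' full feature set: one hidden layer of 50 tanh units per continuous
#' feature, dropout 0.5, L2 lambda 1e-4, positive class weighted 100x,
#' batch size 256, Adam at its conventional default learning rate 0.001,
#' learning rate divided by 10 after 5 epochs without improvement, at most
#' 100 epochs.
#'
#' @param n_hidden_layers Hidden layers per continuous-feature subnetwork
#'   (1-4 in the canonical grid).
#' @param layer_size Units per hidden layer.
#' @param hidden_activation `"tanh"` or `"relu"`.
#' @param dropout_p Dropout probability on hidden activations during
#'   training.
#' @param l2_lambda L2 penalty on weight matrices (biases excluded).
#' @param positive_class_weight Loss weight for positive samples, to
#'   counter rare-outcome imbalance.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_reduce_factor Divisor applied to the learning rate on plateau.
#' @param lr_patience_epochs Epochs without monitored-loss improvement
#'   before a reduction.
#' @param min_lr Learning-rate floor.
#' @param early_stop Stop when the learning rate is floored and the
#'   monitored loss still fails to improve for a full patience window
#'   (off by default: training runs to `max_epochs`).
#' @param seed Integer seed driving weight initialization, shuffling and
#'   dropout.
#'
#' @return A `gamnn_config` object.
#' @export
gamnn_config <- function(n_hidden_layers = 1L,
                         layer_size = 50L,
                         hidden_activation = c("tanh", "relu"),
                         dropout_p = 0.5,
                         l2_lambda = 1e-4,
                         positive_class_weight = 100,
                         batch_size = 256L,
                         max_epochs = 100L,
                         learning_rate = 0.001,
                         lr_reduce_factor = 10,
                         lr_patience_epochs = 5L,
                         min_lr = 1e-6,
                         early_stop = FALSE,
                         seed = 1L) {
  hidden_activation <- match.arg(hidden_activation)
  if (n_hidden_layers < 1L) abort("Need at least one hidden layer.")
  if (layer_size < 1L) abort("`layer_size` must be positive.")
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must be in [0, 1).")
  if (l2_lambda < 0) abort("`l2_lambda` must be nonnegative.")
  if (positive_class_weight <= 0) abort("`positive_class_weight` must be positive.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  if (lr_reduce_factor <= 1) abort("`lr_reduce_factor` must exceed 1.")
  structure(
    list(
      n_hidden_layers = as.integer(n_hidden_layers),
      layer_size = as.integer(layer_size),
      hidden_activation = hidden_activation,
      dropout_p = dropout_p,
      l2_lambda = l2_lambda,
      positive_class_weight = positive_class_weight,
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      learning_rate = learning_rate,
      lr_reduce_factor = lr_reduce_factor,
      lr_patience_epochs = as.integer(lr_patience_epochs),
      min_lr = min_lr,
      early_stop = isTRUE(early_stop),
      seed = as.integer(seed)
    ),
    class = "gamnn_config"
  )
}

#' @export
print.gamnn_config <- function(x, ...) {
  cat(sprintf(
    "<gamnn_config> %d hidden layer(s) x %d %s units, dropout %.2f, L2 %g, w+ %g, batch %d, <=%d epochs, seed %d\n",
    x$n_hidden_layers, x$layer_size, x$hidden_activation, x$dropout_p,
    x$l2_lambda, x$positive_class_weight, x$batch_size, x$max_epochs, x$seed
  ))
  invisible(x)
}

activation_fun <- function(name) {
  switch(name, tanh = tanh, relu = function(z) pmax(z, 0))
}

activation_grad <- function(name) {
  switch(name,
    tanh = function(z, a) 1 - a^2,
    relu = function(z, a) (z > 0) * 1
  )
}

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build an untrained GAM-NN
#'
#' Constructs the additive architecture: every continuous feature gets its
#' own subnetwork (`n_hidden_layers` dense layers of `layer_size` units,
#' then a single tanh unit that bounds the subnetwork output in (-1, 1));
#' binary features connect directly to the final logistic layer. All
#' subnetwork bottleneck outputs and binary inputs are concatenated into
#' the logistic layer, whose weights are the contribution multipliers.
#' Weight initialization is Glorot-uniform, seeded by `config$seed`.
#'
#' @param schema A [feature_schema()] with at least one feature.
#' @param config A [gamnn_config()].
#' @return A `gamnn_model`.
#' @export
build_model <- function(schema, config = gamnn_config()) {
  feats <- schema_feature_names(schema)
  if (length(feats) == 0L) abort("Schema has no features.")
  kinds <- schema_kinds(schema)
  cont <- feats[kinds == "continuous"]
  H <- config$layer_size
  L <- config$n_hidden_layers
  params <- with_seed(derive_seed(config$seed, "init"), {
    p <- list()
    for (f in cont) {
      dims_in <- c(1L, rep(H, L))
      dims_out <- c(rep(H, L), 1L)
      for (l in seq_len(L + 1L)) {
        p[[paste0(f, ".W", l)]] <- glorot_init(dims_in[l], dims_out[l])
        p[[paste0(f, ".b", l)]] <- numeric(dims_out[l])
      }
    }
    p[["logistic.w"]] <- as.numeric(glorot_init(length(feats), 1L))
    p[["logistic.b0"]] <- 0
    p
  })
  structure(
    list(
      feature_names = feats,
      kinds = kinds,
      cont_features = cont,
      bin_features = feats[kinds == "binary"],
      config = config,
      params = params
    ),
    class = "gamnn_model"
  )
}

#' @export
print.gamnn_model <- function(x, ...) {
  cat(sprintf(
    "<gamnn_model> %d features (%d subnetworks + %d direct binary), %d hidden layer(s) x %d %s\n",
    length(x$feature_names), length(x$cont_features), length(x$bin_features),
    x$config$n_hidden_layers, x$config$layer_size, x$config$hidden_activation
  ))
  invisible(x)
}

# Coerce a feature vector / matrix / dataset into a schema-ordered matrix.
as_input_matrix <- function(model, x) {
  F_n <- length(model$feature_names)
  if (inherits(x, "gamnn_dataset")) {
    X <- x$values
  } else if (is.matrix(x) || is.data.frame(x)) {
    X <- as.matrix(x)
  } else {
    X <- matrix(as.numeric(x), nrow = 1L)
    if (!is.null(names(x))) colnames(X) <- names(x)
  }
  if (!is.null(colnames(X))) {
    missing_f <- setdiff(model$feature_names, colnames(X))
    if (length(missing_f) > 0L) {
      abort(sprintf("Input lacks feature(s): %s.", paste(missing_f, collapse = ", ")))
    }
    X <- X[, model$feature_names, drop = FALSE]
  } else if (ncol(X) != F_n) {
    abort(sprintf("Input has %d columns; model expects %d.", ncol(X), F_n))
  }
  if (anyNA(X)) abort("Model inputs must be complete; run preprocessing first.")
  storage.mode(X) <- "double"
  X
}

# Full forward pass. With training = TRUE, applies inverted dropout to
# hidden activations (masks drawn from the current RNG stream) and returns
# the caches backprop needs. `units` is the n x F matrix of concatenated
# bottleneck outputs / raw binary inputs.
forward_pass <- function(model, X, training = FALSE) {
  cfg <- model$config
  act <- activation_fun(cfg$hidden_activation)
  L <- cfg$n_hidden_layers
  p <- model$params
  n <- nrow(X)
  feats <- model$feature_names
  U <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  caches <- if (training) vector("list", length(model$cont_features)) else NULL
  if (training) names(caches) <- model$cont_features
  keep <- 1 - cfg$dropout_p
  for (f in model$cont_features) {
    A <- X[, f, drop = FALSE]
    As <- vector("list", L + 1L)  # layer inputs
    Zs <- vector("list", L)
    Hs <- vector("list", L)       # post-activation (pre-dropout)
    masks <- vector("list", L)
    for (l in seq_len(L)) {
      As[[l]] <- A
      Z <- A %*% p[[paste0(f, ".W", l)]]
      Z <- sweep(Z, 2L, p[[paste0(f, ".b", l)]], "+")
      A <- act(Z)
      Zs[[l]] <- Z
      Hs[[l]] <- A
      if (training && cfg$dropout_p > 0) {
        m <- matrix(runif(length(A)) < keep, nrow(A), ncol(A))
        A <- A * m / keep
        masks[[l]] <- m
      }
    }
    As[[L + 1L]] <- A
    Zb <- A %*% p[[paste0(f, ".W", L + 1L)]] + p[[paste0(f, ".b", L + 1L)]]
    Tb <- tanh(Zb)
    U[, f] <- Tb
    if (training) {
      caches[[f]] <- list(As = As, Zs = Zs, Hs = Hs, masks = masks, Tb = Tb)
    }
  }
  bin <- model$bin_features
  if (length(bin) > 0L) U[, bin] <- X[, bin, drop = FALSE]
  logit <- as.numeric(U %*% p[["logistic.w"]] + p[["logistic.b0"]])
  list(logit = logit, units = U, caches = caches)
}

#' Compute the model logit
#'
#' The logit is the intercept plus the sum over features of their additive
#' contributions: for continuous features the subnetwork's tanh output
#' times its logistic weight, for binary features the raw input times its
#' logistic weight. Dropout is inactive at inference.
#'
#' @param model A `gamnn_model`.
#' @param x A feature vector (named or schema-ordered), matrix, data frame
#'   or `gamnn_dataset` of preprocessed inputs.
#' @return Numeric vector of logits, one per row.
#' @export
forward_logit <- function(model, x) {
  X <- as_input_matrix(model, x)
  forward_pass(model, X, training = FALSE)$logit
}

#' Predict outcome probabilities
#'
#' Applies the logistic link to [forward_logit()]; strictly monotone in
#' the logit.
#'
#' @inheritParams forward_logit
#' @return Probabilities in (0, 1).
#' @export
predict_proba <- function(model, x) {
  sigmoid(forward_logit(model, x))
}

#' @export
predict.gamnn_model <- function(object, newdata,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  z <- forward_logit(object, newdata)
  if (type == "response") sigmoid(z) else z
}

#' Additive contribution of one feature
#'
#' For a continuous feature, the subnetwork's bounded tanh output times its
#' logistic weight — hence always inside `(-|w_j|, |w_j|)`. For a binary
#' feature, the input value times its logistic weight. The intercept is
#' never allocated to any feature.
#'
#' @param model A `gamnn_model`.
#' @param x A preprocessed feature vector (or matrix of rows).
#' @param feature Feature name.
#' @return Numeric contribution(s) on the logit scale.
#' @export
feature_contribution <- function(model, x, feature) {
  if (!feature %in% model$feature_names) {
    abort(sprintf("Unknown feature '%s'.", feature))
  }
  X <- as_input_matrix(model, x)
  fp <- forward_pass(model, X, training = FALSE)
  w <- model$params[["logistic.w"]]
  j <- match(feature, model$feature_names)
  unname(fp$units[, j] * w[j])
}

#' Per-sample, per-feature contribution table
#'
#' Decomposes every sample's logit into additive per-feature contributions
#' plus the shared intercept; the decomposition is exact (the intercept
#' plus the row sum of contributions reconstructs the forward logit).
#'
#' @param model A `gamnn_model`.
#' @param ds Preprocessed `gamnn_dataset` (or matrix).
#' @return A `gamnn_contributions` object: a long tibble with columns
#'   `sample`, `feature`, `contribution`, carrying the intercept, the
#'   per-sample logits and the feature kinds as attributes.
#' @export
contributions_table <- function(model, ds) {
  X <- as_input_matrix(model, ds)
  fp <- forward_pass(model, X, training = FALSE)
  w <- model$params[["logistic.w"]]
  C <- sweep(fp$units, 2L, w, "*")
  out <- tibble::tibble(
    sample = rep(seq_len(nrow(C)), times = ncol(C)),
    feature = rep(model$feature_names, each = nrow(C)),
    contribution = as.numeric(C)
  )
  structure(
    out,
    intercept = model$params[["logistic.b0"]],
    logit = fp$logit,
    kinds = model$kinds,
    class = c("gamnn_contributions", class(out))
  )
}

#' Logistic-layer weights of a GAM-NN
#'
#' @param x A `gamnn_model`.
#' @param ... Unused.
#' @return Tibble with `feature`, `kind` and the logistic `weight` (the
#'   contribution multiplier); the intercept is in [glance.gamnn_model()].
#' @export
tidy.gamnn_model <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_names,
    kind = unname(x$kinds[x$feature_names]),
    weight = x$params[["logistic.w"]]
  )
}

#' One-row model summary
#'
#' @param x A `gamnn_model`.
#' @param ... Unused.
#' @return One-row tibble with architecture fields and the intercept.
#' @export
glance.gamnn_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_subnetworks = length(x$cont_features),
    n_hidden_layers = x$config$n_hidden_layers,
    layer_size = x$config$layer_size,
    hidden_activation = x$config$hidden_activation,
    intercept = x$params[["logistic.b0"]]
  )
}

#' Save a GAM-NN to a JSON archive
#'
#' Writes config, feature metadata and all weight arrays at full numeric
#' precision, so save -> load -> predict reproduces predictions on the
#' same platform.
#'
#' @param model A `gamnn_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_gamnn <- function(model, path) {
  obj <- list(
    format = "gamnn-model-v1",
    config = unclass(model$config),
    feature_names = model$feature_names,
    kinds = as.list(model$kinds),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a GAM-NN saved with [save_gamnn()]
#'
#' @param path Archive path.
#' @return A `gamnn_model`.
#' @export
load_gamnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "gamnn-model-v1")) {
    abort("Not a recognized gamnn model archive.")
  }
  cfg <- do.call(gamnn_config, obj$config)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2L) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else {
      as.numeric(p$data)
    }
  })
  kinds <- unlist(obj$kinds)
  feats <- obj$feature_names
  structure(
    list(
      feature_names = feats,
      kinds = kinds[feats],
      cont_features = feats[kinds[feats] == "continuous"],
      bin_features = feats[kinds[feats] == "binary"],
      config = cfg,
      params = params
    ),
    class = "gamnn_model"
  )
}
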