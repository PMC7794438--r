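#' Deterministic train/test split
#'
#' Randomly partitions `n` rows into training and testing index sets. The
#' training partition has `round(train_fraction * n)` rows, which
#' reproduces the canonical 80/20 split of a 59,985-record cohort into
#' 47,988 training and 11,997 testing records.
#'
#' @param n Number of rows (>= 2).
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed; the same `(n, train_fraction, seed)` always
#'   yields the same split.
#'
#' @return A list with `train_idx`, `test_idx` and `seed`, of class
#'   `gamnn_split`.
#' @export
train_test_split <- function(n, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(n) || n < 2) abort("Need n >= 2 to form both partitions.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  n <- as.integer(n)
  n_train <- as.integer(round(train_fraction * n))
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  structure(
    list(
      train_idx = sort(perm[seq_len(n_train)]),
      test_idx = sort(perm[(n_train + 1L):n]),
      seed = as.integer(seed)
    ),
    class = "gamnn_split"
  )
}

#' Training-set imputation statistics
#'
#' Computes the per-feature mean of observed (non-missing) training values
#' for every feature whose imputation policy is `train_mean`. These means
#' are the only data-derived imputation parameters and must come from
#' training rows alone.
#'
#' @param train_ds Training `gamnn_dataset` (may contain missing values).
#' @param schema The [feature_schema()].
#' @return Named numeric vector of training means.
#' @export
impute_stats <- function(train_ds, schema) {
  feats <- schema_feature_names(schema)
  mean_feats <- feats[vapply(schema$specs, function(s) s$impute_policy, character(1)) == "train_mean"]
  out <- vapply(mean_feats, function(f) {
    v <- train_ds$values[, f]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      abort(sprintf(
        "Feature '%s' is entirely missing in the training data; its mean is undefined.", f
      ))
    }
    mean(v)
  }, double(1))
  setNames(out, mean_feats)
}

#' Impute missing values according to the schema
#'
#' Fills every missing cell: constant-policy features with their declared
#' constant (e.g. ASA score with the modal class 3), zero-policy features
#' with 0 (infusions never administered), and train-mean-policy features
#' with the training-set mean of observed values — never the mean of the
#' dataset being imputed.
#'
#' @param ds Dataset to impute (train or test).
#' @param schema The [feature_schema()].
#' @param train_stats Named means from [impute_stats()], computed on
#'   training rows.
#' @return The imputed `gamnn_dataset` with no missing values.
#' @export
impute <- function(ds, schema, train_stats) {
  values <- ds$values
  for (s in schema$specs) {
    miss <- is.na(values[, s$name])
    if (!any(miss)) next
    fill <- switch(s$impute_policy,
      constant = s$constant_value,
      zero = 0,
      train_mean = {
        if (!s$name %in% names(train_stats)) {
          abort(sprintf("train_stats has no mean for feature '%s'.", s$name))
        }
        train_stats[[s$name]]
      }
    )
    values[miss, s$name] <- fill
  }
  new_dataset(values, ds$labels, ds$feature_names)
}

#' Clip values to clinical plausibility bounds
#'
#' Values above a feature's `clip_max` (a clinically normal maximum) are
#' replaced by the bound, and symmetrically for `clip_min`. Features
#' without bounds are untouched. Bounds are schema constants, never
#' data-derived, and apply identically to both partitions.
#'
#' @param ds Imputed `gamnn_dataset`.
#' @param schema The [feature_schema()].
#' @return The clipped `gamnn_dataset`.
#' @export
clip_values <- function(ds, schema) {
  values <- ds$values
  for (s in schema$specs) {
    if (!is.null(s$clip_max)) {
      v <- values[, s$name]
      values[v > s$clip_max & !is.na(v), s$name] <- s$clip_max
    }
    if (!is.null(s$clip_min)) {
      v <- values[, s$name]
      values[v < s$clip_min & !is.na(v), s$name] <- s$clip_min
    }
  }
  new_dataset(values, ds$labels, ds$feature_names)
}

#' Fit standardization statistics on training data
#'
#' Computes per-feature mean and population standard deviation
#' (divide-by-n) over the training rows, for continuous features only by
#' default: binary 0/1 flags are left on their natural scale so that a
#' flag's contribution is its raw value times its logistic weight. Set
#' `standardize_binary = TRUE` for the literal all-features reading.
#'
#' @param train_ds Complete (imputed, clipped) training dataset.
#' @param schema The [feature_schema()].
#' @param standardize_binary Also standardize binary features?
#' @return A `gamnn_std_stats` object (tibble of feature/mean/sd with
#'   `sd = NA` for pass-through features).
#' @export
standardize_fit <- function(train_ds, schema, standardize_binary = FALSE) {
  if (anyNA(train_ds$values)) {
    abort("Standardization requires complete data; impute first.")
  }
  kinds <- schema_kinds(schema)
  feats <- schema_feature_names(schema)
  do_std <- kinds == "continuous" | standardize_binary
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  stats <- tibble::tibble(
    feature = feats,
    mean = NA_real_,
    sd = NA_real_
  )
  for (f in feats[do_std]) {
    v <- train_ds$values[, f]
    s <- pop_sd(v)
    if (s == 0) {
      abort(sprintf("Feature '%s' is constant in the training data; cannot standardize.", f))
    }
    stats$mean[stats$feature == f] <- mean(v)
    stats$sd[stats$feature == f] <- s
  }
  structure(
    list(stats = stats, fitted_on = "train"),
    class = "gamnn_std_stats"
  )
}

#' @export
print.gamnn_std_stats <- function(x, ...) {
  cat(sprintf(
    "<gamnn_std_stats> %d features (%d standardized), fitted on %s\n",
    nrow(x$stats), sum(!is.na(x$stats$sd)), x$fitted_on
  ))
  invisible(x)
}

#' Apply training-fitted standardization
#'
#' Rescales each standardized feature as `(x - mean) / sd` using the
#' training statistics, whichever partition `ds` comes from. Applying the
#' stats back to the training set yields per-feature mean 0 and sd 1.
#'
#' @param ds Complete dataset (train or test).
#' @param stats A `gamnn_std_stats` from [standardize_fit()].
#' @return The standardized `gamnn_dataset`.
#' @export
standardize_apply <- function(ds, stats) {
  unknown <- setdiff(ds$feature_names, stats$stats$feature)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "Standardization stats have no entry for feature(s): %s.",
      paste(unknown, collapse = ", ")
    ))
  }
  values <- ds$values
  st <- stats$stats[!is.na(stats$stats$sd), ]
  for (i in seq_len(nrow(st))) {
    f <- st$feature[i]
    if (f %in% ds$feature_names) {
      values[, f] <- (values[, f] - st$mean[i]) / st$sd[i]
    }
  }
  new_dataset(values, ds$labels, ds$feature_names)
}

#' Fit the full preprocessing pipeline on training data
#'
#' Convenience wrapper running the fixed pipeline impute -> clip ->
#' standardize: computes imputation means and standardization statistics
#' from training rows only.
#'
#' @param train_ds Raw training dataset.
#' @param schema The [feature_schema()].
#' @param standardize_binary Passed to [standardize_fit()].
#' @return A `gamnn_preprocessor` holding both statistic sets.
#' @export
preprocess_fit <- function(train_ds, schema, standardize_binary = FALSE) {
  imp <- impute_stats(train_ds, schema)
  prepped <- clip_values(impute(train_ds, schema, imp), schema)
  std <- standardize_fit(prepped, schema, standardize_binary = standardize_binary)
  structure(
    list(schema = schema, impute_means = imp, std_stats = std),
    class = "gamnn_preprocessor"
  )
}

#' Apply a fitted preprocessing pipeline
#'
#' @param ds Raw dataset (train or test).
#' @param prep A `gamnn_preprocessor` from [preprocess_fit()].
#' @return The fully preprocessed `gamnn_dataset`.
#' @export
preprocess_apply <- function(ds, prep) {
  ds |>
    impute(prep$schema, prep$impute_means) |>
    clip_values(prep$schema) |>
    standardize_apply(prep$std_stats)
}

#' Serialize a fitted preprocessor to JSON
#'
#' Stores imputation means and standardization statistics so a trained
#' pipeline can be applied to new files (the schema travels separately).
#'
#' @param prep A `gamnn_preprocessor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preprocessor <- function(prep, path) {
  obj <- list(
    impute_means = as.list(prep$impute_means),
    std = setNames(
      lapply(seq_len(nrow(prep$std_stats$stats)), function(i) {
        row <- prep$std_stats$stats[i, ]
        if (is.na(row$sd)) list(standardized = FALSE)
        else list(standardized = TRUE, mean = row$mean, sd = row$sd)
      }),
      prep$std_stats$stats$feature
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a preprocessor written by [write_preprocessor()]
#'
#' @param path JSON path.
#' @param schema The matching [feature_schema()].
#' @return A `gamnn_preprocessor`.
#' @export
read_preprocessor <- function(path, schema) {
  obj <- jsonlite::read_json(path)
  stats <- tibble::tibble(
    feature = names(obj$std),
    mean = vapply(obj$std, function(e) if (isTRUE(e$standardized)) e$mean else NA_real_,
                  double(1), USE.NAMES = FALSE),
    sd = vapply(obj$std, function(e) if (isTRUE(e$standardized)) e$sd else NA_real_,
                double(1), USE.NAMES = FALSE)
  )
  structure(
    list(
      schema = schema,
      impute_means = unlist(obj$impute_means) %||% setNames(numeric(0), character(0)),
      std_stats = structure(list(stats = stats, fitted_on = "train"),
                            class = "gamnn_std_stats")
    ),
    class = "gamnn_preprocessor"
  )
}

#' Serialize standardization statistics to JSON
#'
#' @param stats A `gamnn_std_stats`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_standardization <- function(stats, path) {
  entries <- stats$stats
  obj <- setNames(
    lapply(seq_len(nrow(entries)), function(i) {
      if (is.na(entries$sd[i])) list(standardized = FALSE)
      else list(standardized = TRUE, mean = entries$mean[i], sd = entries$sd[i])
    }),
    entries$feature
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read standardization statistics from JSON
#'
#' @param path Path written by [write_standardization()].
#' @return A `gamnn_std_stats`.
#' @export
read_standardization <- function(path) {
  obj <- jsonlite::read_json(path)
  stats <- tibble::tibble(
    feature = names(obj),
    mean = vapply(obj, function(e) if (isTRUE(e$standardized)) e$mean else NA_real_,
                  double(1), USE.NAMES = FALSE),
    sd = vapply(obj, function(e) if (isTRUE(e$standardized)) e$sd else NA_real_,
                double(1), USE.NAMES = FALSE)
  )
  structure(list(stats = stats, fitted_on = "train"), class = "gamnn_std_stats")
}
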