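#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive is scored above a randomly chosen negative, with ties counted
#' one half. Invariant under any strictly monotone transform of the
#' scores.
#'
#' @param labels 0/1 outcome vector.
#' @param scores Numeric scores (probabilities or logits).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- assert_binary_labels(labels)
  if (length(labels) != length(scores)) abort("labels and scores must align.")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUC is undefined when only one class is present.")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision
#'
#' Area under the precision-recall curve via step-wise summation over the
#' score-descending ranking (no interpolation):
#' `AP = sum_k (R_k - R_{k-1}) * P_k`, which reduces to the mean of the
#' precision at each positive's rank. Ties are broken by stable original
#' order after the descending sort.
#'
#' @inheritParams roc_auc
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(labels, scores) {
  labels <- assert_binary_labels(labels)
  if (length(labels) != length(scores)) abort("labels and scores must align.")
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) abort("Average precision is undefined with no positives.")
  ord <- order(-scores)  # stable: ties keep original order
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / n_pos
}

#' Percentile bootstrap confidence interval for a ranking metric
#'
#' Draws `n_bootstrap` paired resamples with replacement of
#' (label, score); resamples containing a single class are discarded and
#' redrawn (up to 10x `n_bootstrap` total attempts). Returns the empirical
#' 2.5th and 97.5th percentiles of the metric across resamples.
#'
#' @param metric `roc_auc`, `average_precision`, or a function with the
#'   same signature.
#' @param labels 0/1 outcome vector.
#' @param scores Numeric scores.
#' @param n_bootstrap Number of resamples (default 1000).
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric, labels, scores, n_bootstrap = 1000L,
                         seed = 1L, level = 0.95) {
  metric_fn <- if (is.function(metric)) metric else match.fun(metric)
  point <- metric_fn(labels, scores)  # errors early if undefined
  stopifnot(is.finite(point))
  n <- length(labels)
  vals <- numeric(n_bootstrap)
  with_seed(derive_seed(seed, "bootstrap"), {
    got <- 0L
    attempts <- 0L
    max_attempts <- 10L * n_bootstrap
    while (got < n_bootstrap) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort("Too many single-class bootstrap resamples; data are too degenerate.")
      }
      idx <- sample.int(n, n, replace = TRUE)
      lb <- labels[idx]
      if (sum(lb == 1) == 0L || sum(lb == 0) == 0L) next
      val <- tryCatch(metric_fn(lb, scores[idx]), error = function(e) NA_real_)
      if (is.na(val)) next
      got <- got + 1L
      vals[got] <- val
    }
  })
  alpha <- (1 - level) / 2
  unname(quantile(vals, c(alpha, 1 - alpha)))
}

#' Evaluate scores against labels
#'
#' Assembles ROC AUC and average precision with 95% percentile bootstrap
#' confidence intervals (1000 resamples by default) into one report.
#'
#' @param scores Predicted scores.
#' @param labels 0/1 outcomes.
#' @param n_bootstrap Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return A `gamnn_eval` report with `auc`, `auc_ci`, `ap`, `ap_ci`,
#'   `n_bootstrap`, `seed`.
#' @export
evaluate_scores <- function(scores, labels, n_bootstrap = 1000L, seed = 1L) {
  structure(
    list(
      auc = roc_auc(labels, scores),
      auc_ci = bootstrap_ci(roc_auc, labels, scores, n_bootstrap, seed),
      ap = average_precision(labels, scores),
      ap_ci = bootstrap_ci(average_precision, labels, scores, n_bootstrap,
                           derive_seed(seed, "ap")),
      n_bootstrap = as.integer(n_bootstrap),
      seed = as.integer(seed)
    ),
    class = "gamnn_eval"
  )
}

#' @export
print.gamnn_eval <- function(x, ...) {
  cat(sprintf(
    "<gamnn_eval> AUC %.3f (%.3f-%.3f), AP %.3f (%.3f-%.3f), %d bootstrap resamples\n",
    x$auc, x$auc_ci[1], x$auc_ci[2], x$ap, x$ap_ci[1], x$ap_ci[2], x$n_bootstrap
  ))
  invisible(x)
}

#' Evaluation report as a tibble
#'
#' @param x A `gamnn_eval`.
#' @param ... Unused.
#' @return Tibble with one row per metric and its interval.
#' @export
tidy.gamnn_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("auc", "average_precision"),
    estimate = c(x$auc, x$ap),
    conf.low = c(x$auc_ci[1], x$ap_ci[1]),
    conf.high = c(x$auc_ci[2], x$ap_ci[2])
  )
}

#' Write an evaluation report as JSON
#'
#' @param report A `gamnn_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(
      auc = report$auc, auc_ci = report$auc_ci,
      ap = report$ap, ap_ci = report$ap_ci,
      n_bootstrap = report$n_bootstrap, seed = report$seed
    ),
    path, auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}

#' Read an evaluation report written by [write_eval_report()]
#'
#' @param path JSON path.
#' @return A `gamnn_eval`.
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      auc = obj$auc, auc_ci = as.numeric(obj$auc_ci),
      ap = obj$ap, ap_ci = as.numeric(obj$ap_ci),
      n_bootstrap = as.integer(obj$n_bootstrap), seed = as.integer(obj$seed)
    ),
    class = "gamnn_eval"
  )
}

# Weak ridge strength for the LR baseline: effectively maximum likelihood
# while keeping the fit defined under separation or degenerate columns.
LR_RIDGE_LAMBDA <- 1e-6

#' Logistic-regression baseline
#'
#' Fits a plain logistic model on exactly the same (preprocessed) features
#' the GAM-NN sees. The fit carries a very weak ridge penalty
#' (`lambda = 1e-6`, on the standardized scale the data already have) so
#' coefficients stay defined under perfect separation or constant
#' columns; at that strength it is numerically a maximum-likelihood fit.
#' Constant columns are flagged with a warning.
#'
#' @param train_ds Preprocessed training `gamnn_dataset`.
#' @param schema The [feature_schema()].
#' @return A `gamnn_lr` with per-feature `coefficients` and `intercept`.
#' @export
fit_lr_baseline <- function(train_ds, schema) {
  X <- train_ds$values
  y <- train_ds$labels
  if (length(unique(y)) < 2L) abort("Both classes are required to fit the baseline.")
  const_cols <- colnames(X)[apply(X, 2L, function(v) max(v) == min(v))]
  if (length(const_cols) > 0L) {
    warn(sprintf(
      "Constant feature column(s) %s: coefficients defined only through regularization.",
      paste(const_cols, collapse = ", ")
    ))
  }
  if (ncol(X) >= 2L) {
    # glmnet warns on very small classes; the ridge penalty already keeps
    # the fit defined there
    fit <- suppressWarnings(glmnet::glmnet(
      X, y, family = "binomial", alpha = 0, lambda = LR_RIDGE_LAMBDA,
      standardize = FALSE
    ))
    co <- as.numeric(coef(fit, s = LR_RIDGE_LAMBDA))
    intercept <- co[1]
    coefs <- setNames(co[-1], colnames(X))
  } else {
    df <- data.frame(y = y, x = X[, 1])
    fit <- suppressWarnings(glm(y ~ x, data = df, family = binomial()))
    intercept <- unname(coef(fit)[1])
    coefs <- setNames(unname(coef(fit)[2]), colnames(X)[1])
  }
  structure(
    list(
      coefficients = coefs,
      intercept = intercept,
      regularization = sprintf("ridge, lambda = %g", LR_RIDGE_LAMBDA),
      feature_names = train_ds$feature_names
    ),
    class = "gamnn_lr"
  )
}

#' @export
print.gamnn_lr <- function(x, ...) {
  cat(sprintf(
    "<gamnn_lr> logistic baseline, %d features, intercept %.4f (%s)\n",
    length(x$coefficients), x$intercept, x$regularization
  ))
  invisible(x)
}

#' LR baseline coefficients
#'
#' @param x A `gamnn_lr`.
#' @param ... Unused.
#' @return Tibble of feature/estimate pairs (standardized scale).
#' @export
tidy.gamnn_lr <- function(x, ...) {
  tibble::tibble(feature = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
predict.gamnn_lr <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "gamnn_dataset")) newdata$values else as.matrix(newdata)
  X <- X[, object$feature_names, drop = FALSE]
  z <- as.numeric(X %*% object$coefficients + object$intercept)
  if (type == "response") sigmoid(z) else z
}
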