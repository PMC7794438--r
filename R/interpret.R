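#' Logistic-regression contribution of one feature
#'
#' In the linear baseline a feature's contribution is simply its
#' (standardized) value times its learned coefficient — always exactly
#' linear, which is what the GAM-NN shape curves are contrasted against.
#'
#' @param lr A `gamnn_lr` from [fit_lr_baseline()].
#' @param x A standardized feature vector (named) or matrix of rows.
#' @param feature Feature name.
#' @return Numeric contribution(s) on the logit scale.
#' @export
lr_contribution <- function(lr, x, feature) {
  if (!feature %in% names(lr$coefficients)) {
    abort(sprintf("Unknown feature '%s'.", feature))
  }
  v <- if (is.matrix(x) || is.data.frame(x)) {
    as.matrix(x)[, feature]
  } else if (inherits(x, "gamnn_dataset")) {
    x$values[, feature]
  } else {
    if (!is.null(names(x))) x[[feature]] else abort("Vector input must be named.")
  }
  unname(lr$coefficients[[feature]] * v)
}

#' Shape curves: learned contribution versus raw feature value
#'
#' For every continuous feature, pairs each sample's raw (clinical-unit,
#' pre-standardization) value with the GAM-NN contribution and the LR
#' contribution at that sample. Plotting contribution against raw value
#' shows the learned univariate risk shape; the LR curve is linear in the
#' standardized value by construction. The more negative a contribution,
#' the less that value adds to the predicted risk.
#'
#' @param model A trained `gamnn_model`.
#' @param lr A `gamnn_lr` baseline fitted on the same features.
#' @param ds Preprocessed `gamnn_dataset` (what the models consume).
#' @param raw_ds Row-aligned raw-value twin of `ds` (post-clipping,
#'   pre-standardization, for readable axes).
#' @param features Continuous features to include (default: all).
#' @return A `gamnn_shape_curves` tibble: `feature`, `sample`,
#'   `raw_value`, `gamnn_contribution`, `lr_contribution`.
#' @export
shape_curves <- function(model, lr, ds, raw_ds, features = NULL) {
  if (nrow(ds$values) != nrow(raw_ds$values)) {
    abort("`ds` and `raw_ds` must be row-aligned (same samples, same order).")
  }
  features <- features %||% model$cont_features
  unknown <- setdiff(features, model$cont_features)
  if (length(unknown) > 0L) {
    abort(sprintf("Not continuous model feature(s): %s.", paste(unknown, collapse = ", ")))
  }
  fp <- forward_pass(model, as_input_matrix(model, ds), training = FALSE)
  w <- model$params[["logistic.w"]]
  out <- purrr::map_dfr(features, function(f) {
    j <- match(f, model$feature_names)
    tibble::tibble(
      feature = f,
      sample = seq_len(nrow(ds$values)),
      raw_value = raw_ds$values[, f],
      gamnn_contribution = fp$units[, j] * w[j],
      lr_contribution = lr_contribution(lr, ds$values, f)
    )
  })
  structure(out, class = c("gamnn_shape_curves", class(out)))
}

#' Plot shape curves
#'
#' Scatter of per-sample GAM-NN and LR contributions against the raw
#' feature value, faceted by feature — both series share the logit-scale
#' y-axis.
#'
#' @param object A `gamnn_shape_curves` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gamnn_shape_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("gamnn_contribution", "lr_contribution"),
    names_to = "model", values_to = "contribution"
  )
  long$model <- ifelse(long$model == "gamnn_contribution", "GAM-NN", "LR")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$raw_value, y = .data$contribution, colour = .data$model
  )) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(
      x = "Feature value (clinical units)",
      y = "Risk contribution (logit scale)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Export shape curves as tidy TSV
#'
#' @param curves A `gamnn_shape_curves`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_curves <- function(curves, path) {
  readr::write_tsv(tibble::as_tibble(curves), path, progress = FALSE)
  invisible(path)
}

#' Bin-average a shape curve
#'
#' Equal-count binned mean of the learned contribution along the raw
#' value axis — a light smoother used to locate interior minima/maxima of
#' a learned shape (e.g. a U-shaped blood-pressure effect) without
#' fitting a model to the scatter.
#'
#' @param curves A `gamnn_shape_curves`.
#' @param feature Feature to smooth.
#' @param n_bins Number of equal-count bins.
#' @return Tibble with `bin_center` and `mean_contribution`.
#' @export
bin_shape_curve <- function(curves, feature, n_bins = 20L) {
  d <- curves[curves$feature == feature, ]
  if (nrow(d) == 0L) abort(sprintf("No curve for feature '%s'.", feature))
  qs <- quantile(d$raw_value, probs = seq(0, 1, length.out = n_bins + 1L))
  bins <- cut(d$raw_value, breaks = unique(qs), include.lowest = TRUE)
  d |>
    dplyr::mutate(.bin = bins) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(
      bin_center = mean(.data$raw_value),
      mean_contribution = mean(.data$gamnn_contribution),
      .groups = "drop"
    ) |>
    dplyr::select("bin_center", "mean_contribution")
}

#' Rank features by mean contribution
#'
#' Orders features by their mean contribution across samples, descending —
#' the selection rule behind "top contributing features" displays.
#' Binary features can be excluded (their two-valued scatter is rarely
#' informative to plot).
#'
#' @param table A `gamnn_contributions` from [contributions_table()].
#' @param continuous_only Drop binary features before ranking?
#' @return Tibble with `feature`, `kind`, `mean_contribution`, sorted
#'   descending.
#' @export
rank_features_by_mean_contribution <- function(table, continuous_only = FALSE) {
  if (nrow(table) == 0L) abort("Contribution table is empty.")
  kinds <- attr(table, "kinds")
  out <- tibble::as_tibble(table) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_contribution = mean(.data$contribution), .groups = "drop") |>
    dplyr::mutate(kind = unname(kinds[.data$feature])) |>
    dplyr::arrange(dplyr::desc(.data$mean_contribution)) |>
    dplyr::select("feature", "kind", "mean_contribution")
  if (continuous_only) out <- dplyr::filter(out, .data$kind == "continuous")
  out
}

#' Per-patient top-k contribution report
#'
#' Ranks one patient's features by their additive contribution to the
#' predicted logit, descending, and keeps the top `k`. Values are shown in
#' raw clinical units (pre-standardization) while contributions are on the
#' logit scale; the intercept is reported separately, never allocated to a
#' feature.
#'
#' @param model A trained `gamnn_model`.
#' @param x_raw Named raw feature vector (post-clipping clinical units).
#' @param x_prep Its preprocessed twin (what the model consumes).
#' @param k Number of features to report (default 10).
#' @return A `gamnn_patient_report` tibble: `feature`, `value`,
#'   `contribution`, with `intercept` and `logit` attributes.
#' @export
patient_report <- function(model, x_raw, x_prep, k = 10L) {
  if (k < 1L) abort("`k` must be at least 1.")
  Xp <- as_input_matrix(model, x_prep)
  if (nrow(Xp) != 1L) abort("patient_report expects a single sample.")
  fp <- forward_pass(model, Xp, training = FALSE)
  w <- model$params[["logistic.w"]]
  contrib <- as.numeric(fp$units[1, ] * w)
  raw <- if (is.null(names(x_raw))) {
    if (length(x_raw) != length(model$feature_names)) {
      abort("Unnamed `x_raw` must be schema-ordered and full length.")
    }
    as.numeric(x_raw)
  } else {
    as.numeric(x_raw[model$feature_names])
  }
  out <- tibble::tibble(
    feature = model$feature_names,
    value = raw,
    contribution = contrib
  ) |>
    dplyr::arrange(dplyr::desc(.data$contribution)) |>
    head(min(k, length(model$feature_names)))
  structure(
    out,
    intercept = model$params[["logistic.b0"]],
    logit = fp$logit[1],
    class = c("gamnn_patient_report", class(out))
  )
}

#' Export a patient report as TSV
#'
#' @param report A `gamnn_patient_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_report <- function(report, path) {
  readr::write_tsv(tibble::as_tibble(report), path, progress = FALSE)
  invisible(path)
}

#' Plot a patient report
#'
#' Horizontal bars of the top-k per-feature contributions for one
#' patient, labelled with raw clinical values.
#'
#' @param object A `gamnn_patient_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gamnn_patient_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$label <- sprintf("%s = %g", d$feature, d$value)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$contribution,
    y = stats::reorder(.data$label, .data$contribution)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Risk contribution (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}
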