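#' Declare a single input feature
#'
#' A feature specification records everything preprocessing and the model
#' need to know about one input column: whether it is continuous (gets its
#' own subnetwork) or binary (direct connection to the logistic layer), how
#' missing values are imputed, and optional clinical clipping bounds.
#'
#' @param name Column name in the data file.
#' @param kind `"continuous"` or `"binary"`.
#' @param impute_policy One of `"constant"`, `"zero"`, `"train_mean"`.
#'   Defaults to `"train_mean"` for continuous features and `"zero"` for
#'   binary features (binary flags are absent-means-no indicators, e.g. a
#'   drug that was never infused).
#' @param constant_value Fill value, required when `impute_policy =
#'   "constant"` (e.g. ASA score missing values filled with the modal
#'   class, ASA 3).
#' @param clip_min,clip_max Optional clinical plausibility bounds; values
#'   outside are clipped to the bound after imputation.
#'
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(name,
                         kind = c("continuous", "binary"),
                         impute_policy = NULL,
                         constant_value = NULL,
                         clip_min = NULL,
                         clip_max = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  kind <- match.arg(kind)
  if (is.null(impute_policy)) {
    impute_policy <- if (kind == "continuous") "train_mean" else "zero"
  }
  if (!impute_policy %in% c("constant", "zero", "train_mean")) {
    abort(sprintf(
      "Unknown impute_policy '%s' for feature '%s' (use constant, zero or train_mean).",
      impute_policy, name
    ))
  }
  if (impute_policy == "constant") {
    if (is.null(constant_value)) {
      abort(sprintf(
        "Feature '%s' uses impute_policy = 'constant' but has no constant_value.",
        name
      ))
    }
    assert_scalar_number(constant_value, "constant_value")
  }
  if (!is.null(clip_min)) assert_scalar_number(clip_min, "clip_min")
  if (!is.null(clip_max)) assert_scalar_number(clip_max, "clip_max")
  if (!is.null(clip_min) && !is.null(clip_max) && clip_min >= clip_max) {
    abort(sprintf("Feature '%s': clip_min must be < clip_max.", name))
  }
  structure(
    list(
      name = name, kind = kind, impute_policy = impute_policy,
      constant_value = constant_value, clip_min = clip_min, clip_max = clip_max
    ),
    class = "feature_spec"
  )
}

#' Assemble a feature schema
#'
#' The schema is an ordered list of [feature_spec()]s plus the name of the
#' binary outcome column. Its order defines column order everywhere
#' downstream (datasets, model weights, contribution tables).
#'
#' @param specs List of [feature_spec()] objects.
#' @param outcome Name of the 0/1 outcome column.
#'
#' @return A `feature_schema` object.
#' @export
feature_schema <- function(specs, outcome) {
  if (length(specs) == 0L) abort("A schema needs at least one feature.")
  if (!all(vapply(specs, inherits, logical(1), "feature_spec"))) {
    abort("`specs` must be a list of feature_spec objects.")
  }
  nms <- vapply(specs, function(s) s$name, character(1))
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate feature name(s): %s.", paste(unique(dup), collapse = ", ")))
  }
  if (!is.character(outcome) || length(outcome) != 1L || !nzchar(outcome)) {
    abort("`outcome` must be a non-empty string.")
  }
  if (outcome %in% nms) {
    abort(sprintf("Outcome column '%s' must not also be a feature.", outcome))
  }
  structure(
    list(specs = specs, outcome_name = outcome),
    class = "feature_schema"
  )
}

schema_feature_names <- function(schema) {
  vapply(schema$specs, function(s) s$name, character(1))
}

schema_kinds <- function(schema) {
  setNames(vapply(schema$specs, function(s) s$kind, character(1)),
           schema_feature_names(schema))
}

schema_spec <- function(schema, name) {
  i <- match(name, schema_feature_names(schema))
  if (is.na(i)) abort(sprintf("Unknown feature '%s'.", name))
  schema$specs[[i]]
}

#' @export
print.feature_schema <- function(x, ...) {
  kinds <- schema_kinds(x)
  cat(sprintf(
    "<feature_schema> %d features (%d continuous, %d binary), outcome '%s'\n",
    length(kinds), sum(kinds == "continuous"), sum(kinds == "binary"),
    x$outcome_name
  ))
  invisible(x)
}

#' Summarize a schema as a tibble
#'
#' @param x A `feature_schema`.
#' @param ... Unused.
#' @return A tibble with one row per feature.
#' @export
tidy.feature_schema <- function(x, ...) {
  tibble::tibble(
    feature = schema_feature_names(x),
    kind = unname(schema_kinds(x)),
    impute_policy = vapply(x$specs, function(s) s$impute_policy, character(1)),
    constant_value = vapply(x$specs, function(s) s$constant_value %||% NA_real_, double(1)),
    clip_min = vapply(x$specs, function(s) s$clip_min %||% NA_real_, double(1)),
    clip_max = vapply(x$specs, function(s) s$clip_max %||% NA_real_, double(1))
  )
}

#' Read a feature schema from a YAML or JSON config
#'
#' The document must contain a `features` list (each entry with `name`,
#' `kind` and optional `impute_policy`, `constant_value`, `clip_min`,
#' `clip_max`) and an `outcome` name. Defaults follow [feature_spec()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `feature_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort(sprintf("Schema file not found: %s", path))
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$features) || is.null(doc$outcome)) {
    abort("Schema config must contain `features` and `outcome` entries.")
  }
  specs <- lapply(doc$features, function(f) {
    if (is.null(f$name) || is.null(f$kind)) {
      abort("Every schema feature needs `name` and `kind`.")
    }
    if (!f$kind %in% c("continuous", "binary")) {
      abort(sprintf("Unknown feature kind '%s' for '%s'.", f$kind, f$name))
    }
    feature_spec(
      name = f$name, kind = f$kind,
      impute_policy = f$impute_policy,
      constant_value = f$constant_value,
      clip_min = f$clip_min, clip_max = f$clip_max
    )
  })
  feature_schema(specs, outcome = doc$outcome)
}

#' Write a feature schema to YAML
#'
#' @param schema A `feature_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  doc <- list(
    features = lapply(schema$specs, function(s) {
      drop_null(list(
        name = s$name, kind = s$kind, impute_policy = s$impute_policy,
        constant_value = s$constant_value,
        clip_min = s$clip_min, clip_max = s$clip_max
      ))
    }),
    outcome = schema$outcome_name
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
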