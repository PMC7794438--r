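#' Construct a dataset
#'
#' The dataset is the single currency passed between pipeline stages: a
#' numeric feature matrix in schema column order plus a 0/1 label vector.
#' Missing values are allowed before imputation only.
#'
#' @param values Numeric matrix, one column per feature.
#' @param labels Integer vector of 0/1 outcomes, one per row.
#' @param feature_names Column names in schema order.
#'
#' @return A `gamnn_dataset` object.
#' @export
new_dataset <- function(values, labels, feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) abort("Feature names are required.")
  if (ncol(values) != length(feature_names)) {
    abort("Column count must match the number of feature names.")
  }
  labels <- assert_binary_labels(labels)
  if (length(labels) != nrow(values)) {
    abort("Label length must equal the number of rows.")
  }
  colnames(values) <- feature_names
  structure(
    list(values = values, labels = labels, feature_names = feature_names),
    class = "gamnn_dataset"
  )
}

#' @export
print.gamnn_dataset <- function(x, ...) {
  cat(sprintf(
    "<gamnn_dataset> %d samples x %d features, %d positive (%.2f%%)%s\n",
    nrow(x$values), ncol(x$values), sum(x$labels),
    if (nrow(x$values) > 0) 100 * mean(x$labels) else 0,
    if (anyNA(x$values)) ", contains missing values" else ""
  ))
  invisible(x)
}

#' Convert a dataset to a tibble
#'
#' @param x A `gamnn_dataset`.
#' @param ... Unused.
#' @return A tibble with the feature columns plus a `.label` column.
#' @export
as_tibble.gamnn_dataset <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$values))
  out$.label <- x$labels
  out
}

#' @export
dim.gamnn_dataset <- function(x) dim(x$values)

subset_dataset <- function(ds, rows) {
  new_dataset(ds$values[rows, , drop = FALSE], ds$labels[rows], ds$feature_names)
}

#' Read a dataset from CSV against a schema
#'
#' Reads a comma-delimited UTF-8 file with a header row, checks that every
#' schema feature and the outcome column are present, reorders columns into
#' schema order, parses empty cells as missing, and validates labels
#' (strictly 0/1) and binary features (0/1/missing only).
#'
#' @param path CSV file path.
#' @param schema A [feature_schema()].
#' @return A `gamnn_dataset`.
#' @export
read_dataset <- function(path, schema) {
  if (!file.exists(path)) abort(sprintf("Data file not found: %s", path))
  feats <- schema_feature_names(schema)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  needed <- c(feats, schema$outcome_name)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "Input file is missing required column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  parse_num <- function(chr, col) {
    chr[chr == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(chr))
    bad <- which(is.na(out) & !is.na(chr))
    if (length(bad) > 0L) {
      abort(sprintf(
        "Non-numeric value '%s' in column '%s', row %d.",
        chr[bad[1]], col, bad[1]
      ))
    }
    out
  }
  values <- vapply(
    feats, function(f) parse_num(raw[[f]], f),
    numeric(nrow(raw))
  )
  if (nrow(raw) == 1L) values <- matrix(values, nrow = 1L, dimnames = list(NULL, feats))
  if (nrow(raw) == 0L) values <- matrix(numeric(0), nrow = 0L, ncol = length(feats),
                                        dimnames = list(NULL, feats))
  labels_raw <- parse_num(raw[[schema$outcome_name]], schema$outcome_name)
  labels <- assert_binary_labels(labels_raw)
  kinds <- schema_kinds(schema)
  for (f in feats[kinds == "binary"]) {
    v <- values[, f]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad) > 0L) {
      abort(sprintf(
        "Binary feature '%s' has non-0/1 value %s at row %d.",
        f, format(v[bad[1]]), bad[1]
      ))
    }
  }
  new_dataset(values, labels, feats)
}

#' Write a dataset to CSV
#'
#' Values are serialized at full double precision (17 significant digits)
#' so that a read/write round trip reproduces them exactly; missing values
#' become empty cells.
#'
#' @param ds A `gamnn_dataset`.
#' @param path Output path.
#' @param outcome_name Name for the label column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, outcome_name = ".label") {
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else sprintf("%.17g", v)
    }, character(1))
    out
  }
  cols <- lapply(seq_along(ds$feature_names), function(j) fmt(ds$values[, j]))
  names(cols) <- ds$feature_names
  cols[[outcome_name]] <- as.character(ds$labels)
  df <- tibble::as_tibble(cols)
  tryCatch(
    readr::write_csv(df, path, na = "", progress = FALSE),
    error = function(e) abort(sprintf("Cannot write dataset to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}
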