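#' @importFrom rlang abort warn %||% .data
#' @importFrom stats plogis qlogis quantile rbinom rnorm runif sd uniroot
#'   predict coef glm binomial setNames cor
#' @importFrom utils head modifyList
NULL

# Numerically safe sigmoid on the logit scale.
sigmoid <- function(z) plogis(z)

# Clamp probabilities away from {0,1} before taking logs in the loss.
PROB_EPS <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never clobber the
# session's seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562L) + 1L
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

assert_binary_labels <- function(labels) {
  bad <- !(labels %in% c(0, 1)) | is.na(labels)
  if (any(bad)) {
    abort(sprintf(
      "Labels must be 0 or 1; found invalid value(s) at row(s) %s.",
      paste(head(which(bad), 5L), collapse = ", ")
    ))
  }
  invisible(as.integer(labels))
}
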