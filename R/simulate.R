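#' Declare a continuous synthetic feature effect
#'
#' Each continuous feature is drawn from a truncated normal in clinical
#' units and enters the outcome logit through a known univariate shape
#' function evaluated on the feature's standardized scale
#' `z = (x - mean) / sd`:
#' \describe{
#'   \item{linear}{`scale * z`}
#'   \item{u_shaped}{`scale * ((z - vertex)^2 - (1 + vertex^2))` — a
#'     centered quadratic with an interior minimum at `z = vertex`}
#'   \item{threshold}{`scale * (1[z > threshold_at] - P(Z > threshold_at))`,
#'     a centered step}
#'   \item{flat}{identically 0 (a null feature, for false-positive-shape
#'     checks)}
#' }
#'
#' @param name Feature name.
#' @param shape Shape-function tag.
#' @param scale Effect scale on the logit.
#' @param mean,sd Location/scale of the generating normal (clinical units).
#' @param lower,upper Truncation bounds of the generating distribution.
#' @param vertex U-shape vertex on the standardized scale.
#' @param threshold_at Step location on the standardized scale.
#' @param integer_valued Round drawn values to integers (ordinal scores).
#' @param missing_rate Fraction of cells blanked after label generation.
#' @param impute_policy,constant_value,clip_min,clip_max Schema fields for
#'   the emitted [feature_spec()].
#' @param out_of_range_rate Fraction of cells replaced by implausibly
#'   large values (beyond `clip_max`) after label generation, to exercise
#'   clipping.
#' @return A `cont_effect` description.
#' @export
cont_effect <- function(name,
                        shape = c("linear", "u_shaped", "threshold", "flat"),
                        scale = 1,
                        mean = 0, sd = 1,
                        lower = -Inf, upper = Inf,
                        vertex = 0, threshold_at = 0,
                        integer_valued = FALSE,
                        missing_rate = 0,
                        impute_policy = "train_mean",
                        constant_value = NULL,
                        clip_min = NULL, clip_max = NULL,
                        out_of_range_rate = 0) {
  shape <- match.arg(shape)
  if (sd <= 0) abort("`sd` must be positive.")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1).")
  if (out_of_range_rate < 0 || out_of_range_rate >= 1) abort("`out_of_range_rate` must be in [0, 1).")
  structure(
    list(
      name = name, shape = shape, scale = scale, mean = mean, sd = sd,
      lower = lower, upper = upper, vertex = vertex,
      threshold_at = threshold_at, integer_valued = integer_valued,
      missing_rate = missing_rate, impute_policy = impute_policy,
      constant_value = constant_value, clip_min = clip_min,
      clip_max = clip_max, out_of_range_rate = out_of_range_rate
    ),
    class = "cont_effect"
  )
}

#' Declare a binary synthetic feature effect
#'
#' A Bernoulli flag (device/procedure indicator) entering the logit as
#' `weight * x`.
#'
#' @param name Feature name.
#' @param prevalence Flag prevalence in (0, 1).
#' @param weight Log-odds weight.
#' @param missing_rate Fraction of cells blanked after label generation
#'   (imputed back to 0 downstream: absent means not placed).
#' @return A `bin_effect` description.
#' @export
bin_effect <- function(name, prevalence, weight, missing_rate = 0) {
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0, 1).")
  structure(
    list(name = name, prevalence = prevalence, weight = weight,
         missing_rate = missing_rate),
    class = "bin_effect"
  )
}

#' Assemble a synthetic cohort specification
#'
#' @param n_samples Number of samples.
#' @param continuous List of [cont_effect()]s.
#' @param binary List of [bin_effect()]s.
#' @param intercept Logit intercept; if `NULL`, calibrated at generation
#'   time so the expected outcome prevalence matches
#'   `target_prevalence`.
#' @param target_prevalence Desired positive fraction (used when
#'   `intercept` is `NULL`).
#' @param seed Integer seed; the same spec is bit-reproducible.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, continuous, binary = list(),
                        intercept = NULL, target_prevalence = NULL,
                        seed = 1L) {
  if (n_samples < 2) abort("Need at least 2 samples.")
  if (length(continuous) == 0L) abort("Need at least one continuous effect.")
  if (is.null(intercept) && is.null(target_prevalence)) {
    abort("Give either `intercept` or `target_prevalence`.")
  }
  structure(
    list(
      n_samples = as.integer(n_samples),
      continuous = continuous, binary = binary,
      intercept = intercept, target_prevalence = target_prevalence,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

shape_value <- function(eff, x) {
  z <- (x - eff$mean) / eff$sd
  switch(eff$shape,
    linear = eff$scale * z,
    u_shaped = eff$scale * ((z - eff$vertex)^2 - (1 + eff$vertex^2)),
    threshold = eff$scale * ((z > eff$threshold_at) -
                               stats::pnorm(eff$threshold_at, lower.tail = FALSE)),
    flat = rep(0, length(z))
  )
}

#' Generate a synthetic cohort with known additive ground truth
#'
#' Draws features per the spec, assembles the true logit additively
#' (`intercept + sum_j f_j(x_j)`), draws labels Bernoulli(sigmoid(logit)),
#' and only then degrades the feature matrix with missing cells and
#' out-of-range spikes — labels always reflect the true values, so
#' downstream imputation/clipping robustness is isolated from label
#' noise. Deterministic under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `dataset` (raw `gamnn_dataset`, possibly with missing
#'   values and out-of-range spikes), `truth` (a `gamnn_ground_truth`:
#'   per-feature true contributions, true logit, intercept, shape
#'   descriptions), and `schema` (the matching [feature_schema()]).
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_samples
  cont_names <- vapply(spec$continuous, function(e) e$name, character(1))
  bin_names <- vapply(spec$binary, function(e) e$name, character(1))
  feats <- c(cont_names, bin_names)
  X <- with_seed(derive_seed(spec$seed, "features"), {
    M <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
    for (e in spec$continuous) {
      x <- rtruncnorm(n, e$mean, e$sd, e$lower, e$upper)
      if (e$integer_valued) x <- pmin(pmax(round(x), ceiling(e$lower)), floor(e$upper))
      M[, e$name] <- x
    }
    for (e in spec$binary) {
      M[, e$name] <- rbinom(n, 1L, e$prevalence)
    }
    M
  })
  contrib <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  for (e in spec$continuous) contrib[, e$name] <- shape_value(e, X[, e$name])
  for (e in spec$binary) contrib[, e$name] <- e$weight * X[, e$name]
  feature_logit <- rowSums(contrib)
  intercept <- spec$intercept
  if (is.null(intercept)) {
    intercept <- uniroot(
      function(b) mean(sigmoid(b + feature_logit)) - spec$target_prevalence,
      lower = -40, upper = 40, tol = 1e-10
    )$root
  }
  true_logit <- intercept + feature_logit
  labels <- with_seed(derive_seed(spec$seed, "labels"), {
    rbinom(n, 1L, sigmoid(true_logit))
  })
  if (sum(labels) == 0L || sum(labels) == n) {
    abort("Degenerate outcome: every label identical; adjust intercept/prevalence or n.")
  }
  X_obs <- with_seed(derive_seed(spec$seed, "degrade"), {
    M <- X
    for (e in spec$continuous) {
      if (e$out_of_range_rate > 0 && !is.null(e$clip_max)) {
        hit <- runif(n) < e$out_of_range_rate
        M[hit, e$name] <- e$clip_max * 2 + 5 * e$sd
      }
      if (e$missing_rate > 0) {
        M[runif(n) < e$missing_rate, e$name] <- NA_real_
      }
    }
    for (e in spec$binary) {
      if (e$missing_rate > 0) {
        M[runif(n) < e$missing_rate, e$name] <- NA_real_
      }
    }
    M
  })
  schema <- feature_schema(
    c(
      lapply(spec$continuous, function(e) {
        feature_spec(
          e$name, "continuous",
          impute_policy = e$impute_policy,
          constant_value = e$constant_value,
          clip_min = e$clip_min, clip_max = e$clip_max
        )
      }),
      lapply(spec$binary, function(e) feature_spec(e$name, "binary"))
    ),
    outcome = "IN_HOSPITAL_MORTALITY"
  )
  truth <- structure(
    list(
      shapes = tibble::tibble(
        feature = feats,
        shape = c(
          vapply(spec$continuous, function(e) e$shape, character(1)),
          rep("binary", length(bin_names))
        ),
        scale = c(
          vapply(spec$continuous, function(e) e$scale, double(1)),
          vapply(spec$binary, function(e) e$weight, double(1))
        )
      ),
      contributions = contrib,
      true_logit = true_logit,
      intercept = intercept,
      true_values = X
    ),
    class = "gamnn_ground_truth"
  )
  list(
    dataset = new_dataset(X_obs, labels, feats),
    truth = truth,
    schema = schema
  )
}

#' @export
print.gamnn_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<gamnn_ground_truth> %d samples, %d features, intercept %.3f\n",
    length(x$true_logit), nrow(x$shapes), x$intercept
  ))
  invisible(x)
}

#' Ready-made perioperative-style cohort template
#'
#' A cohort specification emulating end-of-surgery tabular features: a
#' U-shaped mean-arterial-pressure effect (risk rising below ~50 and
#' above ~80 mmHg), a protective minimum diastolic pressure, a monotone
#' age effect, an ordinal ASA physical-status score with a high-risk
#' threshold (missing values filled with the modal class 3), a null lab
#' feature with out-of-range spikes to exercise clinical clipping, and
#' three device/procedure flags at realistic prevalences. The outcome is
#' rare by default (0.8% prevalence, the regime of in-hospital mortality
#' after surgery); lift `prevalence` for smaller stable experiments.
#'
#' @param n Number of samples (>= 1000).
#' @param seed Integer seed.
#' @param prevalence Target outcome prevalence (default 0.008).
#' @return A [cohort_spec()].
#' @export
perioperative_cohort_spec <- function(n, seed = 1L, prevalence = 0.008) {
  if (n < 1000) abort("The template is calibrated for n >= 1000.")
  cohort_spec(
    n_samples = n,
    continuous = list(
      cont_effect("AVG_MAP", "u_shaped", scale = 1.2,
                  mean = 75, sd = 12, lower = 35, upper = 130,
                  vertex = -0.8, clip_max = 140, out_of_range_rate = 0.002),
      cont_effect("MIN_DBP", "linear", scale = -1.0,
                  mean = 45, sd = 12, lower = 10, upper = 90,
                  missing_rate = 0.02),
      cont_effect("AGE", "linear", scale = 0.8,
                  mean = 56, sd = 17, lower = 18, upper = 89),
      cont_effect("ASA_SCORE", "threshold", scale = 0.9, threshold_at = 1,
                  mean = 2.6, sd = 0.9, lower = 1, upper = 6,
                  integer_valued = TRUE, missing_rate = 0.03,
                  impute_policy = "constant", constant_value = 3),
      cont_effect("MAX_GLUCOSE", "flat",
                  mean = 140, sd = 40, lower = 60, upper = 400,
                  clip_max = 350, out_of_range_rate = 0.003,
                  missing_rate = 0.02)
    ),
    binary = list(
      bin_effect("ART_LINE_YN", prevalence = 0.18, weight = 1.0),
      bin_effect("CVC_ANES_YN", prevalence = 0.05, weight = 0.8),
      bin_effect("HCUP_CAT_1_YN", prevalence = 0.02, weight = 1.2)
    ),
    target_prevalence = prevalence,
    seed = seed
  )
}

#' Write ground truth to JSON
#'
#' @param truth A `gamnn_ground_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(
      shapes = truth$shapes,
      intercept = truth$intercept,
      true_logit = truth$true_logit
    ),
    path, auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}
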