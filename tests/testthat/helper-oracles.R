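# Independent naive transcriptions of the point- and probability-assignment
# formulas, used as brute-force oracles against the package engines. Kept
# deliberately loop-based and separate from the implementation.

oracle_scores <- function(model) {
  s <- numeric(nrow(model))
  for (i in seq_len(nrow(model))) {
    s[i] <- abs(model$coef[i]) * (model$max[i] - model$min[i])
  }
  s
}

oracle_initializer <- function(model) {
  s <- oracle_scores(model)
  init <- 1
  for (i in seq_along(s)) if (s[i] > s[init]) init <- i
  init
}

oracle_max_points <- function(model, p_max = 100) {
  s <- oracle_scores(model)
  p_max * s / s[oracle_initializer(model)]
}

oracle_points <- function(model, values, p_max = 100) {
  pimax <- oracle_max_points(model, p_max)
  out <- numeric(nrow(model))
  for (i in seq_len(nrow(model))) {
    rng <- model$max[i] - model$min[i]
    out[i] <- if (model$coef[i] >= 0) {
      (values[i] - model$min[i]) / rng * pimax[i]
    } else {
      (model$max[i] - values[i]) / rng * pimax[i]
    }
  }
  out
}

oracle_linear_range <- function(model) {
  b0 <- model_intercept(model)
  lo <- b0; hi <- b0
  for (i in seq_len(nrow(model))) {
    if (model$coef[i] >= 0) {
      lo <- lo + model$coef[i] * model$min[i]
      hi <- hi + model$coef[i] * model$max[i]
    } else {
      lo <- lo + model$coef[i] * model$max[i]
      hi <- hi + model$coef[i] * model$min[i]
    }
  }
  c(lo, hi)
}

oracle_total_to_probability <- function(model, p_total, p_max = 100) {
  rng <- oracle_linear_range(model)
  ptm <- sum(oracle_max_points(model, p_max))
  v <- rng[1] + p_total / ptm * (rng[2] - rng[1])
  1 / (1 + exp(-v))
}

oracle_logistic <- function(model, values) {
  eta <- model_intercept(model)
  for (i in seq_len(nrow(model))) eta <- eta + model$coef[i] * values[i]
  1 / (1 + exp(-eta))
}

# one informative continuous predictor; handy for closed-form checks
unit_model <- function(coef = 1, min = 0, max = 1, intercept = 0,
                       threshold = NULL) {
  nomo_model(
    tibble::tibble(feature = "x", coef = coef, min = min, max = max,
                   type = "continuous", position = "up"),
    intercept = intercept, threshold = threshold
  )
}

cmv_template_path <- function() {
  system.file("extdata", "cmv_model.csv", package = "nomolog")
}

expect_model_equal <- function(a, b) {
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_equal(model_intercept(a), model_intercept(b))
  expect_equal(model_threshold(a), model_threshold(b))
}
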