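#' The refractory/recurrent CMV infection model
#'
#' The published logistic model for refractory or recurrent
#' cytomegalovirus infection after haploidentical-donor stem-cell
#' transplantation, a standard worked example for coefficient-only
#' nomogram construction: log-odds = 0.0322 age − 0.0696 gender +
#' 0.5492 underlying disease + 0.0963 cumulative prednisone dose −
#' 0.0771 CD34+ cell count − 1.2926, with decision threshold 0.5243.
#'
#' The publication prints the coefficients, intercept and threshold but
#' not the predictor ranges (those appear only in its figures). The
#' ranges used here — age 0–100 years, gender and underlying disease 0/1,
#' prednisone dose 0–50, CD34+ count 0–20 — are this package's defaults,
#' not published values. Exact-mode probabilities are invariant to the
#' range choice; only the printed axes and point readings depend on it.
#'
#' @return A [nomo_model()] with 5 predictors.
#' @examples
#' evaluate_patients(c(50, 1, 1, 14, 7), nomogram(cmv_model()))
#' @export
cmv_model <- function() {
  nomo_model(
    tibble::tibble(
      feature = c("age", "gender", "underlying_disease",
                  "prednisone_dose", "cd34_count"),
      coef = c(0.0322, -0.0696, 0.5492, 0.0963, -0.0771),
      min = c(0, 0, 0, 0, 0),
      max = c(100, 1, 1, 50, 20),
      type = c("continuous", "nominal", "nominal", "continuous",
               "continuous"),
      position = c("up", "up", "up", "up", "up")
    ),
    intercept = -1.2926,
    threshold = 0.5243
  )
}

#' Generate a random valid model specification
#'
#' Draws a model that passes every template invariant, for property
#' testing and simulation. Each predictor takes one of four range styles:
#' `unit` (`[0, 1]` continuous), `wide` (a continuous range of arbitrary
#' location and width), `binary` (a 0/1 nominal indicator), or
#' `nominal-k` (a k-level nominal variable encoded as k − 1 one-hot rows
#' sharing a `parent::level` name). Coefficients are centred Gaussian
#' draws; at least one predictor is guaranteed informative.
#'
#' @param d Number of predictor *variables* (a nominal-k variable counts
#'   once but contributes several rows).
#' @param seed Integer seed; fully determines the model.
#' @param coef_scale Standard deviation of the coefficient draws.
#' @param range_styles Styles to sample from; `"nominal-k"` picks k in
#'   3..4.
#' @param threshold Include a decision threshold (default `TRUE`).
#' @return A [nomo_model()].
#' @export
random_model <- function(d = 4, seed = 1L, coef_scale = 1,
                         range_styles = c("unit", "wide", "binary",
                                          "nominal-k"),
                         threshold = TRUE) {
  stopifnot(d >= 1)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(d)) {
    style <- sample(range_styles, 1)
    if (style == "nominal-k") {
      k <- sample(3:4, 1)
      rows[[i]] <- tibble::tibble(
        feature = sprintf("var%d::level%d", i, seq_len(k - 1)),
        coef = stats::rnorm(k - 1, sd = coef_scale),
        min = 0, max = 1, type = "nominal",
        position = sample(c("up", "down"), 1)
      )
    } else {
      rng <- switch(style,
        unit = c(0, 1),
        binary = c(0, 1),
        wide = sort(stats::rnorm(2, sd = 50)) + c(0, 1)  # nonzero width
      )
      rows[[i]] <- tibble::tibble(
        feature = sprintf("var%d", i),
        coef = stats::rnorm(1, sd = coef_scale),
        min = rng[1], max = rng[2],
        type = if (style == "binary") "nominal" else
          sample(c("continuous", "discrete", "ordinal"), 1,
                 prob = c(0.8, 0.1, 0.1)),
        position = sample(c("up", "down"), 1)
      )
    }
  }
  pred <- dplyr::bind_rows(rows)
  # guarantee an informative predictor
  if (all(abs(pred$coef) * (pred$max - pred$min) == 0)) {
    pred$coef[1] <- coef_scale
  }
  nomo_model(pred,
             intercept = stats::rnorm(1, sd = coef_scale),
             threshold = if (threshold) stats::runif(1, 0.05, 0.95)
                         else NULL)
}

#' Generate random patients within a model's predictor box
#'
#' Uniform draws inside every predictor's `[min, max]`, except one-hot
#' nominal groups, where each patient activates at most one level (the
#' implicit baseline is drawn with equal probability).
#'
#' @param model A [nomo_model()].
#' @param n Number of patients.
#' @param seed Integer seed.
#' @return An `n` x `d` numeric matrix in predictor order, usable
#'   directly with [evaluate_patients()].
#' @export
random_patients <- function(model, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  d <- nrow(model)
  parent <- nominal_parent(model)
  values <- matrix(0, nrow = n, ncol = d)
  plain <- which(is.na(parent))
  for (j in plain) {
    lv_lo <- ceiling(model$min[j]); lv_hi <- floor(model$max[j])
    if (model$type[j] %in% c("discrete", "ordinal", "nominal") &&
        lv_lo <= lv_hi) {
      values[, j] <- sample(lv_lo:lv_hi, n, replace = TRUE)
    } else {
      values[, j] <- stats::runif(n, model$min[j], model$max[j])
    }
  }
  for (grp in unique(parent[!is.na(parent)])) {
    members <- which(!is.na(parent) & parent == grp)
    # pick baseline (0) or one active level, uniformly
    choice <- sample(0:length(members), n, replace = TRUE)
    for (m in seq_along(members)) {
      values[, members[m]] <- as.numeric(choice == m)
    }
  }
  colnames(values) <- model$feature
  values
}
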