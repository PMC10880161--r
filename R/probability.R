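#' Numerically stable sigmoid
#'
#' `1 / (1 + exp(-x))`, computed branch-wise so neither tail overflows;
#' inputs are clipped at +/-700 before exponentiation.
#'
#' @param x Numeric vector.
#' @return Probabilities in `[0, 1]`.
#' @export
sigmoid <- function(x) {
  x <- pmin(pmax(x, -700), 700)
  ifelse(x >= 0,
         1 / (1 + exp(-x)),
         exp(x) / (1 + exp(x)))
}

#' Attainable range of the linear predictor
#'
#' Tight bounds of `intercept + sum(coef * x)` over the predictor box
#' `[min, max]^d`: each positive-coefficient predictor contributes its
#' minimum (maximum) to the lower (upper) bound and each
#' negative-coefficient predictor the reverse.
#'
#' @param model A [nomo_model()].
#' @return Named numeric vector `c(min_value, max_value)`.
#' @export
linear_range <- function(model) {
  b0 <- model_intercept(model)
  lo <- sum(ifelse(model$coef >= 0, model$coef * model$min,
                   model$coef * model$max)) + b0
  hi <- sum(ifelse(model$coef >= 0, model$coef * model$max,
                   model$coef * model$min)) + b0
  c(min_value = lo, max_value = hi)
}

#' Total maximum points
#'
#' Sum of per-predictor point maxima: the right-hand end of the total
#' points ruler. One-hot levels of a nominal variable each contribute
#' their own maximum, so for models with nominal groups the ruler covers a
#' superset of the totals attainable under mutual exclusivity.
#'
#' @param scales A `nomo_scales` tibble.
#' @return Nonnegative scalar, at least `p_max`.
#' @export
total_max_points <- function(scales) {
  sum(scales$max_points)
}

#' Map between total points and probability
#'
#' `probability_map()` packages the quantities linking the total-points
#' ruler to the probability scale: the linear predictor's attainable range
#' and the total maximum points. `total_points_to_probability()` then maps
#' a point total affinely onto that range and through the sigmoid —
#' exactly the model's predicted probability when the points were assigned
#' without rounding. `probability_to_total_points()` is the inverse (it
#' places the decision-threshold marker on the total ruler);
#' `probability_curve()` samples the map uniformly in total points for the
#' evenly scaled probability panel.
#'
#' @param model A [nomo_model()].
#' @param scales Matching `nomo_scales` from [build_point_scales()].
#' @return `probability_map()`: a `nomo_probmap` list with elements
#'   `min_value`, `max_value`, `total_max_points`, `intercept`, `p_max`.
#' @examples
#' m <- cmv_model()
#' pm <- probability_map(m, build_point_scales(m))
#' total_points_to_probability(pm, 0)  # sigmoid at the range's lower end
#' @export
probability_map <- function(model, scales) {
  rng <- linear_range(model)
  structure(
    list(min_value = unname(rng[1]), max_value = unname(rng[2]),
         total_max_points = total_max_points(scales),
         intercept = model_intercept(model),
         p_max = attr(scales, "p_max")),
    class = "nomo_probmap"
  )
}

#' @rdname probability_map
#' @param pm A `nomo_probmap`.
#' @param p_total Total points, in `[0, total_max_points]`.
#' @param strict If `TRUE` (default), out-of-range totals are an error;
#'   otherwise they are clamped.
#' @export
total_points_to_probability <- function(pm, p_total, strict = TRUE) {
  stopifnot(inherits(pm, "nomo_probmap"))
  bad <- p_total < 0 | p_total > pm$total_max_points
  if (any(bad)) {
    if (strict) {
      stop("total points outside [0, ", format(pm$total_max_points), "]",
           call. = FALSE)
    }
    p_total <- pmin(pmax(p_total, 0), pm$total_max_points)
  }
  v <- pm$min_value +
    (p_total / pm$total_max_points) * (pm$max_value - pm$min_value)
  sigmoid(v)
}

#' @rdname probability_map
#' @param p Probability within the attainable range
#'   `[sigmoid(min_value), sigmoid(max_value)]`.
#' @export
probability_to_total_points <- function(pm, p) {
  stopifnot(inherits(pm, "nomo_probmap"))
  lo <- sigmoid(pm$min_value); hi <- sigmoid(pm$max_value)
  if (any(p < lo | p > hi)) {
    stop("probability not attainable by this model over its predictor box ",
         sprintf("[%.4g, %.4g]", lo, hi), call. = FALSE)
  }
  v <- stats::qlogis(p)
  (v - pm$min_value) / (pm$max_value - pm$min_value) * pm$total_max_points
}

#' @rdname probability_map
#' @param n_samples Number of uniformly spaced totals to sample (>= 2).
#' @export
probability_curve <- function(pm, n_samples = 512) {
  stopifnot(inherits(pm, "nomo_probmap"), n_samples >= 2)
  totals <- seq(0, pm$total_max_points, length.out = n_samples)
  tibble::tibble(
    total_points = totals,
    probability = total_points_to_probability(pm, totals)
  )
}

#' @export
print.nomo_probmap <- function(x, ...) {
  cat("<nomo_probmap> linear predictor in [",
      format(x$min_value), ", ", format(x$max_value),
      "]; total points 0..", format(x$total_max_points),
      "; probability in [", format(sigmoid(x$min_value), digits = 4),
      ", ", format(sigmoid(x$max_value), digits = 4), "]\n", sep = "")
  invisible(x)
}
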