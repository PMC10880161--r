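#' Absolute maximum beta value
#'
#' The influence score used to rank predictors: `|coef| * (max - min)`, the
#' largest absolute contribution a predictor can make to the linear
#' predictor over its stated range. The predictor maximising this score
#' anchors the point scale at `p_max` points.
#'
#' @param model A [nomo_model()] (or any data frame with `coef`, `min`,
#'   `max` columns).
#' @return Numeric vector of nonnegative scores, one per predictor row.
#' @export
absolute_max_beta <- function(model) {
  abs(model$coef) * (model$max - model$min)
}

#' Choose the initializing predictor
#'
#' Index of the predictor with the largest absolute maximum beta value,
#' ties broken towards the earliest file row so the choice is
#' deterministic. This predictor's axis spans the full 0..`p_max` ruler.
#'
#' @inheritParams absolute_max_beta
#' @return Integer index into the predictor rows.
#' @export
select_initializer <- function(model) {
  scores <- absolute_max_beta(model)
  if (all(scores <= 0)) {
    stop("model has no informative predictor (all |coef| * range are zero)",
         call. = FALSE)
  }
  which.max(scores)
}

#' Maximum points for one predictor
#'
#' Scales a predictor's influence score against the initializer's so the
#' initializer lands on exactly `p_max` and every other predictor on a
#' proportional share.
#'
#' @param score The predictor's absolute maximum beta value.
#' @param initializer_score The initializer's (must be positive).
#' @param p_max Point value anchoring the initializer, usually 100.
#' @return `p_max * score / initializer_score`.
#' @export
max_points <- function(score, initializer_score, p_max = 100) {
  if (initializer_score <= 0) {
    stop("initializer score must be positive", call. = FALSE)
  }
  p_max * score / initializer_score
}

#' Build the value-to-points scales for a model
#'
#' Constructs one affine value-to-points map per predictor. A predictor
#' with a nonnegative coefficient maps `min` to 0 points and `max` to its
#' maximum points (ascending); a negative coefficient reverses the
#' orientation, so higher risk always means more points. Points are kept
#' as exact reals; rounding belongs to display and to the graphical-reading
#' simulator only.
#'
#' @param model A [nomo_model()].
#' @param p_max Maximum point value on the shared points ruler
#'   (self-designed point range; default 100).
#' @return A `nomo_scales` tibble with one row per predictor: the template
#'   columns plus `group` (nominal parent or `NA`), `abs_max_beta`,
#'   `max_points`, `orientation`, and the affine coefficients `slope`,
#'   `offset` with `points = slope * value + offset`. Attributes:
#'   `initializer` (row index) and `p_max`.
#' @examples
#' scales <- build_point_scales(cmv_model())
#' attr(scales, "initializer")  # prednisone dose dominates
#' @export
build_point_scales <- function(model, p_max = 100) {
  stopifnot(is.numeric(p_max), length(p_max) == 1, p_max > 0)
  init <- select_initializer(model)
  scores <- absolute_max_beta(model)
  pmax_i <- max_points(scores, scores[init], p_max)
  range_i <- model$max - model$min
  ascending <- model$coef >= 0
  slope <- ifelse(range_i > 0,
                  ifelse(ascending, 1, -1) * pmax_i / range_i, 0)
  offset <- ifelse(ascending, -model$min * slope, model$max * pmax_i / range_i)

  scales <- tibble::as_tibble(model)
  scales$group <- nominal_parent(model)
  scales$abs_max_beta <- scores
  scales$max_points <- pmax_i
  scales$orientation <- ifelse(ascending, "ascending", "descending")
  scales$slope <- slope
  scales$offset <- offset
  structure(scales, initializer = init, p_max = p_max,
            class = c("nomo_scales", class(tibble::tibble())))
}

#' Map predictor values to points and back
#'
#' `value_to_points()` applies each predictor's affine map to a vector of
#' patient values (one value per predictor row, in order);
#' `points_to_value()` inverts it. Predictors with zero maximum points have
#' no inverse and `points_to_value()` refuses them.
#'
#' @param scales A `nomo_scales` tibble from [build_point_scales()].
#' @param values Numeric vector, one value per predictor.
#' @param strict If `TRUE` (default), values outside a predictor's
#'   `[min, max]` are an error naming the predictor; if `FALSE` they are
#'   clamped to the range with a warning.
#' @return Numeric vector of points in `[0, max_points]` per predictor.
#' @export
value_to_points <- function(scales, values, strict = TRUE) {
  stopifnot(inherits(scales, "nomo_scales"))
  if (length(values) != nrow(scales)) {
    stop("expected ", nrow(scales), " values (one per predictor), got ",
         length(values), call. = FALSE)
  }
  out_of_range <- values < scales$min | values > scales$max
  if (any(out_of_range)) {
    offending <- scales$feature[out_of_range]
    if (strict) {
      stop("value out of range for predictor(s): ",
           paste(offending, collapse = ", "), call. = FALSE)
    }
    warning("clamping out-of-range value(s) for: ",
            paste(offending, collapse = ", "), call. = FALSE)
    values <- pmin(pmax(values, scales$min), scales$max)
  }
  pts <- scales$slope * unname(values) + scales$offset
  # guard rounding slop at the endpoints
  pmin(pmax(pts, 0), scales$max_points)
}

#' @rdname value_to_points
#' @param points Numeric vector of point values, one per predictor, each in
#'   `[0, max_points]`.
#' @export
points_to_value <- function(scales, points, strict = TRUE) {
  stopifnot(inherits(scales, "nomo_scales"))
  if (length(points) != nrow(scales)) {
    stop("expected ", nrow(scales), " point values, got ", length(points),
         call. = FALSE)
  }
  if (any(scales$max_points == 0)) {
    stop("predictor(s) with zero maximum points have no inverse map: ",
         paste(scales$feature[scales$max_points == 0], collapse = ", "),
         call. = FALSE)
  }
  bad <- points < 0 | points > scales$max_points
  if (any(bad) && strict) {
    stop("points out of [0, max_points] for predictor(s): ",
         paste(scales$feature[bad], collapse = ", "), call. = FALSE)
  }
  (unname(points) - scales$offset) / scales$slope
}

#' @export
print.nomo_scales <- function(x, ...) {
  cat("<nomo_scales> p_max = ", attr(x, "p_max"),
      ", initializer = ", x$feature[attr(x, "initializer")], "\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
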