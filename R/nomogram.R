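#' Build a nomogram from a model specification
#'
#' Bundles everything needed to use a logistic-regression nomogram: the
#' model, the per-predictor point scales, the total-points-to-probability
#' map, and the laid-out geometry. Build one either from a [nomo_model()]
#' or directly from a template file path.
#'
#' @param model A [nomo_model()], or a path to a `.csv`/`.xlsx` template.
#' @param p_max Point value anchoring the most influential predictor
#'   (default 100).
#' @param style A [nomo_style()] list of layout/render options.
#' @return A `nomogram` object (list with elements `model`, `scales`,
#'   `pm`, `geometry`).
#' @examples
#' nomo <- nomogram(cmv_model())
#' glance(nomo)
#' @export
nomogram <- function(model, p_max = 100, style = nomo_style()) {
  if (is.character(model)) model <- read_model_template(model)
  stopifnot(inherits(model, "nomo_model"))
  scales <- build_point_scales(model, p_max = p_max)
  pm <- probability_map(model, scales)
  structure(
    list(model = model, scales = scales, pm = pm,
         geometry = compute_layout(model, scales, pm, style)),
    class = "nomogram"
  )
}

#' @export
print.nomogram <- function(x, ...) {
  thr <- model_threshold(x$model)
  cat("<nomogram> ", nrow(x$model), " predictor(s), ",
      sum(!is.na(unique(x$scales$group))), " nominal group(s)\n", sep = "")
  cat("  initializer: ", x$scales$feature[attr(x$scales, "initializer")],
      " (", attr(x$scales, "p_max"), " points)\n", sep = "")
  cat("  total points 0..", format(x$pm$total_max_points),
      " -> probability [", format(sigmoid(x$pm$min_value), digits = 4),
      ", ", format(sigmoid(x$pm$max_value), digits = 4), "]\n", sep = "")
  if (!is.null(thr)) cat("  threshold: ", thr, "\n", sep = "")
  invisible(x)
}

#' Broom-style accessors for nomograms
#'
#' `tidy()` returns one row per predictor axis with its influence score,
#' maximum points, and orientation; `glance()` returns a one-row summary
#' of the whole nomogram.
#'
#' @param x A `nomogram`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nomogram <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x$scales),
                "feature", "coef", "min", "max", "type", "group",
                "abs_max_beta", "max_points", "orientation")
}

#' @rdname tidy.nomogram
#' @export
glance.nomogram <- function(x, ...) {
  thr <- model_threshold(x$model)
  tibble::tibble(
    n_predictors = nrow(x$model),
    n_axes = sum(x$geometry$axes$kind == "predictor"),
    p_max = attr(x$scales, "p_max"),
    initializer = x$scales$feature[attr(x$scales, "initializer")],
    total_max_points = x$pm$total_max_points,
    min_value = x$pm$min_value,
    max_value = x$pm$max_value,
    prob_lo = sigmoid(x$pm$min_value),
    prob_hi = sigmoid(x$pm$max_value),
    threshold = if (is.null(thr)) NA_real_ else thr
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
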