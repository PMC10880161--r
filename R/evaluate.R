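#' Evaluate patients on a nomogram
#'
#' Runs the nomogram calculation flow for each patient: assign each value
#' its points on the predictor axes, sum to a total, map the total through
#' the probability scale, and (when the model carries a threshold)
#' classify as high or low risk. `mode = "exact"` keeps points as exact
#' reals and reproduces the logistic formula to machine precision;
#' `mode = "graphical"` mimics reading the printed chart by rounding each
#' per-axis point and the total-ruler lookup to the nearest multiple of
#' `granularity` points.
#'
#' @param patients Data frame of patient values: either one column per
#'   predictor named as in the model (any order), or exactly `d` unnamed
#'   columns in predictor order. A bare numeric vector is taken as one
#'   patient.
#' @param nomo A [nomogram()].
#' @param mode `"exact"` (default) or `"graphical"`.
#' @param granularity Tick step in points for graphical mode (default 10,
#'   the coarse step at which printed nomograms are typically read).
#' @param strict Error on out-of-range values (default) or clamp them.
#' @return A tibble, one row per patient: `total_points`, `probability`,
#'   `risk` (`"high"`/`"low"`, `NA` when the model has no threshold),
#'   `mode`, and `points`, a list-column of per-predictor point tibbles.
#' @examples
#' patient <- data.frame(age = 50, gender = 1, underlying_disease = 1,
#'                       prednisone_dose = 14, cd34_count = 7)
#' evaluate_patients(patient, nomogram(cmv_model()))
#' @export
evaluate_patients <- function(patients, nomo, mode = c("exact", "graphical"),
                              granularity = 10, strict = TRUE) {
  stopifnot(inherits(nomo, "nomogram"))
  mode <- match.arg(mode)
  if (mode == "graphical" && (!is.numeric(granularity) || granularity <= 0)) {
    stop("graphical mode requires granularity > 0", call. = FALSE)
  }
  values <- patient_matrix(patients, nomo$model)

  rows <- purrr::map(seq_len(nrow(values)), function(i) {
    pts <- value_to_points(nomo$scales, values[i, ], strict = strict)
    if (mode == "graphical") {
      pts <- round_to(pts, granularity)
    }
    total <- sum(pts)
    if (mode == "graphical") {
      total <- round_to(total, granularity)
      total <- min(max(total, 0), nomo$pm$total_max_points)
    }
    prob <- total_points_to_probability(nomo$pm, total, strict = strict)
    thr <- model_threshold(nomo$model)
    tibble::tibble(
      patient = i,
      total_points = total,
      probability = prob,
      risk = if (is.null(thr)) NA_character_ else classify(prob, thr),
      mode = mode,
      granularity = if (mode == "graphical") granularity else NA_real_,
      points = list(tibble::tibble(feature = nomo$scales$feature,
                                   value = values[i, ],
                                   points = pts))
    )
  })
  dplyr::bind_rows(rows)
}

#' Classify a probability against a decision threshold
#'
#' `"high"` when the probability strictly exceeds the threshold, `"low"`
#' otherwise; the boundary case `p == threshold` is classified low, since
#' the high-risk label is defined by a strict inequality.
#'
#' @param probability Numeric vector of probabilities.
#' @param threshold Scalar in (0, 1).
#' @return Character vector of `"high"`/`"low"`.
#' @export
classify <- function(probability, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold < 1)
  ifelse(probability > threshold, "high", "low")
}

round_to <- function(x, step) round(x / step) * step

# Coerce patient input to an n x d matrix in predictor order.
patient_matrix <- function(patients, model) {
  d <- nrow(model)
  if (is.numeric(patients) && is.null(dim(patients))) {
    patients <- matrix(patients, nrow = 1)
  }
  if (is.data.frame(patients)) {
    if (all(model$feature %in% names(patients))) {
      patients <- as.matrix(patients[model$feature])
    } else if (ncol(patients) == d) {
      patients <- as.matrix(patients)
    } else {
      stop("patient columns must either be named after the ", d,
           " predictors or be exactly ", d, " columns in predictor order",
           call. = FALSE)
    }
  }
  if (!is.matrix(patients) || ncol(patients) != d) {
    stop("expected ", d, " values per patient, got ", ncol(patients),
         call. = FALSE)
  }
  storage.mode(patients) <- "double"
  unname(patients)
}
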