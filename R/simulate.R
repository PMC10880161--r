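#' Simulate graphical readings of a nomogram
#'
#' Models a human reading the printed chart: for each patient, every
#' per-axis point value receives independent Gaussian noise
#' (`noise_sd`, in points) and is then rounded to the nearest multiple of
#' `granularity`, clamped to its axis; the noisy total is looked up on the
#' probability scale. With `granularity = 0` and `noise_sd = 0` the read
#' probabilities equal the exact ones. The whole study is reproducible
#' from `seed`.
#'
#' @param patients Patient values, as accepted by [evaluate_patients()].
#' @param nomo A [nomogram()].
#' @param granularity Reading granularity in points (>= 0; default 10).
#' @param noise_sd Standard deviation of per-axis reading noise in points
#'   (>= 0; default 0).
#' @param seed Integer seed driving the noise draws.
#' @return A `nomo_reading_study` tibble, one row per patient:
#'   `exact_probability`, `read_probability`, and (when the model has a
#'   threshold) `exact_label`, `read_label`. Attributes record
#'   `granularity`, `noise_sd`, `seed`, and the threshold.
#' @export
simulate_readings <- function(patients, nomo, granularity = 10,
                              noise_sd = 0, seed = 1L) {
  stopifnot(inherits(nomo, "nomogram"),
            granularity >= 0, noise_sd >= 0)
  values <- patient_matrix(patients, nomo$model)
  d <- nrow(nomo$scales)
  thr <- model_threshold(nomo$model)

  exact <- evaluate_patients(values, nomo, mode = "exact")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  read_prob <- purrr::map_dbl(seq_len(nrow(values)), function(i) {
    pts <- value_to_points(nomo$scales, values[i, ])
    pts <- pts + stats::rnorm(d, sd = noise_sd)
    if (granularity > 0) pts <- round_to(pts, granularity)
    pts <- pmin(pmax(pts, 0), nomo$scales$max_points)
    total <- sum(pts)
    if (granularity > 0) total <- round_to(total, granularity)
    total <- min(max(total, 0), nomo$pm$total_max_points)
    total_points_to_probability(nomo$pm, total)
  })

  study <- tibble::tibble(
    patient = seq_len(nrow(values)),
    exact_probability = exact$probability,
    read_probability = read_prob
  )
  if (!is.null(thr)) {
    study$exact_label <- classify(study$exact_probability, thr)
    study$read_label <- classify(study$read_probability, thr)
  }
  structure(study, granularity = granularity, noise_sd = noise_sd,
            seed = seed, threshold = thr,
            class = c("nomo_reading_study", class(tibble::tibble())))
}

#' Summarise a simulated reading study
#'
#' Discrimination and calibration summaries of a [simulate_readings()]
#' study: a confusion matrix and accuracy of read against exact risk
#' labels, and a binned calibration table — equal-width bins on read
#' probability, with each bin's mean exact probability and a
#' normal-approximation confidence half-width.
#'
#' @param study A `nomo_reading_study`.
#' @param n_bins Number of equal-width probability bins (default 10).
#' @param conf_level Confidence level for the bin intervals (default
#'   0.95).
#' @return A `nomo_calibration` list: `bins` (tibble with `bin`,
#'   `bin_mid`, `n`, `mean_read`, `mean_exact`, `ci_half`), `accuracy`,
#'   `confusion` (tibble of exact-by-read label counts; `NULL` without a
#'   threshold), `n_cases`.
#' @export
summarize_readings <- function(study, n_bins = 10, conf_level = 0.95) {
  stopifnot(inherits(study, "nomo_reading_study"), n_bins >= 1,
            nrow(study) > 0)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(study$read_probability, breaks,
                           rightmost.closed = TRUE), n_bins)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  bins <- purrr::map(seq_len(n_bins), function(b) {
    idx <- bin == b
    n <- sum(idx)
    ex <- study$exact_probability[idx]
    tibble::tibble(
      bin = b,
      bin_mid = (breaks[b] + breaks[b + 1]) / 2,
      n = n,
      mean_read = if (n > 0) mean(study$read_probability[idx]) else NA_real_,
      mean_exact = if (n > 0) mean(ex) else NA_real_,
      ci_half = if (n > 1) z * stats::sd(ex) / sqrt(n) else NA_real_
    )
  })
  bins <- dplyr::bind_rows(bins)

  confusion <- NULL
  accuracy <- NA_real_
  if (!is.null(attr(study, "threshold"))) {
    lv <- c("low", "high")
    confusion <- as.data.frame(table(
      exact = factor(study$exact_label, lv),
      read = factor(study$read_label, lv)
    ), responseName = "n")
    confusion <- tibble::as_tibble(confusion)
    accuracy <- mean(study$exact_label == study$read_label)
  }

  structure(
    list(bins = bins, accuracy = accuracy, confusion = confusion,
         n_cases = nrow(study), conf_level = conf_level),
    class = "nomo_calibration"
  )
}

#' @export
print.nomo_calibration <- function(x, ...) {
  cat("<nomo_calibration> ", x$n_cases, " simulated readings\n", sep = "")
  if (!is.na(x$accuracy)) {
    cat("  label accuracy: ", format(x$accuracy, digits = 4), "\n", sep = "")
  }
  cat("  calibration bins (", 100 * x$conf_level, "% CI):\n", sep = "")
  print(x$bins, ...)
  invisible(x)
}

#' Plot a calibration summary
#'
#' Mean exact probability against mean read probability per bin, with
#' confidence-interval error bars and the identity diagonal.
#'
#' @param object A `nomo_calibration` from [summarize_readings()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nomo_calibration <- function(object, ...) {
  bins <- dplyr::filter(object$bins, .data$n > 0)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_read,
                                     y = .data$mean_exact)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_exact - .data$ci_half,
                   ymax = .data$mean_exact + .data$ci_half),
      width = 0.02, na.rm = TRUE
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean read probability",
                  y = "Mean model probability", size = "Cases") +
    ggplot2::theme_minimal()
}

#' Analytic bound on graphical reading error
#'
#' Upper bound on the probability error introduced by rounding every axis
#' to a tick granularity `g`: each of the `d` predictor axes and the total
#' ruler is off by at most `g / 2` points, the affine map to the sigmoid
#' input has slope `(max_value - min_value) / total_max_points`, and the
#' sigmoid's Lipschitz constant is 1/4.
#'
#' @param nomo A [nomogram()].
#' @param granularity Tick step in points.
#' @return Scalar probability-error bound.
#' @export
reading_error_bound <- function(nomo, granularity) {
  d <- nrow(nomo$scales)
  0.25 * (nomo$pm$max_value - nomo$pm$min_value) / nomo$pm$total_max_points *
    (d + 1) * (granularity / 2)
}
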