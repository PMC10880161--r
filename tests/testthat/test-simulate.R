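test_that("zero granularity and zero noise read exactly", {
  nomo <- nomogram(cmv_model())
  patients <- random_patients(nomo$model, 20, seed = 2)
  study <- simulate_readings(patients, nomo, granularity = 0, noise_sd = 0)
  expect_equal(study$read_probability, study$exact_probability)
  expect_equal(study$read_label, study$exact_label)
})

test_that("a fixed seed reproduces the study exactly", {
  nomo <- nomogram(cmv_model())
  patients <- random_patients(nomo$model, 15, seed = 4)
  s1 <- simulate_readings(patients, nomo, granularity = 5, noise_sd = 3,
                          seed = 99)
  s2 <- simulate_readings(patients, nomo, granularity = 5, noise_sd = 3,
                          seed = 99)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
})

test_that("noise-free readings respect the analytic error bound", {
  for (seed in 1:10) {
    m <- random_model(d = sample(2:6, 1), seed = seed)
    nomo <- suppressWarnings(nomogram(m))
    patients <- random_patients(m, 30, seed = seed + 40)
    study <- simulate_readings(patients, nomo, granularity = 10,
                               noise_sd = 0)
    bound <- reading_error_bound(nomo, 10)
    expect_true(all(abs(study$read_probability -
                          study$exact_probability) <= bound + 1e-12))
  }
})

test_that("noise-free misclassification happens only near the threshold", {
  for (seed in 1:10) {
    m <- random_model(d = sample(2:5, 1), seed = seed)
    thr <- model_threshold(m)
    if (is.null(thr)) next
    nomo <- suppressWarnings(nomogram(m))
    patients <- random_patients(m, 50, seed = seed + 70)
    study <- simulate_readings(patients, nomo, granularity = 10,
                               noise_sd = 0)
    bound <- reading_error_bound(nomo, 10)
    wrong <- study$read_label != study$exact_label
    expect_true(all(abs(study$exact_probability[wrong] - thr) <=
                      bound + 1e-12))
  }
})

test_that("perfect readings give diagonal calibration and accuracy 1", {
  nomo <- nomogram(cmv_model())
  patients <- random_patients(nomo$model, 200, seed = 8)
  study <- simulate_readings(patients, nomo, granularity = 0, noise_sd = 0)
  summ <- summarize_readings(study, n_bins = 10)
  expect_equal(summ$accuracy, 1)
  occupied <- summ$bins[summ$bins$n > 0, ]
  expect_equal(occupied$mean_read, occupied$mean_exact, tolerance = 1e-12)
  expect_equal(sum(summ$bins$n), 200)
  expect_equal(sum(summ$confusion$n), 200)
  # all agreement sits on the confusion diagonal
  off <- summ$confusion[summ$confusion$exact != summ$confusion$read, ]
  expect_equal(sum(off$n), 0)
})

test_that("coarse reading of near-threshold cases concentrates the errors", {
  # one predictor on the logit scale: exact probability = sigmoid(x);
  # 154 readings at controlled distances from the 0.5 threshold
  m <- unit_model(coef = 1, min = -8, max = 8, intercept = 0,
                  threshold = 0.5)
  nomo <- nomogram(m)
  xs <- rep(c(0.1, -1, 1, -3, 3, -5, 5), each = 22)
  study <- simulate_readings(matrix(xs, ncol = 1), nomo,
                             granularity = 10, noise_sd = 0)
  summ <- summarize_readings(study)
  expect_lt(summ$accuracy, 1)
  wrong <- which(study$read_label != study$exact_label)
  expect_gt(length(wrong), 0)
  dist <- abs(study$exact_probability - 0.5)
  expect_true(all(dist[wrong] == min(dist)))
})

test_that("accuracy does not improve as reading noise grows", {
  nomo <- nomogram(cmv_model())
  patients <- random_patients(nomo$model, 120, seed = 10)
  acc <- purrr::map_dbl(c(0, 4, 25), function(sd) {
    mean(purrr::map_dbl(1:5, function(s) {
      study <- simulate_readings(patients, nomo, granularity = 5,
                                 noise_sd = sd, seed = s)
      summarize_readings(study)$accuracy
    }))
  })
  expect_true(all(diff(acc) <= 0.02))  # nonincreasing in expectation
})

test_that("empty bins are reported with zero count and no interval", {
  nomo <- nomogram(cmv_model())
  study <- simulate_readings(matrix(c(50, 1, 1, 14, 7), nrow = 1), nomo,
                             granularity = 0, noise_sd = 0)
  summ <- summarize_readings(study, n_bins = 10)
  expect_equal(nrow(summ$bins), 10)
  empty <- summ$bins[summ$bins$n == 0, ]
  expect_true(all(is.na(empty$ci_half)))
})

test_that("the calibration plot builds", {
  nomo <- nomogram(cmv_model())
  patients <- random_patients(nomo$model, 80, seed = 12)
  study <- simulate_readings(patients, nomo, granularity = 10,
                             noise_sd = 2, seed = 3)
  p <- autoplot(summarize_readings(study))
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
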