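test_that("sigmoid is correct, symmetric, and stable in the tails", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(0.5), 0.62246, tolerance = 1e-5)
  set.seed(1)
  x <- rnorm(100, sd = 5)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 100))
  expect_equal(sigmoid(c(-1e6, 1e6)), c(0, 1))
  expect_true(all(is.finite(sigmoid(c(-750, 750)))))
})

test_that("linear_range gives tight bounds of the linear predictor", {
  m <- nomo_model(
    tibble::tibble(feature = c("a", "b"), coef = c(1, -1),
                   min = 0, max = 1, type = "continuous", position = "up"),
    intercept = 0
  )
  expect_equal(unname(linear_range(m)), c(-1, 1))

  allpos <- nomo_model(
    tibble::tibble(feature = c("a", "b"), coef = c(2, 3), min = 0,
                   max = c(1, 4), type = "continuous", position = "up"),
    intercept = -1.5
  )
  expect_equal(unname(linear_range(allpos)[1]), -1.5)

  # Monte-Carlo containment over the predictor box
  for (seed in 1:5) {
    mm <- random_model(d = 4, seed = seed)
    rng <- linear_range(mm)
    x <- matrix(runif(1e4 * nrow(mm), mm$min, mm$max),
                ncol = nrow(mm), byrow = TRUE)
    eta <- model_intercept(mm) + drop(x %*% mm$coef)
    expect_true(all(eta >= rng[1] - 1e-9 & eta <= rng[2] + 1e-9))
  }
})

test_that("total_max_points sums the per-axis maxima", {
  solo <- build_point_scales(unit_model())
  expect_equal(total_max_points(solo), 100)
  m <- cmv_model()
  s <- build_point_scales(m)
  expect_equal(total_max_points(s), sum(s$max_points))
  # algebraic identity: (max_value - min_value) * p_max / initializer score
  for (seed in 1:20) {
    mm <- random_model(d = sample(1:6, 1), seed = seed)
    ss <- build_point_scales(mm)
    rng <- linear_range(mm)
    init_score <- absolute_max_beta(mm)[attr(ss, "initializer")]
    expect_equal(total_max_points(ss),
                 unname(rng[2] - rng[1]) * 100 / init_score,
                 tolerance = 1e-10)
  }
})

test_that("total points map to probability through the sigmoid range", {
  m <- unit_model()
  pm <- probability_map(m, build_point_scales(m))
  expect_equal(total_points_to_probability(pm, 0), sigmoid(0))
  expect_equal(total_points_to_probability(pm, 100), sigmoid(1))
  expect_equal(total_points_to_probability(pm, 50), 0.62246,
               tolerance = 1e-5)
  expect_error(total_points_to_probability(pm, 101), "total points")
  expect_equal(total_points_to_probability(pm, 150, strict = FALSE),
               sigmoid(1))
})

test_that("probability_to_total_points inverts the forward map", {
  m <- cmv_model()
  pm <- probability_map(m, build_point_scales(m))
  expect_equal(probability_to_total_points(pm, sigmoid(pm$min_value)), 0)
  set.seed(3)
  totals <- runif(100, 0, pm$total_max_points)
  p <- total_points_to_probability(pm, totals)
  expect_equal(probability_to_total_points(pm, p), totals,
               tolerance = 1e-8)
  expect_error(probability_to_total_points(pm, 0.9999), "not attainable")
})

test_that("the threshold lands inside the total ruler (bisection check)", {
  m <- cmv_model()
  pm <- probability_map(m, build_point_scales(m))
  t_thr <- probability_to_total_points(pm, 0.5243)
  expect_gt(t_thr, 0)
  expect_lt(t_thr, pm$total_max_points)
  # independent root-finder on the forward map
  root <- uniroot(function(t) total_points_to_probability(pm, t) - 0.5243,
                  c(0, pm$total_max_points), tol = 1e-12)$root
  expect_equal(t_thr, root, tolerance = 1e-8)
})

test_that("the probability curve is uniform in totals, increasing, exact at ends", {
  m <- cmv_model()
  pm <- probability_map(m, build_point_scales(m))
  two <- probability_curve(pm, 2)
  expect_equal(two$total_points, c(0, pm$total_max_points))
  expect_equal(two$probability,
               sigmoid(c(pm$min_value, pm$max_value)))
  crv <- probability_curve(pm, 257)
  expect_equal(diff(range(diff(crv$total_points))), 0, tolerance = 1e-9)
  expect_true(all(diff(crv$probability) > 0))
  # symmetric model: midpoint probability is exactly one half
  sym <- unit_model(coef = 2, min = -1, max = 1, intercept = 0)
  pms <- probability_map(sym, build_point_scales(sym))
  mid <- probability_curve(pms, 3)
  expect_equal(mid$probability[2], 0.5)
})

test_that("master round-trip identity: points recover the logistic formula", {
  n_checked <- 0
  for (seed in 1:100) {
    m <- random_model(d = sample(1:8, 1), seed = seed)
    nomo <- suppressWarnings(nomogram(m))
    patients <- random_patients(m, 12, seed = seed + 5000)
    res <- evaluate_patients(patients, nomo)
    direct <- apply(patients, 1, function(v) oracle_logistic(m, v))
    expect_equal(res$probability, unname(direct), tolerance = 1e-9)
    n_checked <- n_checked + nrow(patients)
  }
  expect_gte(n_checked, 1000)
})
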