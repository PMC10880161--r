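test_that("influence scores are |coef| times range", {
  m <- cmv_model()
  expect_equal(absolute_max_beta(m),
               c(3.22, 0.0696, 0.5492, 4.815, 1.542))
  expect_equal(absolute_max_beta(unit_model(coef = 0)), 0)
  expect_equal(absolute_max_beta(unit_model(coef = -0.0771, min = 0,
                                            max = 20)), 1.542)
})

test_that("the initializer maximises the score, ties to file order", {
  m <- cmv_model()
  expect_equal(select_initializer(m), 4)  # prednisone dose dominates
  tie <- nomo_model(
    tibble::tibble(feature = c("a", "b"), coef = c(1, -1),
                   min = 0, max = 1, type = "continuous", position = "up"),
    intercept = 0
  )
  expect_equal(select_initializer(tie), 1)
  solo <- unit_model()
  expect_equal(select_initializer(solo), 1)
  allzero <- nomo_model(
    tibble::tibble(feature = "z", coef = 0, min = 0, max = 1,
                   type = "continuous", position = "up"),
    intercept = 0
  )
  expect_error(select_initializer(allzero), "no informative predictor")
})

test_that("maximum points scale proportionally to the initializer", {
  expect_equal(max_points(2.746, 2.746), 100)
  expect_equal(max_points(0.5492, 2.746), 20)
  expect_equal(max_points(0, 2.746), 0)
  expect_error(max_points(1, 0), "positive")
})

test_that("value-to-points hits the endpoints dictated by orientation", {
  m <- cmv_model()
  s <- build_point_scales(m)
  expect_equal(s$max_points[4], 100)  # initializer anchored exactly
  pts_min <- value_to_points(s, m$min)
  pts_max <- value_to_points(s, m$max)
  asc <- m$coef >= 0
  expect_equal(pts_min[asc], rep(0, sum(asc)))
  expect_equal(pts_min[!asc], s$max_points[!asc])
  expect_equal(pts_max[asc], s$max_points[asc])
  expect_equal(pts_max[!asc], rep(0, sum(!asc)))
})

test_that("value-to-points interpolates linearly", {
  s <- build_point_scales(unit_model())
  expect_equal(value_to_points(s, 0.5), 50)
  expect_equal(value_to_points(s, 0.25), 25)
})

test_that("out-of-range values error in strict mode, clamp in lenient", {
  s <- build_point_scales(cmv_model())
  v <- c(150, 1, 1, 14, 7)
  expect_error(value_to_points(s, v), "age")
  expect_warning(pts <- value_to_points(s, v, strict = FALSE), "age")
  expect_equal(pts[1], s$max_points[1])
})

test_that("points_to_value inverts value_to_points", {
  set.seed(42)
  for (seed in 1:10) {
    m <- random_model(d = 4, seed = seed, range_styles = c("unit", "wide"))
    s <- build_point_scales(m)
    v <- runif(nrow(m), m$min, m$max)
    expect_equal(points_to_value(s, value_to_points(s, v)), v,
                 tolerance = 1e-9)
  }
  zero <- nomo_model(
    tibble::tibble(feature = c("a", "b"), coef = c(1, 0),
                   min = 0, max = 1, type = "continuous", position = "up"),
    intercept = 0
  )
  sz <- build_point_scales(zero)
  expect_error(points_to_value(sz, c(10, 0)), "no inverse")
})

test_that("the engine matches a naive transcription of the formulas", {
  for (seed in 1:50) {
    m <- random_model(d = sample(1:8, 1), seed = seed)
    s <- build_point_scales(m)
    expect_equal(attr(s, "initializer"), oracle_initializer(m))
    expect_equal(s$max_points, oracle_max_points(m), tolerance = 1e-12)
    v <- random_patients(m, 1, seed = seed + 1000)[1, ]
    expect_equal(value_to_points(s, v), oracle_points(m, v),
                 tolerance = 1e-12)
  }
})

test_that("point scales are invariant under coefficient rescaling", {
  base <- random_model(d = 5, seed = 11)
  s0 <- build_point_scales(base)
  v <- random_patients(base, 1, seed = 12)[1, ]
  p0 <- value_to_points(s0, v)
  for (c_mult in c(0.5, 2, 1024)) {  # powers of two: exact fp identity
    scaled <- nomo_model(
      dplyr::mutate(tibble::as_tibble(base), coef = coef * c_mult),
      intercept = model_intercept(base), threshold = model_threshold(base)
    )
    s1 <- build_point_scales(scaled)
    expect_identical(s1$max_points, s0$max_points)
    expect_identical(value_to_points(s1, v), p0)
  }
  for (c_mult in c(0.137, 3.9, 77)) {
    scaled <- nomo_model(
      dplyr::mutate(tibble::as_tibble(base), coef = coef * c_mult),
      intercept = model_intercept(base), threshold = model_threshold(base)
    )
    s1 <- build_point_scales(scaled)
    expect_equal(s1$max_points, s0$max_points, tolerance = 1e-12)
    expect_equal(value_to_points(s1, v), p0, tolerance = 1e-10)
  }
})

test_that("value_to_points is monotone with the coefficient sign", {
  for (seed in 1:10) {
    m <- random_model(d = 3, seed = seed, range_styles = c("unit", "wide"))
    s <- build_point_scales(m)
    grid <- purrr::map(seq_len(nrow(m)),
                       ~seq(m$min[.x], m$max[.x], length.out = 9))
    for (i in seq_len(nrow(m))) {
      pts <- purrr::map_dbl(grid[[i]], function(g) {
        v <- m$min; v[i] <- g
        value_to_points(s, v)[i]
      })
      d <- diff(pts)
      if (m$coef[i] > 0) expect_true(all(d > 0))
      if (m$coef[i] < 0) expect_true(all(d < 0))
      if (m$coef[i] == 0) expect_true(all(d == 0))
    }
  }
})

test_that("the initializer is the unique scale attaining p_max (up to ties)", {
  for (seed in 1:20) {
    m <- random_model(d = sample(2:6, 1), seed = seed)
    s <- build_point_scales(m, p_max = 80)
    at_max <- which(abs(s$max_points - 80) < 1e-12)
    expect_true(attr(s, "initializer") %in% at_max)
    expect_true(all(s$max_points <= 80 + 1e-12))
  }
})
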