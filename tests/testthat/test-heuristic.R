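test_that("bisector rasters cover the analytic special cases", {
  # horizontal pair -> vertical column through the midpoint
  r <- bisector_raster(c(0, 4), c(8, 4), 9, 9)
  expect_equal(sort(r$y), 0:8)
  expect_true(all(r$x == 4))

  # main-diagonal pair -> anti-diagonal through (2, 2)
  r2 <- bisector_raster(c(0, 0), c(4, 4), 5, 5)
  expect_true(any(r2$x == 2 & r2$y == 2))
  expect_equal(r2$x + r2$y, rep(4, nrow(r2)))

  # argument order does not matter
  r3 <- bisector_raster(c(4, 4), c(0, 0), 5, 5)
  expect_setequal(paste(r2$x, r2$y), paste(r3$x, r3$y))

  expect_error(bisector_raster(c(1, 1), c(1, 1), 5, 5),
               class = "symspike_degenerate_pair")
})

test_that("every raster point is nearly equidistant to the pair", {
  withr::local_seed(13)
  for (rep in 1:1000) {
    p <- random_points(2, 64, 64)
    r <- bisector_raster(c(p$x[1], p$y[1]), c(p$x[2], p$y[2]), 64, 64)
    if (nrow(r) == 0) next
    d1 <- sqrt((r$x - p$x[1])^2 + (r$y - p$y[1])^2)
    d2 <- sqrt((r$x - p$x[2])^2 + (r$y - p$y[2])^2)
    expect_lte(max(abs(d1 - d2)), 1)
  }
})

test_that("bisection density counts covering pairs", {
  pts <- data.frame(x = c(0, 8), y = c(4, 4))
  map <- bisection_density(pts, width = 9, height = 9)
  r <- bisector_raster(c(0, 4), c(8, 4), 9, 9)
  expect_equal(sum(map$value), nrow(r))
  expect_true(all(map$value[map$x == 4] == 1))

  # three non-collinear points: three bisectors, circumcenter up to 3
  tri <- data.frame(x = c(1, 9, 5), y = c(2, 2, 9))
  map3 <- bisection_density(tri, width = 11, height = 11)
  rasters <- list(
    bisector_raster(c(1, 2), c(9, 2), 11, 11),
    bisector_raster(c(1, 2), c(5, 9), 11, 11),
    bisector_raster(c(9, 2), c(5, 9), 11, 11)
  )
  acc <- matrix(0, 11, 11)
  for (r in rasters) acc[cbind(r$y + 1, r$x + 1)] <- acc[cbind(r$y + 1, r$x + 1)] + 1
  expect_equal(map_as_matrix(map3), acc, ignore_attr = TRUE)
  expect_lte(max(map3$value), 3)

  expect_error(bisection_density(data.frame(x = 1, y = 1), width = 5, height = 5),
               class = "symspike_insufficient_input")
})

test_that("the distance limit filters pairs in the exact variant", {
  pts <- data.frame(x = c(0, 2, 10), y = c(0, 0, 0))
  full <- bisection_density(pts, width = 12, height = 3)
  limited <- bisection_density(pts, width = 12, height = 3, dist_limit = 3)
  # only the (0,0)-(2,0) pair survives the limit
  expect_equal(sum(limited$value), nrow(bisector_raster(c(0, 0), c(2, 0), 12, 3)))
  expect_lte(sum(limited$value), sum(full$value))
})

test_that("the threshold point array fills every slot and keeps every point", {
  pts <- data.frame(x = c(1, 3, 5, 7, 9), y = c(1, 2, 3, 4, 5))
  for (seed in 1:10) {
    tpa <- threshold_point_array(pts, M = 20, K = 2, seed = seed)
    expect_false(any(is.na(tpa$slots)))
    expect_setequal(unique(tpa$slots), 1:5)
  }
  t1 <- threshold_point_array(pts, M = 20, K = 2, seed = 1)
  t2 <- threshold_point_array(pts, M = 20, K = 2, seed = 1)
  expect_identical(t1$slots, t2$slots)
})

test_that("randomized midpoints land on the rounded pair midpoints only", {
  pts <- data.frame(x = c(2, 7), y = c(2, 5))
  map <- randomized_midpoint_density(pts, n_draws = 500, seed = 5,
                                     width = 10, height = 10)
  nz <- map[map$value > 0, ]
  expect_equal(nrow(nz), 1)
  expect_equal(c(nz$x, nz$y), c(5, 4))  # ((2+7)/2, (2+5)/2) rounded half-away
  expect_equal(sum(map$value), attr(map, "n_increments"))

  zero <- randomized_midpoint_density(pts, n_draws = 0, width = 10, height = 10)
  expect_true(all(zero$value == 0))

  expect_error(
    randomized_midpoint_density(data.frame(x = integer(), y = integer()),
                                n_draws = 10, width = 5, height = 5),
    class = "symspike_empty_input"
  )
})

test_that("the heuristic is reproducible and respects the distance limit", {
  pts <- data.frame(x = c(1, 4, 9, 2), y = c(1, 6, 1, 9))
  a <- randomized_midpoint_density(pts, n_draws = 2000, seed = 11,
                                   width = 12, height = 12)
  b <- randomized_midpoint_density(pts, n_draws = 2000, seed = 11,
                                   width = 12, height = 12)
  expect_equal(a$value, b$value)
  lim <- randomized_midpoint_density(pts, n_draws = 2000, seed = 11,
                                     dist_limit = 6, width = 12, height = 12)
  # all surviving increments stem from pairs within the limit
  pairs <- t(combn(4, 2))
  d <- sqrt((pts$x[pairs[, 1]] - pts$x[pairs[, 2]])^2 +
              (pts$y[pairs[, 1]] - pts$y[pairs[, 2]])^2)
  ok_mid <- unique(data.frame(
    x = round_half_away((pts$x[pairs[d <= 6, 1]] + pts$x[pairs[d <= 6, 2]]) / 2),
    y = round_half_away((pts$y[pairs[d <= 6, 1]] + pts$y[pairs[d <= 6, 2]]) / 2)
  ))
  nz <- lim[lim$value > 0, c("x", "y")]
  expect_true(all(paste(nz$x, nz$y) %in% paste(ok_mid$x, ok_mid$y)))
})

test_that("midpoints lie on the corresponding bisector rasters", {
  withr::local_seed(19)
  for (rep in 1:50) {
    p <- random_points(2, 32, 32)
    r <- bisector_raster(c(p$x[1], p$y[1]), c(p$x[2], p$y[2]), 32, 32)
    mx <- round_half_away((p$x[1] + p$x[2]) / 2)
    my <- round_half_away((p$y[1] + p$y[2]) / 2)
    # the rounded midpoint is within one pixel of the raster
    if (nrow(r)) {
      expect_lte(min(abs(r$x - mx) + abs(r$y - my)), 1)
    }
  }
})

test_that("the normalized heuristic converges to the slot-pair distribution", {
  pts <- data.frame(x = c(2, 12, 7, 3, 11), y = c(2, 2, 7, 11, 12))
  map <- randomized_midpoint_density(pts, n_draws = 1e5, seed = 2,
                                     width = 15, height = 15)
  tpa <- attr(map, "point_array")
  exact <- brute_midpoint_distribution(tpa, 15, 15)
  tv <- 0.5 * sum(abs(map_as_matrix(map) / 1e5 - exact))
  expect_lt(tv, 0.05)
})
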