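#' Rasterize the perpendicular bisector of a point pair
#'
#' A Bresenham-style line walk with the slope inverted (negative
#' reciprocal): instead of drawing the line between the two points it draws
#' the line bisecting them, anchored at the pair midpoint and extended to
#' the domain boundary in both directions. The raster is 8-connected and
#' ordered along its major axis; every raster point r satisfies
#' `|d(r, p1) - d(r, p2)| <= 1` pixel (Euclidean), since each raster point
#' lies within half a pixel of the true bisector.
#'
#' @param p1,p2 distinct grid points (`c(x, y)` or single-row data frames).
#' @param width,height domain bounds in pixels.
#' @return tibble of raster points `x`, `y` (0-based), ordered.
#' @examples
#' bisector_raster(c(0, 4), c(8, 4), 9, 9)  # the column x = 4
#' @export
bisector_raster <- function(p1, p2, width, height) {
  p1 <- as_xy(p1); p2 <- as_xy(p2)
  if (all(p1 == p2)) stop_symspike("bisector of a degenerate pair", "degenerate_pair")
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  mx <- (p1[1] + p2[1]) / 2; my <- (p1[2] + p2[2]) / 2
  # perpendicular direction: slope inverted, (-dy, dx)
  vx <- -dy; vy <- dx
  if (abs(vx) >= abs(vy)) {
    # major axis x: walk every column, minor y follows the inverted slope
    xs <- 0:(width - 1)
    ys <- round_half_away(my + (xs - mx) * vy / vx)
    keep <- ys >= 0 & ys <= height - 1
    out <- tibble(x = as.integer(xs[keep]), y = as.integer(ys[keep]))
  } else {
    ys <- 0:(height - 1)
    xs <- round_half_away(mx + (ys - my) * vx / vy)
    keep <- xs >= 0 & xs <= width - 1
    out <- tibble(x = as.integer(xs[keep]), y = as.integer(ys[keep]))
  }
  out
}

#' Exact bisection-line density (all-pairs)
#'
#' The GPU-tailored exact variant: every unordered pair of above-threshold
#' points votes for the full raster of its perpendicular bisector; the
#' output value at a pixel is the number of pairs whose bisector covers it.
#' Deterministic. Pairs farther apart than `dist_limit` are skipped
#' (a priori scale selection).
#'
#' @param field a [scalar_field()] (e.g. an edge-magnitude map), or a point
#'   set data frame used as-is.
#' @param threshold point-extraction cutoff (strict), ignored for point
#'   input.
#' @param dist_limit optional maximum pair distance in pixels (Euclidean).
#' @param width,height output domain; default to the field dimensions.
#' @return a `symmetry_map` of bisector counts.
#' @export
bisection_density <- function(field, threshold = 128, dist_limit = NULL,
                              width = NULL, height = NULL) {
  if (is.data.frame(field)) {
    pts <- as_point_tbl(field)
    if (is.null(width) || is.null(height)) {
      stop_symspike("width and height are required for point input", "invalid_input")
    }
  } else {
    pts <- extract_points(field, threshold)
    width <- width %||% ncol(field)
    height <- height %||% nrow(field)
  }
  n <- nrow(pts)
  if (n < 2) stop_symspike("need at least 2 above-threshold points", "insufficient_input")
  acc <- matrix(0, nrow = height, ncol = width)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.null(dist_limit)) {
        d <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
        if (d > dist_limit) next
      }
      r <- bisector_raster(c(pts$x[i], pts$y[i]), c(pts$x[j], pts$y[j]),
                           width, height)
      if (nrow(r)) {
        idx <- cbind(r$y + 1, r$x + 1)
        acc[idx] <- acc[idx] + 1
      }
    }
  }
  map <- new_symmetry_map(acc, source = "bisection")
  attr(map, "config") <- list(threshold = threshold, dist_limit = dist_limit)
  map
}

#' Fixed-length threshold point array
#'
#' Lock-free GPU slot filling, reproduced sequentially: over `K` passes,
#' every source point writes its index into a uniformly random slot of an
#' `M`-slot array (later writes overwrite earlier ones). Slots still empty
#' afterwards are filled by a final sequential sweep through the point list,
#' so every slot holds some above-threshold point. Any source point that was
#' completely overwritten is re-inserted at a seeded random slot so each
#' point keeps multiplicity >= 1.
#'
#' @param points point set (data frame with `x`, `y`).
#' @param M array capacity (slots).
#' @param K write passes per point.
#' @param seed RNG seed; filling is deterministic given it.
#' @return a `threshold_point_array`: list with `slots` (integer point index
#'   per slot), `points`, `M`, `K`, `seed`.
#' @export
threshold_point_array <- function(points, M, K = 2, seed = 1L) {
  pts <- as_point_tbl(points, allow_empty = FALSE)
  n <- nrow(pts)
  if (M < 1 || K < 1) stop_symspike("M and K must be >= 1", "invalid_input")
  slots <- with_seed(seed, {
    s <- rep(NA_integer_, M)
    for (pass in seq_len(K)) {
      idx <- sample.int(M, n, replace = TRUE)
      s[idx] <- seq_len(n)
    }
    empty <- which(is.na(s))
    if (length(empty)) s[empty] <- rep_len(seq_len(n), length(empty))
    missing <- setdiff(seq_len(n), unique(s))
    if (length(missing)) s[sample.int(M, length(missing))] <- missing
    s
  })
  structure(list(slots = slots, points = pts, M = as.integer(M),
                 K = as.integer(K), seed = as.integer(seed)),
            class = "threshold_point_array")
}

#' Randomized midpoint density (mutex-free heuristic)
#'
#' The simplified GPU variant: `n_draws` iterations each draw two slots of
#' the threshold point array, skip the draw if both slots hold the same
#' point or the pair is farther apart than `dist_limit`, and otherwise
#' increment the pair's rounded midpoint (half-away-from-zero per
#' coordinate). Normalized by the number of draws, the map converges to the
#' exact pair-midpoint distribution induced by the slot multiplicities.
#' Sequential semantics; deterministic given `seed`. The satellite-image
#' experiment ran this with threshold 128, `dist_limit = 50` px and
#' `n_draws = 177828`.
#'
#' @inheritParams bisection_density
#' @param M slot capacity; defaults to 4x the number of points.
#' @param K write passes for the slot filling.
#' @param n_draws number of iterations N (>= 0; 0 gives an all-zero map).
#' @param seed RNG seed covering slot filling and draws.
#' @return a `symmetry_map` of midpoint counts; attribute `n_increments`
#'   counts the draws that survived the skip rules.
#' @export
randomized_midpoint_density <- function(field, threshold = 128,
                                        dist_limit = NULL,
                                        M = NULL, K = 2, n_draws = 177828,
                                        seed = 1L,
                                        width = NULL, height = NULL) {
  if (is.data.frame(field)) {
    pts <- as_point_tbl(field)
    if (is.null(width) || is.null(height)) {
      stop_symspike("width and height are required for point input", "invalid_input")
    }
  } else {
    pts <- extract_points(field, threshold)
    width <- width %||% ncol(field)
    height <- height %||% nrow(field)
  }
  if (nrow(pts) == 0) stop_symspike("no above-threshold points", "empty_input")
  if (n_draws < 0) stop_symspike("n_draws must be >= 0", "invalid_input")
  M <- M %||% max(4L * nrow(pts), 8L)
  tpa <- threshold_point_array(pts, M, K, seed)
  acc <- matrix(0, nrow = height, ncol = width)
  n_inc <- 0L
  if (n_draws > 0) {
    draws <- with_seed(seed + 1L, {
      list(a = sample.int(M, n_draws, replace = TRUE),
           b = sample.int(M, n_draws, replace = TRUE))
    })
    ia <- tpa$slots[draws$a]
    ib <- tpa$slots[draws$b]
    valid <- !(pts$x[ia] == pts$x[ib] & pts$y[ia] == pts$y[ib])
    if (!is.null(dist_limit)) {
      d <- sqrt((pts$x[ia] - pts$x[ib])^2 + (pts$y[ia] - pts$y[ib])^2)
      valid <- valid & d <= dist_limit
    }
    ia <- ia[valid]; ib <- ib[valid]
    if (length(ia)) {
      mxs <- round_half_away((pts$x[ia] + pts$x[ib]) / 2)
      mys <- round_half_away((pts$y[ia] + pts$y[ib]) / 2)
      cell <- mys * width + mxs + 1
      counts <- tabulate(cell, nbins = width * height)
      acc <- acc + matrix(counts, nrow = height, ncol = width, byrow = TRUE)
      n_inc <- length(ia)
    }
  }
  map <- new_symmetry_map(acc, source = "randomized-midpoint")
  attr(map, "config") <- list(threshold = threshold, dist_limit = dist_limit,
                              M = M, K = K, n_draws = n_draws, seed = seed)
  attr(map, "n_increments") <- n_inc
  attr(map, "point_array") <- tpa
  map
}
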