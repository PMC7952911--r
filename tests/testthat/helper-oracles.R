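# Independent brute-force oracles, deliberately written with naive loops and
# base-R tabulation so they share no code path with the package internals.

# distance-histogram mode count at every grid point, by direct enumeration
brute_density <- function(points, width, height, metric = "euclidean",
                          decimals = 1, limit = NULL) {
  half_away <- function(v, dg) sign(v) * floor(abs(v) * 10^dg + 0.5) / 10^dg
  vals <- matrix(0, nrow = height, ncol = width)
  for (yy in 0:(height - 1)) {
    for (xx in 0:(width - 1)) {
      labs <- character(0)
      for (i in seq_len(nrow(points))) {
        dx <- points$x[i] - xx
        dy <- points$y[i] - yy
        d <- if (metric == "euclidean") sqrt(dx^2 + dy^2) else abs(dx) + abs(dy)
        if (!is.null(limit) && d > limit) next
        labs <- c(labs, sprintf("%.6f", half_away(d, decimals)))
      }
      vals[yy + 1, xx + 1] <- if (length(labs)) max(table(labs)) else 0
    }
  }
  vals
}

# the equidistant set of a point pair on a grid, by direct evaluation
brute_equidistant <- function(a, b, width, height, metric = "manhattan") {
  g <- expand.grid(x = 0:(width - 1), y = 0:(height - 1))
  d <- function(p, q) {
    if (metric == "euclidean") sqrt((p[1] - q$x)^2 + (p[2] - q$y)^2)
    else abs(p[1] - q$x) + abs(p[2] - q$y)
  }
  g[d(a, g) == d(b, g), c("x", "y")]
}

# exact per-draw increment distribution of the randomized midpoint sampler
# given the slot contents (skip outcomes carry no mass on either side)
brute_midpoint_distribution <- function(tpa, width, height, limit = NULL) {
  half_away <- function(v) sign(v) * floor(abs(v) + 0.5)
  M <- tpa$M
  pts <- tpa$points
  p <- matrix(0, nrow = height, ncol = width)
  for (s1 in seq_len(M)) {
    for (s2 in seq_len(M)) {
      i <- tpa$slots[s1]; j <- tpa$slots[s2]
      if (pts$x[i] == pts$x[j] && pts$y[i] == pts$y[j]) next
      if (!is.null(limit)) {
        d <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
        if (d > limit) next
      }
      mx <- half_away((pts$x[i] + pts$x[j]) / 2)
      my <- half_away((pts$y[i] + pts$y[j]) / 2)
      p[my + 1, mx + 1] <- p[my + 1, mx + 1] + 1 / M^2
    }
  }
  p
}

# reflect a density-map matrix across the vertical midline
reflect_cols <- function(m) m[, ncol(m):1, drop = FALSE]

# random point set on a grid (unique points), for property loops
random_points <- function(n, width, height) {
  idx <- sample.int(width * height, n)
  data.frame(x = (idx - 1) %% width, y = (idx - 1) %/% width)
}
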