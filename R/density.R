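#' Density computation settings
#'
#' Bundles the tunable parameters of the distance-histogram symmetry-density
#' algorithm.
#'
#' @param metric distance metric, `"euclidean"` or `"manhattan"`.
#' @param decimals binning precision (decimal places of distance rounding).
#'   `decimals = 0` bins on whole pixels, which is exactly the integer-cycle
#'   binning of the delay-line spiking network.
#' @param input_threshold pixel cutoff for [extract_points()].
#' @param weighting `"binary"` counts each contribution as 1;
#'   `"pixel_value"` accumulates the source-point weight instead.
#' @param distance_limit optional maximum distance in pixels; point
#'   contributions farther than this are skipped (scale selection).
#' @param distance_noise_sd optional Gaussian sd added to each point-pair
#'   distance before binning (noise relaxes strict coincidence).
#' @param rng_seed seed for the distance noise; ignored when
#'   `distance_noise_sd` is 0 or `NULL`.
#' @return a `density_config` list.
#' @export
density_config <- function(metric = c("euclidean", "manhattan"),
                           decimals = 1,
                           input_threshold = 0,
                           weighting = c("binary", "pixel_value"),
                           distance_limit = NULL,
                           distance_noise_sd = NULL,
                           rng_seed = 1L) {
  metric <- arg_match(metric)
  weighting <- arg_match(weighting)
  if (!is.null(distance_limit) && distance_limit <= 0) {
    stop_symspike("distance_limit must be positive when set", "invalid_input")
  }
  if (!is.null(distance_noise_sd) && distance_noise_sd < 0) {
    stop_symspike("distance_noise_sd must be >= 0", "invalid_input")
  }
  structure(
    list(metric = metric, decimals = decimals,
         input_threshold = input_threshold, weighting = weighting,
         distance_limit = distance_limit,
         distance_noise_sd = distance_noise_sd,
         rng_seed = as.integer(rng_seed)),
    class = "density_config"
  )
}

# internal: symmetry_map constructor from a value matrix (height x width)
new_symmetry_map <- function(values, config = NULL, source = "histogram") {
  h <- nrow(values); w <- ncol(values)
  out <- tibble(
    x = rep(0:(w - 1), times = h),
    y = rep(0:(h - 1), each = w),
    value = as.vector(t(values))
  )
  structure(out,
            class = c("symmetry_map", class(out)),
            width = w, height = h, config = config, source = source)
}

#' @export
print.symmetry_map <- function(x, ...) {
  cat(sprintf("<symmetry_map %d x %d px (%s), max %g>\n",
              attr(x, "width"), attr(x, "height"),
              attr(x, "source") %||% "histogram", max(x$value)))
  NextMethod()
}

#' Matrix view of a symmetry map
#'
#' @param map a `symmetry_map` (tibble with `x`, `y`, `value`).
#' @return numeric matrix with `height` rows and `width` columns.
#' @export
map_as_matrix <- function(map) {
  w <- attr(map, "width") %||% (max(map$x) + 1)
  h <- attr(map, "height") %||% (max(map$y) + 1)
  m <- matrix(0, nrow = h, ncol = w)
  m[cbind(map$y + 1, map$x + 1)] <- map$value
  m
}

# internal: binned-distance contributions from `points` to a set of probe
# locations; returns list(keys = m x n integer matrix, w = weights, keep =
# logical matrix of surviving contributions)
density_contributions <- function(gx, gy, points, config) {
  d <- distance_matrix(gx, gy, points$x, points$y, config$metric)
  keep <- NULL
  if (!is.null(config$distance_limit)) keep <- d <= config$distance_limit
  sd <- config$distance_noise_sd %||% 0
  if (sd > 0) {
    noise <- with_seed(config$rng_seed, rnorm(length(d), 0, sd))
    d <- pmax(0, d + noise)
  }
  list(keys = matrix(bin_keys(d, config$decimals), nrow = length(gx)),
       keep = keep)
}

# internal: mode (peak accumulated weight) of one row of contributions
row_mode <- function(keys, w, binary) {
  if (length(keys) == 0) return(0)
  if (binary && all(w == 1)) return(max(tabulate(keys + 1L)))
  max(vapply(split(w, keys), sum, numeric(1)))
}

#' Distance histogram at one probe point
#'
#' The histogram of binned distances from probe point `p` to every input
#' point: the discrete form of the contour integral of the image surface on
#' circles around `p`. Its peak (`mode_count`) is the symmetry density at
#' `p`. One contribution is accumulated per input point (weight 1, or the
#' point weight under `"pixel_value"` weighting); contributions beyond
#' `distance_limit` are skipped; optional Gaussian distance noise is applied
#' before binning.
#'
#' @param p probe point, `c(x, y)` or a single-row data frame.
#' @param points point set (data frame with `x`, `y`, optional `weight`).
#' @param config a [density_config()].
#' @return tibble with columns `bin` (label), `distance` (bin value) and
#'   `count`, sorted by distance; attribute `mode_count` holds the peak.
#' @examples
#' distance_histogram(c(0, 0), data.frame(x = 5, y = 4))
#' @export
distance_histogram <- function(p, points, config = density_config()) {
  points <- as_point_tbl(points, allow_empty = FALSE)
  p <- as_xy(p)
  contrib <- density_contributions(p[1], p[2], points, config)
  keys <- contrib$keys[1, ]
  w <- if (config$weighting == "pixel_value") points$weight else rep(1, nrow(points))
  if (!is.null(contrib$keep)) {
    keys <- keys[contrib$keep[1, ]]
    w <- w[contrib$keep[1, ]]
  }
  counts <- vapply(split(w, keys), sum, numeric(1))
  key_vals <- as.integer(names(counts))
  out <- tibble(
    bin = key_to_label(key_vals, config$decimals),
    distance = key_vals / 10^config$decimals,
    count = as.numeric(counts)
  )
  out <- out[order(out$distance), ]
  structure(out, class = c("distance_histogram", class(out)),
            mode_count = if (nrow(out)) max(out$count) else 0,
            config = config)
}

#' @rdname distance_histogram
#' @param histogram a `distance_histogram`.
#' @export
mode_count <- function(histogram) attr(histogram, "mode_count")

#' Mirror-symmetry density of a point set
#'
#' For every grid point p of the `width` x `height` output domain, the
#' density value is the peak of the histogram of binned distances from p to
#' all input points. Loci equidistant from many point pairs — perpendicular
#' bisectors, centers of symmetric figures — accumulate many contributions in
#' one bin and stand out. Cost is O(m n) for m domain points and n input
#' points.
#'
#' @param points point set: data frame with integer columns `x`, `y`
#'   (0-based, origin top-left) and optional `weight`.
#' @param width,height output domain size in pixels.
#' @param config a [density_config()].
#' @return a `symmetry_map`: tibble with `x`, `y`, `value` (row-major) and
#'   attributes `width`, `height`, `config`. Unweighted values lie in
#'   `[0, nrow(points)]`.
#' @examples
#' corners <- data.frame(x = c(0, 8, 0, 8), y = c(0, 0, 8, 8))
#' m <- symmetry_density(corners, 9, 9)
#' m[m$value == max(m$value), ]  # the center
#' @export
symmetry_density <- function(points, width, height, config = density_config()) {
  points <- as_point_tbl(points, allow_empty = FALSE)
  m <- width * height
  gx <- rep(0:(width - 1), times = height)
  gy <- rep(0:(height - 1), each = width)
  contrib <- density_contributions(gx, gy, points, config)
  w <- if (config$weighting == "pixel_value") points$weight else rep(1, nrow(points))
  binary <- config$weighting == "binary"
  vals <- vapply(seq_len(m), function(i) {
    keys <- contrib$keys[i, ]
    wi <- w
    if (!is.null(contrib$keep)) {
      sel <- contrib$keep[i, ]
      keys <- keys[sel]; wi <- w[sel]
    }
    row_mode(keys, wi, binary)
  }, numeric(1))
  new_symmetry_map(matrix(vals, nrow = height, ncol = width, byrow = TRUE),
                   config = config)
}

#' Iterated (hierarchical) symmetry density
#'
#' Applies the density repeatedly: after each pass, grid points whose density
#' exceeds `feedback_threshold` are unioned with the original point set and
#' the density is recomputed. Symmetries between input points and previously
#' found symmetry points emerge, producing fractal-like hierarchies.
#'
#' @inheritParams symmetry_density
#' @param iterations number of passes k (>= 1); `k = 1` is plain
#'   [symmetry_density()].
#' @param feedback_threshold density cutoff for feeding a grid point back;
#'   defaults to the mean of the current map (recomputed each pass).
#' @return the k-th `symmetry_map`.
#' @export
iterate_density <- function(points, width, height, config = density_config(),
                            iterations = 1, feedback_threshold = NULL) {
  if (iterations < 1) stop_symspike("iterations must be >= 1", "invalid_input")
  original <- as_point_tbl(points, allow_empty = FALSE)
  current <- original
  map <- symmetry_density(current, width, height, config)
  if (iterations == 1) return(map)
  for (i in seq_len(iterations - 1)) {
    thr <- feedback_threshold %||% mean(map$value)
    fed <- map[map$value > thr, c("x", "y")]
    fed$weight <- 1
    current <- distinct(bind_rows(original[, c("x", "y", "weight")], fed),
                        .data$x, .data$y, .keep_all = TRUE)
    map <- symmetry_density(current, width, height, config)
  }
  map
}

#' Mean squared error between two density maps
#'
#' @param a,b `symmetry_map`s over identical domains.
#' @return mean over pixels of the squared value difference.
#' @export
density_mse <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(attr(a, "width"), attr(b, "width")) ||
      !identical(attr(a, "height"), attr(b, "height"))) {
    stop_symspike("density maps must share dimensions", "invalid_input")
  }
  mean((a$value - b$value)^2)
}
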