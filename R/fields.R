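#' Scalar fields on a pixel grid
#'
#' A `scalar_field` is a non-negative real surface S(x, y) sampled on a
#' `width` x `height` pixel grid: an image channel, an edge-magnitude map, or
#' a symmetry-density output. It is stored as a numeric matrix with `height`
#' rows and `width` columns; the pixel at 0-based column `x`, row `y` (origin
#' top-left, raster convention) is `values[y + 1, x + 1]`.
#'
#' @param values numeric matrix (rows = height, cols = width) or a vector of
#'   `width * height` values in row-major order (x fastest), all >= 0.
#' @param width,height grid dimensions in pixels; inferred when `values` is a
#'   matrix.
#' @return A `scalar_field` object (numeric matrix subclass).
#' @examples
#' f <- scalar_field(matrix(0, 4, 4))
#' field_dims(f)
#' @export
scalar_field <- function(values, width = NULL, height = NULL) {
  if (is.matrix(values)) {
    m <- values
  } else {
    if (is.null(width) || is.null(height)) {
      stop_symspike("width and height are required for vector input", "invalid_input")
    }
    if (length(values) != width * height) {
      stop_symspike("values must have exactly width * height entries", "invalid_input")
    }
    m <- matrix(values, nrow = height, ncol = width, byrow = TRUE)
  }
  if (length(m) == 0) stop_symspike("field must be non-empty", "invalid_input")
  if (any(m < 0)) stop_symspike("field values must be non-negative", "invalid_input")
  storage.mode(m) <- "double"
  class(m) <- c("scalar_field", class(matrix()))
  m
}

#' @rdname scalar_field
#' @param field a `scalar_field`.
#' @export
field_dims <- function(field) {
  c(width = ncol(field), height = nrow(field))
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field %d x %d px, range [%g, %g]>\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

#' Convert a scalar field to / from a tidy pixel table
#'
#' The tidy form has one row per pixel with 0-based integer coordinates
#' (`x` = column, `y` = row, origin top-left) and the pixel `value`, in
#' row-major order.
#'
#' @param field a [scalar_field()].
#' @return `field_as_tibble()`: a tibble with columns `x`, `y`, `value`.
#' @export
field_as_tibble <- function(field) {
  w <- ncol(field); h <- nrow(field)
  tibble(
    x = rep(0:(w - 1), times = h),
    y = rep(0:(h - 1), each = w),
    value = as.vector(t(unclass(field)))
  )
}

#' @rdname field_as_tibble
#' @param df data frame with columns `x`, `y`, `value` covering the full grid.
#' @param width,height grid dimensions; default to `max + 1` of the coordinates.
#' @return `field_from_tibble()`: a [scalar_field()].
#' @export
field_from_tibble <- function(df, width = max(df$x) + 1, height = max(df$y) + 1) {
  m <- matrix(0, nrow = height, ncol = width)
  m[cbind(df$y + 1, df$x + 1)] <- df$value
  scalar_field(m)
}

#' Extract above-threshold points from a field
#'
#' Returns every grid point whose value is strictly greater than
#' `input_threshold`, in row-major order. This is the point-extraction step of
#' the density algorithm; in the spiking view it is the activation threshold
#' of the input-layer neurons. With `weighting = "pixel_value"` the pixel
#' values are carried along as per-point weights for the weighted density
#' variant.
#'
#' @param field a [scalar_field()].
#' @param input_threshold pixel cutoff; points must exceed it strictly.
#'   The satellite-image experiment uses 128 on 0-255 edge magnitudes.
#' @param weighting `"binary"` (weight 1 per point) or `"pixel_value"`.
#' @return A tibble with columns `x`, `y`, `weight` (a point set). An empty
#'   result is valid.
#' @examples
#' f <- scalar_field(matrix(c(0, 200, 0, 0), 2, 2))
#' extract_points(f, 128)
#' @export
extract_points <- function(field, input_threshold = 0,
                           weighting = c("binary", "pixel_value")) {
  weighting <- arg_match(weighting)
  px <- field_as_tibble(field)
  px <- px[px$value > input_threshold, , drop = FALSE]
  tibble(
    x = as.integer(px$x),
    y = as.integer(px$y),
    weight = if (weighting == "pixel_value") px$value else rep(1, nrow(px))
  )
}

# internal: validate/coerce a point-set data frame, add unit weights
as_point_tbl <- function(points, allow_empty = TRUE) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    stop_symspike("points must be a data frame with columns x and y", "invalid_input")
  }
  if (!allow_empty && nrow(points) == 0) {
    stop_symspike("point set is empty", "empty_input")
  }
  w <- if ("weight" %in% names(points)) points$weight else rep(1, nrow(points))
  if (any(w < 0)) stop_symspike("point weights must be non-negative", "invalid_input")
  tibble(x = as.integer(points$x), y = as.integer(points$y), weight = as.numeric(w))
}

# internal: reflect points across the vertical midline of a width-wide domain
mirror_points <- function(points, width) {
  points$x <- as.integer(width - 1L - points$x)
  points
}
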