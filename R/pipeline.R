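#' Read an image as a scalar field
#'
#' Reads PNG, TIFF or JPEG-free formats supported by the png/tiff readers,
#' keeps the first channel of multi-channel images, and scales intensities
#' to 0-255.
#'
#' @param path image file (.png, .tif/.tiff).
#' @return a [scalar_field()] with values in 0-255.
#' @export
read_image_field <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_symspike(paste0("unsupported image format: .", ext), "invalid_input")
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  scalar_field(img * 255)
}

#' Sobel-Feldman edge magnitude
#'
#' Convolves the image with the standard 3x3 Sobel-Feldman kernels and
#' returns the gradient magnitude `sqrt(gx^2 + gy^2)`. Borders are handled
#' by reflect padding, so a constant image maps to an all-zero edge map and
#' an interior vertical step of height h responds with 4h along the edge.
#'
#' @param image a [scalar_field()] (single channel).
#' @return a [scalar_field()] of edge magnitudes.
#' @export
sobel_edges <- function(image) {
  if (length(image) == 0) stop_symspike("empty image", "invalid_input")
  m <- unclass(image)
  h <- nrow(m); w <- ncol(m)
  # reflect padding by one pixel
  ri <- c(1, seq_len(h), h)
  ci <- c(1, seq_len(w), w)
  p <- m[ri, ci, drop = FALSE]
  sh <- function(dr, dc) p[(1 + dr):(h + dr), (1 + dc):(w + dc), drop = FALSE]
  # Sobel kernels: gx = [-1 0 1; -2 0 2; -1 0 1], gy = t(gx)
  gx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) - (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  gy <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) - (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  scalar_field(sqrt(gx^2 + gy^2))
}

#' Run the image symmetry-density experiment
#'
#' The end-to-end pipeline used on satellite tiles: first channel ->
#' Sobel-Feldman edges -> above-threshold point extraction -> symmetry
#' density, with either the exact all-pairs bisection variant or the
#' randomized midpoint heuristic. The configuration and seed are recorded in
#' the output metadata. The reference configuration is threshold 128,
#' distance limit 50 px and 177828 heuristic draws.
#'
#' @param image a [scalar_field()] or an image file path.
#' @param threshold edge-magnitude cutoff for point extraction.
#' @param dist_limit maximum pair distance in pixels.
#' @param n_draws heuristic iteration count (ignored by `"exact"`).
#' @param algorithm `"heuristic"` (randomized midpoints) or `"exact"`
#'   (all-pairs bisector rasters).
#' @param seed RNG seed for the heuristic.
#' @param M,K heuristic slot-array parameters, see
#'   [randomized_midpoint_density()].
#' @return a `symmetry_map`; `attr(, "config")` round-trips the settings.
#' @export
run_experiment <- function(image, threshold = 128, dist_limit = 50,
                           n_draws = 177828,
                           algorithm = c("heuristic", "exact"),
                           seed = 1L, M = NULL, K = 2) {
  algorithm <- arg_match(algorithm)
  if (is.character(image)) image <- read_image_field(image)
  edges <- sobel_edges(image)
  map <- if (algorithm == "heuristic") {
    randomized_midpoint_density(edges, threshold = threshold,
                                dist_limit = dist_limit, M = M, K = K,
                                n_draws = n_draws, seed = seed)
  } else {
    bisection_density(edges, threshold = threshold, dist_limit = dist_limit)
  }
  attr(map, "config") <- list(threshold = threshold, dist_limit = dist_limit,
                              n_draws = n_draws, algorithm = algorithm,
                              seed = seed)
  map
}

#' Polygon region annotation
#'
#' Closed, non-self-intersecting vertex rings in pixel coordinates, e.g.
#' building footprints on a tile.
#'
#' @param polygons list of data frames / matrices with `x`, `y` vertex
#'   columns; rings are closed (first vertex repeated last) — an open ring
#'   is closed automatically.
#' @param labels optional character labels, recycled.
#' @return a `region_annotation` list.
#' @export
region_annotation <- function(polygons, labels = NULL) {
  polygons <- map(polygons, function(p) {
    p <- as.data.frame(p)
    if (is.null(names(p)) || !all(c("x", "y") %in% names(p))) {
      names(p)[1:2] <- c("x", "y")
    }
    v <- nrow(p)
    if (v < 3) stop_symspike("polygon rings need at least 3 vertices", "invalid_annotation")
    if (p$x[1] != p$x[v] || p$y[1] != p$y[v]) p <- rbind(p, p[1, ])
    if (ring_self_intersects(p)) {
      stop_symspike("polygon ring is self-intersecting", "invalid_annotation")
    }
    p[, c("x", "y")]
  })
  labels <- labels %||% paste0("region_", seq_along(polygons))
  structure(list(polygons = polygons,
                 labels = rep_len(labels, length(polygons))),
            class = "region_annotation")
}

# internal: proper-crossing test between non-adjacent edges (even-odd rings)
ring_self_intersects <- function(p) {
  n <- nrow(p) - 1
  if (n < 4) return(FALSE)
  seg <- cbind(p$x[1:n], p$y[1:n], p$x[2:(n + 1)], p$y[2:(n + 1)])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      d1 <- cross(seg[i, 3] - seg[i, 1], seg[i, 4] - seg[i, 2],
                  seg[j, 1] - seg[i, 1], seg[j, 2] - seg[i, 2])
      d2 <- cross(seg[i, 3] - seg[i, 1], seg[i, 4] - seg[i, 2],
                  seg[j, 3] - seg[i, 1], seg[j, 4] - seg[i, 2])
      d3 <- cross(seg[j, 3] - seg[j, 1], seg[j, 4] - seg[j, 2],
                  seg[i, 1] - seg[j, 1], seg[i, 2] - seg[j, 2])
      d4 <- cross(seg[j, 3] - seg[j, 1], seg[j, 4] - seg[j, 2],
                  seg[i, 3] - seg[j, 1], seg[i, 4] - seg[j, 2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Region statistics of a density map
#'
#' Mean density inside each polygon region (pixels whose centers fall inside
#' the ring, even-odd rule) against the whole-image mean: human-made
#' structures are expected to exceed the image mean. The pooled statistic
#' aggregates all region pixels of the image, matching the per-image
#' building-area comparison.
#'
#' @param density a `symmetry_map`.
#' @param regions a [region_annotation()] (or list of polygons coerced to
#'   one).
#' @return a `region_stats` tibble with columns `region_id`, `label`,
#'   `n_pixels`, `region_mean`, `image_mean`, `exceeds`; attributes
#'   `fraction_exceeding` (share of regions above the image mean, strict),
#'   `pooled_region_mean` and `pooled_exceeds`. With zero regions the
#'   fractions are `NA` (not applicable).
#' @export
region_stats <- function(density, regions) {
  if (!inherits(regions, "region_annotation")) regions <- region_annotation(regions)
  w <- attr(density, "width"); h <- attr(density, "height")
  img_mean <- mean(density$value)
  centers <- cbind(density$x, density$y)
  res <- vector("list", length(regions$polygons))
  pooled <- logical(nrow(density))
  for (i in seq_along(regions$polygons)) {
    poly <- regions$polygons[[i]]
    if (any(poly$x < -0.5 | poly$x > w - 0.5 | poly$y < -0.5 | poly$y > h - 0.5)) {
      stop_symspike("polygon extends outside the image", "invalid_annotation")
    }
    inside <- mgcv::in.out(as.matrix(poly[, c("x", "y")]), centers)
    pooled <- pooled | inside
    res[[i]] <- tibble(
      region_id = i, label = regions$labels[i],
      n_pixels = sum(inside),
      region_mean = if (any(inside)) mean(density$value[inside]) else NA_real_,
      image_mean = img_mean
    )
  }
  out <- if (length(res)) {
    bind_rows(res)
  } else {
    tibble(region_id = integer(), label = character(), n_pixels = integer(),
           region_mean = numeric(), image_mean = numeric())
  }
  out$exceeds <- !is.na(out$region_mean) & out$region_mean > out$image_mean
  structure(out,
            class = c("region_stats", class(out)),
            fraction_exceeding = if (nrow(out)) mean(out$exceeds) else NA_real_,
            pooled_region_mean = if (any(pooled)) mean(density$value[pooled]) else NA_real_,
            pooled_exceeds = if (any(pooled)) mean(density$value[pooled]) > img_mean else NA)
}

#' Read / write polygon regions as GeoJSON
#'
#' Pixel-coordinate polygons stored as a GeoJSON FeatureCollection.
#'
#' @param path file path.
#' @return `read_regions_geojson()`: a [region_annotation()].
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  polys <- map(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    data.frame(x = map_dbl(ring, 1), y = map_dbl(ring, 2))
  })
  labels <- map(feats, function(f) f$properties$label %||% NA_character_)
  region_annotation(polys, unlist(labels))
}

#' @rdname read_regions_geojson
#' @param regions a [region_annotation()].
#' @export
write_regions_geojson <- function(regions, path) {
  feats <- map2(regions$polygons, regions$labels, function(p, lab) {
    list(type = "Feature",
         properties = list(label = lab),
         geometry = list(
           type = "Polygon",
           coordinates = list(map2(p$x, p$y, function(x, y) c(x, y)))
         ))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
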