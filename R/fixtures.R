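# Synthetic inputs: shape outlines, IFS fractal, satellite-like tiles.
# Every generator is a pure function of its arguments; symmetric kinds are
# pixel-exact mirror symmetric about the vertical midline by construction
# (the right half is drawn and OR-ed with its reflection).

# internal: draw an 8-connected segment into a matrix (values set to `value`)
draw_segment <- function(m, x0, y0, x1, y1, value = 255) {
  n <- max(abs(x1 - x0), abs(y1 - y0), 1)
  t <- seq(0, 1, length.out = n + 1)
  xs <- as.integer(round_half_away(x0 + t * (x1 - x0)))
  ys <- as.integer(round_half_away(y0 + t * (y1 - y0)))
  keep <- xs >= 0 & xs < ncol(m) & ys >= 0 & ys < nrow(m)
  m[cbind(ys[keep] + 1, xs[keep] + 1)] <- value
  m
}

draw_polygon_outline <- function(m, xs, ys, value = 255) {
  k <- length(xs)
  for (i in seq_len(k)) {
    j <- if (i == k) 1 else i + 1
    m <- draw_segment(m, xs[i], ys[i], xs[j], ys[j], value)
  }
  m
}

# internal: OR a binary field with its vertical-midline mirror
mirror_symmetrize <- function(m) {
  pmax(m, m[, ncol(m):1, drop = FALSE])
}

#' Generate a binary shape outline
#'
#' Deterministic test patterns for the symmetry detectors: outlines with
#' values 0/255. All kinds except `"ifs_triangle"` are pixel-exact mirror
#' symmetric about the vertical midline (`x -> size - 1 - x`). The
#' `"aircraft_like"` kind is a bilaterally symmetric polygon (fuselage,
#' swept wings, tail) standing in for a fighter-jet silhouette.
#'
#' @param kind one of `"two_point"`, `"circle"`, `"square"`, `"triangle"`,
#'   `"star"`, `"aircraft_like"`, `"ifs_triangle"`.
#' @param size image side in pixels (>= 16; square output).
#' @param seed accepted for interface uniformity; the outline kinds are
#'   fully deterministic.
#' @param depth fractal depth for `"ifs_triangle"` (see
#'   [make_ifs_fractal()]).
#' @return a [scalar_field()] with values in {0, 255}.
#' @examples
#' f <- make_outline("circle", 32)
#' sum(f > 0)
#' @export
make_outline <- function(kind = c("two_point", "circle", "square", "triangle",
                                  "star", "aircraft_like", "ifs_triangle"),
                         size = 32, seed = 1L, depth = 3) {
  kind <- arg_match(kind)
  if (size < 16) stop_symspike("size must be >= 16", "invalid_spec")
  if (kind == "ifs_triangle") return(make_ifs_fractal(depth, size, seed))
  s <- size
  m <- matrix(0, s, s)
  cx <- (s - 1) / 2; cy <- (s - 1) / 2
  m <- switch(kind,
    two_point = {
      off <- max(2, s %/% 4)
      x_left <- as.integer(round_half_away(cx)) - off
      x_right <- s - 1L - x_left  # exact mirror partner
      m[cbind(as.integer(round_half_away(cy)) + 1, c(x_left, x_right) + 1)] <- 255
      m
    },
    circle = {
      r <- s / 3
      xs <- rep(0:(s - 1), times = s); ys <- rep(0:(s - 1), each = s)
      d <- sqrt((xs - cx)^2 + (ys - cy)^2)
      ring <- abs(d - r) <= 0.5
      m[cbind(ys[ring] + 1, xs[ring] + 1)] <- 255
      m
    },
    square = {
      a <- s %/% 6; b <- s - 1 - a
      draw_polygon_outline(m, c(a, b, b, a), c(a, a, b, b))
    },
    triangle = {
      a <- s %/% 8
      draw_polygon_outline(m, c(cx, s - 1 - a, a), c(a, s - 1 - a, s - 1 - a))
    },
    star = {
      k <- 5
      ang <- -pi / 2 + (0:(2 * k - 1)) * pi / k
      rad <- rep(c(s * 0.45, s * 0.18), k)
      draw_polygon_outline(m, cx + rad * cos(ang), cy + rad * sin(ang))
    },
    aircraft_like = {
      u <- function(fx, fy) c(fx * (s - 1), fy * (s - 1))
      right <- list(u(0.5, 0.04), u(0.56, 0.30), u(0.96, 0.52), u(0.96, 0.60),
                    u(0.58, 0.56), u(0.56, 0.80), u(0.72, 0.90), u(0.72, 0.96),
                    u(0.5, 0.92))
      xs <- vapply(right, `[`, numeric(1), 1)
      ys <- vapply(right, `[`, numeric(1), 2)
      # draw the right half open (mirroring closes the figure)
      for (i in seq_len(length(xs) - 1)) {
        m <- draw_segment(m, xs[i], ys[i], xs[i + 1], ys[i + 1])
      }
      m
    }
  )
  m <- mirror_symmetrize(m)
  scalar_field(m)
}

#' Sierpinski-style IFS triangle fractal
#'
#' Applies the three half-scale corner maps of the triangle iterated
#' function system `depth` times and renders the resulting `3^depth`
#' triangle outlines. A multi-scale symmetry test pattern: distance limits
#' select which scale of its self-similar structure dominates the density.
#'
#' @param depth number of IFS applications (>= 1; depth 1 gives three
#'   triangle outlines).
#' @param size image side in pixels.
#' @param seed accepted for interface uniformity; generation is
#'   deterministic.
#' @return a [scalar_field()] with values in {0, 255}; attribute
#'   `n_triangles` holds `3^depth`.
#' @export
make_ifs_fractal <- function(depth = 3, size = 64, seed = 1L) {
  if (depth < 1) stop_symspike("depth must be >= 1", "invalid_input")
  s <- size
  m <- matrix(0, s, s)
  top <- c((s - 1) / 2, 0.05 * (s - 1))
  bl <- c(0.02 * (s - 1), 0.95 * (s - 1))
  br <- c(0.98 * (s - 1), 0.95 * (s - 1))
  n_tri <- 0L
  recurse <- function(a, b, c3, d) {
    if (d == 0) {
      m <<- draw_polygon_outline(m, c(a[1], b[1], c3[1]), c(a[2], b[2], c3[2]))
      n_tri <<- n_tri + 1L
      return(invisible(NULL))
    }
    ab <- (a + b) / 2; ac <- (a + c3) / 2; bc <- (b + c3) / 2
    recurse(a, ab, ac, d - 1)
    recurse(ab, b, bc, d - 1)
    recurse(ac, bc, c3, d - 1)
  }
  recurse(top, bl, br, depth)
  f <- scalar_field(m)
  attr(f, "n_triangles") <- n_tri
  f
}

#' Synthetic satellite-like tile with building footprints
#'
#' Emulates the edge-geometry statistics of overhead imagery tiles: a
#' low-intensity textured background, Poisson-placed irregular clutter blobs
#' (vegetation-like, few equidistant edge pairs), and bright axis-aligned
#' rectangular "buildings" whose straight parallel edges contribute many
#' equidistant point pairs. Returns the matching building polygons (rings
#' offset half a pixel outwards so border pixels count as inside).
#' Deterministic given the seed. It does not model ground-sample distance,
#' sensor noise or georeferencing — only the geometry the symmetry method
#' consumes.
#'
#' @param n_buildings number of rectangles (>= 0).
#' @param clutter expected number of clutter blobs (Poisson).
#' @param size tile side in pixels.
#' @param seed RNG seed.
#' @return list with `field` (a [scalar_field()], 0-255) and `regions`
#'   (a [region_annotation()] of building footprints; empty when
#'   `n_buildings = 0`).
#' @export
make_synthetic_tile <- function(n_buildings = 4, clutter = 10, size = 64,
                                seed = 1L) {
  if (n_buildings < 0) stop_symspike("n_buildings must be >= 0", "invalid_input")
  s <- size
  with_seed(seed, {
    m <- matrix(runif(s * s, 0, 25), s, s)
    # clutter: irregular soft blobs
    n_cl <- rpois(1, clutter)
    xs <- rep(0:(s - 1), times = s); ys <- rep(0:(s - 1), each = s)
    for (i in seq_len(n_cl)) {
      cx <- runif(1, 0, s - 1); cy <- runif(1, 0, s - 1)
      r <- runif(1, 1, 2.5); amp <- runif(1, 60, 140)
      d2 <- (xs - cx)^2 + (ys - cy)^2
      blob <- d2 <= r^2 * (1 + 0.6 * sin(3 * atan2(ys - cy, xs - cx)))
      m[cbind(ys[blob] + 1, xs[blob] + 1)] <- amp * runif(sum(blob), 0.7, 1)
    }
    # buildings: non-overlapping bright rectangles
    rects <- list()
    for (b in seq_len(n_buildings)) {
      placed <- FALSE
      for (attempt in 1:100) {
        bw <- sample(max(4, s %/% 8):max(5, s %/% 4), 1)
        bh <- sample(max(4, s %/% 8):max(5, s %/% 4), 1)
        x0 <- sample(1:(s - bw - 2), 1)
        y0 <- sample(1:(s - bh - 2), 1)
        cand <- c(x0, y0, x0 + bw - 1, y0 + bh - 1)
        ok <- TRUE
        for (r0 in rects) {
          if (cand[1] <= r0[3] + 2 && cand[3] >= r0[1] - 2 &&
              cand[2] <= r0[4] + 2 && cand[4] >= r0[2] - 2) { ok <- FALSE; break }
        }
        if (ok) { rects[[b]] <- cand; placed <- TRUE; break }
      }
      if (!placed) {
        stop_symspike("could not place buildings without overlap", "placement_failure")
      }
    }
    for (r0 in rects) {
      amp <- runif(1, 190, 250)
      m[(r0[2] + 1):(r0[4] + 1), (r0[1] + 1):(r0[3] + 1)] <- amp
    }
    polys <- map(rects, function(r0) {
      data.frame(x = c(r0[1], r0[3], r0[3], r0[1], r0[1]) + c(-0.5, 0.5, 0.5, -0.5, -0.5),
                 y = c(r0[2], r0[2], r0[4], r0[4], r0[2]) + c(-0.5, -0.5, 0.5, 0.5, -0.5))
    })
    regions <- if (length(polys)) {
      region_annotation(polys, paste0("building_", seq_along(polys)))
    } else {
      region_annotation(list())
    }
    list(field = scalar_field(m), regions = regions)
  })
}
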