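#' Round half away from zero
#'
#' Deterministic rounding used throughout the package (distance binning,
#' delay-line lengths, midpoint rasterization): ties at .5 round away from
#' zero, unlike base [round()]'s banker's rounding. Fixing the tie rule makes
#' the histogram algorithm and the delay-coded spiking network agree bin for
#' bin.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return numeric vector rounded at `digits` places.
#' @examples
#' round_half_away(2.5)   # 3, where round(2.5) == 2
#' round_half_away(6.403, 1)
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Distance between two grid points
#'
#' A metric on the pixel grid: non-negative, zero on identical points,
#' symmetric in its arguments, and satisfying the triangle inequality.
#' `"euclidean"` is sqrt((bx-ax)^2 + (by-ay)^2); `"manhattan"` is
#' |bx-ax| + |by-ay|, attractive in hardware because it needs no
#' multiplication or square root. Distances are in pixel units.
#'
#' @param a,b grid points: length-2 numeric vectors `c(x, y)` or single-row
#'   data frames with `x`, `y` columns.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return non-negative scalar distance.
#' @examples
#' point_distance(c(0, 0), c(5, 4))              # sqrt(41) ~ 6.403
#' point_distance(c(0, 0), c(5, 4), "manhattan") # 9
#' @export
point_distance <- function(a, b, metric = c("euclidean", "manhattan")) {
  metric <- arg_match(metric)
  a <- as_xy(a); b <- as_xy(b)
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  if (metric == "euclidean") sqrt(dx^2 + dy^2) else abs(dx) + abs(dy)
}

as_xy <- function(p) {
  if (is.data.frame(p)) c(p$x[1], p$y[1]) else as.numeric(p[1:2])
}

# internal: vectorized distances from one point to many / many to many
distance_matrix <- function(ax, ay, bx, by, metric) {
  dx <- outer(ax, bx, "-")
  dy <- outer(ay, by, "-")
  if (metric == "euclidean") sqrt(dx^2 + dy^2) else abs(dx) + abs(dy)
}

#' Bin a distance at a configurable decimal precision
#'
#' Distances are rounded half-away-from-zero at `decimals` places; two
#' distances differing by less than `0.5 * 10^-decimals` land in the same
#' bin. The bin label is the canonical decimal string of the rounded value
#' with trailing zeros trimmed (so `bin_distance(0, 1)` is `"0"`, not
#' `"0.0"`).
#'
#' @param d non-negative distance(s).
#' @param decimals integer number of decimal places.
#' @return character vector of bin labels.
#' @examples
#' bin_distance(6.403, 1)  # "6.4"
#' bin_distance(2.5, 0)    # "3"
#' @export
bin_distance <- function(d, decimals = 1) {
  if (any(d < 0)) stop_symspike("distances must be non-negative", "invalid_distance")
  r <- round_half_away(d, decimals)
  lab <- formatC(r, format = "f", digits = max(decimals, 0))
  lab <- sub("\\.?0+$", "", lab)
  lab[lab == ""] <- "0"
  lab
}

# internal: integer bin keys (value * 10^decimals, half-away rounding)
bin_keys <- function(d, decimals) {
  as.integer(round_half_away(d * 10^decimals, 0))
}

# internal: label for an integer key
key_to_label <- function(key, decimals) {
  bin_distance(key / 10^decimals, decimals)
}

#' Lower bound on switching energy of a delay-coded detector
#'
#' For a physical implementation running at the ultimate speed limit, the
#' threshold layer must resolve pulses separated by the propagation time of
#' the array pitch d_p at the speed of light, Delta-t = d_p / c. The
#' time-energy uncertainty relation then bounds the average switching energy:
#' E >= pi * hbar / (2 Delta-t) = pi * hbar * c / (2 d_p). The bound is
#' monotonically decreasing in the pitch.
#'
#' @param pitch_dp array pitch in meters (> 0).
#' @return energy bound in joules.
#' @examples
#' min_energy_bound(1)  # ~ 4.97e-26 J
#' @export
min_energy_bound <- function(pitch_dp) {
  if (any(pitch_dp <= 0)) stop_symspike("pitch must be positive", "invalid_input")
  hbar <- 1.054571817e-34  # J s (CODATA)
  c0 <- 299792458          # m / s
  pi * hbar * c0 / (2 * pitch_dp)
}
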