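#' Tidy and summarize symmetry maps
#'
#' @param x a `symmetry_map`.
#' @param ... unused.
#' @return `tidy()`: a plain tibble with `x`, `y`, `value`; `glance()`: a
#'   one-row tibble with the domain size, value range and mean.
#' @method tidy symmetry_map
#' @export
tidy.symmetry_map <- function(x, ...) {
  out <- tibble(x = x$x)
  out$y <- x$y
  out$value <- x$value
  out
}

#' @rdname tidy.symmetry_map
#' @method glance symmetry_map
#' @export
glance.symmetry_map <- function(x, ...) {
  tibble(width = attr(x, "width"), height = attr(x, "height"),
         source = attr(x, "source") %||% "histogram",
         max_value = max(x$value), mean_value = mean(x$value))
}

#' Tidy and summarize simulation traces
#'
#' The tidy form is the event log of the cycle-accurate simulation: one row
#' per event with columns `cycle`, `neuron_kind` (`"input"`/`"output"`),
#' `neuron_x`, `neuron_y`, `event` (`"inject"`, `"arrive"`, `"fire"`) and
#' `value` (pulse count for arrivals, 1 otherwise).
#'
#' @param x an `snn_trace` from [run_symmetry()].
#' @param ... unused.
#' @method tidy snn_trace
#' @export
tidy.snn_trace <- function(x, ...) {
  neurons <- x$topology$neurons
  ev_inject <- tibble(cycle = 0L, neuron_kind = "input",
                      neuron_x = x$input$x, neuron_y = x$input$y,
                      event = "inject", value = 1)
  arr <- which(x$arrivals > 0, arr.ind = TRUE)
  ev_arrive <- tibble(cycle = arr[, 1], neuron_kind = "output",
                      neuron_x = neurons$x[arr[, 2]],
                      neuron_y = neurons$y[arr[, 2]],
                      event = "arrive",
                      value = x$arrivals[arr])
  fr <- which(x$fires, arr.ind = TRUE)
  ev_fire <- tibble(cycle = fr[, 1], neuron_kind = "output",
                    neuron_x = neurons$x[fr[, 2]],
                    neuron_y = neurons$y[fr[, 2]],
                    event = "fire", value = 1)
  out <- bind_rows(ev_inject, ev_arrive, ev_fire)
  arrange(out, .data$cycle, .data$event, .data$neuron_y, .data$neuron_x)
}

#' @rdname tidy.snn_trace
#' @method glance snn_trace
#' @export
glance.snn_trace <- function(x, ...) {
  fire_cycles <- which(apply(x$fires, 1, any))
  tibble(cycles = x$cycles, n_inputs = nrow(x$input),
         n_fires = sum(x$fires),
         first_fire_cycle = if (length(fire_cycles)) min(fire_cycles) else NA_integer_,
         max_coincidence = max(x$arrivals))
}

#' @rdname region_stats
#' @param x a `region_stats` object.
#' @param ... unused.
#' @method glance region_stats
#' @export
glance.region_stats <- function(x, ...) {
  tibble(n_regions = nrow(x),
         image_mean = if (nrow(x)) x$image_mean[1] else NA_real_,
         pooled_region_mean = attr(x, "pooled_region_mean"),
         fraction_exceeding = attr(x, "fraction_exceeding"))
}

#' Plot a symmetry map
#'
#' Raster heat map in image orientation (origin top-left). For overlay-style
#' rendering on the 0-350 color scale used for the satellite tiles, pass
#' `limits = c(0, 350)`.
#'
#' @param object a `symmetry_map`.
#' @param limits optional fill-scale limits, e.g. `c(0, 350)`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot symmetry_map
#' @export
autoplot.symmetry_map <- function(object, limits = NULL, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = limits, oob = scales::squish) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "density")
}

#' @rdname autoplot.symmetry_map
#' @method autoplot scalar_field
#' @export
autoplot.scalar_field <- function(object, ...) {
  df <- field_as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed()
}

#' @rdname autoplot.symmetry_map
#' @method autoplot distance_histogram
#' @export
autoplot.distance_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance, y = .data$count)) +
    ggplot2::geom_col(width = 0.8 * 10^-(attr(object, "config")$decimals %||% 0)) +
    ggplot2::labs(x = "binned distance (px)", y = "count")
}

#' Overlay a density map on its source image
#'
#' @param field the source [scalar_field()].
#' @param map the `symmetry_map` to overlay.
#' @param limits overlay color limits (default the 0-350 render range).
#' @param alpha overlay opacity.
#' @return a ggplot.
#' @export
plot_overlay <- function(field, map, limits = c(0, 350), alpha = 0.6) {
  img <- field_as_tibble(field)
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = img,
                         ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_raster(data = tidy(map)[map$value > 0, ],
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      alpha = .data$value), fill = "red") +
    ggplot2::scale_alpha_continuous(range = c(0, alpha), limits = limits) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
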