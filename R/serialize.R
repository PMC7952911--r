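#' Write / read a density map as CSV
#'
#' Plain-text round-trip format: a `width,height` header line followed by
#' the row-major value grid, one image row per line.
#'
#' @param map a `symmetry_map`.
#' @param path output file.
#' @return `write_density_csv()`: the path, invisibly;
#'   `read_density_csv()`: a `symmetry_map`.
#' @export
write_density_csv <- function(map, path) {
  w <- attr(map, "width"); h <- attr(map, "height")
  m <- map_as_matrix(map)
  lines <- c("width,height",
             paste(w, h, sep = ","),
             apply(m, 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(lines[2], ",")[[1]])
  vals <- do.call(rbind, lapply(lines[-(1:2)], function(l) {
    as.numeric(strsplit(l, ",")[[1]])
  }))
  stopifnot(nrow(vals) == dims[2], ncol(vals) == dims[1])
  new_symmetry_map(vals)
}

#' Write a density map as a grayscale PNG
#'
#' Values are clipped to `[0, max_value]` and scaled to the PNG range; the
#' scale factor is returned so intensities can be mapped back. The default
#' `max_value` matches the 0-350 render range used for the satellite-tile
#' overlays.
#'
#' @param map a `symmetry_map`.
#' @param path output file.
#' @param max_value value mapped to full white.
#' @return the scale factor (`max_value`), invisibly.
#' @export
write_density_png <- function(map, path, max_value = 350) {
  m <- pmin(map_as_matrix(map), max_value) / max_value
  png::writePNG(m, path)
  invisible(max_value)
}

#' Export a simulation trace as a CSV event log
#'
#' Columns: `cycle`, `neuron_kind`, `neuron_x`, `neuron_y`, `event`
#' (inject / arrive / fire), `value`.
#'
#' @param trace an `snn_trace`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tidy(trace), path)
  invisible(path)
}
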