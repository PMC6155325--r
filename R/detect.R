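#' Construct a maxima set from known positions
#'
#' Wraps externally supplied particle positions (e.g. from another
#' detection tool) so they can feed [nearest_neighbor_pairs()] and
#' [measure_nn_distances()]. Positions use the pixel-centre convention:
#' `x` = column, `y` = row, so a position maps to
#' `((x - 0.5) * pixel_size, (y - 0.5) * pixel_size)` nm.
#'
#' @param x,y positions in pixel units (continuous).
#' @param dim map dimensions `c(rows, cols)` in pixels.
#' @param height optional peak heights in nm.
#' @param pixel_size nm per pixel.
#' @return a `maxima_set`.
#' @export
#' @examples
#' maxima_set(c(10, 20, 30), c(50, 50, 50), dim = c(100, 100), pixel_size = 2)
maxima_set <- function(x, y, dim, height = NULL, pixel_size = 1) {
  stopifnot(length(x) == length(y), length(dim) == 2L, all(dim >= 1),
            pixel_size > 0)
  if (length(x) && (any(x < 0.5) || any(x > dim[2] + 0.5) ||
                    any(y < 0.5) || any(y > dim[1] + 0.5)))
    stop("positions must lie inside the map bounds")
  if (is.null(height)) height <- rep(NA_real_, length(x))
  new_maxima_set(x, y, height, rep(Inf, length(x)), dim, pixel_size)
}

new_maxima_set <- function(x, y, height, prominence, dim, pixel_size) {
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 height = as.numeric(height),
                 prominence = as.numeric(prominence),
                 dim = as.integer(dim), pixel_size = as.numeric(pixel_size)),
            class = "maxima_set")
}

#' @export
print.maxima_set <- function(x, ...) {
  cat(sprintf("Maxima set: %d maxima on a %d x %d px map (%.4g nm/px)\n",
              length(x$x), x$dim[1], x$dim[2], x$pixel_size))
  invisible(x)
}

#' @export
as.data.frame.maxima_set <- function(x, ...) {
  data.frame(x_px = x$x, y_px = x$y,
             x_nm = (x$x - 0.5) * x$pixel_size,
             y_nm = (x$y - 0.5) * x$pixel_size,
             height_nm = x$height, prominence_nm = x$prominence)
}

#' Robust pixel-noise estimate of a height map
#'
#' Median absolute deviation (scaled to be consistent with a Gaussian s.d.)
#' of the pixel heights. On sparsely occupied maps the particles barely
#' perturb it, so it estimates the additive noise level.
#'
#' @param map an [afm_map()].
#' @return noise s.d. estimate in nm.
#' @export
robust_noise <- function(map) {
  stopifnot(inherits(map, "afm_map"))
  mad(as.vector(map$grid))
}

#' Detect particles as local height maxima
#'
#' The map is first smoothed with a small median filter, then local maxima
#' are extracted together with their topographic prominence: the drop in
#' height required before a higher pixel can be reached along any connected
#' path (computed by a persistence/watershed-style merge over pixels in
#' decreasing height order). A maximum is kept when its (filtered) height
#' exceeds `threshold` -- the guard against false positives on the
#' background -- and its prominence exceeds `noise_tolerance`.
#'
#' Both knobs default to data-driven values: 3x the map's robust noise
#' estimate, with the threshold additionally offset by the median background
#' level.
#'
#' @param map an [afm_map()].
#' @param median_filter_size odd filter window width in pixels (1 disables
#'   filtering; default 3).
#' @param noise_tolerance minimum prominence in nm; default
#'   `3 * robust_noise(map)`.
#' @param threshold minimum absolute pixel height in nm; default
#'   `median(grid) + 3 * robust_noise(map)`.
#' @return a `maxima_set`: positions in pixel units (pixel-centre
#'   convention, `x` = column, `y` = row), filtered peak heights in nm, and
#'   prominences.
#' @export
#' @examples
#' f <- generate_random_field(50, c(1000, 1000), seed = 1)
#' m <- render_height_map(f, 4, noise_sd = 0.05, seed = 2)
#' detect_maxima(m)
detect_maxima <- function(map, median_filter_size = 3,
                          noise_tolerance = NULL, threshold = NULL) {
  stopifnot(inherits(map, "afm_map"))
  if (median_filter_size < 1 || median_filter_size %% 2 != 1)
    stop("`median_filter_size` must be a positive odd integer")
  if (any(dim(map$grid) < median_filter_size))
    stop("map (", paste(dim(map$grid), collapse = "x"),
         ") is smaller than the median filter window")
  filtered <- if (median_filter_size > 1)
    median_filter_cpp(map$grid, as.integer(median_filter_size))
  else map$grid
  # noise from the raw map: filtering shrinks the apparent noise and would
  # make the default thresholds too permissive
  noise <- mad(as.vector(map$grid))
  if (is.null(noise_tolerance)) noise_tolerance <- 3 * noise
  if (is.null(threshold)) threshold <- median(filtered) + 3 * noise
  if (noise_tolerance < 0) stop("`noise_tolerance` must be >= 0")
  if (threshold < 0) stop("`threshold` must be >= 0")
  pk <- detect_peaks_cpp(filtered)
  keep <- pk$height > threshold & pk$prominence > noise_tolerance
  new_maxima_set(x = pk$col[keep], y = pk$row[keep],
                 height = pk$height[keep], prominence = pk$prominence[keep],
                 dim = dim(map$grid), pixel_size = map$pixel_size)
}
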