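#' Expected nearest-neighbour distance of a Poisson surface
#'
#' For a homogeneous Poisson point process of intensity `lambda` (per um^2)
#' the mean distance from a point to its nearest neighbour is
#' `1 / (2 sqrt(lambda))`; returned in nm. This is the theory curve linking
#' sprayed concentration to intermolecular distance on the surface.
#'
#' @param lambda_um2 surface density in um^-2 (positive).
#' @return mean nearest-neighbour distance in nm (vectorised).
#' @export
#' @examples
#' expected_nn_distance(100)  # 50 nm
expected_nn_distance <- function(lambda_um2) {
  if (any(lambda_um2 <= 0)) stop("`lambda_um2` must be positive")
  1 / (2 * sqrt(lambda_um2)) * 1e3
}

#' Measure nearest-neighbour distances on a maxima set
#'
#' Per-point nearest-neighbour distances in nm, with the same border rule as
#' the ordering analysis: a point whose nearest-neighbour distance exceeds
#' its distance to the closest image border is discarded (its true nearest
#' neighbour could lie outside the imaged area).
#'
#' @param maxima a `maxima_set` (at least 2 points).
#' @param pixel_size nm per pixel; defaults to the value carried by
#'   `maxima`.
#' @return list with `mean_nm`, `sd_nm`, `n`, `n_discarded_border`, and the
#'   retained `distances_nm`.
#' @export
measure_nn_distances <- function(maxima, pixel_size = maxima$pixel_size) {
  stopifnot(inherits(maxima, "maxima_set"))
  n <- length(maxima$x)
  if (n < 2L) stop("need at least 2 maxima to measure distances")
  x_nm <- (maxima$x - 0.5) * pixel_size
  y_nm <- (maxima$y - 0.5) * pixel_size
  width_nm <- maxima$dim[2] * pixel_size
  height_nm <- maxima$dim[1] * pixel_size
  j <- nn_index_cpp(x_nm, y_nm)
  d <- sqrt((x_nm - x_nm[j])^2 + (y_nm - y_nm[j])^2)
  border <- pmin(x_nm, width_nm - x_nm, y_nm, height_nm - y_nm)
  keep <- d <= border
  list(mean_nm = mean(d[keep]), sd_nm = sd(d[keep]),
       n = sum(keep), n_discarded_border = sum(!keep),
       distances_nm = d[keep])
}

#' Deposition model predicting surface density from spray parameters
#'
#' The sprayed volume `Q * t` carries `C * N_A * V` molecules; spread over
#' the spray footprint `pi (d tan(cone/2))^2` with a sticking/deposition
#' efficiency, the expected surface density is linear in concentration and
#' spray time:
#' `lambda = C * N_A * volume * efficiency / footprint`.
#'
#' @param concentration_uM solution concentration in uM.
#' @param flow_rate_ul_h spray flow rate in ul h^-1.
#' @param spray_time_s deposition time in s.
#' @param distance_cm nozzle-to-surface distance in cm.
#' @param cone_full_angle_deg spray cone full apex angle in degrees.
#' @param efficiency deposition efficiency in (0, 1\]; default 1 (the spray
#'   deposits the full solution content).
#' @return an `occupancy_model` with the predicted `lambda_um2`.
#' @export
#' @examples
#' m <- occupancy_model(2, 100, 5, 4)
#' m$lambda_um2
#' expected_nn_distance(m$lambda_um2)
occupancy_model <- function(concentration_uM, flow_rate_ul_h = 100,
                            spray_time_s = 5, distance_cm = 4,
                            cone_full_angle_deg = 18, efficiency = 1) {
  stopifnot(concentration_uM >= 0, flow_rate_ul_h >= 0, spray_time_s >= 0,
            distance_cm > 0, cone_full_angle_deg > 0, cone_full_angle_deg < 90,
            efficiency > 0, efficiency <= 1)
  volume_L <- flow_rate_ul_h * 1e-6 * spray_time_s / 3600
  footprint_um2 <- pi * (distance_cm * 1e4 *
                           tan(cone_full_angle_deg / 2 * pi / 180))^2
  n_molecules <- concentration_uM * 1e-6 * .const$N_A * volume_L * efficiency
  structure(list(concentration_uM = concentration_uM,
                 sprayed_volume_L = volume_L,
                 footprint_um2 = footprint_um2,
                 efficiency = efficiency,
                 lambda_um2 = n_molecules / footprint_um2),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf(
    "Deposition model: %.3g uM, %.3g uL sprayed over %.3g um^2 -> lambda = %.4g / um^2\n",
    x$concentration_uM, x$sprayed_volume_L * 1e6, x$footprint_um2,
    x$lambda_um2))
  if (x$lambda_um2 > 0)
    cat(sprintf("  expected NN distance: %.3g nm\n",
                expected_nn_distance(x$lambda_um2)))
  invisible(x)
}

#' Predicted surface density of a deposition model
#'
#' @param model an [occupancy_model()].
#' @return `lambda` in um^-2.
#' @export
predict_density <- function(model) {
  stopifnot(inherits(model, "occupancy_model"))
  model$lambda_um2
}

#' Fit the deposition efficiency to observed nearest-neighbour distances
#'
#' The deposition model has one free parameter, the sticking efficiency.
#' Given observed mean NN distances at several concentrations, finds the
#' efficiency in (0, 1] minimising the squared distance residuals against
#' `expected_nn_distance(efficiency * lambda_1(C))`, where `lambda_1` is
#' the model prediction at efficiency 1.
#'
#' @param concentrations_uM concentrations of the sprayed solutions.
#' @param observed_nn_nm observed mean NN distance (nm) for each.
#' @param ... further arguments to [occupancy_model()] (flow rate, time,
#'   distance, cone angle).
#' @return list with `efficiency` and the fitted `predicted_nn_nm`.
#' @export
fit_deposition_efficiency <- function(concentrations_uM, observed_nn_nm, ...) {
  stopifnot(length(concentrations_uM) == length(observed_nn_nm),
            length(concentrations_uM) >= 1L, all(observed_nn_nm > 0))
  lambda1 <- vapply(concentrations_uM, function(C)
    occupancy_model(C, ..., efficiency = 1)$lambda_um2, numeric(1))
  obj <- function(eff)
    sum((observed_nn_nm - expected_nn_distance(eff * lambda1))^2)
  fit <- optimize(obj, c(1e-6, 1))
  list(efficiency = fit$minimum,
       predicted_nn_nm = expected_nn_distance(fit$minimum * lambda1))
}

#' Cross-sectional particle heights above local background
#'
#' For each detected maximum the particle height is the peak pixel value
#' minus the local background, estimated as the median of an annulus around
#' the particle (median for robustness to neighbouring particles falling in
#' the annulus). Local background subtraction makes the statistic invariant
#' to a constant offset or slowly varying tilt of the map.
#'
#' @param map an [afm_map()].
#' @param maxima a `maxima_set` detected on that map.
#' @param background_window inner radius of the background annulus in
#'   pixels (>= 3); defaults to 15 px (about 3x the particle sigma at the
#'   generator's default geometry).
#' @param annulus_width radial width of the annulus in pixels (default 4).
#' @return a `height_stats`: per-particle `heights_nm`, `median`, `q1`,
#'   `q3`, `n`.
#' @export
particle_heights <- function(map, maxima, background_window = 15,
                             annulus_width = 4) {
  stopifnot(inherits(map, "afm_map"), inherits(maxima, "maxima_set"))
  if (background_window < 3) stop("`background_window` must be >= 3 pixels")
  if (annulus_width < 1) stop("`annulus_width` must be >= 1 pixel")
  r_out <- background_window + annulus_width
  if (2 * r_out + 1 > min(dim(map$grid)))
    stop("background annulus (radius ", r_out,
         " px) exceeds the map dimensions")
  grid <- map$grid
  nr <- nrow(grid); nc <- ncol(grid)
  heights <- vapply(seq_along(maxima$x), function(k) {
    ci <- round(maxima$y[k]); cj <- round(maxima$x[k])
    rows <- max(1L, ci - r_out):min(nr, ci + r_out)
    cols <- max(1L, cj - r_out):min(nc, cj + r_out)
    rr <- outer((rows - ci)^2, (cols - cj)^2, "+")
    ann <- rr >= background_window^2 & rr <= r_out^2
    bg <- median(grid[rows, cols][ann])
    grid[ci, cj] - bg
  }, numeric(1))
  qs <- quantile(heights, c(0.25, 0.5, 0.75))
  structure(list(heights_nm = heights, median = unname(qs[2]),
                 q1 = unname(qs[1]), q3 = unname(qs[3]),
                 n = length(heights)),
            class = "height_stats")
}

#' @export
print.height_stats <- function(x, ...) {
  cat(sprintf(
    "Particle heights: n = %d, median %.3g nm (IQR %.3g-%.3g nm)\n",
    x$n, x$median, x$q1, x$q3))
  invisible(x)
}
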