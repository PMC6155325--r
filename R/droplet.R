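#' Ambient air state for evaporation modelling
#'
#' Temperature and humidity drive every evaporation rate in the package via
#' the far-field vapour concentration deficit
#' `delta_c = c_sat * (1 - relative_humidity)`. The saturation vapour
#' concentration is computed from the Magnus relation for the saturation
#' pressure, `e_s(T) = 610.94 exp(17.625 T / (T + 243.04))` Pa (T in deg C),
#' converted with the ideal gas law (about 23 g m^-3 at 25 deg C).
#'
#' @param temperature_C air temperature in degrees Celsius.
#' @param relative_humidity fraction in \[0, 1\]. Note: droplets sprayed
#'   under the pressurised dry-N2 jet dry in a vapour-free local atmosphere;
#'   use 0 for that regime.
#' @param vapor_diffusivity diffusivity of water vapour in air, m^2 s^-1.
#' @return an `air_state` with `c_sat` and `delta_c` (kg m^-3).
#' @export
#' @examples
#' air_state(25, 0.5)
air_state <- function(temperature_C = 25, relative_humidity = 0.5,
                      vapor_diffusivity = .const$D_vapor) {
  stopifnot(relative_humidity >= 0, relative_humidity <= 1,
            temperature_C > -273.15, vapor_diffusivity > 0)
  e_sat <- 610.94 * exp(17.625 * temperature_C / (temperature_C + 243.04))
  c_sat <- e_sat * .const$M_water / (.const$R_gas * (temperature_C + 273.15))
  structure(list(temperature_C = temperature_C,
                 relative_humidity = relative_humidity,
                 D_v = vapor_diffusivity,
                 c_sat = c_sat,
                 delta_c = c_sat * (1 - relative_humidity)),
            class = "air_state")
}

#' @export
print.air_state <- function(x, ...) {
  cat(sprintf("Air: %.1f degC, RH %.0f%%, c_sat %.3g kg/m^3 (D_v %.3g m^2/s)\n",
              x$temperature_C, 100 * x$relative_humidity, x$c_sat, x$D_v))
  invisible(x)
}

#' Sessile droplet description
#'
#' A droplet is described by its volume (fL) and, when sessile, its
#' spherical-cap geometry (contact radius `a` in um and contact angle in
#' degrees). The airborne equivalent spherical radius is derived from the
#' volume. Liquid properties default to water at 25 deg C.
#'
#' @param volume_fL droplet volume in fL (1 fL = 1 um^3).
#' @param contact_angle_deg equilibrium contact angle; default 15.3 deg, the
#'   measured value for the fluorescein model solution on glass.
#' @param density liquid density, kg m^-3.
#' @param surface_tension liquid-air surface tension, N m^-1.
#' @return a `droplet` with derived `radius_um` (airborne sphere) and
#'   `contact_radius_um`/`imprint_area_um2` (sessile cap).
#' @export
#' @examples
#' droplet(100)
droplet <- function(volume_fL, contact_angle_deg = 15.3,
                    density = .const$rho_water,
                    surface_tension = .const$gamma_water) {
  stopifnot(volume_fL >= 0, contact_angle_deg > 0, contact_angle_deg < 90,
            density > 0, surface_tension > 0)
  area <- if (volume_fL > 0) imprint_area(volume_fL, contact_angle_deg) else 0
  structure(list(volume_fL = volume_fL,
                 radius_um = (3 * volume_fL / (4 * pi))^(1 / 3),
                 contact_angle_deg = contact_angle_deg,
                 imprint_area_um2 = area,
                 contact_radius_um = sqrt(area / pi),
                 density = density,
                 surface_tension = surface_tension,
                 evaporated = volume_fL == 0),
            class = "droplet")
}

#' @export
print.droplet <- function(x, ...) {
  cat(sprintf(
    "Droplet: %.4g fL (R = %.3g um airborne; a = %.3g um, theta = %.3g deg sessile)%s\n",
    x$volume_fL, x$radius_um, x$contact_radius_um, x$contact_angle_deg,
    if (x$evaporated) " [fully evaporated]" else ""))
  invisible(x)
}

#' Spherical-cap volume from imprint area and contact angle
#'
#' Small sessile droplets (Bond number << 1) are spherical caps, so the
#' dried imprint area left on the substrate determines the landed volume
#' once the equilibrium contact angle is known: contact radius
#' `a = sqrt(area/pi)`, cap height `h = a tan(theta/2)`, volume
#' `V = pi h (3 a^2 + h^2) / 6`.
#'
#' @param imprint_area_um2 imprint (droplet base) area in um^2.
#' @param contact_angle_deg contact angle in degrees, in (0, 180).
#' @return volume in fL.
#' @export
#' @examples
#' cap_volume(200, 15.3)  # ~108 fL
cap_volume <- function(imprint_area_um2, contact_angle_deg) {
  if (any(imprint_area_um2 <= 0)) stop("`imprint_area_um2` must be positive")
  if (any(contact_angle_deg <= 0) || any(contact_angle_deg >= 180))
    stop("`contact_angle_deg` must lie in (0, 180)")
  a <- sqrt(imprint_area_um2 / pi)
  h <- a * tan(contact_angle_deg * pi / 360)
  pi * h * (3 * a^2 + h^2) / 6
}

#' Imprint area of a spherical-cap droplet of known volume
#'
#' Inverse of [cap_volume()]: with `t = tan(theta/2)` the cap volume is
#' `V = (pi/6) a^3 t (3 + t^2)`, so `a = (6 V / (pi t (3 + t^2)))^(1/3)`
#' and the base area is `pi a^2`.
#'
#' @param volume_fL droplet volume in fL.
#' @param contact_angle_deg contact angle in degrees, in (0, 180).
#' @return base (imprint) area in um^2.
#' @export
imprint_area <- function(volume_fL, contact_angle_deg) {
  if (any(volume_fL <= 0)) stop("`volume_fL` must be positive")
  if (any(contact_angle_deg <= 0) || any(contact_angle_deg >= 180))
    stop("`contact_angle_deg` must lie in (0, 180)")
  t <- tan(contact_angle_deg * pi / 360)
  a <- (6 * volume_fL / (pi * t * (3 + t^2)))^(1 / 3)
  pi * a^2
}

#' Bond number
#'
#' Ratio of gravitational to capillary forces, `Bo = rho g L^2 / gamma`.
#' `Bo << 1` justifies treating sessile droplets as spherical caps; for the
#' micrometre-scale droplets produced by the spray nozzle it is of order
#' 1e-5.
#'
#' @param length_scale_um characteristic length (e.g. contact radius), um.
#' @param density liquid density, kg m^-3.
#' @param surface_tension surface tension, N m^-1.
#' @return dimensionless Bond number.
#' @export
#' @examples
#' bond_number(sqrt(250 / pi))  # largest observed imprints, ~1e-5
bond_number <- function(length_scale_um, density = .const$rho_water,
                        surface_tension = .const$gamma_water) {
  stopifnot(all(length_scale_um > 0), density > 0, surface_tension > 0)
  density * .const$g * (length_scale_um * 1e-6)^2 / surface_tension
}

#' Maxwell (diffusion-limited) evaporation rate of an airborne droplet
#'
#' Classical quasi-steady vapour diffusion from a sphere:
#' `dV/dt = 4 pi R D_v c_sat (1 - RH) / rho`, returned in fL per ms. Linear
#' in the radius; zero at saturation (RH = 1). For a 100 fL droplet
#' (R = 2.88 um) at 25 deg C and RH 0.5 the rate is about 10 fL/ms.
#'
#' @param radius_um droplet radius in um.
#' @param air an [air_state()].
#' @param density liquid density, kg m^-3.
#' @return evaporation rate in fL ms^-1.
#' @export
flight_evaporation_rate <- function(radius_um, air = air_state(),
                                    density = .const$rho_water) {
  stopifnot(all(radius_um > 0), inherits(air, "air_state"))
  rate_m3_s <- 4 * pi * radius_um * 1e-6 * air$D_v * air$delta_c / density
  rate_m3_s * 1e15   # m^3/s -> fL/ms
}

#' Evaporate a droplet over its flight to the surface
#'
#' Maxwell evaporation integrates in closed form as the R^2 law:
#' `R(t)^2 = R0^2 - K t` with `K = 2 D_v c_sat (1 - RH) / rho`, over the
#' flight time `t = distance / velocity` (constant velocity; drag and
#' cooling neglected, consistent with an order-of-magnitude treatment).
#' Droplets that dry out before landing are flagged with volume 0.
#'
#' @param drop a [droplet()].
#' @param distance_cm nozzle-to-surface distance in cm.
#' @param velocity_m_s droplet velocity in m s^-1 (measured range 10-30).
#' @param air an [air_state()].
#' @return the landed [droplet()] (same contact angle), with `evaporated`
#'   set when nothing remains.
#' @export
#' @examples
#' evolve_in_flight(droplet(100), 4, 20, air_state(25, 0.5))  # ~80 fL
evolve_in_flight <- function(drop, distance_cm, velocity_m_s = 20,
                             air = air_state()) {
  stopifnot(inherits(drop, "droplet"), distance_cm >= 0, velocity_m_s > 0,
            inherits(air, "air_state"))
  if (drop$evaporated || distance_cm == 0) return(drop)
  t_s <- distance_cm * 1e-2 / velocity_m_s
  K <- 2 * air$D_v * air$delta_c / drop$density          # m^2 s^-1
  R2 <- (drop$radius_um * 1e-6)^2 - K * t_s
  if (R2 <= 0)
    return(droplet(0, drop$contact_angle_deg, drop$density,
                   drop$surface_tension))
  R_um <- sqrt(R2) * 1e6
  droplet(4 / 3 * pi * R_um^3, drop$contact_angle_deg, drop$density,
          drop$surface_tension)
}

#' Drying time of a sessile droplet with a pinned contact line
#'
#' For contact angles below 90 deg the contact line pins during
#' evaporation, so the base radius `a` stays fixed while the cap flattens.
#' The diffusion-limited evaporation rate of such a cap is
#' `dV/dt = -(pi a D_v delta_c / rho) (0.27 theta^2 + 1.30)` (theta in
#' radians), constant under pinning, so the drying time is simply
#' `V / |dV/dt|`. At `delta_c = 0` the droplet never dries (`Inf`).
#'
#' @param drop a sessile [droplet()] (valid contact radius and angle).
#' @param air an [air_state()].
#' @return drying time in ms (possibly `Inf`).
#' @export
#' @examples
#' # 100 fL, ~200 um^2 imprint, dry air: about 5 ms
#' sessile_drying_time(droplet(100), air_state(25, 0))
sessile_drying_time <- function(drop, air = air_state()) {
  stopifnot(inherits(drop, "droplet"), inherits(air, "air_state"))
  if (drop$evaporated || drop$volume_fL == 0) return(0)
  if (air$delta_c == 0) return(Inf)
  theta <- drop$contact_angle_deg * pi / 180
  a_m <- drop$contact_radius_um * 1e-6
  rate_m3_s <- pi * a_m * air$D_v * air$delta_c *
    (0.27 * theta^2 + 1.30) / drop$density
  drop$volume_fL * 1e-18 / rate_m3_s * 1e3   # s -> ms
}

#' Spray configuration
#'
#' Geometry and operating point of the spray: flow rate, nozzle distance,
#' cone angle (the 18 deg default is the measured full apex angle, so the
#' half-angle is 9 deg), droplet velocity, and the lognormal initial droplet
#' volume distribution parameterised by its median and interquartile range
#' (defaults match the measured fluorescein imprint statistics at 2 cm:
#' median 100 fL, IQR 40-210 fL).
#'
#' @param flow_rate_ul_h liquid flow rate in ul h^-1.
#' @param nozzle_distance_cm nozzle-to-surface distance in cm.
#' @param cone_full_angle_deg full apex angle of the spray cone in degrees.
#' @param droplet_velocity_m_s droplet speed in m s^-1.
#' @param volume_median_fL median of the initial droplet volume (fL).
#' @param volume_iqr_fL quartiles `c(q1, q3)` of the initial volume (fL).
#' @param contact_angle_deg equilibrium contact angle on the substrate.
#' @return a `spray_config`.
#' @export
spray_config <- function(flow_rate_ul_h = 100, nozzle_distance_cm = 4,
                         cone_full_angle_deg = 18,
                         droplet_velocity_m_s = 20,
                         volume_median_fL = 100,
                         volume_iqr_fL = c(40, 210),
                         contact_angle_deg = 15.3) {
  stopifnot(flow_rate_ul_h >= 0, nozzle_distance_cm > 0,
            cone_full_angle_deg > 0, cone_full_angle_deg < 90,
            droplet_velocity_m_s > 0, volume_median_fL > 0,
            length(volume_iqr_fL) == 2L, all(volume_iqr_fL > 0),
            volume_iqr_fL[1] < volume_iqr_fL[2])
  structure(list(flow_rate_ul_h = flow_rate_ul_h,
                 nozzle_distance_cm = nozzle_distance_cm,
                 cone_full_angle_deg = cone_full_angle_deg,
                 droplet_velocity_m_s = droplet_velocity_m_s,
                 volume_median_fL = volume_median_fL,
                 volume_iqr_fL = volume_iqr_fL,
                 contact_angle_deg = contact_angle_deg),
            class = "spray_config")
}

#' Spray footprint area on the substrate
#'
#' `pi (d tan(cone/2))^2` in um^2.
#'
#' @param config a [spray_config()].
#' @return area in um^2.
#' @export
spray_footprint_area <- function(config) {
  stopifnot(inherits(config, "spray_config"))
  r_um <- config$nozzle_distance_cm * 1e4 *
    tan(config$cone_full_angle_deg / 2 * pi / 180)
  pi * r_um^2
}

#' Lognormal parameters from a median and interquartile range
#'
#' `meanlog = log(median)`; the spread comes from the quartile ratio,
#' `sdlog = log(q3/q1) / (2 z_0.75)`. When median and quartiles are not
#' exactly consistent with one lognormal (as for the printed droplet
#' summaries), the median is honoured exactly and the quartile ratio sets
#' the width.
#'
#' @param median_ distribution median.
#' @param q1,q3 first and third quartiles.
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormal_from_quartiles <- function(median_, q1, q3) {
  stopifnot(median_ > 0, q1 > 0, q3 > q1)
  list(meanlog = log(median_), sdlog = log(q3 / q1) / (2 * qnorm(0.75)))
}

#' Sample an ensemble of initial droplet volumes
#'
#' Draws `n` initial (at-nozzle) droplet volumes from the lognormal
#' distribution specified by the spray configuration.
#'
#' @param n number of droplets.
#' @param config a [spray_config()].
#' @param seed optional integer seed.
#' @return a `droplet_ensemble`: data frame with `volume_fL` plus the
#'   config as an attribute.
#' @export
sample_droplet_ensemble <- function(n, config = spray_config(), seed = NULL) {
  stopifnot(n >= 1, inherits(config, "spray_config"))
  local_seed(seed)
  ln <- lognormal_from_quartiles(config$volume_median_fL,
                                 config$volume_iqr_fL[1],
                                 config$volume_iqr_fL[2])
  structure(data.frame(volume_fL = rlnorm(n, ln$meanlog, ln$sdlog)),
            class = c("droplet_ensemble", "data.frame"),
            config = config)
}

#' Drying-time distribution of a sprayed droplet ensemble
#'
#' Runs every droplet through the deposition pipeline: initial volume ->
#' in-flight evaporation over the nozzle distance ([evolve_in_flight()]) ->
#' landing as a spherical cap at the equilibrium contact angle (volume
#' conserved at impact) -> pinned-line sessile drying
#' ([sessile_drying_time()]). Droplets that evaporate completely in flight
#' are counted but excluded from the landed summaries.
#'
#' @param ensemble a `droplet_ensemble` (or data frame with `volume_fL`).
#' @param config a [spray_config()].
#' @param air an [air_state()]; the spray deposits under the dry N2 jet, so
#'   the dry-air state is the physically relevant default here.
#' @return a `drying_summary` list: per-droplet data frame `droplets`
#'   (`volume0_fL`, `landed_fL`, `imprint_um2`, `drying_ms`), medians and
#'   IQRs of landed volume and drying time, and the landed fraction.
#' @export
#' @examples
#' ens <- sample_droplet_ensemble(500, spray_config(), seed = 1)
#' drying_time_distribution(ens, spray_config(), air_state(25, 0))
drying_time_distribution <- function(ensemble, config = spray_config(),
                                     air = air_state(25, 0)) {
  if (is.null(nrow(ensemble)) || nrow(ensemble) == 0L)
    stop("`ensemble` must be a nonempty droplet ensemble")
  stopifnot(inherits(config, "spray_config"), inherits(air, "air_state"))
  v0 <- ensemble$volume_fL
  landed <- vapply(v0, function(v) {
    d <- evolve_in_flight(droplet(v, config$contact_angle_deg),
                          config$nozzle_distance_cm,
                          config$droplet_velocity_m_s, air)
    d$volume_fL
  }, numeric(1))
  alive <- landed > 0
  imprint <- rep(NA_real_, length(v0))
  drying <- rep(NA_real_, length(v0))
  if (any(alive)) {
    imprint[alive] <- imprint_area(landed[alive], config$contact_angle_deg)
    drying[alive] <- vapply(landed[alive], function(v)
      sessile_drying_time(droplet(v, config$contact_angle_deg), air),
      numeric(1))
  }
  qs <- function(x) if (any(is.finite(x)))
    unname(quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)) else rep(NA_real_, 3)
  ql <- qs(landed[alive]); qd <- qs(drying[alive])
  structure(list(droplets = data.frame(volume0_fL = v0, landed_fL = landed,
                                       imprint_um2 = imprint,
                                       drying_ms = drying),
                 n = length(v0), n_landed = sum(alive),
                 landed_fraction = mean(alive),
                 landed_median_fL = ql[2], landed_iqr_fL = ql[c(1, 3)],
                 drying_median_ms = qd[2], drying_iqr_ms = qd[c(1, 3)],
                 mean_imprint_um2 = mean(imprint[alive])),
            class = "drying_summary")
}

#' @export
print.drying_summary <- function(x, ...) {
  cat(sprintf("Droplet ensemble: %d droplets, %d landed (%.1f%%)\n",
              x$n, x$n_landed, 100 * x$landed_fraction))
  if (x$n_landed > 0) {
    cat(sprintf("  landed volume: median %.3g fL, IQR %.3g-%.3g fL\n",
                x$landed_median_fL, x$landed_iqr_fL[1], x$landed_iqr_fL[2]))
    cat(sprintf("  drying time:   median %.3g ms, IQR %.3g-%.3g ms\n",
                x$drying_median_ms, x$drying_iqr_ms[1], x$drying_iqr_ms[2]))
  }
  invisible(x)
}

#' Root-mean-square 2D diffusion displacement
#'
#' `sqrt(4 D t)` in nm: the upper bound on how far a protein can wander on
#' the liquid-solid interface while a droplet dries. With the typical
#' interfacial diffusion constant 0.2 um^2/s and a 2 ms drying time this is
#' 40 nm, i.e. molecules are effectively frozen in place at the AFM imaging
#' scale.
#'
#' @param D_um2_s lateral diffusion constant in um^2 s^-1.
#' @param t_ms time in ms.
#' @return RMS displacement in nm (vectorised).
#' @export
#' @examples
#' diffusion_displacement(0.2, 2)  # 40 nm
diffusion_displacement <- function(D_um2_s, t_ms) {
  stopifnot(all(D_um2_s >= 0), all(t_ms >= 0))
  sqrt(4 * D_um2_s * t_ms * 1e-3) * 1e3   # um -> nm
}

#' Wet-surface coverage and coalescence regime
#'
#' A landing droplet can coalesce with a still-wet predecessor. With
#' arrival rate `flow_rate / median volume`, spray footprint
#' `pi (d tan(cone/2))^2`, and each droplet wet for one drying time, the
#' expected fractional area covered by wet droplets in a drying window is
#' `arrival_rate * drying_time * mean_imprint_area / footprint`. Regime I
#' (well-resolved droplets) holds while this wet coverage stays below the
#' coalescence threshold; otherwise the spray lays down continuous streams
#' (regime II). The coalescence probability for an incoming droplet is
#' estimated from a Poisson (Boolean-model) overlap argument,
#' `1 - exp(-4 * coverage)` (a landing centre must avoid disks of twice the
#' imprint radius).
#'
#' @param config a [spray_config()].
#' @param mean_imprint_area_um2 mean single-droplet imprint area, um^2.
#' @param median_volume_fL median landing droplet volume, fL.
#' @param drying_time_ms droplet drying time, ms.
#' @param coalescence_threshold wet-coverage fraction separating regimes
#'   (default 0.05).
#' @return a list: `arrival_rate_per_ms`, `droplets_per_window`,
#'   `footprint_um2`, `wet_coverage`, `p_coalescence`, `regime`
#'   (`"I"` or `"II"`).
#' @export
#' @examples
#' coverage_and_regime(spray_config(flow_rate_ul_h = 300), 150, 250, 15)
coverage_and_regime <- function(config, mean_imprint_area_um2,
                                median_volume_fL, drying_time_ms,
                                coalescence_threshold = 0.05) {
  stopifnot(inherits(config, "spray_config"),
            mean_imprint_area_um2 > 0, median_volume_fL > 0,
            drying_time_ms >= 0, coalescence_threshold > 0)
  footprint <- spray_footprint_area(config)
  if (footprint <= 0) stop("zero spray footprint")
  q_fl_ms <- config$flow_rate_ul_h * 1e9 / 3.6e6   # ul/h -> fL/ms
  arrival <- q_fl_ms / median_volume_fL            # droplets per ms
  coverage <- arrival * drying_time_ms * mean_imprint_area_um2 / footprint
  list(arrival_rate_per_ms = arrival,
       droplets_per_window = arrival * drying_time_ms,
       footprint_um2 = footprint,
       wet_coverage = coverage,
       p_coalescence = 1 - exp(-4 * coverage),
       regime = if (coverage < coalescence_threshold) "I" else "II")
}

#' Sensitivity of the drying time to ambient conditions
#'
#' Reports how much the sessile drying time of a droplet moves under small
#' ambient perturbations (default +/-2 deg C and +/-10% RH, typical
#' air-conditioned laboratory drift), as the largest absolute change over
#' the four one-sided perturbations.
#'
#' @param drop a sessile [droplet()].
#' @param air the reference [air_state()].
#' @param dT temperature perturbation, deg C.
#' @param dRH relative-humidity perturbation, fraction.
#' @return list with `t_ref_ms`, `delta_T_ms`, `delta_RH_ms` (worst-case
#'   absolute changes).
#' @export
drying_time_sensitivity <- function(drop, air = air_state(25, 0),
                                    dT = 2, dRH = 0.1) {
  stopifnot(inherits(drop, "droplet"), inherits(air, "air_state"))
  t0 <- sessile_drying_time(drop, air)
  t_T <- vapply(c(-dT, dT), function(d)
    sessile_drying_time(drop, air_state(air$temperature_C + d,
                                        air$relative_humidity, air$D_v)),
    numeric(1))
  rh <- pmin(1, pmax(0, air$relative_humidity + c(-dRH, dRH)))
  t_RH <- vapply(rh, function(r)
    sessile_drying_time(drop, air_state(air$temperature_C, r, air$D_v)),
    numeric(1))
  list(t_ref_ms = t0,
       delta_T_ms = max(abs(t_T - t0)),
       delta_RH_ms = max(abs(t_RH - t0)))
}
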