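test_that("spherical-cap volume matches limits and a numerical oracle", {
  # hemisphere: theta = 90 deg, a = 1 um -> V = 2*pi/3 fL
  expect_equal(cap_volume(pi, 90), 2 * pi / 3)
  # numerical oracle: revolve the cap profile, V = int_0^h pi r(z)^2 dz
  cap_oracle <- function(area, theta_deg) {
    a <- sqrt(area / pi)
    th <- theta_deg * pi / 180
    Rs <- a / sin(th)               # sphere radius
    h <- Rs * (1 - cos(th))         # cap height
    integrate(function(z) pi * (Rs^2 - (Rs - h + z)^2), 0, h,
              rel.tol = 1e-10)$value
  }
  for (case in list(c(200, 15.3), c(50, 40), c(120, 75))) {
    expect_equal(cap_volume(case[1], case[2]), cap_oracle(case[1], case[2]),
                 tolerance = 1e-8)
  }
  expect_equal(cap_volume(200, 15.3), 107.9, tolerance = 1e-3)
  # monotone in both arguments, -> 0 with area
  expect_true(cap_volume(100, 20) < cap_volume(200, 20))
  expect_true(cap_volume(100, 20) < cap_volume(100, 30))
  expect_lt(cap_volume(1e-6, 20), 1e-8)
  expect_error(cap_volume(-1, 20), "positive")
})

test_that("imprint area inverts cap volume to machine precision", {
  for (V in c(1, 5, 25, 100, 250)) {
    for (th in c(5, 15.3, 30, 60, 89)) {
      expect_equal(cap_volume(imprint_area(V, th), th), V,
                   tolerance = 1e-9)
    }
  }
})

test_that("Bond number reproduces the capillary length and spray-droplet scales", {
  # capillary length: Bo = 1 by definition
  lc_um <- sqrt(0.072 / (997 * 9.81)) * 1e6
  expect_equal(bond_number(lc_um), 1, tolerance = 1e-9)
  # contact radius of a 200 um^2 imprint
  expect_equal(bond_number(7.98), 8.7e-6, tolerance = 0.01)
  # Bo << 1 across the whole observed imprint range (<= 250 um^2)
  a_max <- sqrt(250 / pi)
  expect_lt(bond_number(a_max), 1e-4)
})

test_that("Maxwell in-flight evaporation rate behaves as specified", {
  air <- air_state(25, 0.5)
  # saturated air: no evaporation
  expect_equal(flight_evaporation_rate(2.88, air_state(25, 1)), 0)
  # ~10 fL/ms for a 100 fL droplet at lab conditions
  expect_equal(flight_evaporation_rate(2.88, air), 10, tolerance = 0.1)
  # linear in R
  expect_equal(flight_evaporation_rate(4, air),
               2 * flight_evaporation_rate(2, air))
})

test_that("in-flight evolution follows the R^2 law and its oracle", {
  air <- air_state(25, 0.5)
  d0 <- droplet(100)
  # distance 0 and saturated air leave the droplet unchanged
  expect_equal(evolve_in_flight(d0, 0, 20, air)$volume_fL, 100)
  expect_equal(evolve_in_flight(d0, 10, 20, air_state(25, 1))$volume_fL, 100)
  # closed form vs explicit time-stepping of dR/dt = -D dc / (rho R)
  d1 <- evolve_in_flight(d0, 4, 20, air)
  expect_equal(d1$radius_um, 2.67, tolerance = 1e-3)
  expect_equal(d1$volume_fL, 80, tolerance = 0.01)
  R <- d0$radius_um * 1e-6
  dt <- 1e-7
  for (t in seq(0, 2e-3 - dt, by = dt))
    R <- R - dt * air$D_v * air$delta_c / (997 * R)
  expect_equal(d1$radius_um, R * 1e6, tolerance = 1e-4)
  # semigroup: flying 4 cm equals 1.5 cm then 2.5 cm
  d2 <- evolve_in_flight(evolve_in_flight(d0, 1.5, 20, air), 2.5, 20, air)
  expect_equal(d1$volume_fL, d2$volume_fL, tolerance = 1e-9)
  # never increases volume; tiny droplets evaporate fully and are flagged
  expect_lte(d1$volume_fL, 100)
  gone <- evolve_in_flight(droplet(0.5), 10, 10, air)
  expect_true(gone$evaporated)
  expect_equal(gone$volume_fL, 0)
})

test_that("pinned-line sessile drying matches the measured anchor", {
  dry <- air_state(25, 0)
  # 100 fL droplet, ~200 um^2 imprint at 15.3 deg: about 5 ms measured;
  # require agreement within a factor of 3
  t100 <- sessile_drying_time(droplet(100), dry)
  expect_gt(t100, 5 / 3)
  expect_lt(t100, 5 * 3)
  # drying time linear in volume at fixed (a, theta, air): constant dV/dt
  d <- droplet(100)
  d2 <- d; d2$volume_fL <- 50          # same cap geometry, half the liquid
  expect_equal(sessile_drying_time(d2, dry),
               sessile_drying_time(d, dry) / 2)
  # saturated air never dries
  expect_equal(sessile_drying_time(d, air_state(25, 1)), Inf)
})

test_that("drying slows with humidity and accelerates with temperature", {
  d <- droplet(100)
  t_rh <- vapply(c(0, 0.3, 0.6, 0.9), function(rh)
    sessile_drying_time(d, air_state(25, rh)), numeric(1))
  expect_true(all(diff(t_rh) > 0))
  t_T <- vapply(c(15, 20, 25, 30), function(Tc)
    sessile_drying_time(d, air_state(Tc, 0.5)), numeric(1))
  expect_true(all(diff(t_T) < 0))
  sens <- drying_time_sensitivity(d, air_state(25, 0))
  expect_gt(sens$delta_T_ms, 0)
  expect_gt(sens$delta_RH_ms, 0)
})

test_that("lognormal ensemble honours the median and quartile ratio", {
  ln <- lognormal_from_quartiles(100, 40, 210)
  expect_equal(exp(ln$meanlog), 100)
  expect_equal(qlnorm(0.75, ln$meanlog, ln$sdlog) /
                 qlnorm(0.25, ln$meanlog, ln$sdlog), 210 / 40)
  ens <- sample_droplet_ensemble(20000, spray_config(), seed = 5)
  expect_equal(median(ens$volume_fL), 100, tolerance = 0.05)
})

test_that("drying-time distribution pipeline summarises the ensemble", {
  cfg <- spray_config()
  dry <- air_state(25, 0)
  # monodisperse ensemble -> zero IQR
  mono <- data.frame(volume_fL = rep(100, 50))
  s <- drying_time_distribution(mono, cfg, dry)
  expect_equal(s$drying_iqr_ms[1], s$drying_iqr_ms[2])
  expect_equal(s$landed_fraction, 1)
  # all droplets evaporating in flight is reported, not an error
  tiny <- data.frame(volume_fL = rep(0.2, 10))
  s2 <- drying_time_distribution(tiny,
                                 spray_config(nozzle_distance_cm = 10), dry)
  expect_equal(s2$n_landed, 0L)
  expect_error(drying_time_distribution(data.frame(volume_fL = numeric())),
               "nonempty")
  # full ensemble lands in the low-millisecond range
  ens <- sample_droplet_ensemble(2000, cfg, seed = 6)
  s3 <- drying_time_distribution(ens, cfg, dry)
  expect_gt(s3$drying_median_ms, 0.5)
  expect_lt(s3$drying_median_ms, 5)
})

test_that("diffusion displacement reproduces the 40 nm bound", {
  expect_equal(diffusion_displacement(0.2, 0), 0)
  expect_equal(diffusion_displacement(0.2, 2), 40)
  span <- diffusion_displacement(0.2, c(0.7, 4.3))
  expect_equal(span, c(23.66, 58.65), tolerance = 1e-3)
})

test_that("coverage stays tiny in the non-coalescence regime and scales correctly", {
  cfg <- spray_config(flow_rate_ul_h = 300, nozzle_distance_cm = 4)
  cov <- coverage_and_regime(cfg, mean_imprint_area_um2 = 150,
                             median_volume_fL = 250, drying_time_ms = 15)
  # Q t / V arithmetic: 300 ul/h for 15 ms at 250 fL -> 5000 droplets
  expect_equal(cov$droplets_per_window, 5000)
  expect_lt(cov$wet_coverage, 0.05)
  expect_equal(cov$regime, "I")
  # zero flow: no coverage, regime I
  cov0 <- coverage_and_regime(spray_config(flow_rate_ul_h = 0), 150, 250, 15)
  expect_equal(cov0$wet_coverage, 0)
  expect_equal(cov0$regime, "I")
  # coverage strictly decreases with distance (footprint ~ d^2)
  covs <- vapply(c(1, 2, 4, 8), function(d)
    coverage_and_regime(spray_config(flow_rate_ul_h = 300,
                                     nozzle_distance_cm = d),
                        150, 250, 15)$wet_coverage, numeric(1))
  expect_true(all(diff(covs) < 0))
  # close + fast flow coalesces (regime II)
  cov2 <- coverage_and_regime(spray_config(flow_rate_ul_h = 1000,
                                           nozzle_distance_cm = 0.5),
                              150, 100, 15)
  expect_equal(cov2$regime, "II")
})
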