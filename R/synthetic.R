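#' Parameters for synthetic particle-field generation
#'
#' Controls the synthetic fields that emulate spray-deposited (random) or
#' surface-self-organised (aligned) protein-scale particles on an atomically
#' flat substrate.
#'
#' `order_strength` moves the generator between the two regimes: at 0 every
#' particle is placed independently and uniformly (the random-deposition
#' null); at 1 every particle belongs to a chain whose bonds follow the
#' lattice orientations exactly. In between, a fraction `s` of particles sit
#' in chains and the per-bond angular jitter shrinks linearly to zero,
#' `sd = jitter_max_deg * (1 - s)`, giving a single interpretable ordering
#' knob.
#'
#' @param density particles per um^2.
#' @param order_strength s in \[0, 1\].
#' @param lattice_orientations chain bond orientations in degrees
#'   (default `c(0, 60, 120)`, the three-fold symmetry of mica/HOPG).
#' @param chain_spacing distance between consecutive chain particles in nm
#'   (default 20: beads resolvable as individual maxima at the default
#'   particle sigma of 5 nm, yet closer than the random nearest-neighbour
#'   distance at typical densities).
#' @param chain_length number of particles per chain.
#' @param jitter_max_deg angular jitter s.d. (degrees) at `s = 0`,
#'   interpolated to 0 at `s = 1`.
#' @param particle_height median particle amplitude in nm (monomer-scale
#'   default 0.4 nm).
#' @param height_sdlog lognormal spread of particle amplitudes (0 for
#'   identical heights).
#' @param particle_sigma Gaussian footprint sigma in nm.
#' @param noise_sd additive pixel noise s.d. in nm used by
#'   [render_height_map()] when not overridden.
#' @return a list of class `generation_params`.
#' @export
generation_params <- function(density = 100,
                              order_strength = 0,
                              lattice_orientations = c(0, 60, 120),
                              chain_spacing = 20,
                              chain_length = 5,
                              jitter_max_deg = 10,
                              particle_height = 0.4,
                              height_sdlog = 0.25,
                              particle_sigma = 5,
                              noise_sd = 0.05) {
  stopifnot(density >= 0,
            order_strength >= 0, order_strength <= 1,
            chain_spacing > 0, chain_length >= 2,
            jitter_max_deg >= 0,
            particle_height > 0, height_sdlog >= 0, particle_sigma > 0,
            noise_sd >= 0)
  if (order_strength > 0 && length(lattice_orientations) == 0L)
    stop("`lattice_orientations` must be nonempty when order_strength > 0")
  structure(list(density = density, order_strength = order_strength,
                 lattice_orientations = lattice_orientations,
                 chain_spacing = chain_spacing, chain_length = chain_length,
                 jitter_max_deg = jitter_max_deg,
                 particle_height = particle_height,
                 height_sdlog = height_sdlog,
                 particle_sigma = particle_sigma, noise_sd = noise_sd),
            class = "generation_params")
}

new_particle_field <- function(x, y, height, sigma, extent) {
  stopifnot(length(x) == length(y), length(height) == length(x),
            length(sigma) == length(x))
  if (length(x)) {
    stopifnot(all(x >= 0 & x <= extent[1]), all(y >= 0 & y <= extent[2]),
              all(height > 0), all(sigma > 0))
  }
  structure(list(x = x, y = y, height = height, sigma = sigma,
                 extent = as.numeric(extent)),
            class = "particle_field")
}

#' @export
print.particle_field <- function(x, ...) {
  cat(sprintf("Particle field: %d particles on %.4g x %.4g nm (%.3g / um^2)\n",
              length(x$x), x$extent[1], x$extent[2],
              length(x$x) / prod(x$extent) * 1e6))
  invisible(x)
}

draw_particle_geometry <- function(n, params) {
  height <- if (params$height_sdlog > 0)
    rlnorm(n, meanlog = log(params$particle_height), sdlog = params$height_sdlog)
  else rep(params$particle_height, n)
  sigma <- rep(params$particle_sigma, n)
  list(height = height, sigma = sigma)
}

#' Generate a completely random (Poisson) particle field
#'
#' Positions are an independent uniform sample over the extent with
#' Poisson-distributed count of mean `density * area`; this is the
#' random-deposition null model of the ordering analysis, for which the
#' nearest-neighbour angle distribution is flat.
#'
#' @param density particles per um^2.
#' @param extent `c(width, height)` in nm.
#' @param params a [generation_params()] supplying particle geometry.
#' @param seed optional integer seed (RNG untouched when `NULL`).
#' @return a `particle_field` with per-particle positions (nm), heights (nm)
#'   and Gaussian sigmas (nm).
#' @export
#' @examples
#' f <- generate_random_field(100, c(2000, 2000), seed = 1)
#' f
generate_random_field <- function(density, extent = c(2000, 2000),
                                  params = generation_params(), seed = NULL) {
  if (!is.numeric(density) || density < 0)
    stop("`density` must be a non-negative number (per um^2)")
  if (any(extent <= 0)) stop("`extent` must be positive (nm)")
  local_seed(seed)
  n <- rpois(1L, density * 1e-6 * prod(extent))
  x <- runif(n, 0, extent[1])
  y <- runif(n, 0, extent[2])
  geom <- draw_particle_geometry(n, params)
  new_particle_field(x, y, geom$height, geom$sigma, extent)
}

#' Generate a partially ordered particle field
#'
#' Emulates surface self-organisation along crystallographic lattice
#' directions: a fraction `s = params$order_strength` of the particles is
#' laid down in chains of `chain_length` points spaced `chain_spacing` nm
#' apart, each bond oriented along a randomly chosen lattice direction plus
#' Gaussian angular jitter of s.d. `jitter_max_deg * (1 - s)` degrees; the
#' remaining particles are uniform. At `s = 0` the generator reduces exactly
#' to [generate_random_field()] (same RNG consumption), and at `s = 1` with a
#' single orientation the within-chain bond angles equal that orientation
#' exactly.
#'
#' @inheritParams generate_random_field
#' @return a `particle_field`.
#' @export
#' @examples
#' p <- generation_params(order_strength = 0.8)
#' f <- generate_ordered_field(100, c(2000, 2000), p, seed = 1)
generate_ordered_field <- function(density, extent = c(2000, 2000),
                                   params = generation_params(), seed = NULL) {
  s <- params$order_strength
  if (s == 0) return(generate_random_field(density, extent, params, seed))
  if (length(params$lattice_orientations) == 0L)
    stop("`lattice_orientations` must be nonempty when order_strength > 0")
  if (any(extent <= 0)) stop("`extent` must be positive (nm)")
  local_seed(seed)
  n <- rpois(1L, density * 1e-6 * prod(extent))
  n_chain <- round(s * n)
  n_free <- n - n_chain
  x <- runif(n_free, 0, extent[1])
  y <- runif(n_free, 0, extent[2])
  jitter_sd <- params$jitter_max_deg * (1 - s) * pi / 180
  placed <- 0L
  while (placed < n_chain) {
    len <- min(params$chain_length, n_chain - placed)
    for (try in 1:100) {
      x0 <- runif(1, 0, extent[1])
      y0 <- runif(1, 0, extent[2])
      orients <- params$lattice_orientations
      base <- orients[sample.int(length(orients), 1L)] * pi / 180
      cx <- numeric(len); cy <- numeric(len)
      cx[1] <- x0; cy[1] <- y0
      ok <- TRUE
      if (len > 1L) for (k in 2:len) {
        ang <- base + if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0
        cx[k] <- cx[k - 1] + params$chain_spacing * cos(ang)
        cy[k] <- cy[k - 1] + params$chain_spacing * sin(ang)
        if (cx[k] < 0 || cx[k] > extent[1] || cy[k] < 0 || cy[k] > extent[2]) {
          ok <- FALSE
          break
        }
      }
      if (ok) break
    }
    if (!ok) stop("could not place a chain inside the extent; ",
                  "extent too small for chain_spacing * chain_length")
    x <- c(x, cx); y <- c(y, cy)
    placed <- placed + len
  }
  geom <- draw_particle_geometry(length(x), params)
  new_particle_field(x, y, geom$height, geom$sigma, extent)
}

#' Rasterise a particle field into an AFM height map
#'
#' Each particle contributes an isotropic 2D Gaussian bump (amplitude =
#' particle height, sigma = particle width) evaluated at pixel centres;
#' overlapping bumps add linearly. Independent Gaussian pixel noise of s.d.
#' `noise_sd` is then added. Deterministic given `seed`.
#'
#' @param field a `particle_field`.
#' @param pixel_size nm per pixel.
#' @param noise_sd additive noise s.d. in nm; default taken from the field's
#'   generation defaults is not assumed -- pass 0 for a noiseless map.
#' @param seed optional integer seed for the noise draw.
#' @return an [afm_map()].
#' @export
#' @examples
#' f <- generate_random_field(50, c(1000, 1000), seed = 1)
#' m <- render_height_map(f, pixel_size = 4, noise_sd = 0.05, seed = 2)
render_height_map <- function(field, pixel_size, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(field, "particle_field"))
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive (nm)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  local_seed(seed)
  nx <- max(1L, ceiling(field$extent[1] / pixel_size))
  ny <- max(1L, ceiling(field$extent[2] / pixel_size))
  grid <- matrix(0, ny, nx)
  if (length(field$x)) {
    for (k in seq_along(field$x)) {
      s <- field$sigma[k]
      half <- ceiling(4 * s / pixel_size)
      jc <- field$x[k] / pixel_size + 0.5   # fractional column index
      ic <- field$y[k] / pixel_size + 0.5
      cols <- max(1L, floor(jc - half)):min(nx, ceiling(jc + half))
      rows <- max(1L, floor(ic - half)):min(ny, ceiling(ic + half))
      dx <- (cols - 0.5) * pixel_size - field$x[k]
      dy <- (rows - 0.5) * pixel_size - field$y[k]
      bump <- field$height[k] *
        exp(-(outer(dy^2, dx^2, "+")) / (2 * s^2))
      grid[rows, cols] <- grid[rows, cols] + bump
    }
  }
  if (noise_sd > 0)
    grid <- grid + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
  afm_map(grid, pixel_size)
}

#' Ground-truth maxima from a particle field
#'
#' Wraps the generator's exact particle positions as a [maxima_set] (1 nm
#' "pixels"), so the ordering and occupancy statistics can be computed on
#' ground truth without rasterisation and detection -- useful for null-model
#' calibration where detection error is not the question.
#'
#' @param field a `particle_field`.
#' @return a `maxima_set`.
#' @export
field_maxima <- function(field) {
  stopifnot(inherits(field, "particle_field"))
  new_maxima_set(x = field$x + 0.5, y = field$y + 0.5,
                 height = field$height,
                 prominence = rep(Inf, length(field$x)),
                 dim = c(ceiling(field$extent[2]), ceiling(field$extent[1])),
                 pixel_size = 1)
}

#' Write particle-field ground truth to CSV
#'
#' Columns: `x_nm, y_nm, height_nm, sigma_nm`.
#'
#' @param field a `particle_field`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "particle_field"))
  write.csv(data.frame(x_nm = field$x, y_nm = field$y,
                       height_nm = field$height, sigma_nm = field$sigma),
            path, row.names = FALSE)
  invisible(path)
}
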