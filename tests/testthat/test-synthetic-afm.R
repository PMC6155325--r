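test_that("zero density gives an empty field and negative inputs are rejected", {
  f <- generate_random_field(0, c(1000, 1000), seed = 1)
  expect_length(f$x, 0)
  expect_error(generate_random_field(-1, c(1000, 1000)), "non-negative")
  expect_error(generate_random_field(10, c(-5, 1000)), "positive")
})

test_that("random-field particle count is Poisson with mean density x area", {
  counts <- vapply(1:40, function(k)
    length(generate_random_field(100, c(10000, 10000),
                                 seed = split_seed(5, k))$x),
    numeric(1))
  # mean 10000, sd sqrt(10000) = 100; 40 seeds -> se ~ 16
  expect_lt(abs(mean(counts) - 10000), 5 * 100 / sqrt(40))
})

test_that("all particles lie inside the extent with positive geometry", {
  for (s in c(0, 0.6, 1)) {
    p <- generation_params(order_strength = s)
    f <- generate_ordered_field(150, c(1500, 1500), p, seed = 17 + s * 10)
    expect_true(all(f$x >= 0 & f$x <= 1500))
    expect_true(all(f$y >= 0 & f$y <= 1500))
    expect_true(all(f$height > 0) && all(f$sigma > 0))
  }
})

test_that("order strength 0 reduces exactly to the random generator", {
  p <- generation_params(order_strength = 0)
  f1 <- generate_ordered_field(80, c(2000, 2000), p, seed = 9)
  f2 <- generate_random_field(80, c(2000, 2000), p, seed = 9)
  expect_identical(f1, f2)
})

test_that("fully ordered single-orientation chains have zero bond angles", {
  p <- generation_params(order_strength = 1, lattice_orientations = 0,
                         chain_spacing = 12, chain_length = 5)
  f <- generate_ordered_field(100, c(4000, 4000), p, seed = 3)
  expect_gt(length(f$x), 50)
  # within-chain consecutive bonds are exactly horizontal
  dx <- diff(f$x); dy <- diff(f$y)
  intra <- abs(sqrt(dx^2 + dy^2) - 12) < 1e-9   # consecutive chain members
  expect_gt(sum(intra), 0)
  expect_true(all(abs(dy[intra]) < 1e-9))
})

test_that("empty orientation set with positive order strength is rejected", {
  expect_error(generation_params(order_strength = 0.5,
                                 lattice_orientations = numeric(0)),
               "nonempty")
})

test_that("rendering an empty field without noise gives an all-zero map", {
  f <- generate_random_field(0, c(100, 100))
  m <- render_height_map(f, pixel_size = 4, noise_sd = 0)
  expect_true(all(m$grid == 0))
  expect_equal(dim(m$grid), c(25, 25))
})

test_that("a particle at a pixel centre renders with its exact amplitude", {
  # pixel (row 5, col 8) centre at x = 7.5 * 4 = 30, y = 4.5 * 4 = 18
  f <- fixed_field(x = 30, y = 18, height = 0.5, sigma = 5,
                   extent = c(100, 100))
  m <- render_height_map(f, pixel_size = 4, noise_sd = 0)
  expect_equal(max(m$grid), 0.5)
  expect_equal(which(m$grid == max(m$grid)), (8 - 1) * 25 + 5) # col-major
})

test_that("overlapping bumps add linearly", {
  f1 <- fixed_field(30, 18, 0.5, 5, extent = c(100, 100))
  f2 <- fixed_field(34, 18, 0.3, 5, extent = c(100, 100))
  f12 <- fixed_field(c(30, 34), c(18, 18), c(0.5, 0.3), 5,
                     extent = c(100, 100))
  m1 <- render_height_map(f1, 4, 0)
  m2 <- render_height_map(f2, 4, 0)
  m12 <- render_height_map(f12, 4, 0)
  expect_equal(m12$grid, m1$grid + m2$grid, tolerance = 1e-12)
})

test_that("rendering is deterministic given a seed", {
  f <- generate_random_field(50, c(1000, 1000), seed = 2)
  m1 <- render_height_map(f, 4, noise_sd = 0.05, seed = 10)
  m2 <- render_height_map(f, 4, noise_sd = 0.05, seed = 10)
  expect_identical(m1$grid, m2$grid)
})

test_that("detection recovers nearly all well-separated rendered particles", {
  # 100 particles on a coarse jittered grid: guaranteed >= 40 nm separation
  set.seed(21)
  gx <- rep(1:10, 10) * 190 - 100 + runif(100, -30, 30)
  gy <- rep(1:10, each = 10) * 190 - 100 + runif(100, -30, 30)
  f <- fixed_field(gx, gy, height = 1, sigma = 5, extent = c(2000, 2000))
  m <- render_height_map(f, 4, noise_sd = 0.05, seed = 22)
  mx <- detect_maxima(m)
  # match detections to ground truth within 3 pixels
  d <- sqrt(outer((mx$x - 0.5) * 4, gx, "-")^2 +
              outer((mx$y - 0.5) * 4, gy, "-")^2)
  recovered <- sum(apply(d, 2L, min) < 12)
  expect_gte(recovered, 95)
})

test_that("random-field nearest-neighbour spacing matches Poisson theory", {
  # border-corrected mean NN distance ~ 1/(2 sqrt(lambda)), 20 seeds
  means <- vapply(1:20, function(k) {
    f <- generate_random_field(25, c(20000, 20000), seed = split_seed(31, k))
    measure_nn_distances(field_maxima(f))$mean_nm
  }, numeric(1))
  expect_lt(abs(mean(means) / expected_nn_distance(25) - 1), 0.02)
})

test_that("random-field angle histogram is flat to binomial accuracy", {
  # pool fields until >= 5000 pairs; each bin within 4 binomial sd of N/8
  counts <- rep(0, 8)
  k <- 0L
  while (sum(counts) < 5000) {
    k <- k + 1L
    f <- generate_random_field(75, c(3000, 3000), seed = split_seed(47, k))
    h <- angle_histogram(nearest_neighbor_pairs(field_maxima(f)))
    counts <- counts + h$counts
  }
  N <- sum(counts)
  tol <- 4 * sqrt(N * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - N / 8) < tol))
})

test_that("ground-truth CSV export round-trips", {
  f <- generate_random_field(50, c(1000, 1000), seed = 8)
  path <- tempfile(fileext = ".csv")
  write_field_csv(f, path)
  df <- read.csv(path)
  expect_named(df, c("x_nm", "y_nm", "height_nm", "sigma_nm"))
  expect_equal(df$x_nm, f$x)
  expect_equal(df$height_nm, f$height)
})
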