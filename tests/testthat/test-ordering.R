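test_that("single pair orientations land in the correct bins", {
  # along +x: theta = 0, central bin
  h <- angle_histogram(make_pair_set(px = 10, py = 0))
  expect_equal(h$counts[h$centers == 0], 1)
  expect_equal(sum(h$counts), 1)
  # vertical pairs up and down both go to the single merged end bin
  h2 <- angle_histogram(make_pair_set(px = c(0, 0), py = c(10, -10)))
  expect_equal(h2$counts[8], 2)
  expect_equal(sum(h2$counts), 2)
  # exactly on a bin edge: goes to the higher bin
  edge <- tan(pi / 16)
  h3 <- angle_histogram(make_pair_set(px = 1, py = edge))
  expect_equal(h3$counts[h3$centers == pi / 8], 1)
})

test_that("uniform angles fill all bins to multinomial accuracy", {
  set.seed(77)
  theta <- runif(8000, -pi / 2, pi / 2)
  h <- angle_histogram(make_pair_set(px = cos(theta), py = sin(theta)))
  expect_equal(sum(h$counts), 8000)
  tol <- 4 * sqrt(8000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(h$counts - 1000) < tol))
})

test_that("ordering parameter matches the closed-form extremes", {
  # all pairs in one bin: O = 7 (1 - 1/N)
  r <- order_parameter(make_hist(c(100, rep(0, 7))))
  expect_equal(r$O, 7 * (1 - 1 / 100))
  # perfectly flat: O = -7/N
  r2 <- order_parameter(make_hist(rep(12.5, 8)))
  expect_equal(r2$O, -7 / 100)
  expect_equal(r2$sigma2_sample, 0)
  # sigma_O = (7/N) sqrt(2/8)
  expect_equal(r$sigma_O, 7 / 100 * 0.5)
  expect_equal(r$N, 100)
})

test_that("ordering parameter respects its analytic bounds on random histograms", {
  set.seed(123)
  for (k in 1:300) {
    N <- sample(8:2000, 1)
    counts <- as.vector(rmultinom(1, N, prob = runif(8, 0.01, 1)))
    r <- order_parameter(make_hist(counts))
    mu <- N / 8
    s2b <- N * (1 / 8) * (7 / 8)
    expect_gte(r$O, -s2b / mu^2 - 1e-12)
    expect_lte(r$O, 7 * (1 - 1 / N) + 1e-12)
  }
})

test_that("degenerate histograms are rejected or warned about", {
  expect_error(order_parameter(make_hist(rep(0, 8))), "no counts")
  expect_warning(order_parameter(make_hist(c(3, rep(0, 7)))), "fewer pairs")
})

test_that("p-value follows the printed normal-tail expression", {
  # flat histogram: sigma_x = 0 -> p = 0.5
  expect_equal(order_p_value(make_hist(rep(12.5, 8))), 0.5)
  # frozen case: counts (20,10,...,10,20), N = 100
  # X = (C - 12.5)/sqrt(10.9375); sigma_x^2 = 150/87.5; p = 1 - Phi(sigma_x)
  h <- make_hist(c(20, 10, 10, 10, 10, 10, 10, 20))
  expect_equal(order_p_value(h), pnorm(sqrt(150 / 87.5), lower.tail = FALSE))
  expect_equal(order_p_value(h), 0.0952, tolerance = 1e-3)
  # p is strictly decreasing as counts concentrate
  conc <- seq(0, 80, by = 20)
  p <- vapply(conc, function(c0)
    order_p_value(make_hist(c(12.5 + c0, rep(12.5 - c0 / 7, 7)))),
    numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("inverse-variance combination reproduces hand-computed values", {
  r1 <- order_parameter(make_hist(c(30, rep(10, 7))))
  # single result: unchanged
  c1 <- combine_order(list(r1))
  expect_equal(c1$O, r1$O)
  expect_equal(c1$sigma_O, r1$sigma_O)
  # equal results: same O, sigma/sqrt(2)
  c2 <- combine_order(list(r1, r1))
  expect_equal(c2$O, r1$O)
  expect_equal(c2$sigma_O, r1$sigma_O / sqrt(2))
  # hand-evaluated weighting: (0.1, 0.1) + (0.3, 0.3) -> 0.12, 0.0949
  ra <- structure(list(O = 0.1, sigma_O = 0.1, N = 50), class = "order_result")
  rb <- structure(list(O = 0.3, sigma_O = 0.3, N = 50), class = "order_result")
  cc <- combine_order(list(ra, rb))
  expect_equal(cc$O, 0.12)
  expect_equal(cc$sigma_O, sqrt(1 / (100 + 1 / 0.09)))
  expect_equal(cc$sigma_O, 0.0949, tolerance = 1e-3)
  expect_error(combine_order(list()), "nonempty")
})

test_that("mean ordering parameter rises with generator order strength", {
  svals <- c(0, 0.5, 1)
  meanO <- vapply(svals, function(s) {
    mean(vapply(1:5, function(k) {
      p <- generation_params(order_strength = s)
      f <- generate_ordered_field(100, c(2000, 2000), p,
                                  seed = split_seed(13, s * 100 + k))
      order_parameter(angle_histogram(nearest_neighbor_pairs(
        field_maxima(f))))$O
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanO) > 0))
})

test_that("the full map-level analysis flags an ordered sample", {
  p <- generation_params(order_strength = 0.9, noise_sd = 0.03)
  f <- generate_ordered_field(120, c(2000, 2000), p, seed = 99)
  m <- render_height_map(f, 4, noise_sd = 0.03, seed = 100)
  res <- analyze_ordering(m)
  expect_gt(res$order$O, 3 * res$order$sigma_O)
  expect_lt(res$order$p_value, 0.05)
})
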