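# Fixture builders and independent oracles used across the suite.

# Pair set built directly from displacement vectors (nm).
make_pair_set <- function(px, py) {
  structure(list(pairs = data.frame(i = seq_along(px),
                                    j = seq_along(px) + length(px),
                                    px = px, py = py,
                                    dist_nm = sqrt(px^2 + py^2)),
                 N = length(px),
                 n_discarded_border = 0L, n_coincident = 0L),
            class = "pair_set")
}

# Angle histogram built directly from bin counts (8 bins, merged end bin
# last).
make_hist <- function(counts) {
  stopifnot(length(counts) == 8L)
  structure(list(counts = as.numeric(counts),
                 centers = c((-3:3) * pi / 8, pi / 2),
                 N = sum(counts), n_bins = 8L, merged_end_bin = TRUE),
            class = "angle_histogram")
}

# Brute-force all-pairs nearest-neighbour pairing implementing the pairing
# rules independently: visit points in index order, nearest neighbour by
# full distance matrix (ties to lowest index), unordered dedup on first
# evaluation, coincident exclusion, border discard.
bf_nn_pairs <- function(x_nm, y_nm, width_nm, height_nm) {
  n <- length(x_nm)
  D <- as.matrix(dist(cbind(x_nm, y_nm)))
  diag(D) <- Inf
  seen <- character(0)
  rows <- list()
  nb <- 0L; nc <- 0L
  for (i in seq_len(n)) {
    j <- which.min(D[i, ])          # first minimum = lowest index
    key <- paste(min(i, j), max(i, j))
    if (key %in% seen) next
    seen <- c(seen, key)
    d <- D[i, j]
    if (d == 0) { nc <- nc + 1L; next }
    border <- min(x_nm[i], width_nm - x_nm[i], y_nm[i], height_nm - y_nm[i])
    if (d > border) { nb <- nb + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      i = i, j = unname(j), px = x_nm[i] - x_nm[j], py = y_nm[i] - y_nm[j],
      dist_nm = d)
  }
  list(pairs = if (length(rows)) do.call(rbind, rows) else NULL,
       n_border = nb, n_coincident = nc)
}

# Per-point brute-force nearest-neighbour distances with border discard.
bf_nn_distances <- function(x_nm, y_nm, width_nm, height_nm) {
  D <- as.matrix(dist(cbind(x_nm, y_nm)))
  diag(D) <- Inf
  d <- unname(apply(D, 1L, min))
  border <- pmin(x_nm, width_nm - x_nm, y_nm, height_nm - y_nm)
  d[d <= border]
}

# Particle field with fully specified positions (no randomness).
fixed_field <- function(x, y, height = 1, sigma = 5,
                        extent = c(max(x) + 50, max(y) + 50)) {
  p <- generation_params()
  f <- generate_random_field(0, extent, p)
  f$x <- as.numeric(x); f$y <- as.numeric(y)
  f$height <- rep_len(as.numeric(height), length(x))
  f$sigma <- rep_len(as.numeric(sigma), length(x))
  f
}
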