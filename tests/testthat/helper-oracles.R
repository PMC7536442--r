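# Independent oracle implementations and small fixtures shared by the
# tests. The oracles are deliberately written in the most literal way
# possible (brute-force loops over definitions), independent of the
# package's vectorized implementations.

# Brute-force isodata threshold: iterate t = (mean(values <= t) +
# mean(values > t)) / 2 directly on the raw pixel values (no histogram
# approximation), starting from the mid-range. The package's 256-bin
# version must agree to within one bin width.
isodata_oracle <- function(image) {
  v <- as.vector(image)
  t_cur <- mean(range(v))
  for (i in 1:10000) {
    lo <- v <= t_cur
    if (all(lo) || !any(lo)) break
    t_new <- (mean(v[lo]) + mean(v[!lo])) / 2
    if (abs(t_new - t_cur) < diff(range(v)) * 1e-12) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

# Dense-grid weighted-centroid oracle for a single planted Gaussian peak:
# evaluate the profile on a very fine grid around the peak and take the
# intensity-weighted mean m/z.
centroid_oracle <- function(mu, sigma, half_width = 5 * 0.01) {
  g <- seq(mu - half_width, mu + half_width, length.out = 20001L)
  w <- exp(-0.5 * ((g - mu) / sigma)^2)
  sum(g * w) / sum(w)
}

# Nominal mass by explicit element-count dot product.
nominal_mass_oracle <- function(counts) {
  integer_masses <- c(C = 12, H = 1, N = 14, O = 16, P = 31, S = 32)
  sum(counts * integer_masses[names(counts)])
}

# Dice on explicitly enumerated index sets.
dice_oracle <- function(set_a, set_b) {
  2 * length(intersect(set_a, set_b)) / (length(set_a) + length(set_b))
}

# A small, fast phantom for unit tests (default geometry scales with the
# grid shape).
tiny_spec <- function(...) {
  phantom_spec(shape = c(ny = 24L, nx = 24L, nz = 5L), seed = 42L, ...)
}

# A single noise-free section image with asymmetric structure, for
# registration tests.
structured_image <- function(n = 41L) {
  img <- matrix(0, n, n)
  yy <- row(img); xx <- col(img)
  img <- exp(-(((yy - 22) / 8)^2 + ((xx - 18) / 6)^2)) +
    0.6 * exp(-(((yy - 14) / 3)^2 + ((xx - 27) / 4)^2))
  img
}

# A simple profile spectrum containing Gaussian peaks at the given m/z
# positions and heights, sampled on a regular grid.
gaussian_profile <- function(mus, heights, sigma = 0.01,
                             from = min(mus) - 1, to = max(mus) + 1,
                             step = 0.002, polarity = "positive") {
  grid <- seq(from, to, by = step)
  y <- rep(0, length(grid))
  for (i in seq_along(mus)) {
    y <- y + heights[i] * exp(-0.5 * ((grid - mus[i]) / sigma)^2)
  }
  mass_spectrum(grid, y, polarity, centroided = FALSE)
}
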