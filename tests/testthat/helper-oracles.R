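# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the code paths they are used to check.

# Brute-force Otsu oracle: for every candidate split compute the class
# moments directly from the raw histogram and return the argmin of the
# within-class variance (smallest-t ties). Independent of the package's
# cumulative-sum implementation.
oracle_otsu <- function(hist) {
  n <- length(hist)
  lev <- 0:(n - 1)
  total <- sum(hist)
  best_t <- NA_integer_
  best_wcv <- Inf
  for (t in 0:(n - 2)) {
    c0 <- hist[lev <= t]
    c1 <- hist[lev > t]
    if (sum(c0) == 0 || sum(c1) == 0) next
    l0 <- lev[lev <= t]
    l1 <- lev[lev > t]
    mu0 <- sum(c0 * l0) / sum(c0)
    mu1 <- sum(c1 * l1) / sum(c1)
    v0 <- sum(c0 * (l0 - mu0)^2) / sum(c0)
    v1 <- sum(c1 * (l1 - mu1)^2) / sum(c1)
    wcv <- (sum(c0) * v0 + sum(c1) * v1) / total
    if (wcv < best_wcv - 1e-12) {
      best_wcv <- wcv
      best_t <- t
    }
  }
  best_t
}

# global variance straight from the definition (per-pixel, not per-bin)
oracle_global_variance <- function(hist) {
  vals <- rep(0:(length(hist) - 1), hist)
  mean((vals - mean(vals))^2)
}

oracle_entropy_bits <- function(hist) {
  p <- hist / sum(hist)
  p <- p[p > 0]
  -sum(p * log(p)) / log(2)
}

# rasterized filled disc mask (x^2 + y^2 <= r^2) centered in a square
disc_mask <- function(r, pad = 4L) {
  n <- 2L * (r + pad) + 1L
  ctr <- r + pad + 1L
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  matrix(as.integer((rr - ctr)^2 + (cc - ctr)^2 <= r^2), n, n)
}

# seeded random histogram with a few occupied levels
random_histogram <- function(n = 256L, seed = 1L) {
  set.seed(seed)
  h <- integer(n)
  k <- sample(2:40, 1)
  levels <- sample.int(n, k)
  h[levels] <- sample.int(200, k, replace = TRUE)
  h
}

small_tumor_spec <- function(seed = 11L) {
  phantom_spec(tumor = list(center = c(60, 70), axes = c(10, 8), delta = 80),
               seed = seed)
}
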