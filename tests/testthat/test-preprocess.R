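test_that("histogram counts pixels per level and conserves total mass", {
  img <- matrix(c(0L, 1L, 0L, 3L), 2, 2, byrow = TRUE)
  expect_equal(compute_histogram(img, 4), c(2L, 1L, 0L, 1L))

  const <- matrix(5L, 10, 10)
  h <- compute_histogram(const, 256)
  expect_equal(h[6], 100L)
  expect_equal(sum(h), 100L)

  for (seed in 1:5) {
    set.seed(seed)
    img <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
    expect_equal(sum(compute_histogram(img)), 300L)
  }

  expect_error(compute_histogram(matrix(7L, 2, 2), n = 4),
               class = "lnqdetect_range_error")
})

test_that("equalization map follows the scaled CDF with half-up rounding", {
  expect_equal(equalization_map(c(3, 0, 0, 1), 4), c(2L, 2L, 2L, 3L))

  # uniform histogram: affine LUT ending at the top level
  lut <- equalization_map(rep(4L, 256), 256)
  expect_equal(lut, as.integer(floor(255 * (1:256) / 256 + 0.5)))
  expect_equal(lut[256], 255L)

  # all mass at one level maps that level to the top
  h <- integer(16)
  h[4] <- 99L
  expect_equal(equalization_map(h, 16)[4], 15L)

  expect_error(equalization_map(integer(8), 8),
               class = "lnqdetect_degenerate_error")
})

test_that("every generated LUT is monotone non-decreasing", {
  for (seed in 1:25) {
    h <- random_histogram(seed = seed)
    lut <- equalization_map(h)
    expect_true(all(diff(lut) >= 0))
    expect_true(all(lut >= 0 & lut <= 255))
  }
})

test_that("apply_map substitutes levels and preserves shape", {
  img <- matrix(c(0L, 1L, 0L, 3L), 2, 2, byrow = TRUE)
  ident <- 0:3
  expect_equal(apply_map(img, ident), img)

  expect_equal(apply_map(img, rep(7L, 4)), matrix(7L, 2, 2))

  lut <- equalization_map(c(3, 0, 0, 1), 4)
  expect_equal(apply_map(img, lut), matrix(c(2L, 2L, 2L, 3L), 2, 2, byrow = TRUE))
})

test_that("entropy attains log2(n) only at the uniform histogram", {
  expect_identical(image_entropy(rep(1L, 256)), 8)
  h <- integer(256)
  h[10] <- 50L
  expect_identical(image_entropy(h), 0)
  expect_equal(image_entropy(c(5L, 5L)), 1)

  for (seed in 1:20) {
    h <- random_histogram(seed = seed)
    e <- image_entropy(h)
    expect_lte(e, log2(256) + 1e-12)
    expect_gte(e, 0)
    expect_equal(e, oracle_entropy_bits(h))
  }

  expect_error(image_entropy(integer(4)), class = "lnqdetect_degenerate_error")
})

test_that("clip-and-redistribute conserves mass under the ceiling", {
  h <- c(1L, 5L, 2L, 0L)
  expect_equal(clip_and_redistribute(h, 5L)$counts, h) # ceiling >= max: no-op

  r <- clip_and_redistribute(c(10L, 0L, 0L, 0L), 4L)
  expect_equal(r$counts, c(4L, 3L, 2L, 1L))
  expect_equal(r$spec$n_sum_clip, 6L)

  for (seed in 1:30) {
    h <- random_histogram(n = 64, seed = seed)
    set.seed(seed + 1000)
    ceiling_ <- sample(max(ceiling(sum(h) / 64), 1):max(h, 2), 1)
    r <- clip_and_redistribute(h, ceiling_)
    expect_identical(sum(r$counts), sum(h))
    expect_lte(max(r$counts), ceiling_)
  }

  expect_error(clip_and_redistribute(c(100L, 0L), 10L),
               class = "lnqdetect_infeasible_error")
})

test_that("clip spec records the ceiling arithmetic", {
  sp <- clip_spec(16, 16, n_gray = 256, clip_norm = 0.03)
  expect_equal(sp$n_avg, 1)
  expect_equal(sp$n_cl, 8L) # ceil(0.03 * 256)
  expect_error(clip_spec(8, 8, clip_norm = 0), class = "lnqdetect_config_error")
  expect_error(clip_spec(8, 8, clip_norm = 1.5), class = "lnqdetect_config_error")
})

test_that("CLAHE with one tile and no clipping equals global equalization", {
  set.seed(3)
  img <- matrix(sample(0:255, 30 * 40, replace = TRUE), 30, 40)
  global <- apply_map(img, equalization_map(compute_histogram(img)))
  expect_identical(clahe(img, 1, 1, clip_norm = 1), global)
})

test_that("CLAHE maps a constant image to a constant image", {
  img <- matrix(42L, 32, 32)
  out <- clahe(img)
  expect_equal(length(unique(as.vector(out))), 1L)
})

test_that("CLAHE stretches a low-contrast phantom across the gray range", {
  ph <- make_phantom(phantom_spec(seed = 5))
  expect_lte(diff(range(ph$image[ph$brain_mask == 1])), 45) # low contrast in
  out <- clahe(ph$image)
  expect_gte(diff(range(out)), 0.9 * 255)
  expect_true(all(out >= 0 & out <= 255))
})

test_that("CLAHE rejects a degenerate tile grid", {
  expect_error(clahe(matrix(0L, 4, 4), grid_rows = 8, grid_cols = 8),
               class = "lnqdetect_config_error")
})
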