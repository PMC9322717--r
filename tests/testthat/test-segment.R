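test_that("Otsu threshold matches the exhaustive within-class oracle", {
  # two distant deltas: variance curve is flat on the plateau, smallest t wins
  h <- integer(256)
  h[2] <- 5L
  h[201] <- 5L
  o <- otsu_threshold(h)
  expect_identical(o$threshold, 1L)
  expect_identical(o$threshold, oracle_otsu(h))

  h2 <- c(4, 4, 0, 0, 4, 4)
  expect_identical(otsu_threshold(h2)$threshold, oracle_otsu(h2))

  expect_error(otsu_threshold(c(0L, 9L, 0L)), class = "lnqdetect_no_split_error")
})

test_that("between + within class variance decompose the global variance", {
  for (seed in 1:20) {
    h <- random_histogram(n = 64, seed = seed)
    o <- otsu_threshold(h)
    sigma2 <- oracle_global_variance(h)
    expect_equal(o$sigma_total2, sigma2, tolerance = 1e-12)
    occ <- which(h > 0) - 1L
    for (t in occ[1]:(max(occ) - 1L)) {
      wcv <- within_class_variance(h, t)
      bcv <- between_class_variance(h, t)
      expect_equal(wcv + bcv, sigma2, tolerance = 1e-9)
    }
  }
})

test_that("within-class variance is zero for two-delta splits", {
  h <- integer(32)
  h[3] <- 7L
  h[20] <- 4L
  expect_equal(within_class_variance(h, 10), 0)
  expect_equal(within_class_variance(c(1L, 1L), 0), 0)
  expect_error(within_class_variance(h, 0), class = "lnqdetect_no_split_error")
})

test_that("Otsu agrees with EBImage on a seeded image", {
  set.seed(9)
  img <- matrix(as.integer(c(round(rnorm(300, 60, 10)), round(rnorm(300, 180, 10)))),
                20, 30)
  img <- matrix(pmin(pmax(img, 0L), 255L), 20, 30)
  t_pkg <- otsu_threshold(compute_histogram(img))$threshold
  t_ebi <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1), levels = 256)
  # both thresholds may sit anywhere on the same empty-gap plateau of the
  # between-class variance, so compare the induced masks, not the levels
  expect_identical(apply_threshold(img, t_pkg),
                   matrix(as.integer(img / 255 > t_ebi), nrow(img), ncol(img)))
})

test_that("apply_threshold produces the expected binary masks", {
  img <- matrix(c(2L, 2L, 2L, 3L), 2, 2, byrow = TRUE)
  expect_equal(apply_threshold(img, 2), matrix(c(0L, 0L, 0L, 1L), 2, 2, byrow = TRUE))
  expect_equal(apply_threshold(img, 1), matrix(1L, 2, 2))
  expect_equal(apply_threshold(img, 255), matrix(0L, 2, 2))
  expect_equal(apply_threshold(img, 2, polarity = "below"),
               matrix(c(1L, 1L, 1L, 0L), 2, 2, byrow = TRUE))
})

test_that("component labeling is 8-connected", {
  m <- matrix(0L, 5, 5)
  m[cbind(1:5, 1:5)] <- 1L # diagonal chain
  lab <- label_components(m)
  expect_equal(max(lab), 1L)

  m2 <- matrix(0L, 5, 5)
  m2[1, 1] <- 1L
  m2[5, 5] <- 1L
  expect_equal(max(label_components(m2)), 2L)
})

test_that("candidate extraction picks the largest qualifying component", {
  expect_null(extract_tumor_candidate(matrix(0L, 10, 10)))

  m <- matrix(0L, 20, 30)
  m[2:3, 2:4] <- 1L # ~6 px blob
  m[10:16, 10:17] <- 1L # 56 px blob
  cand <- extract_tumor_candidate(m, min_area = 10)
  expect_equal(cand$area, 56L)
  expect_equal(unname(cand$bbox), c(10L, 16L, 10L, 17L))

  # boundary inclusive: area exactly min_area qualifies
  m3 <- matrix(0L, 10, 10)
  m3[4:5, 4:5] <- 1L
  expect_equal(extract_tumor_candidate(m3, min_area = 4)$area, 4L)
  expect_null(extract_tumor_candidate(m3, min_area = 5))
})

test_that("a two-valued image is segmented with zero pixel errors", {
  set.seed(4)
  img <- matrix(40L, 24, 24)
  truth <- matrix(0L, 24, 24)
  truth[8:14, 9:17] <- 1L
  img[truth == 1L] <- 200L
  t <- otsu_threshold(compute_histogram(img))$threshold
  expect_identical(apply_threshold(img, t), truth)
})

test_that("binary opening removes speckle but keeps solid blobs", {
  m <- matrix(0L, 15, 15)
  m[7:11, 7:11] <- 1L
  m[2, 2] <- 1L # isolated pixel
  op <- binary_opening(m)
  expect_equal(op[2, 2], 0L)
  expect_equal(sum(op[7:11, 7:11]), 25L)
})
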