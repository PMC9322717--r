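test_that("phantom generation is a pure function of spec and seed", {
  sp <- small_tumor_spec(seed = 11)
  p1 <- make_phantom(sp)
  p2 <- make_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$truth_mask, p2$truth_mask)
  p3 <- make_phantom(small_tumor_spec(seed = 12))
  expect_false(identical(p1$image, p3$image))
})

test_that("tumor-free phantoms have empty masks and the no-tumor label", {
  p <- make_phantom(phantom_spec(seed = 2))
  expect_equal(sum(p$truth_mask), 0L)
  expect_equal(p$label, "no_tumor")
})

test_that("the tumor is hyperintense by its delta over the surrounding ring", {
  sp <- small_tumor_spec(seed = 11)
  p <- make_phantom(sp)
  expect_equal(p$label, "tumor")
  inside <- p$image[p$truth_mask == 1L]
  # ring: dilated tumor ellipse minus the tumor, restricted to brain
  ring_outer <- lnqdetect:::ellipse_mask(sp$rows, sp$cols, sp$tumor$center,
                                         sp$tumor$axes + 4)
  ring <- ring_outer == 1L & p$truth_mask == 0L & p$brain_mask == 1L
  expect_lt(abs(mean(inside) - mean(p$image[ring]) - 80), 3)
})

test_that("tumor specs outside the brain are rejected", {
  expect_error(
    phantom_spec(tumor = list(center = c(10, 10), axes = c(12, 12), delta = 80)),
    class = "lnqdetect_spec_error"
  )
})

test_that("cohorts are reproducible with the requested tumor mix", {
  co <- make_cohort(50, 0.5, phantom_spec(), seed = 7)
  labels <- vapply(co, `[[`, "", "label")
  expect_equal(sum(labels == "tumor"), 25L)
  masks_nonempty <- vapply(co, function(p) sum(p$truth_mask) > 0, logical(1))
  expect_identical(masks_nonempty, labels == "tumor") # label/mask consistency

  co2 <- make_cohort(50, 0.5, phantom_spec(), seed = 7)
  expect_identical(lapply(co, `[[`, "image"), lapply(co2, `[[`, "image"))

  co0 <- make_cohort(5, 0, phantom_spec(), seed = 3)
  expect_true(all(vapply(co0, function(p) sum(p$truth_mask) == 0, logical(1))))

  expect_error(make_cohort(0), class = "lnqdetect_degenerate_error")
})

test_that("cluster datasets are seeded with controllable separation", {
  d1 <- make_cluster_dataset(3, 6, 20, seed = 9)
  d2 <- make_cluster_dataset(3, 6, 20, seed = 9)
  expect_identical(d1, d2)
  expect_true(all(as.matrix(d1[, 1:6]) >= 0 & as.matrix(d1[, 1:6]) <= 1))

  # one sample per class sits near its center (within a few sigma)
  d3 <- make_cluster_dataset(4, 3, 1, sigma = 0.01, seed = 4)
  expect_equal(nrow(d3), 4L)

  # clusters wider than their center spacing give near-chance accuracy
  dov <- make_cluster_dataset(2, 2, 60, sigma = 0.5, separation = 1e-4, seed = 6)
  set.seed(6)
  idx <- sample(nrow(dov), 80)
  m <- lnq(dov[idx, ], seed = 6, epochs = 20)
  acc <- mean(predict(m, dov[-idx, 1:2]) == dov$label[-idx])
  expect_lt(acc, 0.7) # chance is 1/2; far from the separable-case >= 0.95

  expect_error(make_cluster_dataset(40, 1, 5, sigma = 0.5, separation = 10),
               class = "lnqdetect_spec_error")
})
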