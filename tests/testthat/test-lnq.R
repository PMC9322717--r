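test_that("max-min similarity satisfies its axioms", {
  expect_equal(maxmin_similarity(c(0.3, 0.7), c(0.3, 0.7)), 1)
  expect_equal(maxmin_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(maxmin_similarity(c(0.5, 0.5), c(1, 1)), 0.5)

  set.seed(21)
  for (i in 1:50) {
    d <- sample(1:10, 1)
    x <- runif(d)
    w <- runif(d)
    s <- maxmin_similarity(x, w)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s, maxmin_similarity(w, x)) # symmetry
    if (!isTRUE(all.equal(x, w))) expect_lt(s, 1) # identity of indiscernibles
    expect_equal(maxmin_similarity(x, x), 1)
  }

  expect_error(maxmin_similarity(c(0, 0), c(0, 0)),
               class = "lnqdetect_undefined_similarity_error")
  expect_error(maxmin_similarity(c(0.1), c(0.1, 0.2)),
               class = "lnqdetect_schema_error")
  expect_error(maxmin_similarity(c(1.2), c(0.1)),
               class = "lnqdetect_range_error")
})

test_that("classification picks the most similar class with a stable tie rule", {
  cb <- rbind(A = c(0.9, 0.9), B = c(0.1, 0.1))
  model <- structure(
    list(codebook = unname(cb), cluster_class = c("A", "B"),
         classes = c("A", "B"), d = 2L, feature_names = c("f1", "f2"),
         loss = numeric(0), config = list(), ranges = NULL,
         quantization = NULL),
    class = "lnq"
  )
  nd <- matrix(c(0.8, 0.8), 1, dimnames = list(NULL, c("f1", "f2")))
  out <- predict(model, nd, type = "both")
  expect_equal(out$label, "A")
  expect_equal(out$similarity, 1.6 / 1.8)
  sims <- predict(model, nd, type = "similarity")
  expect_equal(unname(sims[1, "B"]), 0.2 / 1.6)

  # exact reference match
  nd2 <- matrix(c(0.1, 0.1), 1, dimnames = list(NULL, c("f1", "f2")))
  out2 <- predict(model, nd2, type = "both")
  expect_equal(out2$label, "B")
  expect_equal(out2$similarity, 1)

  # equidistant: first class in codebook order wins
  model$codebook <- rbind(c(0.4, 0.4), c(0.4, 0.4))
  expect_equal(predict(model, nd, type = "class"), "A")
})

test_that("training is seeded, deterministic, and zero epochs keep the init", {
  ds <- make_cluster_dataset(3, 6, 30, seed = 5)
  m1 <- lnq(ds, seed = 99)
  m2 <- lnq(ds, seed = 99)
  expect_identical(m1$codebook, m2$codebook)
  m3 <- lnq(ds, seed = 100)
  expect_false(identical(m1$codebook, m3$codebook))

  m0 <- lnq(ds, epochs = 0, seed = 99)
  x <- as.matrix(ds[, 1:6])
  expect_true(all(apply(m0$codebook, 1, function(w) {
    any(apply(x, 1, function(r) isTRUE(all.equal(unname(r), unname(w)))))
  })))

  # single-class dataset: everything classifies to that class
  ds1 <- ds[ds$label == "class1", ]
  msingle <- lnq(ds1, seed = 3)
  expect_true(all(predict(msingle, ds[, 1:6]) == "class1"))

  expect_error(lnq(ds), class = "lnqdetect_config_error") # seed mandatory
})

test_that("well-separated clusters are recovered with high accuracy", {
  ds <- make_cluster_dataset(3, 6, 50, sigma = 0.05, separation = 5, seed = 17)
  set.seed(17)
  idx <- sample(nrow(ds), round(0.7 * nrow(ds)))
  model <- lnq(ds[idx, ], seed = 17)
  acc <- mean(predict(model, ds[-idx, 1:6]) == ds$label[-idx])
  expect_gte(acc, 0.95)
  # training loss ends low and the curve is recorded per epoch
  expect_length(model$loss, model$config$epochs)
  expect_lt(model$loss[length(model$loss)], 0.2)
})

test_that("mid-rise quantization hits cell centers with bounded error", {
  expect_setequal(unique(quantize_weights(c(0, 0.2, 0.5, 0.7, 1), 1)),
                  c(0.25, 0.75))

  w <- seq(0, 1, length.out = 1001)
  expect_lte(max(abs(quantize_weights(w, 16) - w)), 2^-16)

  # reconstruction levels are fixed points
  recon <- (0:7 + 0.5) / 8
  expect_equal(quantize_weights(recon, 3), recon)

  expect_error(quantize_weights(0.5, 0), class = "lnqdetect_config_error")
  expect_error(quantize_weights(1.5, 4), class = "lnqdetect_range_error")
})

test_that("SQNR closed form, scale invariance, and Inf for exact match", {
  w <- c(1, 1, -1, -1) # mean square 1
  c0 <- 0.01
  expect_equal(measure_sqnr(w, w + c0), 10 * log10(1 / c0^2))
  # jointly scaling signal and error leaves the ratio unchanged
  expect_equal(measure_sqnr(2 * w, 2 * (w + c0)), measure_sqnr(w, w + c0))
  expect_identical(measure_sqnr(w, w), Inf)
})

test_that("SQNR grows about 6 dB per bit on uniform weights", {
  set.seed(8)
  w <- runif(2e4)
  sc <- sqnr_scan(w, betas = 2:10)
  expect_gte(sc$kappa, 5.5)
  expect_lte(sc$kappa, 6.5)
  expect_true(all(diff(sc$table$noise_power) <= 0))
  d84 <- sc$table$sqnr_db[sc$table$beta == 8] - sc$table$sqnr_db[sc$table$beta == 4]
  expect_lt(abs(d84 - 24), 1.5)
})

test_that("quantizing a model updates the codebook and reports noise", {
  ds <- make_cluster_dataset(2, 4, 25, seed = 2)
  model <- lnq(ds, seed = 2)
  qm <- quantize(model, 8)
  expect_equal(qm$quantization$beta, 8L)
  expect_equal(qm$codebook - model$codebook, qm$quantization$n_w)
  expect_lte(max(abs(qm$quantization$n_w)), 2^-9 + 1e-15)
  expect_gte(qm$quantization$noise_power, 0)

  # stochastic mode is seeded and bounded by half a cell
  q1 <- quantize_weights(model$codebook, 6, stochastic = TRUE, seed = 4)
  q2 <- quantize_weights(model$codebook, 6, stochastic = TRUE, seed = 4)
  expect_identical(q1, q2)
  expect_lte(max(abs(q1 - model$codebook)), 2^-7)
})

test_that("model methods print, summarise, plot and expose the codebook", {
  ds <- make_cluster_dataset(2, 3, 20, seed = 13)
  model <- lnq(ds, seed = 13)
  expect_output(print(model), "Learning-quantization")
  expect_output(summary(model), "codebook")
  cb <- coef(model)
  expect_equal(dim(cb), c(6L, 3L))
  expect_true(all(grepl("^class[12]\\.", rownames(cb))))
  pdf(NULL)
  expect_silent(plot(model))
  dev.off()
})

test_that("codebook JSON round-trips through write/read", {
  ds <- make_cluster_dataset(2, 5, 20, seed = 23)
  rng <- fit_feature_ranges(as.matrix(ds[, 1:5]))
  model <- lnq(ds, seed = 23, ranges = rng)
  path <- tempfile(fileext = ".json")
  write_codebook(model, path)
  back <- read_codebook(path)
  expect_equal(back$codebook, model$codebook, ignore_attr = TRUE)
  expect_equal(back$classes, model$classes)
  expect_equal(predict(back, ds[, 1:5]), predict(model, ds[, 1:5]))
})
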