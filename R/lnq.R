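#' Max-min similarity between two normalized vectors
#'
#' `S(x, w) = sum(min(x_i, w_i)) / sum(max(x_i, w_i))`, a fuzzy
#' Jaccard-type score on `[0,1]^d`. `S` lies in `[0, 1]`, is symmetric,
#' and equals 1 exactly when `x == w` componentwise; disjoint supports
#' give 0. Undefined when both vectors are all-zero.
#'
#' @param x,w numeric vectors of equal length with components in `[0, 1]`.
#' @return similarity in `[0, 1]`.
#' @export
maxmin_similarity <- function(x, w) {
  if (length(x) != length(w)) stop_schema("vectors must have equal length")
  if (length(x) < 1L) stop_schema("vectors must be non-empty")
  if (any(x < 0 | x > 1) || any(w < 0 | w > 1)) {
    stop_range("components must lie in [0, 1]")
  }
  denom <- sum(pmax(x, w))
  if (denom == 0) {
    abort_lnq("similarity undefined for two all-zero vectors",
              "lnqdetect_undefined_similarity_error")
  }
  sum(pmin(x, w)) / denom
}

# similarities of one vector against every row of a codebook matrix
similarity_rows <- function(x, W) {
  mins <- t(pmin(t(W), x))
  maxs <- t(pmax(t(W), x))
  rowSums(mins) / rowSums(maxs)
}

#' Fit a learning-quantization (LVQ-style) classifier
#'
#' Each class owns `clusters_per_class` reference vectors ("codebook
#' vectors") in `[0,1]^d`. Matching uses the max-min similarity
#' ([maxmin_similarity()]); training is LVQ1 with a linearly decaying
#' learning rate: the codebook is initialized from class-stratified
#' seeded samples of the training data, then for each epoch (seeded
#' shuffle) the globally most similar reference vector is pulled toward
#' the sample if its class matches and pushed away otherwise, and clamped
#' back to `[0,1]`. The mean of `1 - S_correct` over the training set is
#' tracked per epoch as the training loss.
#'
#' @param x numeric matrix of normalized features (rows = samples, values
#'   in `[0,1]`), or a data frame with a `label` column; alternatively a
#'   formula `label ~ .` with `data`.
#' @param y class labels (ignored when `x` carries a `label` column).
#' @param clusters_per_class reference vectors per class (default 3).
#' @param epochs training epochs `T` (default 50); `epochs = 0` returns
#'   the initialization.
#' @param learning_rate initial rate `alpha0` in (0, 1), default 0.1; the
#'   rate at epoch `t` (0-based) is `alpha0 * (1 - t/T)`.
#' @param seed integer seed; mandatory, training is fully deterministic
#'   given the data and seed.
#' @param ranges optional [fit_feature_ranges()] object stored with the
#'   model so [predict.lnq()] can normalize raw features.
#' @param ... unused.
#' @return an object of class `"lnq"`: `codebook` (matrix), `cluster_class`
#'   (class of each codebook row), `classes`, `d`, `feature_names`,
#'   `loss` (per-epoch), `config`, `ranges`, `quantization` (`NULL` until
#'   [quantize()]).
#' @export
lnq <- function(x, ...) UseMethod("lnq")

#' @rdname lnq
#' @param formula a formula of the form `label ~ .`.
#' @param data data frame holding the features and the label.
#' @export
lnq.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  xs <- mf[, -1L, drop = FALSE]
  lnq.default(as.matrix(xs), y, ...)
}

#' @rdname lnq
#' @export
lnq.data.frame <- function(x, y = NULL, ...) {
  if (is.null(y)) {
    if (!"label" %in% names(x)) stop_schema("data frame must have a 'label' column")
    y <- x$label
    x <- x[, setdiff(names(x), "label"), drop = FALSE]
  }
  lnq.default(as.matrix(x), y, ...)
}

#' @rdname lnq
#' @export
lnq.default <- function(x, y, clusters_per_class = 3L, epochs = 50L,
                        learning_rate = 0.1, seed, ranges = NULL, ...) {
  if (missing(seed) || !is.numeric(seed)) {
    stop_config("a numeric seed is mandatory for training")
  }
  if (learning_rate <= 0 || learning_rate >= 1) {
    stop_config("learning_rate must lie in (0, 1)")
  }
  if (epochs < 0L) stop_config("epochs must be >= 0")
  if (clusters_per_class < 1L) stop_config("clusters_per_class must be >= 1")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    stop_range("training features must be normalized to [0, 1]")
  }
  y <- as.character(y)
  if (length(y) != nrow(x)) stop_schema("length(y) must match nrow(x)")
  classes <- unique(y)
  counts <- table(factor(y, levels = classes))
  if (any(counts == 0)) stop_data("every class needs at least one sample")

  d <- ncol(x)
  with_seed(as.integer(seed), {
    # class-stratified random initialization
    cb <- NULL
    cb_class <- character(0)
    for (cl in classes) {
      rows <- which(y == cl)
      pick <- if (length(rows) >= clusters_per_class) {
        sample(rows, clusters_per_class)
      } else {
        sample(rows, clusters_per_class, replace = TRUE)
      }
      cb <- rbind(cb, x[pick, , drop = FALSE])
      cb_class <- c(cb_class, rep(cl, clusters_per_class))
    }
    rownames(cb) <- NULL

    loss <- numeric(epochs)
    n <- nrow(x)
    if (epochs > 0L) {
      for (ep in seq_len(epochs)) {
        alpha <- learning_rate * (1 - (ep - 1) / epochs)
        ord <- sample.int(n)
        for (i in ord) {
          xi <- x[i, ]
          s <- similarity_rows(xi, cb)
          win <- which.max(s)
          sign <- if (cb_class[win] == y[i]) 1 else -1
          cb[win, ] <- clamp(cb[win, ] + sign * alpha * (xi - cb[win, ]), 0, 1)
        }
        loss[ep] <- mean_correct_loss(x, y, cb, cb_class, classes)
      }
    }
    structure(
      list(
        codebook = cb, cluster_class = cb_class, classes = classes,
        d = d, feature_names = colnames(x), loss = loss,
        config = list(
          clusters_per_class = as.integer(clusters_per_class),
          epochs = as.integer(epochs), learning_rate = learning_rate,
          seed = as.integer(seed)
        ),
        ranges = ranges, quantization = NULL
      ),
      class = "lnq"
    )
  })
}

mean_correct_loss <- function(x, y, cb, cb_class, classes) {
  s_correct <- vapply(seq_len(nrow(x)), function(i) {
    rows <- which(cb_class == y[i])
    max(similarity_rows(x[i, ], cb[rows, , drop = FALSE]))
  }, numeric(1))
  mean(1 - s_correct)
}

#' Classify normalized feature vectors with a fitted lnq model
#'
#' For each sample the best (maximum) similarity over each class's
#' codebook vectors is computed; the predicted label is the class with
#' the global maximum, ties broken by codebook class order.
#'
#' @param object a fitted `"lnq"` model.
#' @param newdata matrix or data frame of feature rows. If the model
#'   carries `ranges` and the data is not already in `[0,1]`, raw
#'   features are normalized first.
#' @param type `"class"` (default: labels), `"similarity"` (per-class
#'   best-similarity matrix) or `"both"` (data frame of label and winning
#'   similarity).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.lnq <- function(object, newdata,
                        type = c("class", "similarity", "both"), ...) {
  type <- match.arg(type)
  m <- as_feature_matrix(as.data.frame(newdata))
  check_feature_names(colnames(m), object$feature_names)
  m <- m[, object$feature_names, drop = FALSE]
  if (any(m < 0 | m > 1)) {
    if (is.null(object$ranges)) {
      stop_range("features outside [0,1] and model has no stored ranges")
    }
    m <- normalize_features(m, object$ranges)
  }
  sims <- matrix(NA_real_, nrow(m), length(object$classes),
                 dimnames = list(NULL, object$classes))
  for (i in seq_len(nrow(m))) {
    s <- similarity_rows(m[i, ], object$codebook)
    for (cl in object$classes) {
      sims[i, cl] <- max(s[object$cluster_class == cl])
    }
  }
  labels <- object$classes[apply(sims, 1L, which.max)]
  switch(type,
    class = labels,
    similarity = sims,
    both = data.frame(
      label = labels,
      similarity = sims[cbind(seq_len(nrow(sims)), match(labels, colnames(sims)))],
      stringsAsFactors = FALSE
    )
  )
}

#' @export
print.lnq <- function(x, ...) {
  q <- if (is.null(x$quantization)) "unquantized" else {
    sprintf("quantized at beta = %d bits", x$quantization$beta)
  }
  cat(sprintf(
    "Learning-quantization classifier: %d classes x %d clusters, d = %d (%s)\n",
    length(x$classes), x$config$clusters_per_class, x$d, q
  ))
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  if (length(x$loss)) {
    cat(sprintf("final training loss (1 - mean best-correct similarity): %.4f\n",
                x$loss[length(x$loss)]))
  }
  invisible(x)
}

#' @export
summary.lnq <- function(object, ...) {
  print(object)
  cat("\ncodebook:\n")
  print(round(coef(object), 3))
  if (!is.null(object$quantization)) {
    cat("\n")
    print(object$quantization)
  }
  invisible(object)
}

#' @export
coef.lnq <- function(object, ...) {
  cb <- object$codebook
  rownames(cb) <- paste(object$cluster_class,
                        stats::ave(seq_along(object$cluster_class),
                                   object$cluster_class, FUN = seq_along),
                        sep = ".")
  colnames(cb) <- object$feature_names
  cb
}

#' @export
plot.lnq <- function(x, ...) {
  if (!length(x$loss)) {
    stop_degenerate("model trained with 0 epochs has no loss curve")
  }
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "training loss (1 - S_correct)",
                 main = "lnq training loss", ...)
  invisible(x)
}
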