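# End-to-end pipeline: CLAHE preprocessing -> Otsu segmentation ->
# candidate extraction -> region features -> learning-quantization
# classification, with optional evaluation against ground truth.

default_config <- function() {
  list(
    seed = 1L,
    verbosity = 0L,
    preprocess = list(grid_rows = 8L, grid_cols = 8L, clip_norm = 0.03,
                      n_levels = 256L),
    segment = list(polarity = "above", min_area = 25L, opening = FALSE,
                   stages = 2L),
    features = list(),
    lnq = list(clusters_per_class = 3L, epochs = 50L, learning_rate = 0.1,
               beta = NULL),
    evaluation = list(positive = "tumor"),
    synthetic = list(rows = 128L, cols = 128L, tumor_fraction = 0.5,
                     noise_sigma = 5, bias_amplitude = 8,
                     tissue_window = c(100, 140))
  )
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults and overrides them with the supplied
#' nested values. Unknown keys at any level are rejected, so a typo in a
#' config file cannot silently fall back to a default.
#'
#' @param ... named overrides, e.g.
#'   `pipeline_config(seed = 7, segment = list(min_area = 40))`.
#' @return nested list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  cfg <- merge_config(default_config(), overrides, path = "")
  cfg$segment$polarity <- match.arg(cfg$segment$polarity, c("above", "below"))
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0L) return(base)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) {
    stop_config(sprintf("config entries under '%s' must be named", path))
  }
  unknown <- setdiff(nm, names(base))
  if (length(unknown)) {
    stop_config(sprintf("unknown config key%s: %s",
                        if (length(unknown) > 1) "s" else "",
                        paste0(path, unknown, collapse = ", ")))
  }
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(overrides[[k]])) {
        stop_config(sprintf("config key '%s%s' must be a section", path, k))
      }
      base[[k]] <- merge_config(base[[k]], overrides[[k]],
                                paste0(path, k, "."))
    } else {
      base[[k]] <- overrides[[k]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path; `.json` is parsed as JSON, anything else as
#'   YAML (JSON being a YAML subset, both parse).
#' @return validated `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such config file: %s", path))
  raw <- if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline config\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Segment one image: head extraction then lesion thresholding
#'
#' Stage 1 runs Otsu on the CLAHE-enhanced image to separate the head
#' from the dark background. With `stages = 2` (the default) the lesion
#' threshold is a second Otsu computed on the native-intensity histogram
#' restricted to the head region; equalization is rank-based within each
#' tile, so absolute-intensity statistics for the lesion are taken on the
#' native scale. With `stages = 1` the stage-1 threshold itself defines
#' the lesion mask (useful for two-valued images). The largest
#' 8-connected component of the lesion mask with area `>= min_area` is
#' the tumor candidate; absence of one is a regular outcome, not an
#' error.
#'
#' @param img integer intensity matrix.
#' @param config a [pipeline_config()].
#' @return list: `enhanced`, `head_mask`, `lesion_mask`, `candidate`
#'   (`NULL` or `"region_candidate"`), thresholds `t_head`, `t_lesion`.
#' @export
segment_image <- function(img, config = pipeline_config()) {
  pp <- config$preprocess
  sg <- config$segment
  enhanced <- clahe(img, pp$grid_rows, pp$grid_cols, pp$clip_norm, pp$n_levels)
  h1 <- compute_histogram(enhanced, pp$n_levels)
  t1 <- otsu_threshold(h1)$threshold
  head_mask <- apply_threshold(enhanced, t1, "above")

  t2 <- NA_integer_
  if (sg$stages >= 2L) {
    head_comp <- extract_tumor_candidate(head_mask, min_area = sg$min_area)
    if (is.null(head_comp)) {
      return(list(enhanced = enhanced, head_mask = head_mask,
                  lesion_mask = matrix(0L, nrow(img), ncol(img)),
                  candidate = NULL, t_head = t1, t_lesion = t2))
    }
    inside <- img[head_comp$mask == 1L]
    h2 <- tabulate(inside + 1L, nbins = pp$n_levels)
    if (sum(h2 > 0) < 2L) {
      lesion <- matrix(0L, nrow(img), ncol(img))
    } else {
      t2 <- otsu_threshold(h2)$threshold
      lesion <- apply_threshold(img, t2, sg$polarity) * head_comp$mask
    }
  } else {
    lesion <- apply_threshold(enhanced, t1, sg$polarity)
  }
  if (isTRUE(sg$opening)) lesion <- binary_opening(lesion)
  candidate <- extract_tumor_candidate(lesion, min_area = sg$min_area)
  list(enhanced = enhanced, head_mask = head_mask, lesion_mask = lesion,
       candidate = candidate, t_head = t1, t_lesion = t2)
}

# segment, but treat "no valid split" (e.g. a constant image) as the
# no-candidate outcome: inside the pipeline absence is a prediction.
segment_or_empty <- function(img, config) {
  tryCatch(
    segment_image(img, config),
    lnqdetect_no_split_error = function(e) {
      list(enhanced = img, head_mask = matrix(0L, nrow(img), ncol(img)),
           lesion_mask = matrix(0L, nrow(img), ncol(img)),
           candidate = NULL, t_head = NA_integer_, t_lesion = NA_integer_)
    }
  )
}

# phantoms / matrices / file paths -> list of image matrices (+ metadata)
coerce_images <- function(images) {
  if (inherits(images, "phantom")) images <- list(images)
  if (is.matrix(images)) images <- list(images)
  if (is.character(images)) {
    return(list(imgs = lapply(images, read_gray_image),
                truth = NULL, labels = NULL, ids = basename(images)))
  }
  if (!is.list(images)) stop_schema("images must be a list, matrix or paths")
  if (all(vapply(images, inherits, logical(1), "phantom"))) {
    return(list(
      imgs = lapply(images, `[[`, "image"),
      truth = lapply(images, `[[`, "truth_mask"),
      labels = vapply(images, `[[`, character(1), "label"),
      ids = sprintf("phantom_%04d", seq_along(images))
    ))
  }
  list(imgs = lapply(images, as_gray_image), truth = NULL, labels = NULL,
       ids = sprintf("image_%04d", seq_along(images)))
}

#' Extract labeled training features from a cohort
#'
#' Runs preprocessing, segmentation and feature extraction on every
#' sample and returns one feature row per image that produced a
#' candidate, labeled with the image's true label. Images with no
#' candidate contribute nothing (they carry no region to learn from).
#'
#' @param cohort list of `"phantom"` objects (or list of images plus a
#'   `labels` vector).
#' @param config a [pipeline_config()].
#' @param labels true labels, required when `cohort` is not phantoms.
#' @return data frame of raw (unnormalized) features plus `label`.
#' @export
cohort_features <- function(cohort, config = pipeline_config(), labels = NULL) {
  cc <- coerce_images(cohort)
  if (is.null(cc$labels)) cc$labels <- labels
  if (is.null(cc$labels)) stop_data("training requires true labels")
  rows <- list()
  for (i in seq_along(cc$imgs)) {
    seg <- segment_or_empty(cc$imgs[[i]], config)
    if (!is.null(seg$candidate)) {
      fv <- region_features(cc$imgs[[i]], seg$candidate)
      rows[[length(rows) + 1L]] <- c(as.list(fv), list(label = cc$labels[i]))
    }
  }
  if (!length(rows)) stop_data("no image produced a candidate region")
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Fit the detector: segmentation-driven features + lnq classifier
#'
#' Convenience trainer: extracts candidate-region features from a labeled
#' cohort ([cohort_features()]), fits min-max normalization ranges, and
#' trains the [lnq()] classifier on the normalized features. The fitted
#' model carries the ranges, so [run_pipeline()] can normalize raw
#' features at test time.
#'
#' @param cohort labeled training cohort (see [cohort_features()]).
#' @param config a [pipeline_config()].
#' @param labels optional labels when `cohort` is not phantoms.
#' @return fitted `"lnq"` model.
#' @export
fit_detector <- function(cohort, config = pipeline_config(), labels = NULL) {
  feats <- cohort_features(cohort, config, labels)
  ranges <- fit_feature_ranges(feats)
  x <- normalize_features(feats, ranges)
  lq <- config$lnq
  model <- lnq(x, feats$label,
               clusters_per_class = lq$clusters_per_class,
               epochs = lq$epochs, learning_rate = lq$learning_rate,
               seed = config$seed, ranges = ranges)
  if (!is.null(lq$beta)) model <- quantize(model, lq$beta)
  model
}

#' Run the detection pipeline over a set of images
#'
#' For each image: CLAHE -> Otsu segmentation -> candidate extraction ->
#' region features -> normalized max-min classification. An image with no
#' surviving candidate is predicted `"no_tumor"` with similarity 0 (a
#' first-class prediction, never an error). When ground truth is
#' available (phantom input or explicit `truth`/`labels`), an evaluation
#' report with confusion metrics and mean Dice over true tumor cases is
#' attached.
#'
#' @param images list of `"phantom"` objects, list of intensity matrices,
#'   or character vector of PNG/TIFF paths.
#' @param model fitted `"lnq"` model (see [fit_detector()]); its feature
#'   schema must match the extractor.
#' @param config a [pipeline_config()].
#' @param truth optional list of 0/1 truth masks (taken from phantoms
#'   automatically).
#' @param labels optional true labels (taken from phantoms automatically).
#' @param out_dir optional directory; when given, candidate masks are
#'   written as 0/255 PNGs and the per-image table as CSV.
#' @return object of class `"pipeline_result"`: `per_image` data frame
#'   (id, predicted label, similarity, candidate area, Dice when truth is
#'   known), `report` (`"eval_report"` or `NULL`), `masks` (list of
#'   candidate masks).
#' @export
run_pipeline <- function(images, model, config = pipeline_config(),
                         truth = NULL, labels = NULL, out_dir = NULL) {
  if (!inherits(model, "lnq")) stop_config("model must be a fitted lnq object")
  if (!identical(sort(model$feature_names), sort(lnq_feature_names()))) {
    stop_config("codebook feature schema does not match the feature extractor")
  }
  cc <- coerce_images(images)
  if (is.null(cc$truth)) cc$truth <- truth
  if (is.null(cc$labels)) cc$labels <- labels
  positive <- config$evaluation$positive

  n <- length(cc$imgs)
  pred <- character(n)
  simil <- numeric(n)
  area <- integer(n)
  dice_v <- rep(NA_real_, n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    img <- cc$imgs[[i]]
    seg <- segment_or_empty(img, config)
    if (is.null(seg$candidate)) {
      pred[i] <- "no_tumor"
      simil[i] <- 0
      area[i] <- 0L
      masks[[i]] <- matrix(0L, nrow(img), ncol(img))
    } else {
      fv <- region_features(img, seg$candidate)
      xn <- normalize_features(fv, model$ranges)
      out <- predict(model, t(as.matrix(xn)), type = "both")
      pred[i] <- out$label
      simil[i] <- out$similarity
      area[i] <- seg$candidate$area
      masks[[i]] <- seg$candidate$mask
    }
    if (!is.null(cc$truth)) {
      dice_v[i] <- dice(masks[[i]], cc$truth[[i]])
    }
  }

  per_image <- data.frame(
    id = cc$ids, predicted = pred, similarity = simil,
    candidate_area = area, stringsAsFactors = FALSE
  )
  report <- NULL
  if (!is.null(cc$labels)) {
    per_image$truth <- cc$labels
    cm <- confusion_counts(pred, cc$labels, positive = positive)
    tumor_idx <- which(cc$labels == positive)
    report <- structure(
      list(
        confusion = cm,
        accuracy = accuracy(cm),
        precision = tryCatch(precision(cm), error = function(e) NA_real_),
        specificity = tryCatch(specificity(cm), error = function(e) NA_real_),
        mean_dice = if (length(tumor_idx) && !is.null(cc$truth)) {
          mean(dice_v[tumor_idx])
        } else {
          NULL
        },
        n_tumor_cases = length(tumor_idx),
        loss = model$loss
      ),
      class = "eval_report"
    )
  }
  if (!is.null(cc$truth)) per_image$dice <- dice_v

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      write_mask(masks[[i]], file.path(out_dir, paste0(cc$ids[i], "_mask.png")))
    }
    utils::write.csv(per_image, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  structure(list(per_image = per_image, report = report, masks = masks),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d image(s), %d predicted tumor\n",
              nrow(x$per_image), sum(x$per_image$predicted == "tumor")))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Serialize a fitted lnq model (codebook) to JSON
#'
#' @param model fitted `"lnq"` object.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(model, path) {
  if (!inherits(model, "lnq")) stop_config("model must be a fitted lnq object")
  clusters <- lapply(model$classes, function(cl) {
    unname(apply(model$codebook[model$cluster_class == cl, , drop = FALSE],
                 1L, as.numeric, simplify = FALSE))
  })
  names(clusters) <- model$classes
  obj <- list(
    classes = model$classes,
    d = model$d,
    feature_names = model$feature_names,
    clusters = clusters,
    ranges = if (is.null(model$ranges)) NULL else {
      lapply(model$ranges, function(r) unname(as.numeric(r)))
    },
    quantization = if (is.null(model$quantization)) NULL else {
      list(beta = model$quantization$beta)
    },
    config = model$config,
    loss = model$loss
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a codebook JSON back into an lnq model
#'
#' @param path `.json` written by [write_codebook()].
#' @return `"lnq"` object usable with [predict.lnq()] and
#'   [run_pipeline()].
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such codebook file: %s", path))
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cb <- NULL
  cb_class <- character(0)
  for (cl in obj$classes) {
    m <- obj$clusters[[cl]]
    if (is.list(m)) m <- do.call(rbind, m)
    m <- matrix(as.numeric(m), ncol = obj$d)
    cb <- rbind(cb, m)
    cb_class <- c(cb_class, rep(cl, nrow(m)))
  }
  colnames(cb) <- obj$feature_names
  ranges <- NULL
  if (!is.null(obj$ranges)) {
    ranges <- lapply(obj$ranges, function(r) c(min = r[1], max = r[2]))
    class(ranges) <- "feature_ranges"
  }
  structure(
    list(
      codebook = cb, cluster_class = cb_class, classes = obj$classes,
      d = obj$d, feature_names = obj$feature_names,
      loss = as.numeric(obj$loss),
      config = obj$config, ranges = ranges,
      quantization = if (is.null(obj$quantization)) NULL else {
        list(beta = obj$quantization$beta)
      }
    ),
    class = "lnq"
  )
}
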