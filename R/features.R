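# Region feature extraction: the fixed 8-feature shape+intensity summary
# consumed by the classifier. The set is deliberately small and cheap; it
# is documented as replaceable (the classifier only assumes normalized
# vectors in [0,1]).

lnq_feature_names <- function() {
  c(
    "area", "perimeter", "circularity", "eccentricity",
    "centroid_row", "centroid_col", "mean_intensity", "sd_intensity"
  )
}

#' Shape and intensity features of a detected region
#'
#' Computes the fixed feature set: `area` (pixel count), `perimeter`
#' (Crofton estimate: the count of foreground/background 4-edge crossings,
#' image border counting as background, scaled by `pi/4` so a rasterized
#' circle measures close to its true circumference), `circularity`
#' (`4*pi*A/P^2`, ~1 for a disc), `eccentricity` (`sqrt(1 - l2/l1)` from the eigenvalues of the
#' pixel-coordinate covariance), centroid row/column as fractions of the
#' image extent, and the mean and standard deviation of the image
#' intensity inside the region.
#'
#' @param img integer matrix of intensities the region was detected in.
#' @param region a `"region_candidate"` from [extract_tumor_candidate()],
#'   or a 0/1 mask matrix with at least one foreground pixel.
#' @return named numeric vector of length 8.
#' @export
region_features <- function(img, region) {
  mask <- if (inherits(region, "region_candidate")) region$mask else as_binary_mask(region)
  img <- as_gray_image(img, levels = max(256L, max(img) + 1L))
  if (!all(dim(mask) == dim(img))) {
    stop_schema("region mask and image shapes differ")
  }
  px <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(px) == 0L) stop_degenerate("region is empty")

  area <- nrow(px)
  perim <- perimeter_pixels(mask)
  circ <- 4 * pi * area / perim^2
  vals <- img[mask == 1L]

  if (area == 1L) {
    ecc <- 0
  } else {
    cv <- stats::cov(px)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  }

  out <- c(
    area = area,
    perimeter = perim,
    circularity = circ,
    eccentricity = ecc,
    centroid_row = mean(px[, 1L]) / nrow(img),
    centroid_col = mean(px[, 2L]) / ncol(img),
    mean_intensity = mean(vals),
    sd_intensity = if (area == 1L) 0 else stats::sd(vals)
  )
  out
}

# Crofton perimeter: pi/4 times the count of foreground/background
# 4-edges (image border counts as background). The pi/4 factor makes the
# estimate converge to the true length for smooth boundaries.
perimeter_pixels <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  pr <- rbind(0L, mask, 0L)
  pc <- cbind(0L, mask, 0L)
  crossings <- sum(abs(pr[1:(nr + 1L), ] - pr[2:(nr + 2L), ])) +
    sum(abs(pc[, 1:(nc + 1L)] - pc[, 2:(nc + 2L)]))
  pi / 4 * crossings
}

#' Fit per-feature min/max normalization ranges
#'
#' @param vectors a matrix or data frame (rows = samples, columns =
#'   features), or a list of named feature vectors.
#' @return object of class `"feature_ranges"`: named list of
#'   `c(min, max)` per feature.
#' @export
fit_feature_ranges <- function(vectors) {
  m <- as_feature_matrix(vectors)
  if (nrow(m) < 1L) stop_degenerate("need at least one feature vector")
  rng <- lapply(seq_len(ncol(m)), function(j) {
    c(min = min(m[, j]), max = max(m[, j]))
  })
  names(rng) <- colnames(m)
  structure(rng, class = "feature_ranges")
}

#' Min-max normalize a feature vector (or matrix) into [0,1]
#'
#' `value' = clamp((value - min) / (max - min), 0, 1)`; a degenerate
#' feature (`max == min` in training) maps to 0.5. Out-of-range test-time
#' values are clamped, not rejected: unseen data legitimately exceeds the
#' training ranges.
#'
#' @param fv named numeric vector, or a matrix/data frame of rows to
#'   normalize.
#' @param ranges a [fit_feature_ranges()] object with matching feature
#'   names.
#' @return normalized vector/matrix with all values in `[0, 1]`.
#' @export
normalize_features <- function(fv, ranges) {
  if (!inherits(ranges, "feature_ranges")) {
    stop_schema("ranges must come from fit_feature_ranges()")
  }
  if (is.matrix(fv) || is.data.frame(fv)) {
    m <- as_feature_matrix(fv)
    check_feature_names(colnames(m), names(ranges))
    for (j in seq_len(ncol(m))) {
      m[, j] <- norm_one(m[, j], ranges[[colnames(m)[j]]])
    }
    return(m)
  }
  if (is.null(names(fv))) stop_schema("feature vector must be named")
  check_feature_names(names(fv), names(ranges))
  out <- vapply(names(fv), function(nm) norm_one(fv[[nm]], ranges[[nm]]),
                numeric(1))
  out
}

norm_one <- function(x, r) {
  span <- r["max"] - r["min"]
  if (span == 0) return(rep(0.5, length(x)))
  unname(clamp((x - r["min"]) / span, 0, 1))
}

check_feature_names <- function(have, want) {
  if (!setequal(have, want) || length(have) != length(want)) {
    stop_schema(sprintf(
      "feature names do not match ranges (have: %s; want: %s)",
      paste(have, collapse = ","), paste(want, collapse = ",")
    ))
  }
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, setdiff(names(x), "label"), drop = FALSE])
  } else if (is.list(x) && !is.matrix(x)) {
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_schema("expected a numeric feature matrix")
  }
  if (is.null(colnames(x))) stop_schema("feature matrix must have column names")
  if (any(!is.finite(x))) stop_range("features must be finite")
  x
}
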