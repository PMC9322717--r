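#' Otsu threshold with full variance decomposition
#'
#' Exhaustively evaluates every candidate threshold `t` (class 0 = levels
#' `<= t`, class 1 = levels `> t`, both non-empty) and returns the `t`
#' maximizing the between-class variance
#' `sigma_b^2(t) = w0 w1 (mu0 - mu1)^2`, which by the decomposition
#' `sigma^2 = sigma_w^2(t) + sigma_b^2(t)` is the same `t` that minimizes
#' the within-class variance. Ties are broken by the smallest `t`.
#'
#' @param hist histogram counts occupying at least two distinct levels.
#' @return object of class `"otsu_stats"`: `threshold`, class probabilities
#'   `omega0`/`omega1`, class means `mu0`/`mu1`, global variance
#'   `sigma_total2`, `sigma_within2`, `sigma_between2`, and the unnormalized
#'   first moment `m1_class1` of class 1 (diagnostic).
#' @export
otsu_threshold <- function(hist) {
  check_histogram(hist)
  occupied <- which(hist > 0)
  if (length(occupied) < 2L) {
    stop_no_split("histogram occupies a single level; no valid split exists")
  }
  n <- length(hist)
  lev <- 0:(n - 1L)
  total <- sum(hist)
  p <- hist / total
  mu_total <- sum(p * lev)
  sigma_total2 <- sum(p * (lev - mu_total)^2)

  # cumulative class-0 statistics over all candidate t
  w0 <- cumsum(p)
  m0 <- cumsum(p * lev)
  valid <- w0 > 0 & w0 < 1
  sigma_b2 <- rep(-Inf, n)
  mu0 <- m0 / w0
  mu1 <- (mu_total - m0) / (1 - w0)
  sigma_b2[valid] <- (w0 * (1 - w0) * (mu0 - mu1)^2)[valid]
  t_idx <- which.max(sigma_b2) # first maximum = smallest t
  t <- t_idx - 1L

  structure(
    list(
      threshold = as.integer(t),
      omega0 = w0[t_idx], omega1 = 1 - w0[t_idx],
      mu0 = mu0[t_idx], mu1 = mu1[t_idx],
      sigma_total2 = sigma_total2,
      sigma_between2 = sigma_b2[t_idx],
      sigma_within2 = sigma_total2 - sigma_b2[t_idx],
      m1_class1 = mu_total - m0[t_idx]
    ),
    class = "otsu_stats"
  )
}

#' @export
print.otsu_stats <- function(x, ...) {
  cat(sprintf(
    "Otsu threshold t = %d\n  class probs %.4f / %.4f, means %.2f / %.2f\n  variance %.3f = within %.3f + between %.3f\n",
    x$threshold, x$omega0, x$omega1, x$mu0, x$mu1,
    x$sigma_total2, x$sigma_within2, x$sigma_between2
  ))
  invisible(x)
}

#' Within-class variance at a given threshold
#'
#' The weighted sum of the two class variances,
#' `w0 s0^2 + w1 s1^2`, for class 0 = levels `<= t`, class 1 = levels
#' `> t`. Both classes must be non-empty.
#'
#' @param hist histogram counts.
#' @param t threshold level (0-based).
#' @return within-class variance.
#' @export
within_class_variance <- function(hist, t) {
  check_histogram(hist)
  n <- length(hist)
  if (t < 0 || t > n - 2L) stop_no_split("threshold leaves an empty class")
  lev <- 0:(n - 1L)
  c0 <- hist[lev <= t]
  c1 <- hist[lev > t]
  if (sum(c0) == 0 || sum(c1) == 0) {
    stop_no_split("threshold leaves an empty class")
  }
  l0 <- lev[lev <= t]
  l1 <- lev[lev > t]
  total <- sum(hist)
  w0 <- sum(c0) / total
  w1 <- sum(c1) / total
  mu0 <- sum(c0 * l0) / sum(c0)
  mu1 <- sum(c1 * l1) / sum(c1)
  s0 <- sum(c0 * (l0 - mu0)^2) / sum(c0)
  s1 <- sum(c1 * (l1 - mu1)^2) / sum(c1)
  w0 * s0 + w1 * s1
}

#' Between-class variance at a given threshold
#'
#' `w0 w1 (mu0 - mu1)^2`; complements [within_class_variance()] in the
#' decomposition of the global variance.
#'
#' @inheritParams within_class_variance
#' @return between-class variance.
#' @export
between_class_variance <- function(hist, t) {
  check_histogram(hist)
  n <- length(hist)
  if (t < 0 || t > n - 2L) stop_no_split("threshold leaves an empty class")
  lev <- 0:(n - 1L)
  c0 <- hist[lev <= t]
  c1 <- hist[lev > t]
  if (sum(c0) == 0 || sum(c1) == 0) {
    stop_no_split("threshold leaves an empty class")
  }
  total <- sum(hist)
  w0 <- sum(c0) / total
  w1 <- sum(c1) / total
  mu0 <- sum(c0 * lev[lev <= t]) / sum(c0)
  mu1 <- sum(c1 * lev[lev > t]) / sum(c1)
  w0 * w1 * (mu0 - mu1)^2
}

#' Threshold an image into a binary mask
#'
#' @param img integer matrix of intensities.
#' @param t threshold level.
#' @param polarity `"above"` (mask = pixels `> t`, the default for a
#'   hyperintense lesion) or `"below"` (pixels `<= t`).
#' @return 0/1 integer matrix of the same shape.
#' @export
apply_threshold <- function(img, t, polarity = c("above", "below")) {
  polarity <- match.arg(polarity)
  img <- as_gray_image(img, levels = max(256L, max(img) + 1L))
  m <- if (polarity == "above") img > t else img <= t
  mask <- matrix(as.integer(m), nrow(img), ncol(img))
  mask
}

#' Label 8-connected foreground components
#'
#' @param mask 0/1 matrix.
#' @return integer matrix of the same shape: 0 for background, `1..k` for
#'   the `k` components (labels ordered by first pixel in column-major
#'   order).
#' @export
label_components <- function(mask) {
  mask <- as_binary_mask(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask == 1L) # column-major linear indices
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(lab)
  idx <- integer(nr * nc)
  idx[fg] <- seq_along(fg)

  r <- (fg - 1L) %% nr + 1L
  cc <- (fg - 1L) %/% nr + 1L
  edges <- list()
  k <- 0L
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1L]
    c2 <- cc + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- idx[nb] > 0L
    if (any(hit)) {
      k <- k + 1L
      edges[[k]] <- cbind(idx[fg[ok]][hit], idx[nb][hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (k > 0L) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  # relabel so component ids follow first occurrence in column-major order
  relabel <- integer(max(comp))
  nxt <- 0L
  for (i in seq_along(fg)) {
    if (relabel[comp[i]] == 0L) {
      nxt <- nxt + 1L
      relabel[comp[i]] <- nxt
    }
  }
  lab[fg] <- relabel[comp]
  lab
}

#' Extract the largest candidate region from a binary mask
#'
#' Selects the largest 8-connected foreground component with area at least
#' `min_area`. Absence of a qualifying component is a value (`NULL`), not
#' an error: a tumor-free image legitimately produces no candidate.
#'
#' @param mask 0/1 matrix.
#' @param min_area minimum component area in pixels (default 25).
#' @return object of class `"region_candidate"` (`mask`, `area`, `bbox` as
#'   `c(row_min, row_max, col_min, col_max)`), or `NULL`.
#' @export
extract_tumor_candidate <- function(mask, min_area = 25L) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  if (sizes[best] < min_area) return(NULL)
  m <- matrix(as.integer(lab == best), nrow(lab), ncol(lab))
  px <- which(m == 1L, arr.ind = TRUE)
  structure(
    list(
      mask = m,
      area = as.integer(sizes[best]),
      bbox = c(
        row_min = min(px[, 1L]), row_max = max(px[, 1L]),
        col_min = min(px[, 2L]), col_max = max(px[, 2L])
      )
    ),
    class = "region_candidate"
  )
}

#' @export
print.region_candidate <- function(x, ...) {
  cat(sprintf(
    "region candidate: area %d px, bbox rows %d-%d cols %d-%d\n",
    x$area, x$bbox["row_min"], x$bbox["row_max"],
    x$bbox["col_min"], x$bbox["col_max"]
  ))
  invisible(x)
}

#' 3x3 binary opening (optional mask cleanup)
#'
#' Erosion followed by dilation with a 3x3 square element. Off by default
#' in the pipeline; useful to drop speckle before component extraction.
#'
#' @param mask 0/1 matrix.
#' @return opened 0/1 matrix.
#' @export
binary_opening <- function(mask) {
  mask <- as_binary_mask(mask)
  dilate3 <- function(m) {
    out <- matrix(0L, nrow(m), ncol(m))
    nr <- nrow(m)
    nc <- ncol(m)
    for (dr in -1:1) {
      for (dc in -1:1) {
        rs <- clamp(seq_len(nr) + dr, 1L, nr)
        cs <- clamp(seq_len(nc) + dc, 1L, nc)
        out <- pmax(out, m[rs, cs, drop = FALSE])
      }
    }
    out
  }
  eroded <- 1L - dilate3(1L - mask)
  matrix(as.integer(dilate3(eroded)), nrow(mask), ncol(mask))
}
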