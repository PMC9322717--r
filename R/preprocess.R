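#' Gray-level histogram of an image
#'
#' Counts pixels at each gray level `0..n-1`. The histogram is the basis of
#' equalization, entropy diagnostics and Otsu thresholding.
#'
#' @param img integer matrix of intensities (see [as_gray_image()]).
#' @param n number of gray levels; every pixel must be `< n`. Default 256.
#' @return integer vector of length `n`; element `k+1` is the count of
#'   pixels with value `k`. `sum(counts)` equals the pixel count.
#' @export
compute_histogram <- function(img, n = 256L) {
  img <- as_gray_image(img, levels = max(n, max(img) + 1L))
  if (n < 2L) stop_config("histogram needs at least 2 levels")
  if (any(img >= n)) {
    stop_range(sprintf("pixel value %d out of range for %d levels", max(img), n))
  }
  tabulate(as.integer(img) + 1L, nbins = n)
}

#' Histogram-equalization transfer table (LUT)
#'
#' Builds the monotone gray-level transfer function from the cumulative
#' distribution of a histogram: `lut[i] = round((n_out-1) * CDF(i))` with
#' round-half-up. The top occupied level always maps to `n_out - 1`.
#'
#' @param hist histogram counts (non-negative, positive total mass).
#' @param n_out number of output levels. Default: same as input.
#' @return integer vector `lut` of length `length(hist)`, values in
#'   `[0, n_out-1]`, non-decreasing.
#' @export
equalization_map <- function(hist, n_out = length(hist)) {
  check_histogram(hist)
  if (sum(hist) <= 0) stop_degenerate("cannot equalize an empty histogram")
  cdf <- cumsum(as.numeric(hist)) / sum(hist)
  lut <- round_half_up((n_out - 1) * cdf)
  as.integer(clamp(lut, 0L, n_out - 1L))
}

#' Apply a gray-level transfer table to an image
#'
#' @param img integer matrix of intensities.
#' @param lut transfer table from [equalization_map()]; must cover every
#'   pixel value in `img`.
#' @return image of the same shape with each pixel `p` replaced by
#'   `lut[p + 1]`.
#' @export
apply_map <- function(img, lut) {
  img <- as_gray_image(img, levels = max(length(lut), max(img) + 1L))
  if (max(img) + 1L > length(lut)) {
    stop_range("image has levels beyond the transfer table")
  }
  out <- matrix(as.integer(lut)[as.integer(img) + 1L], nrow(img), ncol(img))
  out
}

#' Shannon entropy of an image histogram, in bits
#'
#' `E = -sum(p_i * log2(p_i))` over occupied levels, with `0*log(0) := 0`.
#' Bounded by `log2(n)`; the bound is attained exactly by the uniform
#' histogram, which is the state global equalization drives an image toward.
#'
#' @param hist histogram counts with positive total mass.
#' @return entropy in bits, in `[0, log2(length(hist))]`.
#' @export
image_entropy <- function(hist) {
  check_histogram(hist)
  total <- sum(hist)
  if (total <= 0) stop_degenerate("entropy of an empty histogram is undefined")
  p <- hist[hist > 0] / total
  -sum(p * log2(p))
}

check_histogram <- function(hist) {
  if (!is.numeric(hist) || length(hist) < 2L) {
    stop_schema("histogram must be a numeric vector with >= 2 bins")
  }
  if (any(hist < 0) || any(hist != floor(hist))) {
    stop_schema("histogram counts must be non-negative integers")
  }
  invisible(hist)
}

#' Clip-limit bookkeeping for one tile
#'
#' Records the quantities of the contrast-limited equalization step:
#' `n_avg = tile_px / n_gray` (mean pixels per level), the actual ceiling
#' `n_cl = max(1, ceiling(clip_norm * tile_px))`, and after clipping the
#' total excess `n_sum_clip` and its per-level share `n_avg_gray`.
#' `clip_norm` is the ceiling expressed as a fraction of the tile's pixel
#' count; `clip_norm = 1` means no clipping is possible.
#'
#' @param tile_rows,tile_cols tile extent in pixels.
#' @param n_gray number of gray levels (histogram bins).
#' @param clip_norm normalized clip limit in `(0, 1]`.
#' @return object of class `"clip_spec"`.
#' @export
clip_spec <- function(tile_rows, tile_cols, n_gray = 256L, clip_norm = 0.03) {
  if (clip_norm <= 0 || clip_norm > 1) {
    stop_config("clip_norm must lie in (0, 1]")
  }
  if (tile_rows < 1L || tile_cols < 1L) stop_config("tile must be at least 1x1")
  tile_px <- as.numeric(tile_rows) * tile_cols
  n_avg <- tile_px / n_gray
  n_cl <- max(1L, as.integer(ceiling(clip_norm * tile_px)))
  structure(
    list(
      tile_rows = as.integer(tile_rows), tile_cols = as.integer(tile_cols),
      n_gray = as.integer(n_gray), clip_norm = clip_norm,
      n_avg = n_avg, n_cl = n_cl,
      n_sum_clip = 0L, n_avg_gray = 0
    ),
    class = "clip_spec"
  )
}

#' @export
print.clip_spec <- function(x, ...) {
  cat(sprintf(
    "clip spec: %dx%d tile, %d levels, clip_norm %.3f -> ceiling %d px/bin (n_avg %.2f)\n",
    x$tile_rows, x$tile_cols, x$n_gray, x$clip_norm, x$n_cl, x$n_avg
  ))
  if (x$n_sum_clip > 0) {
    cat(sprintf(
      "  clipped excess %d px (%.3f px/level)\n", x$n_sum_clip, x$n_avg_gray
    ))
  }
  invisible(x)
}

#' Clip a histogram at a ceiling and redistribute the excess
#'
#' Core step of contrast-limited equalization. Counts above the ceiling are
#' cut off and the clipped mass is put back deterministically: an equal
#' floor share to every bin, then the remainder one count per bin in index
#' order skipping bins already at the ceiling; the histogram is re-clipped
#' and the cycle repeats while the excess shrinks; any residual is dropped
#' one count at a time, round-robin, into bins strictly below the ceiling.
#' Total mass is conserved exactly and no final bin exceeds the ceiling.
#'
#' @param hist histogram counts.
#' @param spec a [clip_spec()] (its `n_gray` must match `length(hist)`), or
#'   a single integer ceiling.
#' @return list with `counts` (redistributed histogram) and `spec` (the
#'   clip spec with `n_sum_clip`/`n_avg_gray` filled in).
#' @export
clip_and_redistribute <- function(hist, spec) {
  check_histogram(hist)
  n <- length(hist)
  if (is.numeric(spec) && length(spec) == 1L) {
    ceiling_ <- as.integer(spec)
    spec <- clip_spec(1L, 1L, n_gray = n, clip_norm = 1)
    spec$n_cl <- ceiling_
  } else if (inherits(spec, "clip_spec")) {
    if (spec$n_gray != n) {
      stop_schema("clip spec n_gray does not match histogram length")
    }
    ceiling_ <- spec$n_cl
  } else {
    stop_schema("spec must be a clip_spec or a single ceiling value")
  }
  if (ceiling_ < 1L) stop_config("clip ceiling must be >= 1")
  total <- sum(hist)
  if (as.numeric(ceiling_) * n < total) {
    stop_infeasible(sprintf(
      "mass %d cannot fit under ceiling %d x %d bins", total, ceiling_, n
    ))
  }

  counts <- as.integer(hist)
  excess <- sum(pmax(0L, counts - ceiling_))
  spec$n_sum_clip <- as.integer(excess)
  spec$n_avg_gray <- excess / n

  while (excess > 0L) {
    counts <- pmin(counts, ceiling_)
    share <- excess %/% n
    counts <- counts + share
    rem <- excess %% n
    if (rem > 0L) {
      open <- which(counts < ceiling_)
      take <- open[seq_len(min(rem, length(open)))]
      counts[take] <- counts[take] + 1L
      rem <- rem - length(take)
      if (rem > 0L) {
        # fewer open bins than remainder: pile round-robin onto open bins
        counts <- counts + distribute_round_robin(rem, counts, ceiling_)
        rem <- 0L
      }
    }
    new_excess <- sum(pmax(0L, counts - ceiling_))
    if (new_excess >= excess) {
      # not converging: clip once more and place the residual directly
      residual <- new_excess
      counts <- pmin(counts, ceiling_)
      if (residual > 0L) {
        counts <- counts + distribute_round_robin(residual, counts, ceiling_)
      }
      excess <- 0L
    } else {
      excess <- new_excess
    }
  }
  stopifnot(sum(counts) == total, all(counts <= ceiling_))
  list(counts = as.integer(counts), spec = spec)
}

# spread `k` counts round-robin over bins strictly below the ceiling;
# returns the increment vector. Feasibility guarantees enough room.
distribute_round_robin <- function(k, counts, ceiling_) {
  inc <- integer(length(counts))
  while (k > 0L) {
    open <- which(counts + inc < ceiling_)
    take <- open[seq_len(min(k, length(open)))]
    inc[take] <- inc[take] + 1L
    k <- k - length(take)
  }
  inc
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' The image is partitioned into a grid of tiles; each tile's histogram is
#' clipped at the normalized clip limit, its excess redistributed
#' ([clip_and_redistribute()]) and turned into an equalization transfer
#' table ([equalization_map()]). Each output pixel is the bilinear blend of
#' the transfer tables of the (up to) four nearest tile centers evaluated
#' at the pixel's input level; pixels beyond the outermost tile centers use
#' the one or two available maps. With a 1x1 grid and `clip_norm = 1` the
#' result is bit-identical to global histogram equalization.
#'
#' When an image dimension is not divisible by the grid count, the last
#' tile row/column absorbs the remainder.
#'
#' @param img integer matrix of intensities in `[0, n_levels-1]`.
#' @param grid_rows,grid_cols tile grid (default 8x8).
#' @param clip_norm normalized clip limit in `(0, 1]`, as a fraction of the
#'   tile pixel count (default 0.03). Small values bound the contrast
#'   amplification; 1 disables clipping.
#' @param n_levels input/output gray levels (default 256).
#' @return equalized image, same shape, values in `[0, n_levels-1]`.
#' @export
clahe <- function(img, grid_rows = 8L, grid_cols = 8L, clip_norm = 0.03,
                  n_levels = 256L) {
  img <- as_gray_image(img, n_levels)
  nr <- nrow(img)
  nc <- ncol(img)
  if (grid_rows < 1L || grid_cols < 1L) stop_config("grid counts must be >= 1")
  if (nr < grid_rows || nc < grid_cols) {
    stop_config("degenerate grid: tiles would be smaller than one pixel")
  }

  # tile extents: equal division, last tile absorbs the remainder
  row_start <- as.integer(nr %/% grid_rows * (seq_len(grid_rows) - 1L)) + 1L
  row_end <- c(row_start[-1L] - 1L, nr)
  col_start <- as.integer(nc %/% grid_cols * (seq_len(grid_cols) - 1L)) + 1L
  col_end <- c(col_start[-1L] - 1L, nc)

  n_tiles <- grid_rows * grid_cols
  luts <- matrix(0L, nrow = n_tiles, ncol = n_levels)
  centers_r <- numeric(grid_rows)
  centers_c <- numeric(grid_cols)
  for (gr in seq_len(grid_rows)) {
    centers_r[gr] <- (row_start[gr] + row_end[gr]) / 2
  }
  for (gc in seq_len(grid_cols)) {
    centers_c[gc] <- (col_start[gc] + col_end[gc]) / 2
  }
  for (gr in seq_len(grid_rows)) {
    for (gc in seq_len(grid_cols)) {
      tile <- img[row_start[gr]:row_end[gr], col_start[gc]:col_end[gc], drop = FALSE]
      spec <- clip_spec(nrow(tile), ncol(tile), n_gray = n_levels,
                        clip_norm = clip_norm)
      h <- compute_histogram(tile, n_levels)
      h <- clip_and_redistribute(h, spec)$counts
      luts[(gr - 1L) * grid_cols + gc, ] <- equalization_map(h, n_levels)
    }
  }

  # bilinear blend of tile maps at each pixel
  rw <- interp_weights(seq_len(nr), centers_r)
  cw <- interp_weights(seq_len(nc), centers_c)
  lo_r <- rw$lo[row(img)]
  hi_r <- rw$hi[row(img)]
  wr <- rw$w[row(img)]
  lo_c <- cw$lo[col(img)]
  hi_c <- cw$hi[col(img)]
  wc <- cw$w[col(img)]
  lev <- as.integer(img) + 1L

  val <- function(tr, tc) luts[cbind((tr - 1L) * grid_cols + tc, lev)]
  out <- wr * wc * val(lo_r, lo_c) +
    wr * (1 - wc) * val(lo_r, hi_c) +
    (1 - wr) * wc * val(hi_r, lo_c) +
    (1 - wr) * (1 - wc) * val(hi_r, hi_c)
  out <- matrix(as.integer(clamp(round_half_up(out), 0L, n_levels - 1L)), nr, nc)
  out
}

# For each coordinate, the two bracketing tile-center indices and the
# weight of the lower one. Coordinates outside the center span use the
# nearest map with weight 1 (weight on `lo`).
interp_weights <- function(pos, centers) {
  k <- length(centers)
  lo <- findInterval(pos, centers)
  hi <- pmin(lo + 1L, k)
  lo_cl <- pmax(lo, 1L)
  w <- numeric(length(pos))
  inside <- lo >= 1L & lo < k
  if (any(inside)) {
    c_lo <- centers[lo_cl[inside]]
    c_hi <- centers[hi[inside]]
    w[inside] <- (c_hi - pos[inside]) / (c_hi - c_lo)
  }
  w[lo < 1L] <- 0 # below first center: all weight on hi (= center 1)
  w[lo >= k] <- 1 # above last center: all weight on lo (= center k)
  below <- lo < 1L
  lo_cl[below] <- 1L
  hi[below] <- 1L
  list(lo = lo_cl, hi = hi, w = w)
}
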