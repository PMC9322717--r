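# Seeded phantom generator. Stands in for clinical MRI slices so that
# every pipeline stage is testable without any download: a bright
# elliptical "brain" on a dark background, tissue compressed into a
# narrow low-contrast window, a smooth polynomial bias field, additive
# Gaussian noise, and an optional compact hyperintense tumor ellipse with
# a ground-truth mask.

#' Specification of a synthetic brain phantom
#'
#' @param rows,cols image shape (default 128 x 128).
#' @param brain_center,brain_axes ellipse center `c(row, col)` and
#'   semi-axes `c(row, col)` of the brain region.
#' @param tissue_window intensity window `c(lo, hi)` the tissue is
#'   compressed into (default `c(100, 140)`, a deliberately low-contrast
#'   setting that stresses direct thresholding).
#' @param base_intensity tissue base level before bias/noise (default the
#'   window midpoint).
#' @param bias_amplitude amplitude of the smooth low-order polynomial
#'   bias field, intensity units (default 8).
#' @param noise_sigma additive Gaussian noise SD, intensity units
#'   (default 5).
#' @param tumor `NULL` (no tumor) or a list with `center = c(row, col)`,
#'   `axes = c(row, col)` and `delta` (hyperintensity above surrounding
#'   tissue, default 80).
#' @param seed integer seed; the phantom is a pure function of spec+seed.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(rows = 128L, cols = 128L,
                         brain_center = c(rows / 2 + 0.5, cols / 2 + 0.5),
                         brain_axes = c(0.33 * rows, 0.38 * cols),
                         tissue_window = c(100, 140),
                         base_intensity = mean(tissue_window),
                         bias_amplitude = 8,
                         noise_sigma = 5,
                         tumor = NULL,
                         seed = 1L) {
  if (rows < 8L || cols < 8L) stop_spec("phantom must be at least 8x8")
  if (tissue_window[1] >= tissue_window[2]) {
    stop_spec("tissue window must satisfy lo < hi")
  }
  if (!is.null(tumor)) {
    tumor$delta <- if (is.null(tumor$delta)) 80 else tumor$delta
    # every point of the tumor ellipse must lie inside the brain ellipse
    th <- seq(0, 2 * pi, length.out = 64L)
    pr <- tumor$center[1] + tumor$axes[1] * sin(th)
    pc <- tumor$center[2] + tumor$axes[2] * cos(th)
    inside <- ((pr - brain_center[1]) / brain_axes[1])^2 +
      ((pc - brain_center[2]) / brain_axes[2])^2 <= 1
    if (!all(inside)) stop_spec("tumor ellipse extends outside the brain")
  }
  structure(
    list(
      rows = as.integer(rows), cols = as.integer(cols),
      brain_center = brain_center, brain_axes = brain_axes,
      tissue_window = tissue_window, base_intensity = base_intensity,
      bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
      tumor = tumor, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

ellipse_mask <- function(rows, cols, center, axes) {
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  m <- ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
  matrix(as.integer(m), rows, cols)
}

# smooth low-order 2D polynomial scaled to [-1, 1], coefficients seeded
bias_field <- function(rows, cols) {
  u <- matrix(seq_len(rows) / rows - 0.5, rows, cols)
  v <- matrix(seq_len(cols) / cols - 0.5, rows, cols, byrow = TRUE)
  coefs <- stats::runif(5, -1, 1)
  f <- coefs[1] * u + coefs[2] * v + coefs[3] * u * v +
    coefs[4] * (u^2 - 1 / 12) + coefs[5] * (v^2 - 1 / 12)
  rng <- max(abs(f))
  if (rng == 0) f else f / rng
}

#' Generate one seeded phantom
#'
#' Background is near 0, tissue is `base + bias` clamped into the tissue
#' window plus noise (re-clamped to the window, keeping the tissue
#' low-contrast), and tumor pixels are the local tissue value plus the
#' tumor `delta`, so the tumor-vs-surrounding offset is exactly `delta`
#' up to noise averaging.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `"phantom"`: `image` (integer matrix),
#'   `truth_mask` (0/1 matrix, empty when no tumor), `label` (`"tumor"`
#'   or `"no_tumor"`), `brain_mask`, and the `spec`.
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_spec("spec must be a phantom_spec")
  with_seed(spec$seed, {
    rows <- spec$rows
    cols <- spec$cols
    brain <- ellipse_mask(rows, cols, spec$brain_center, spec$brain_axes)
    bias <- spec$bias_amplitude * bias_field(rows, cols)
    noise <- matrix(stats::rnorm(rows * cols, 0, spec$noise_sigma), rows, cols)

    img <- matrix(0, rows, cols)
    tissue <- clamp(spec$base_intensity + bias, spec$tissue_window[1],
                    spec$tissue_window[2])
    tissue <- clamp(tissue + noise, spec$tissue_window[1], spec$tissue_window[2])
    img[brain == 1L] <- tissue[brain == 1L]
    img[brain == 0L] <- clamp(noise[brain == 0L], 0, 255)

    if (!is.null(spec$tumor)) {
      tmask <- ellipse_mask(rows, cols, spec$tumor$center, spec$tumor$axes)
      img[tmask == 1L] <- img[tmask == 1L] + spec$tumor$delta
      label <- "tumor"
    } else {
      tmask <- matrix(0L, rows, cols)
      label <- "no_tumor"
    }
    img <- matrix(as.integer(round_half_up(clamp(img, 0, 255))), rows, cols)
    structure(
      list(image = img, truth_mask = tmask, label = label,
           brain_mask = brain, spec = spec),
      class = "phantom"
    )
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom %dx%d, label %s, tumor area %d px\n",
              nrow(x$image), ncol(x$image), x$label, sum(x$truth_mask)))
  invisible(x)
}

#' Generate a seeded cohort of phantoms
#'
#' `round(n * tumor_fraction)` samples carry a tumor with seeded jitter of
#' the tumor center, semi-axes and intensity delta; the rest are
#' tumor-free. Which positions are tumor cases is itself a seeded draw,
#' and the whole cohort is reproducible from `(n, tumor_fraction,
#' base_spec, seed)`.
#'
#' @param n cohort size (`>= 1`).
#' @param tumor_fraction fraction of tumor cases in `[0, 1]` (default
#'   0.5).
#' @param base_spec template [phantom_spec()]; per-sample specs vary only
#'   in seed and tumor geometry.
#' @param seed cohort seed.
#' @return list of `"phantom"` objects.
#' @export
make_cohort <- function(n, tumor_fraction = 0.5, base_spec = phantom_spec(),
                        seed = 1L) {
  if (n < 1L) stop_degenerate("cohort size must be >= 1")
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    stop_spec("tumor_fraction must lie in [0, 1]")
  }
  n_tumor <- round(n * tumor_fraction)
  with_seed(seed, {
    tumor_case <- sample(rep(c(TRUE, FALSE), c(n_tumor, n - n_tumor)))
    sample_seeds <- sample.int(2^30, n)
    jitter <- matrix(stats::runif(5 * n), ncol = 5)
  })
  lapply(seq_len(n), function(i) {
    spec <- base_spec
    spec$seed <- sample_seeds[i]
    if (tumor_case[i]) {
      # jittered compact tumor well inside the brain
      ar <- 7 + 5 * jitter[i, 1]
      ac <- 7 + 5 * jitter[i, 2]
      max_r <- 0.45 * spec$brain_axes[1]
      max_c <- 0.45 * spec$brain_axes[2]
      spec$tumor <- list(
        center = c(
          spec$brain_center[1] + (2 * jitter[i, 3] - 1) * max_r,
          spec$brain_center[2] + (2 * jitter[i, 4] - 1) * max_c
        ),
        axes = c(ar, ac),
        delta = 70 + 20 * jitter[i, 5]
      )
    } else {
      spec$tumor <- NULL
    }
    make_phantom(spec)
  })
}

#' Seeded feature-space cluster dataset
#'
#' `k` class centers are placed uniformly in `[margin, 1-margin]^d` by
#' seeded rejection sampling until all pairwise distances are at least
#' `separation * sigma`; each class then gets `n_per_class`
#' truncated-Gaussian samples (SD `sigma`, clamped to `[0,1]`).
#'
#' @param k number of classes (`>= 2`).
#' @param d dimensionality (`>= 1`).
#' @param n_per_class samples per class.
#' @param sigma within-class SD (default 0.05).
#' @param separation required center separation as a multiple of `sigma`
#'   (default 5).
#' @param seed integer seed.
#' @return data frame with feature columns `f1..fd` and a `label` column.
#' @export
make_cluster_dataset <- function(k, d, n_per_class, sigma = 0.05,
                                 separation = 5, seed = 1L) {
  if (k < 2L) stop_spec("need at least 2 classes")
  if (d < 1L) stop_spec("need at least 1 dimension")
  if (separation <= 0) stop_spec("separation must be positive")
  min_dist <- separation * sigma
  with_seed(seed, {
    centers <- NULL
    tries <- 0L
    while (is.null(centers)) {
      tries <- tries + 1L
      if (tries > 2000L) {
        stop_spec("cannot place centers at the requested separation")
      }
      cand <- matrix(stats::runif(k * d, 0.1, 0.9), k, d)
      if (k == 1L || min(stats::dist(cand)) >= min_dist) centers <- cand
    }
    x <- do.call(rbind, lapply(seq_len(k), function(cl) {
      pts <- matrix(stats::rnorm(n_per_class * d, 0, sigma),
                    n_per_class, d, byrow = TRUE)
      clamp(sweep(pts, 2, centers[cl, ], `+`), 0, 1)
    }))
    colnames(x) <- paste0("f", seq_len(d))
    df <- as.data.frame(x)
    df$label <- rep(paste0("class", seq_len(k)), each = n_per_class)
    df
  })
}
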