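# Bit-width weight quantization and SQNR accounting.
#
# Weights live in [0,1]; the quantizer is the uniform mid-rise quantizer
# with 2^beta cells, reconstruction at cell centers. The per-weight error
# n_w = w~ - w is the quantization noise; SQNR = 10 log10(E[w^2]/E[n_w^2])
# grows by ~6.02 dB per bit for uniform weights (the kappa*beta law).

#' Uniform mid-rise quantization of weights in [0,1]
#'
#' Maps each weight to the center of its cell:
#' `w~ = (floor(w * 2^beta - 1e-12) + 0.5) / 2^beta`, clamped to `[0, 1]`.
#' With `beta = 1` every weight becomes 0.25 or 0.75; the error never
#' exceeds half a cell, `2^-(beta+1)`.
#'
#' @param w numeric vector/matrix of weights in `[0, 1]`.
#' @param beta bit width, integer `>= 1`.
#' @param stochastic if `TRUE`, adds seeded uniform noise on plus/minus
#'   half a cell instead of deterministic rounding (used for SQNR
#'   simulation experiments).
#' @param seed seed for `stochastic = TRUE`.
#' @return quantized weights, same shape.
#' @export
quantize_weights <- function(w, beta, stochastic = FALSE, seed = NULL) {
  if (!is.numeric(beta) || beta < 1 || beta != floor(beta)) {
    stop_config("beta must be an integer >= 1")
  }
  if (any(w < 0 | w > 1)) stop_range("weights must lie in [0, 1]")
  step <- 2^-beta
  if (stochastic) {
    if (is.null(seed)) stop_config("stochastic quantization requires a seed")
    noise <- with_seed(seed, stats::runif(length(w), -step / 2, step / 2))
    out <- clamp(w + noise, 0, 1)
  } else {
    idx <- clamp(floor(w / step - 1e-12), 0, 2^beta - 1)
    out <- (idx + 0.5) * step
  }
  if (is.matrix(w)) out <- matrix(out, nrow(w), ncol(w)) else out
  out
}

#' Signal-to-quantization-noise ratio in dB
#'
#' `10 * log10(mean(w^2) / mean((wq - w)^2))`. Zero noise power is a
#' signal, not an error: `Inf` is returned.
#'
#' @param w original weights.
#' @param wq quantized weights.
#' @return SQNR in dB (`Inf` for exact quantization).
#' @export
measure_sqnr <- function(w, wq) {
  if (length(w) != length(wq) || length(w) < 1L) {
    stop_schema("weight vectors must be non-empty and of equal length")
  }
  noise <- mean((wq - w)^2)
  if (noise == 0) return(Inf)
  10 * log10(mean(w^2) / noise)
}

#' SQNR sweep over bit widths and fitted dB-per-bit slope
#'
#' Quantizes `w` at each bit width, measures the SQNR, and fits
#' `SQNR ~ beta` by least squares. The slope estimates the quantization
#' efficiency kappa (about 6.02 dB/bit for uniform weights).
#'
#' @param w weights in `[0, 1]`.
#' @param betas bit widths to scan (default `2:10`).
#' @return list with `table` (data frame: beta, sqnr_db, noise_power) and
#'   `kappa` (fitted slope, dB/bit).
#' @export
sqnr_scan <- function(w, betas = 2:10) {
  tab <- data.frame(beta = betas, sqnr_db = NA_real_, noise_power = NA_real_)
  for (i in seq_along(betas)) {
    wq <- quantize_weights(w, betas[i])
    tab$noise_power[i] <- mean((wq - w)^2)
    tab$sqnr_db[i] <- measure_sqnr(w, wq)
  }
  kappa <- unname(stats::coef(stats::lm(sqnr_db ~ beta, data = tab))["beta"])
  list(table = tab, kappa = kappa)
}

#' Quantize a model's codebook weights
#'
#' @param object object to quantize.
#' @param ... passed to methods.
#' @export
quantize <- function(object, ...) UseMethod("quantize")

#' @rdname quantize
#' @param beta bit width (integer `>= 1`).
#' @param stochastic,seed see [quantize_weights()].
#' @return for `"lnq"` models: the model with a quantized codebook and a
#'   `quantization` report (class `"quantization_report"`: `beta`, the
#'   per-weight noise `n_w`, signal/noise powers and `sqnr_db`).
#' @export
quantize.lnq <- function(object, beta, stochastic = FALSE, seed = NULL, ...) {
  w <- object$codebook
  wq <- quantize_weights(w, beta, stochastic = stochastic, seed = seed)
  n_w <- wq - w
  report <- structure(
    list(
      beta = as.integer(beta),
      n_w = n_w,
      signal_power = mean(w^2),
      noise_power = mean(n_w^2),
      sqnr_db = measure_sqnr(as.numeric(w), as.numeric(wq))
    ),
    class = "quantization_report"
  )
  object$codebook <- wq
  object$quantization <- report
  object
}

#' @export
print.quantization_report <- function(x, ...) {
  cat(sprintf(
    "quantization: beta = %d bits, signal power %.4g, noise power %.4g, SQNR %s dB\n",
    x$beta, x$signal_power, x$noise_power,
    if (is.infinite(x$sqnr_db)) "Inf" else sprintf("%.2f", x$sqnr_db)
  ))
  invisible(x)
}
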