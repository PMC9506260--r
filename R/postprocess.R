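#' Postprocessing configuration
#'
#' The heatmap-to-mask chain: (a) Gaussian smoothing of the probability
#' channels (reflective boundary, per-pixel renormalisation so the channel
#' pair still sums to 1), (b) thresholding the malignant channel at 0.5
#' (a probability of exactly 0.5 maps to 1), (c) erosion to remove isolated
#' pixels, (d) dilation to restore the extent of surviving regions.
#' Erosion followed by dilation with the same element is a morphological
#' opening.
#'
#' @param gaussian_sigma Smoothing standard deviation in pixels; 0 disables.
#' @param threshold Probability threshold; pixels with malignant
#'   probability `>= threshold` become 1.
#' @param se_size Side of the square structuring element (odd).
#' @param erosion_iterations,dilation_iterations Repetitions of each
#'   morphological step.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(gaussian_sigma = 2.0, threshold = 0.5,
                               se_size = 3L, erosion_iterations = 1L,
                               dilation_iterations = 1L) {
  check_scalar_num(gaussian_sigma, "gaussian_sigma", lower = 0)
  check_scalar_num(threshold, "threshold", lower = 0, upper = 1)
  if (threshold <= 0 || threshold >= 1) {
    stop_rcm("`threshold` must lie strictly in (0, 1).", "bad_arg")
  }
  if (se_size %% 2 != 1) {
    stop_rcm("`se_size` must be odd.", "bad_arg")
  }
  structure(list(gaussian_sigma = gaussian_sigma, threshold = threshold,
                 se_size = as.integer(se_size),
                 erosion_iterations = as.integer(erosion_iterations),
                 dilation_iterations = as.integer(dilation_iterations)),
            class = "postprocess_config")
}

# Separable Gaussian convolution of a matrix with symmetric-reflection
# boundary; kernel truncated at 3 sigma and normalised to unit sum.
gauss_filter_matrix <- function(m, sigma) {
  if (sigma == 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pass <- function(x) {  # filter along rows (dim 1)
    n <- nrow(x)
    idx <- reflect_index((1 - r):(n + r), n)
    xp <- x[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (d in seq_along(k)) {
      out <- out + k[d] * xp[(d - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(pass(t(pass(m))))
}

#' Smooth a heatmap
#'
#' Channel-wise Gaussian filtering with reflective boundaries, then
#' per-pixel renormalisation of the channel pair. `sigma = 0` is the
#' identity; a constant map is unchanged for any sigma.
#'
#' @param heatmap An `rcm_heatmap`.
#' @param sigma Standard deviation in pixels.
#' @return A smoothed `rcm_heatmap`.
#' @export
smooth_heatmap <- function(heatmap, sigma = 2.0) {
  stopifnot(inherits(heatmap, "rcm_heatmap"))
  check_scalar_num(sigma, "sigma", lower = 0)
  if (sigma == 0) return(heatmap)
  p <- heatmap$prob
  for (ch in 1:2) p[, , ch] <- gauss_filter_matrix(heatmap$prob[, , ch],
                                                   sigma)
  s <- p[, , 1] + p[, , 2]
  p[, , 1] <- p[, , 1] / s
  p[, , 2] <- p[, , 2] / s
  heatmap$prob <- p
  heatmap
}

#' Threshold a heatmap into a binary mask
#'
#' @param heatmap An `rcm_heatmap`.
#' @param threshold Pixels whose malignant probability is `>= threshold`
#'   become 1 (probabilities below it become 0, the rest 1 — so exactly 0.5
#'   maps to 1 at the default).
#' @return An integer 0/1 matrix on the heatmap's canvas.
#' @export
binarize_heatmap <- function(heatmap, threshold = 0.5) {
  stopifnot(inherits(heatmap, "rcm_heatmap"))
  matrix(as.integer(heatmap$prob[, , 2] >= threshold),
         dim(heatmap$prob)[1], dim(heatmap$prob)[2])
}

se_brush <- function(cfg) EBImage::makeBrush(cfg$se_size, shape = "box")

#' Binary morphology on segmentation masks
#'
#' Standard erosion / dilation with a square structuring element
#' (`EBImage`); `open_mask()` is erosion then dilation and is idempotent.
#'
#' @param mask Binary 0/1 matrix.
#' @param cfg A [postprocess_config()].
#' @return A binary integer matrix of the same shape.
#' @export
erode_mask <- function(mask, cfg = postprocess_config()) {
  check_binary_matrix(mask, "mask")
  out <- mask
  for (i in seq_len(cfg$erosion_iterations)) {
    out <- EBImage::erode(out, se_brush(cfg))
  }
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, cfg = postprocess_config()) {
  check_binary_matrix(mask, "mask")
  out <- mask
  for (i in seq_len(cfg$dilation_iterations)) {
    out <- EBImage::dilate(out, se_brush(cfg))
  }
  matrix(as.integer(out), nrow(mask), ncol(mask))
}

#' @rdname erode_mask
#' @export
open_mask <- function(mask, cfg = postprocess_config()) {
  dilate_mask(erode_mask(mask, cfg), cfg)
}

#' Full heatmap postprocessing chain
#'
#' Smooth, threshold, erode, dilate — in that order.
#'
#' @param heatmap An `rcm_heatmap`.
#' @param cfg A [postprocess_config()].
#' @return A binary integer segmentation mask on the heatmap's canvas.
#' @export
run_postprocess <- function(heatmap, cfg = postprocess_config()) {
  sm <- smooth_heatmap(heatmap, cfg$gaussian_sigma)
  mask <- binarize_heatmap(sm, cfg$threshold)
  mask <- erode_mask(mask, cfg)
  dilate_mask(mask, cfg)
}
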