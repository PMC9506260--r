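#' Dense-expansion configuration
#'
#' Controls the conversion of the patch classifier into a fully
#' convolutional dense predictor: the global average pool becomes a
#' shape-preserving average pooling (kernel 7 by default; kernel 8 equals
#' the patch classifier's 8x8 global pool exactly on interior cells), the
#' fully connected head becomes a 1x1 convolution with two filters, and the
#' resulting grid is upsampled by the backbone stride. Slices are first
#' mirror-padded (24 px total by default, 12 per side) so a 1000x1000 slice
#' becomes a 1024x1024 canvas whose side is divisible by 32.
#'
#' @param avgpool_kernel Pooling kernel in feature-grid cells (7 or 8).
#' @param avgpool_stride Pooling stride (1).
#' @param upsample_factor Upsampling factor (the backbone total stride, 32).
#' @param upsample_method `"bilinear"` (smooth heatmaps) or `"nearest"`
#'   (each output pixel equals its source grid cell exactly).
#' @param mirror_pad_total Total mirror padding in pixels, split evenly per
#'   side; must be even.
#' @param evaluate_on_padded_canvas If `TRUE` (default) heatmaps, masks and
#'   metrics live on the padded canvas, with truth masks padded by the same
#'   mirror geometry; cropping back to the original window is available via
#'   [crop_heatmap()] / [crop_padded()].
#' @return An `expansion_config` list.
#' @export
expansion_config <- function(avgpool_kernel = 7L, avgpool_stride = 1L,
                             upsample_factor = 32L,
                             upsample_method = c("bilinear", "nearest"),
                             mirror_pad_total = 24L,
                             evaluate_on_padded_canvas = TRUE) {
  check_scalar_num(avgpool_kernel, "avgpool_kernel", lower = 1)
  check_scalar_num(upsample_factor, "upsample_factor", lower = 1)
  check_scalar_num(mirror_pad_total, "mirror_pad_total", lower = 0)
  if (avgpool_stride != 1L) {
    stop_rcm("Only `avgpool_stride = 1` (shape-preserving) is supported.",
             "bad_arg")
  }
  if (mirror_pad_total %% 2 != 0) {
    stop_rcm("`mirror_pad_total` must be even (split across both sides).",
             "bad_arg")
  }
  structure(list(avgpool_kernel = as.integer(avgpool_kernel),
                 avgpool_stride = 1L,
                 upsample_factor = as.integer(upsample_factor),
                 upsample_method = match.arg(upsample_method),
                 mirror_pad_total = as.integer(mirror_pad_total),
                 evaluate_on_padded_canvas =
                   isTRUE(evaluate_on_padded_canvas)),
            class = "expansion_config")
}

#' Mirror-pad an image to a stride-divisible canvas
#'
#' Pads by symmetric reflection (the edge pixel participates: with 12 px of
#' padding, padded row `i` equals original row `13 - i` for `i <= 12`).
#' Interior pixels are unchanged. Errors when the padded side is not
#' divisible by the upsampling factor, suggesting the padding that would
#' make it so.
#'
#' @param image A matrix (image or mask).
#' @param cfg An [expansion_config()] (uses `mirror_pad_total` and
#'   `upsample_factor`).
#' @return The padded matrix.
#' @export
mirror_pad <- function(image, cfg = expansion_config()) {
  stopifnot(is.matrix(image))
  pad <- cfg$mirror_pad_total %/% 2L
  h <- nrow(image); w <- ncol(image)
  f <- cfg$upsample_factor
  for (n in c(h, w)) {
    if ((n + 2L * pad) %% f != 0) {
      need <- f * ceiling(n / f) - n
      stop_rcm(sprintf(
        "Padded size %d is not divisible by %d; use `mirror_pad_total = %d`.",
        n + 2L * pad, f, need), "bad_pad")
    }
  }
  ri <- c(rev(seq_len(min(pad, h))), seq_len(h),
          rev(seq_len(h))[seq_len(min(pad, h))])
  ci <- c(rev(seq_len(min(pad, w))), seq_len(w),
          rev(seq_len(w))[seq_len(min(pad, w))])
  if (pad > h || pad > w) {
    stop_rcm("Mirror padding wider than the image is not supported.",
             "bad_pad")
  }
  image[ri, ci, drop = FALSE]
}

#' Crop a padded matrix back to the original window
#'
#' Inverse of [mirror_pad()]: `crop_padded(mirror_pad(x, cfg), dim(x), cfg)`
#' returns `x` exactly.
#'
#' @param padded A padded matrix.
#' @param orig_dim `c(height, width)` of the original image.
#' @param cfg The [expansion_config()] used to pad.
#' @return The cropped matrix.
#' @export
crop_padded <- function(padded, orig_dim, cfg = expansion_config()) {
  pad <- cfg$mirror_pad_total %/% 2L
  padded[pad + seq_len(orig_dim[1]), pad + seq_len(orig_dim[2]),
         drop = FALSE]
}

# Shape-preserving average pooling over a feature volume, averaging over
# valid (non-padded) cells only, as TensorFlow's SAME average pooling does.
avgpool_same <- function(f, k) {
  if (k == 1L) return(f)
  d <- dim(f)
  ph <- same_pad(d[1], k, 1L); pw <- same_pad(d[2], k, 1L)
  fp <- zero_pad_hw(f, ph[["beg"]], ph[["end"]], pw[["beg"]], pw[["end"]])
  ones <- array(1, c(d[1], d[2], 1L))
  op <- zero_pad_hw(ones, ph[["beg"]], ph[["end"]], pw[["beg"]], pw[["end"]])
  acc <- array(0, d)
  cnt <- array(0, c(d[1], d[2], 1L))
  for (v in seq_len(k)) {
    for (u in seq_len(k)) {
      acc <- acc + fp[u + seq_len(d[1]) - 1L, v + seq_len(d[2]) - 1L, ,
                      drop = FALSE]
      cnt <- cnt + op[u + seq_len(d[1]) - 1L, v + seq_len(d[2]) - 1L, ,
                      drop = FALSE]
    }
  }
  acc / as.vector(cnt)
}

# 1-D interpolation operator taking an n_in-point grid to n_out = f * n_in
# samples at half-pixel-aligned positions; rows sum to 1 so constants are
# preserved.
upsample_matrix <- function(n_in, f, method) {
  n_out <- n_in * f
  if (method == "nearest") {
    src <- floor((seq_len(n_out) - 1L) / f) + 1L
    m <- matrix(0, n_out, n_in)
    m[cbind(seq_len(n_out), src)] <- 1
    return(m)
  }
  pos <- (seq_len(n_out) - 0.5) / f + 0.5
  i0 <- floor(pos)
  wgt <- pos - i0
  lo <- pmin(pmax(i0, 1L), n_in)
  hi <- pmin(pmax(i0 + 1L, 1L), n_in)
  m <- matrix(0, n_out, n_in)
  m[cbind(seq_len(n_out), lo)] <- m[cbind(seq_len(n_out), lo)] + (1 - wgt)
  m[cbind(seq_len(n_out), hi)] <- m[cbind(seq_len(n_out), hi)] + wgt
  m
}

#' Expand a trained patch classifier into a dense predictor
#'
#' Transplants the fully connected head into a 1x1 convolution with two
#' filters — filter `k`, channel `c` carries exactly the weight connecting
#' pooled feature `c` to class `k`, biases likewise — over a
#' shape-preserving average pooling of the backbone feature volume. The
#' backbone weights are shared untouched with the source classifier.
#'
#' @param model A trained `rcm_patch_model`.
#' @param cfg An [expansion_config()].
#' @return An `rcm_dense_model`.
#' @export
expand_model <- function(model, cfg = expansion_config()) {
  stopifnot(inherits(model, "rcm_patch_model"))
  if (!model$trained) {
    stop_rcm("Expand a *trained* patch model (call `train_patch_model()`).",
             "untrained")
  }
  if (nrow(model$head$W) != model$spec$final_channels) {
    stop_rcm("Head weight rows do not match the backbone's final channels.",
             "bad_spec")
  }
  structure(
    list(layers = model$layers,
         conv1x1 = list(W = model$head$W, b = model$head$b),
         spec = model$spec, cfg = cfg, patch_size = model$patch_size),
    class = "rcm_dense_model"
  )
}

#' @export
print.rcm_dense_model <- function(x, ...) {
  cat(sprintf(
    "<rcm_dense_model> pool %dx%d stride 1 same, x%d %s upsampling, pad %d\n",
    x$cfg$avgpool_kernel, x$cfg$avgpool_kernel, x$cfg$upsample_factor,
    x$cfg$upsample_method, x$cfg$mirror_pad_total))
  invisible(x)
}

new_heatmap <- function(prob, orig_dim, cfg) {
  structure(list(prob = prob, orig_dim = as.integer(orig_dim), cfg = cfg),
            class = "rcm_heatmap")
}

#' @export
print.rcm_heatmap <- function(x, ...) {
  cat(sprintf(
    "<rcm_heatmap> %d x %d x 2 on padded canvas (original %d x %d); mean p(malignant) %.3f\n",
    dim(x$prob)[1], dim(x$prob)[2], x$orig_dim[1], x$orig_dim[2],
    mean(x$prob[, , 2])))
  invisible(x)
}

#' Predict a whole-slice probability heatmap
#'
#' Runs mirror padding, the shared backbone, shape-preserving average
#' pooling, the transplanted 1x1 convolution with per-cell softmax, and
#' upsampling by the backbone stride. Each output pixel carries a
#' (healthy, malignant) probability pair summing to 1.
#'
#' @param dense An `rcm_dense_model` from [expand_model()].
#' @param image Integer matrix (0-255), e.g. a slice's `image`.
#' @return An `rcm_heatmap`: `prob` is an `Hp x Wp x 2` array on the padded
#'   canvas plus the original-dimension crop geometry.
#' @export
predict_heatmap <- function(dense, image) {
  stopifnot(inherits(dense, "rcm_dense_model"), is.matrix(image))
  cfg <- dense$cfg
  padded <- mirror_pad(image, cfg)
  x <- patch_to_tensor(padded)
  f <- backbone_forward(dense$layers, x)$out
  pooled <- avgpool_same(f, cfg$avgpool_kernel)
  d <- dim(pooled)
  pm <- matrix(pooled, d[1] * d[2], d[3])
  logits <- sweep(pm %*% dense$conv1x1$W, 2, dense$conv1x1$b, "+")
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  grid <- array(probs, c(d[1], d[2], 2L))
  mr <- upsample_matrix(d[1], cfg$upsample_factor, cfg$upsample_method)
  mc <- upsample_matrix(d[2], cfg$upsample_factor, cfg$upsample_method)
  up <- array(0, c(nrow(mr), nrow(mc), 2L))
  for (ch in 1:2) up[, , ch] <- mr %*% grid[, , ch] %*% t(mc)
  new_heatmap(up, dim(image), cfg)
}

#' Pre-upsample dense probability grid
#'
#' The 2-channel softmax grid before upsampling (e.g. 32 x 32 x 2 for a
#' 1024 x 1024 padded canvas); useful for comparing against
#' [sliding_window_oracle()].
#'
#' @inheritParams predict_heatmap
#' @return A `G x G x 2` array.
#' @export
predict_dense_grid <- function(dense, image) {
  cfg <- dense$cfg
  padded <- mirror_pad(image, cfg)
  x <- patch_to_tensor(padded)
  f <- backbone_forward(dense$layers, x)$out
  pooled <- avgpool_same(f, cfg$avgpool_kernel)
  d <- dim(pooled)
  pm <- matrix(pooled, d[1] * d[2], d[3])
  logits <- sweep(pm %*% dense$conv1x1$W, 2, dense$conv1x1$b, "+")
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  array(e / rowSums(e), c(d[1], d[2], 2L))
}

#' Brute-force sliding-window reference
#'
#' Classifies every full patch-sized window of the mirror-padded slice at
#' the given stride with the *patch* classifier. This is the independent
#' reference the dense expansion is checked against: with
#' `avgpool_kernel` equal to the patch feature-grid size and an aligned
#' backbone, dense grid interior cells equal these window probabilities.
#'
#' Window `(t, u)` (0-based) of the oracle corresponds to dense grid cell
#' `(t + off + 1, u + off + 1)` where `off` is the pooling left pad,
#' `(avgpool_kernel - 1) %/% 2`.
#'
#' @param model A trained `rcm_patch_model`.
#' @param image Integer matrix (0-255) of the original slice.
#' @param cfg An [expansion_config()] (for the mirror padding geometry).
#' @param stride Window step in pixels (the backbone stride).
#' @return An `n x n x 2` array of window probability pairs.
#' @export
sliding_window_oracle <- function(model, image, cfg = expansion_config(),
                                  stride = 32L) {
  stopifnot(inherits(model, "rcm_patch_model"))
  padded <- mirror_pad(image, cfg)
  ps <- model$patch_size
  rows <- grid_offsets(nrow(padded), ps, stride)
  cols <- grid_offsets(ncol(padded), ps, stride)
  out <- array(NA_real_, c(length(rows), length(cols), 2L))
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      win <- padded[rows[i] + seq_len(ps), cols[j] + seq_len(ps)]
      out[i, j, ] <- predict_patch(model, win)
    }
  }
  out
}

#' Interior cells of a dense grid aligned with sliding windows
#'
#' Extracts the sub-grid of [predict_dense_grid()] output whose pooling
#' windows lie fully inside the feature map, aligned so cell `(t, u)` of
#' the result corresponds to oracle window `(t, u)`.
#'
#' @param grid A dense probability grid (`G x G x 2`).
#' @param n_windows Number of sliding windows per axis.
#' @param avgpool_kernel The pooling kernel used by the dense model.
#' @return An `n_windows x n_windows x 2` array.
#' @export
dense_interior_cells <- function(grid, n_windows, avgpool_kernel = 8L) {
  off <- (avgpool_kernel - 1L) %/% 2L
  grid[off + seq_len(n_windows), off + seq_len(n_windows), , drop = FALSE]
}

#' Build a heatmap from a malignant-probability matrix
#'
#' Wraps a matrix of malignant probabilities as a two-channel heatmap
#' object (healthy channel is the complement), e.g. for postprocessing
#' experiments on constructed probability fields.
#'
#' @param p_malignant Numeric matrix with values in `[0, 1]`.
#' @return An `rcm_heatmap` on an unpadded canvas.
#' @export
as_heatmap <- function(p_malignant) {
  stopifnot(is.matrix(p_malignant), all(p_malignant >= 0),
            all(p_malignant <= 1))
  prob <- array(0, c(nrow(p_malignant), ncol(p_malignant), 2L))
  prob[, , 1] <- 1 - p_malignant
  prob[, , 2] <- p_malignant
  cfg <- expansion_config(mirror_pad_total = 0L, upsample_factor = 1L)
  new_heatmap(prob, dim(p_malignant), cfg)
}

#' Crop a heatmap to the original slice window
#'
#' @param heatmap An `rcm_heatmap`.
#' @return An `rcm_heatmap` on the original (unpadded) canvas.
#' @export
crop_heatmap <- function(heatmap) {
  stopifnot(inherits(heatmap, "rcm_heatmap"))
  cfg <- heatmap$cfg
  prob <- array(0, c(heatmap$orig_dim, 2L))
  for (ch in 1:2) {
    prob[, , ch] <- crop_padded(heatmap$prob[, , ch], heatmap$orig_dim, cfg)
  }
  cfg$mirror_pad_total <- 0L
  new_heatmap(prob, heatmap$orig_dim, cfg)
}
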