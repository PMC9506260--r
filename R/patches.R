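#' Patch extraction rule
#'
#' Slices are tiled into square patches on a regular grid and each patch is
#' labelled by the strict-majority rule: a patch is malignant if and only if
#' strictly more than `malignant_fraction_threshold` of its area is
#' annotated as cancer.
#'
#' The default stride of 106 px lays an 8x8 grid over a 1000x1000 slice
#' (about 64 patches per slice).
#'
#' @param patch_size Patch side length in pixels.
#' @param malignant_fraction_threshold Strict lower bound on the annotated
#'   fraction for a malignant label; must lie in (0, 1).
#' @param stride Grid step in pixels.
#' @return A `patch_rule` list.
#' @export
patch_rule <- function(patch_size = 256L,
                       malignant_fraction_threshold = 0.5,
                       stride = 106L) {
  check_scalar_num(patch_size, "patch_size", lower = 1)
  check_scalar_num(stride, "stride", lower = 1)
  check_scalar_num(malignant_fraction_threshold,
                   "malignant_fraction_threshold", lower = 0, upper = 1)
  if (malignant_fraction_threshold <= 0 ||
      malignant_fraction_threshold >= 1) {
    stop_rcm("`malignant_fraction_threshold` must lie strictly in (0, 1).",
             "bad_arg")
  }
  structure(list(patch_size = as.integer(patch_size),
                 malignant_fraction_threshold = malignant_fraction_threshold,
                 stride = as.integer(stride)),
            class = "patch_rule")
}

#' Label one mask patch by the strict-majority rule
#'
#' @param mask_patch Binary matrix of side `rule$patch_size`.
#' @param rule A [patch_rule()].
#' @return `"malignant"` iff the 1-pixel fraction strictly exceeds the
#'   threshold, else `"healthy"`.
#' @export
label_patch <- function(mask_patch, rule = patch_rule()) {
  check_binary_matrix(mask_patch, "mask_patch")
  ps <- rule$patch_size
  if (nrow(mask_patch) != ps || ncol(mask_patch) != ps) {
    stop_rcm(sprintf("`mask_patch` must be %d x %d.", ps, ps), "bad_shape")
  }
  frac <- sum(mask_patch) / (ps * ps)
  if (frac > rule$malignant_fraction_threshold) "malignant" else "healthy"
}

grid_offsets <- function(n, patch, stride) {
  if (n < patch) stop_rcm("slice smaller than the patch size", "bad_shape")
  seq(0L, n - patch, by = stride)
}

#' Tile a slice into labelled patches
#'
#' Lays a regular grid at the rule's stride and labels each patch with
#' [label_patch()]. Offsets are 0-based so a patch covers rows
#' `row_offset + 1 .. row_offset + patch_size`.
#'
#' @param slice An `rcm_slice` (or a one-row dataset tibble's contents via
#'   `image`/`mask`).
#' @param rule A [patch_rule()].
#' @return A tibble: origin columns (`case_id`, `stack_id`, `slice_index`,
#'   `row_offset`, `col_offset`), list-column `pixels`, and `label`.
#' @export
tile_slice <- function(slice, rule = patch_rule()) {
  stopifnot(inherits(slice, "rcm_slice"))
  ps <- rule$patch_size
  rows <- grid_offsets(nrow(slice$image), ps, rule$stride)
  cols <- grid_offsets(ncol(slice$image), ps, rule$stride)
  grid <- expand.grid(row_offset = rows, col_offset = cols)
  out <- purrr::pmap(grid, function(row_offset, col_offset) {
    ri <- row_offset + seq_len(ps); ci <- col_offset + seq_len(ps)
    tibble::tibble(
      case_id = slice$case_id, stack_id = slice$stack_id,
      slice_index = slice$slice_index,
      row_offset = as.integer(row_offset),
      col_offset = as.integer(col_offset),
      pixels = list(slice$image[ri, ci]),
      label = label_patch(slice$mask[ri, ci], rule)
    )
  })
  dplyr::bind_rows(out)
}

#' Tile every slice of a dataset
#'
#' @param dataset A dataset tibble from [generate_dataset()].
#' @param rule A [patch_rule()].
#' @return The row-bound patch manifests of all slices.
#' @export
tile_dataset <- function(dataset, rule = patch_rule()) {
  out <- purrr::pmap(
    dataset[c("case_id", "stack_id", "slice_index", "image", "mask")],
    function(case_id, stack_id, slice_index, image, mask) {
      tile_slice(new_rcm_slice(image, mask, case_id, stack_id, slice_index),
                 rule)
    })
  dplyr::bind_rows(out)
}

#' Augmentation configuration
#'
#' The training-time augmentations: rotation within a symmetric degree
#' range, zoom within a factor range, and horizontal flipping with
#' probability 1/2. Resampling is bilinear with reflective fill, so no flat
#' borders foreign to confocal texture are introduced; labels are never
#' altered.
#'
#' @param rotation_deg Half-width of the symmetric rotation range, degrees.
#' @param zoom Length-2 zoom factor range.
#' @param horizontal_flip Probability of a horizontal flip.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation_deg = 30, zoom = c(0.8, 1.2),
                           horizontal_flip = 0.5) {
  check_scalar_num(rotation_deg, "rotation_deg", lower = 0)
  if (length(zoom) != 2L || any(zoom <= 0) || diff(zoom) < 0) {
    stop_rcm("`zoom` must be a positive, non-decreasing range.", "bad_arg")
  }
  check_scalar_num(horizontal_flip, "horizontal_flip", lower = 0, upper = 1)
  structure(list(rotation_deg = rotation_deg, zoom = as.numeric(zoom),
                 horizontal_flip = horizontal_flip),
            class = "augment_config")
}

#' Apply a fixed affine transform to a patch
#'
#' Deterministic core of the augmentation: horizontal flip, then zoom about
#' the centre, then rotation about the centre, sampled bilinearly with
#' symmetric-reflection fill. `rotation = 0, zoom = 1, flip = FALSE` is the
#' identity.
#'
#' @param pixels Integer matrix (0-255).
#' @param rotation Degrees, counter-clockwise.
#' @param zoom Scale factor (>1 magnifies).
#' @param flip Horizontal flip?
#' @return An integer matrix of the same shape.
#' @export
affine_patch <- function(pixels, rotation = 0, zoom = 1, flip = FALSE) {
  h <- nrow(pixels); w <- ncol(pixels)
  if (rotation == 0 && zoom == 1 && !flip) return(pixels)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- rotation * pi / 180
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  # inverse map: undo rotation, then zoom, then flip
  sy <- (cos(th) * yy + sin(th) * xx) / zoom
  sx <- (-sin(th) * yy + cos(th) * xx) / zoom
  if (flip) sx <- -sx
  sy <- sy + cy; sx <- sx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gi <- function(yi, xi) {
    ri <- reflect_index(yi, h); ci <- reflect_index(xi, w)
    matrix(pixels[(ci - 1L) * h + ri], h, w)
  }
  val <- (1 - fy) * (1 - fx) * gi(y0, x0) +
    (1 - fy) * fx * gi(y0, x0 + 1) +
    fy * (1 - fx) * gi(y0 + 1, x0) +
    fy * fx * gi(y0 + 1, x0 + 1)
  matrix(as.integer(pmin(pmax(round(val), 0L), 255L)), h, w)
}

#' Randomly augment a patch
#'
#' Draws rotation, zoom and flip from an [augment_config()] and applies
#' [affine_patch()]. With `seed` given the draw is reproducible; otherwise
#' the current RNG stream is used (as during training epochs).
#'
#' @param pixels Integer matrix (0-255).
#' @param cfg An [augment_config()].
#' @param seed Optional seed for the draw.
#' @return An integer matrix of the same shape.
#' @export
augment_patch <- function(pixels, cfg = augment_config(), seed = NULL) {
  draw <- function() {
    list(rotation = runif(1, -cfg$rotation_deg, cfg$rotation_deg),
         zoom = runif(1, cfg$zoom[1], cfg$zoom[2]),
         flip = runif(1) < cfg$horizontal_flip)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  affine_patch(pixels, d$rotation, d$zoom, d$flip)
}
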