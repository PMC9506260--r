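#' Parameters for the synthetic RCM slice generator
#'
#' The generator emulates the texture statistics a confocal reflectance image
#' of basal cell carcinoma presents to a patch classifier: a speckle-textured
#' stromal background, one or more bright elliptical tumor islands with
#' elevated local contrast, and a dark peripheral fissure demarcating each
#' island from the surrounding stroma. Ground-truth masks cover the island
#' interiors only, not the fissure, mirroring expert annotation of compact
#' tumor-cell clusters.
#'
#' Speckle is multiplicative Gamma noise with mean 1 (the standard coherent
#' imaging model); `speckle_shape` is the Gamma shape parameter, so the
#' relative intensity standard deviation is `1/sqrt(speckle_shape)`.
#'
#' @param image_height,image_width Slice dimensions in pixels (8-bit
#'   grayscale output).
#' @param n_lesions Integer range `c(min, max)` (or a single count) of tumor
#'   islands per slice.
#' @param lesion_axis_px Range of the full axis lengths of the elliptical
#'   islands, in pixels.
#' @param lesion_contrast Multiplicative intensity offset of island texture
#'   over stroma: island mean intensity is `(1 + lesion_contrast)` times the
#'   local stromal mean. Must be >= 0.
#' @param fissure_width_px Width of the dark rim around each island.
#' @param fissure_contrast Multiplicative intensity factor of the fissure
#'   band relative to stroma (< 1 makes it dark).
#' @param speckle_shape Gamma shape parameter of the multiplicative speckle.
#' @param base_intensity Mean stromal intensity as a fraction of the 8-bit
#'   range.
#' @param slices_per_stack Number of slices acquired per scan site.
#' @param stacks_per_case Range (or single count) of stacks per patient case.
#' @param n_cases Number of patient cases in a generated dataset.
#' @param criteria If `TRUE`, slices also carry a multi-criterion annotation
#'   layer assigning each island one of the five confocal BCC criteria codes
#'   (palette values 2-6); all downstream stages use the binary mask.
#' @param seed Master seed; every slice's random stream is derived from it so
#'   any slice is regenerable in isolation.
#'
#' @return An object of class `rcm_params`.
#' @export
rcm_params <- function(image_height = 1000L,
                       image_width = 1000L,
                       n_lesions = c(1L, 3L),
                       lesion_axis_px = c(300, 500),
                       lesion_contrast = 0.8,
                       fissure_width_px = 12,
                       fissure_contrast = 0.35,
                       speckle_shape = 4,
                       base_intensity = 0.35,
                       slices_per_stack = 10L,
                       stacks_per_case = c(2L, 3L),
                       n_cases = 14L,
                       criteria = FALSE,
                       seed = 1L) {
  check_scalar_num(image_height, "image_height", lower = 8)
  check_scalar_num(image_width, "image_width", lower = 8)
  check_scalar_num(lesion_contrast, "lesion_contrast", lower = 0)
  check_scalar_num(fissure_width_px, "fissure_width_px", lower = 0)
  check_scalar_num(speckle_shape, "speckle_shape", lower = 0,
                   strict_lower = TRUE)
  check_scalar_num(base_intensity, "base_intensity", lower = 0, upper = 1)
  check_scalar_num(n_cases, "n_cases", lower = 1)
  check_scalar_num(slices_per_stack, "slices_per_stack", lower = 1)
  if (length(n_lesions) == 1L) n_lesions <- rep(n_lesions, 2L)
  if (length(stacks_per_case) == 1L) stacks_per_case <- rep(stacks_per_case, 2L)
  if (length(lesion_axis_px) == 1L) lesion_axis_px <- rep(lesion_axis_px, 2L)
  if (any(lesion_axis_px <= 0) || diff(lesion_axis_px) < 0) {
    stop_rcm("`lesion_axis_px` must be a positive, non-decreasing range.",
             "bad_arg")
  }
  if (any(n_lesions < 0) || diff(n_lesions) < 0) {
    stop_rcm("`n_lesions` must be a non-negative, non-decreasing range.",
             "bad_arg")
  }
  # An island plus its fissure must fit inside the slice.
  if (max(lesion_axis_px) + 2 * fissure_width_px > min(image_height,
                                                       image_width)) {
    stop_rcm(paste0("Largest lesion axis plus fissure (",
                    max(lesion_axis_px) + 2 * fissure_width_px,
                    " px) exceeds the image size; shrink `lesion_axis_px`."),
             "lesion_too_large")
  }
  structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         n_lesions = as.integer(n_lesions),
         lesion_axis_px = as.numeric(lesion_axis_px),
         lesion_contrast = lesion_contrast,
         fissure_width_px = fissure_width_px,
         fissure_contrast = fissure_contrast,
         speckle_shape = speckle_shape,
         base_intensity = base_intensity,
         slices_per_stack = as.integer(slices_per_stack),
         stacks_per_case = as.integer(stacks_per_case),
         n_cases = as.integer(n_cases),
         criteria = isTRUE(criteria),
         seed = as.integer(seed)),
    class = "rcm_params"
  )
}

#' @export
print.rcm_params <- function(x, ...) {
  cat("<rcm_params>\n")
  cat(sprintf("  slice: %d x %d px (8-bit)\n", x$image_height, x$image_width))
  cat(sprintf("  lesions/slice: %d-%d, full axes %g-%g px, contrast %g\n",
              x$n_lesions[1], x$n_lesions[2], x$lesion_axis_px[1],
              x$lesion_axis_px[2], x$lesion_contrast))
  cat(sprintf("  fissure: %g px at %g x stroma; speckle shape %g\n",
              x$fissure_width_px, x$fissure_contrast, x$speckle_shape))
  cat(sprintf("  dataset: %d cases x %d-%d stacks x %d slices, seed %d\n",
              x$n_cases, x$stacks_per_case[1], x$stacks_per_case[2],
              x$slices_per_stack, x$seed))
  invisible(x)
}

#' Construct an annotated slice
#'
#' Bundles an 8-bit grayscale image with its pixel-aligned binary lesion
#' mask and (case, stack, slice) identity — the atomic evaluation unit.
#'
#' @param image Integer matrix (0-255).
#' @param mask Binary 0/1 matrix of the same shape (1 = malignant).
#' @param case_id,stack_id,slice_index Identifiers.
#' @return An `rcm_slice`.
#' @export
annotated_slice <- function(image, mask, case_id = "case01",
                            stack_id = "stack01", slice_index = 1L) {
  stopifnot(is.matrix(image))
  check_binary_matrix(mask, "mask")
  if (!identical(dim(image), dim(mask))) {
    stop_rcm("`image` and `mask` must have identical shapes.", "bad_shape")
  }
  new_rcm_slice(image, mask, case_id, stack_id, slice_index)
}

new_rcm_slice <- function(image, mask, case_id, stack_id, slice_index,
                          criteria = NULL) {
  stopifnot(identical(dim(image), dim(mask)))
  structure(
    list(image = image, mask = mask, criteria = criteria,
         case_id = case_id, stack_id = stack_id,
         slice_index = as.integer(slice_index)),
    class = "rcm_slice"
  )
}

#' @export
print.rcm_slice <- function(x, ...) {
  cat(sprintf("<rcm_slice %s/%s/%03d> %d x %d px, lesion fraction %.3f\n",
              x$case_id, x$stack_id, x$slice_index,
              nrow(x$image), ncol(x$image), mean(x$mask)))
  invisible(x)
}

# Place up to n non-overlapping ellipses (bounding-circle test) fully inside
# the image; gives up on a candidate after 200 draws.
place_lesions <- function(n, params) {
  h <- params$image_height; w <- params$image_width
  fw <- params$fissure_width_px
  placed <- list()
  for (i in seq_len(n)) {
    for (try in seq_len(200L)) {
      a <- runif(1, params$lesion_axis_px[1], params$lesion_axis_px[2]) / 2
      b <- runif(1, params$lesion_axis_px[1], params$lesion_axis_px[2]) / 2
      theta <- runif(1, 0, pi)
      r <- max(a, b) + fw
      if (2 * r >= min(h, w)) next
      cy <- runif(1, r + 1, h - r)
      cx <- runif(1, r + 1, w - r)
      clash <- any(vapply(placed, function(p) {
        sqrt((p$cy - cy)^2 + (p$cx - cx)^2) < (max(p$a, p$b) + fw + r)
      }, logical(1)))
      if (!clash) {
        placed[[length(placed) + 1L]] <-
          list(a = a, b = b, theta = theta, cy = cy, cx = cx)
        break
      }
    }
  }
  placed
}

#' Generate one synthetic annotated RCM slice
#'
#' Produces an 8-bit grayscale slice with multiplicative Gamma speckle over a
#' smoothly varying stromal base, elliptical bright tumor islands each ringed
#' by a dark fissure, and a binary ground-truth mask equal to 1 exactly on
#' island interiors (the fissure is background). Bit-identical output for the
#' same parameters and seed.
#'
#' @param params An [rcm_params()] object.
#' @param case_id,stack_id,slice_index Identifiers recorded on the slice.
#' @param seed Seed for this slice; defaults to a stream derived from
#'   `params$seed` and the identifiers.
#'
#' @return An `rcm_slice`: list with integer `image` (0-255) and `mask` (0/1)
#'   matrices of equal shape plus identifiers.
#' @export
generate_slice <- function(params, case_id = "case01", stack_id = "stack01",
                           slice_index = 1L, seed = NULL) {
  stopifnot(inherits(params, "rcm_params"))
  if (is.null(seed)) {
    seed <- derive_seed(params$seed, utf8ToInt(case_id),
                        utf8ToInt(stack_id), slice_index)
  }
  h <- params$image_height; w <- params$image_width
  withr::with_seed(seed, {
    # Smooth stromal base: mean level plus low-frequency cosine undulation.
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    und <- 0
    for (k in 1:3) {
      fy <- runif(1, 0.5, 2) / h; fx <- runif(1, 0.5, 2) / w
      und <- und + runif(1, 0.03, 0.08) *
        cos(2 * pi * (fy * yy + fx * xx) + runif(1, 0, 2 * pi))
    }
    base <- params$base_intensity * (1 + und)

    n <- if (params$n_lesions[1] == params$n_lesions[2]) params$n_lesions[1]
         else sample(params$n_lesions[1]:params$n_lesions[2], 1L)
    lesions <- place_lesions(n, params)

    intensity <- base
    mask <- matrix(0L, h, w)
    crit <- if (params$criteria) matrix(0L, h, w) else NULL
    fw <- params$fissure_width_px
    for (i in seq_along(lesions)) {
      p <- lesions[[i]]
      r_out <- max(p$a, p$b) + fw
      rows <- max(1L, floor(p$cy - r_out)):min(h, ceiling(p$cy + r_out))
      cols <- max(1L, floor(p$cx - r_out)):min(w, ceiling(p$cx + r_out))
      dy <- matrix(rows - p$cy, length(rows), length(cols))
      dx <- matrix(cols - p$cx, length(rows), length(cols), byrow = TRUE)
      u <- dy * cos(p$theta) + dx * sin(p$theta)
      v <- -dy * sin(p$theta) + dx * cos(p$theta)
      inside <- (u / p$a)^2 + (v / p$b)^2 <= 1
      ring <- !inside & ((u / (p$a + fw))^2 + (v / (p$b + fw))^2 <= 1)
      sub <- intensity[rows, cols]
      sub[inside] <- sub[inside] * (1 + params$lesion_contrast)
      sub[ring] <- sub[ring] * params$fissure_contrast
      intensity[rows, cols] <- sub
      msub <- mask[rows, cols]; msub[inside] <- 1L
      mask[rows, cols] <- msub
      if (!is.null(crit)) {
        code <- 2L + ((i - 1L) %% 5L)  # palette codes 2-6: the five criteria
        csub <- crit[rows, cols]; csub[inside] <- code
        crit[rows, cols] <- csub
      }
    }

    speckle <- matrix(rgamma(h * w, shape = params$speckle_shape,
                             rate = params$speckle_shape), h, w)
    img <- pmin(pmax(intensity * speckle, 0), 1)
    image <- matrix(as.integer(round(img * 255)), h, w)
  })
  new_rcm_slice(image, mask, case_id, stack_id, slice_index, criteria = crit)
}

#' Generate a multi-case synthetic RCM dataset
#'
#' Generates `n_cases` patient cases, each holding a number of stacks drawn
#' from `stacks_per_case`, each stack holding `slices_per_stack` ordered
#' slices. Per-slice seeds are derived from the master seed, so the dataset
#' is a pure function of `params` and any slice can be regenerated alone with
#' [generate_slice()].
#'
#' @param params An [rcm_params()] object.
#'
#' @return A tibble with one row per slice: `case_id`, `stack_id`,
#'   `slice_index`, and list-columns `image` and `mask` (plus `criteria` when
#'   enabled).
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "rcm_params"))
  if (params$n_cases < 1L) stop_rcm("`n_cases` must be >= 1.", "bad_arg")
  rows <- list()
  for (ci in seq_len(params$n_cases)) {
    case_id <- sprintf("case%02d", ci)
    ns <- params$stacks_per_case
    n_stacks <- if (ns[1] == ns[2]) ns[1] else
      withr::with_seed(derive_seed(params$seed, ci, 777L),
                       sample(ns[1]:ns[2], 1L))
    for (si in seq_len(n_stacks)) {
      stack_id <- sprintf("stack%02d", si)
      for (zi in seq_len(params$slices_per_stack)) {
        sl <- generate_slice(params, case_id, stack_id, zi)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          case_id = case_id, stack_id = stack_id, slice_index = zi,
          image = list(sl$image), mask = list(sl$mask),
          criteria = list(sl$criteria)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!params$criteria) out$criteria <- NULL
  out
}

#' Write / read a slice dataset as PNG files
#'
#' Slices are written as 8-bit grayscale PNGs named
#' `{case}_{stack}_{slice}.png`; masks as `{case}_{stack}_{slice}_mask.png`
#' with small integer pixel codes (0 = background, 1 = lesion; codes 2-6
#' carry the five-criteria layer when present).
#'
#' @param dataset A tibble as returned by [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `write_dataset()` invisibly returns the file paths;
#'   `read_dataset()` returns a dataset tibble.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_len(nrow(dataset))) {
    stem <- sprintf("%s_%s_%03d", dataset$case_id[i], dataset$stack_id[i],
                    dataset$slice_index[i])
    img_path <- file.path(dir, paste0(stem, ".png"))
    png::writePNG(dataset$image[[i]] / 255, img_path)
    mask <- dataset$mask[[i]]
    if ("criteria" %in% names(dataset) && !is.null(dataset$criteria[[i]])) {
      mask <- pmax(mask, dataset$criteria[[i]])
    }
    mask_path <- file.path(dir, paste0(stem, "_mask.png"))
    png::writePNG(mask / 255, mask_path)
    paths <- c(paths, img_path, mask_path)
  }
  invisible(paths)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "^.*_[0-9]+\\.png$",
                          full.names = TRUE))
  imgs <- imgs[!grepl("_mask\\.png$", imgs)]
  if (length(imgs) == 0) stop_rcm("No slice PNGs found in `dir`.", "io")
  rows <- purrr::map(imgs, function(path) {
    stem <- sub("\\.png$", "", basename(path))
    parts <- strsplit(stem, "_")[[1]]
    px <- png::readPNG(path)
    image <- matrix(as.integer(round(px * 255)), nrow = dim(px)[1])
    m <- png::readPNG(sub("\\.png$", "_mask.png", path))
    codes <- matrix(as.integer(round(m * 255)), nrow = dim(m)[1])
    tibble::tibble(case_id = parts[1], stack_id = parts[2],
                   slice_index = as.integer(parts[3]),
                   image = list(image),
                   mask = list(matrix(as.integer(codes >= 1L), nrow(codes),
                                      ncol(codes))))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$case_id, .data$stack_id,
                 .data$slice_index)
}
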