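test_that("strict-majority labelling follows the >50% rule exactly", {
  rule <- patch_rule()
  zero <- matrix(0L, 256, 256)
  expect_identical(label_patch(zero, rule), "healthy")

  sixty <- matrix(0L, 256, 256)
  sixty[seq_len(39322)] <- 1L  # 60% of 65,536
  expect_identical(label_patch(sixty, rule), "malignant")

  half <- matrix(0L, 256, 256)
  half[seq_len(32768)] <- 1L   # exactly 50% is NOT malignant
  expect_identical(label_patch(half, rule), "healthy")

  half[32769] <- 1L            # one pixel over the line
  expect_identical(label_patch(half, rule), "malignant")
})

test_that("non-binary or mis-sized masks are rejected", {
  rule <- patch_rule()
  expect_error(label_patch(matrix(0.5, 256, 256), rule),
               class = "rcmseg_bad_mask")
  expect_error(label_patch(matrix(0L, 128, 128), rule),
               class = "rcmseg_bad_shape")
})

test_that("tiling counts match the closed-form grid formula", {
  n_expected <- function(n, ps, st) floor((n - ps) / st) + 1
  cases <- list(c(1000L, 256L, 106L), c(1000L, 256L, 248L),
                c(512L, 256L, 32L), c(256L, 256L, 64L),
                c(300L, 128L, 50L))
  for (cs in cases) {
    sl <- annotated_slice(matrix(0L, cs[1], cs[1]),
                          matrix(0L, cs[1], cs[1]))
    tl <- tile_slice(sl, patch_rule(patch_size = cs[2], stride = cs[3]))
    expect_identical(nrow(tl), as.integer(n_expected(cs[1], cs[2], cs[3])^2))
  }
  # the study-scale default: an 8x8 grid of 64 patches per 1000x1000 slice
  sl <- annotated_slice(matrix(0L, 1000, 1000), matrix(0L, 1000, 1000))
  expect_identical(nrow(tile_slice(sl, patch_rule())), 64L)
  expect_error(tile_slice(annotated_slice(matrix(0L, 100, 100),
                                          matrix(0L, 100, 100)),
                          patch_rule()),
               class = "rcmseg_bad_shape")
})

test_that("tile labels equal the brute-force per-patch mask fraction", {
  sl <- generate_slice(small_params(seed = 23L))
  rule <- small_rule()
  tiles <- tile_slice(sl, rule)
  for (i in seq_len(nrow(tiles))) {
    ri <- tiles$row_offset[i] + seq_len(rule$patch_size)
    ci <- tiles$col_offset[i] + seq_len(rule$patch_size)
    frac <- mean(sl$mask[ri, ci])
    expect_identical(tiles$label[i],
                     if (frac > 0.5) "malignant" else "healthy")
  }
  expect_true(any(tiles$label == "malignant"))
})

test_that("the identity draw leaves a patch bit-identical", {
  px <- generate_slice(small_params(seed = 5L))$image[1:128, 1:128]
  expect_identical(affine_patch(px, rotation = 0, zoom = 1, flip = FALSE),
                   px)
})

test_that("horizontal flip is an involution", {
  px <- generate_slice(small_params(seed = 5L))$image[1:128, 1:128]
  once <- affine_patch(px, flip = TRUE)
  expect_false(identical(once, px))
  expect_identical(affine_patch(once, flip = TRUE), px)
})

test_that("augmentation preserves shape and never touches labels", {
  sl <- generate_slice(small_params(seed = 29L))
  tiles <- tile_slice(sl, small_rule())
  cfg <- augment_config()
  i <- which(tiles$label == "malignant")[1]
  aug <- augment_patch(tiles$pixels[[i]], cfg, seed = 99L)
  expect_identical(dim(aug), dim(tiles$pixels[[i]]))
  expect_true(all(aug >= 0L & aug <= 255L))
  # the manifest row is untouched by pixel-space augmentation
  expect_identical(tiles$label[i], "malignant")
  zoomed <- affine_patch(tiles$pixels[[i]], zoom = 1.2)
  expect_identical(dim(zoomed), dim(tiles$pixels[[i]]))
})

test_that("augmentation draws are reproducible under a seed", {
  px <- generate_slice(small_params(seed = 5L))$image[1:128, 1:128]
  a <- augment_patch(px, augment_config(), seed = 42L)
  b <- augment_patch(px, augment_config(), seed = 42L)
  expect_identical(a, b)
})
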