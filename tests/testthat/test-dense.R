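test_that("mirror padding has the stated reflection geometry", {
  cfg <- expansion_config()
  img <- matrix(seq_len(1000 * 1000) %% 251L, 1000, 1000)
  padded <- mirror_pad(img, cfg)
  expect_identical(dim(padded), c(1024L, 1024L))
  # interior unchanged
  expect_identical(padded[13:1012, 13:1012], img)
  # symmetric reflection: padded row i equals original row 13 - i
  for (i in c(1L, 5L, 12L)) {
    expect_identical(padded[i, 13:1012], img[13L - i, ])
  }
  # trailing edge mirrors the last rows
  expect_identical(padded[1013, 13:1012], img[1000, ])
  expect_identical(padded[1024, 13:1012], img[989, ])
})

test_that("padding a constant image yields a constant image", {
  cfg <- expansion_config()
  expect_true(all(mirror_pad(matrix(7L, 1000, 1000), cfg) == 7L))
})

test_that("padding geometry round-trips and rejects bad sizes", {
  cfg <- expansion_config()
  img <- matrix(rpois(232 * 232, 60), 232, 232)
  expect_identical(crop_padded(mirror_pad(img, cfg), dim(img), cfg), img)
  expect_error(mirror_pad(matrix(0L, 990, 990), cfg),
               class = "rcmseg_bad_pad")
  err <- tryCatch(mirror_pad(matrix(0L, 990, 990), cfg),
                  error = conditionMessage)
  expect_match(err, "= 2")  # 990 + 2 = 992 = 31 * 32 is the smallest fix
})

test_that("expansion transplants the head and validates its input", {
  m <- random_weight_model()
  dense <- expand_model(m, expansion_config())
  expect_identical(dense$conv1x1$W, m$head$W)
  expect_identical(dense$conv1x1$b, m$head$b)
  expect_identical(dense$layers, m$layers)
  untrained <- build_patch_model(small_spec(), patch_size = 128L)
  expect_error(expand_model(untrained), class = "rcmseg_untrained")
  broken <- m
  broken$head$W <- broken$head$W[-1, , drop = FALSE]
  expect_error(expand_model(broken), class = "rcmseg_bad_spec")
})

test_that("a zero-weight head yields softmax(b) at every grid cell", {
  m <- random_weight_model()
  m$head$W <- matrix(0, nrow(m$head$W), 2)
  m$head$b <- c(0.3, -0.2)
  dense <- expand_model(m, expansion_config())
  img <- generate_slice(small_params(seed = 3L))$image
  grid <- predict_dense_grid(dense, img)
  want <- exp(c(0.3, -0.2)) / sum(exp(c(0.3, -0.2)))
  expect_equal(max(abs(grid[, , 1] - want[1])), 0, tolerance = 1e-12)
  expect_equal(max(abs(grid[, , 2] - want[2])), 0, tolerance = 1e-12)
})

test_that("heatmaps conserve probability at every pixel", {
  m <- random_weight_model()
  sl <- generate_slice(small_params(seed = 19L))
  for (method in c("bilinear", "nearest")) {
    dense <- expand_model(m, expansion_config(upsample_method = method))
    hm <- predict_heatmap(dense, sl$image)
    expect_identical(dim(hm$prob), c(256L, 256L, 2L))
    expect_lt(max(abs(hm$prob[, , 1] + hm$prob[, , 2] - 1)), 1e-9)
  }
})

test_that("nearest upsampling copies each source cell verbatim", {
  m <- random_weight_model()
  dense <- expand_model(m, expansion_config(upsample_method = "nearest"))
  sl <- generate_slice(small_params(seed = 19L))
  grid <- predict_dense_grid(dense, sl$image)
  hm <- predict_heatmap(dense, sl$image)
  f <- 32L
  for (i in c(1L, 3L, 8L)) {
    for (j in c(2L, 5L, 8L)) {
      block <- hm$prob[(i - 1L) * f + seq_len(f), (j - 1L) * f + seq_len(f), 2]
      expect_true(all(block == grid[i, j, 2]))
    }
  }
})

test_that("dense interior cells equal sliding-window patch predictions", {
  # pool kernel = patch feature grid (4 for a 128 patch) on an aligned
  # backbone: convolutionalization is exact, not approximate
  m <- random_weight_model(seed = 6L)
  cfg <- expansion_config(avgpool_kernel = 4L)
  dense <- expand_model(m, cfg)
  sl <- generate_slice(small_params(seed = 37L))
  grid <- predict_dense_grid(dense, sl$image)   # 8 x 8 x 2 (256 canvas)
  oracle <- sliding_window_oracle(m, sl$image, cfg, stride = 32L)
  expect_identical(dim(oracle), c(5L, 5L, 2L))  # (256-128)/32 + 1
  interior <- dense_interior_cells(grid, 5L, 4L)
  expect_lt(max(abs(interior - oracle)), 1e-10)
})

test_that("the sliding window oracle is constant on constant input", {
  m <- random_weight_model()
  img <- matrix(90L, 232, 232)
  oracle <- sliding_window_oracle(m, img, expansion_config(), stride = 32L)
  expect_lt(diff(range(oracle[, , 2])), 1e-12)
})

test_that("cropping a heatmap inverts the padded canvas", {
  m <- random_weight_model()
  dense <- expand_model(m, expansion_config())
  sl <- generate_slice(small_params(seed = 19L))
  hm <- predict_heatmap(dense, sl$image)
  cropped <- crop_heatmap(hm)
  expect_identical(dim(cropped$prob), c(232L, 232L, 2L))
  expect_identical(cropped$prob[1, 1, 2], hm$prob[13, 13, 2])
})
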