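test_that("backbone specs validate their stride structure", {
  expect_error(backbone_spec(8, c(16, 16), c(2L, 2L)),
               class = "rcmseg_bad_spec")  # 2*2*2 != 32
  spec <- mobilenet_spec(0.5)
  expect_identical(spec$final_channels, 512L)
  expect_identical(prod(spec$stages$stride), 32)
  tiny <- small_spec()
  expect_identical(prod(tiny$stages$stride), 32)
  expect_true(all(tiny$stages$kernel == tiny$stages$stride))
})

test_that("halving the final width preserves all shape invariants", {
  spec <- tiny_backbone_spec(c(2L, 4L, 4L, 8L, 4L))
  m <- random_weight_model(spec, seed = 2L, patch_size = 128L)
  f <- rcmseg:::backbone_forward(
    m$layers, rcmseg:::patch_to_tensor(matrix(128L, 128, 128)))$out
  expect_identical(dim(f), c(4L, 4L, 4L))
})

test_that("feature grids are input size over total stride", {
  m <- random_weight_model(patch_size = 128L)
  for (n in c(128L, 256L)) {
    f <- rcmseg:::backbone_forward(
      m$layers, rcmseg:::patch_to_tensor(matrix(100L, n, n)))$out
    expect_identical(dim(f)[1:2], c(n, n) %/% 32L)
  }
})

test_that("weight initialization is deterministic given the seed", {
  a <- build_patch_model(small_spec(), seed = 9L)
  b <- build_patch_model(small_spec(), seed = 9L)
  expect_identical(a$layers, b$layers)
  expect_identical(a$head, b$head)
  c <- build_patch_model(small_spec(), seed = 10L)
  expect_false(identical(a$layers, c$layers))
})

test_that("predictions are softmax-normalised and deterministic", {
  m <- random_weight_model()
  px <- generate_slice(small_params(seed = 3L))$image[1:128, 1:128]
  p1 <- predict_patch(m, px)
  expect_equal(unname(sum(p1)), 1, tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  expect_identical(p1, predict_patch(m, px))
  expect_error(predict_patch(m, px[1:64, 1:64]),
               class = "rcmseg_bad_shape")
})

test_that("analytic gradients match central finite differences", {
  spec <- tiny_backbone_spec(c(2L, 3L, 3L, 4L, 4L))
  m <- random_weight_model(spec, seed = 5L, patch_size = 32L)
  x <- withr::with_seed(8L, array(runif(32 * 32), c(32, 32, 1)))
  res <- rcmseg:::patch_grad(m$layers, m$head, x, 2L)
  lossfun <- function(layers, head) {
    f <- rcmseg:::backbone_forward(layers, x)$out
    g <- apply(f, 3, mean)
    l <- drop(crossprod(head$W, g)) + head$b
    l <- l - max(l)
    -log(exp(l[2]) / sum(exp(l)))
  }
  eps <- 1e-6
  withr::with_seed(21L, {
    for (li in seq_along(m$layers)) {
      for (rep in 1:3) {
        i <- sample(length(m$layers[[li]]$W), 1)
        lp <- m$layers; lp[[li]]$W[i] <- lp[[li]]$W[i] + eps
        lm <- m$layers; lm[[li]]$W[i] <- lm[[li]]$W[i] - eps
        num <- (lossfun(lp, m$head) - lossfun(lm, m$head)) / (2 * eps)
        expect_equal(res$grads[[li]]$dW[i], num, tolerance = 1e-5)
      }
    }
  })
  # head gradient too
  i <- 1L
  hp <- m$head; hp$W[i] <- hp$W[i] + eps
  hm <- m$head; hm$W[i] <- hm$W[i] - eps
  num <- (lossfun(m$layers, hp) - lossfun(m$layers, hm)) / (2 * eps)
  expect_equal(res$head_grad$dW[i], num, tolerance = 1e-5)
})

test_that("a zero learning rate leaves the weights untouched", {
  ds <- generate_dataset(small_params(seed = 41L))
  patches <- tile_dataset(ds, small_rule())
  m <- build_patch_model(small_spec(), seed = 4L, patch_size = 128L)
  tr <- train_patch_model(m, patches,
                          train_config(learning_rate = 0, epochs = 1L,
                                       batch_size = 8L, seed = 1L))
  expect_identical(tr$layers, m$layers)
  expect_identical(tr$head, m$head)
  expect_true(tr$trained)
})

test_that("training a separable task drives the loss down", {
  m <- trained_small_model()
  log <- tidy(m)
  expect_identical(nrow(log), 12L)
  expect_lt(log$loss[nrow(log)], log$loss[1])
  expect_gt(tail(log$accuracy, 1), 0.75)
  g <- glance(m)
  expect_true(g$trained)
  expect_gt(g$n_parameters, 0)
})

test_that("training refuses a single-class patch set", {
  ds <- generate_dataset(small_params(seed = 41L))
  patches <- tile_dataset(ds, small_rule())
  healthy_only <- patches[patches$label == "healthy", ]
  m <- build_patch_model(small_spec(), seed = 4L, patch_size = 128L)
  expect_error(train_patch_model(m, healthy_only, train_config(epochs = 1L)),
               class = "rcmseg_single_class")
})

test_that("a trained model separates held-out patches by class", {
  m <- trained_small_model()
  ds <- generate_dataset(small_params(seed = 77L))
  patches <- tile_dataset(ds, small_rule())
  p_mal <- vapply(patches$pixels, function(px)
    unname(predict_patch(m, px)[2]), numeric(1))
  acc <- mean((p_mal > 0.5) == (patches$label == "malignant"))
  expect_gt(acc, 0.75)
})
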