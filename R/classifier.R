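#' Backbone specification for the patch classifier
#'
#' The classifier follows the depthwise-separable design of MobileNet: a
#' strided standard convolution stem followed by blocks of depthwise 3x3 +
#' pointwise 1x1 convolutions, with ReLU after every affine stage and a
#' total spatial stride of 32, so a 256x256 patch yields an 8x8 feature grid
#' and a 1024x1024 slice a 32x32 grid. A global average pool and a 2-way
#' fully connected softmax head sit on top.
#'
#' `backbone_spec()` builds a specification from explicit stage tables;
#' [mobilenet_spec()] gives the full 13-block layout, and
#' [tiny_backbone_spec()] a small desk-scale backbone.
#'
#' @param stem_channels Channels produced by the stem convolution.
#' @param block_channels Output channels of each separable block.
#' @param block_strides Stride of each separable block (applied in the
#'   depthwise stage). Together with the stem stride these must multiply to
#'   `total_stride`.
#' @param kernel Spatial kernel size of the stem and depthwise convolutions.
#'   `"aligned"` sets each stage's kernel equal to its stride
#'   (non-overlapping receptive fields; see the package vignette — this
#'   makes dense expansion exactly equivalent to sliding-window patch
#'   classification).
#' @param stem_stride Stride of the stem convolution.
#' @param total_stride Required product of all strides (32).
#'
#' @return A `backbone_spec` object.
#' @export
backbone_spec <- function(stem_channels, block_channels, block_strides,
                          kernel = 3L, stem_stride = 2L, total_stride = 32L) {
  if (length(block_channels) != length(block_strides)) {
    stop_rcm("`block_channels` and `block_strides` must have equal length.",
             "bad_spec")
  }
  prod_stride <- stem_stride * prod(block_strides)
  if (prod_stride != total_stride) {
    stop_rcm(sprintf(
      "Stage strides multiply to %d, not the required total stride %d.",
      prod_stride, total_stride), "bad_spec")
  }
  aligned <- identical(kernel, "aligned")
  stage_kernel <- function(stride) {
    if (aligned) as.integer(stride) else as.integer(kernel)
  }
  stages <- tibble::tibble(
    type = c("conv", rep("sep", length(block_channels))),
    kernel = c(stage_kernel(stem_stride),
               vapply(block_strides, stage_kernel, integer(1))),
    stride = as.integer(c(stem_stride, block_strides)),
    channels = as.integer(c(stem_channels, block_channels))
  )
  structure(
    list(stages = stages,
         final_channels = as.integer(tail(block_channels, 1)),
         total_stride = as.integer(total_stride),
         aligned = aligned),
    class = "backbone_spec"
  )
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone_spec> %d stages, total stride %d, %d final channels%s\n",
              nrow(x$stages), x$total_stride, x$final_channels,
              if (x$aligned) " (aligned kernels)" else ""))
  print(x$stages, n = nrow(x$stages))
  invisible(x)
}

#' MobileNet-v1 backbone at a given width
#'
#' The 13-block MobileNet-v1 layout (strides 1,2,1,2,1,2,1,1,1,1,1,2,1 after
#' a stride-2 stem) scaled by a width multiplier. At `width_multiplier =
#' 0.5` the final stage has 512 channels, matching the 32x32x512 feature
#' volume the dense expansion starts from at slice scale.
#'
#' @param width_multiplier Channel scaling factor.
#' @return A [backbone_spec()].
#' @export
mobilenet_spec <- function(width_multiplier = 0.5) {
  ch <- c(64, 128, 128, 256, 256, 512, 512, 512, 512, 512, 512, 1024, 1024)
  backbone_spec(
    stem_channels = max(1L, round(32 * width_multiplier)),
    block_channels = pmax(1L, round(ch * width_multiplier)),
    block_strides = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L),
    kernel = 3L
  )
}

#' Small desk-scale backbone
#'
#' A stem plus four stride-2 separable blocks (total stride 32) at narrow
#' width, for fast experiments and tests. With `kernel = "aligned"` every
#' stage uses kernel = stride, making receptive fields tile the input
#' exactly.
#'
#' @param channels Five channel counts: stem then the four blocks.
#' @param kernel Kernel size or `"aligned"`.
#' @return A [backbone_spec()].
#' @export
tiny_backbone_spec <- function(channels = c(4L, 8L, 8L, 16L, 16L),
                               kernel = "aligned") {
  stopifnot(length(channels) == 5L)
  backbone_spec(stem_channels = channels[1],
                block_channels = channels[2:5],
                block_strides = c(2L, 2L, 2L, 2L),
                kernel = kernel)
}

init_layers <- function(spec) {
  layers <- list()
  cin <- 1L
  for (i in seq_len(nrow(spec$stages))) {
    st <- spec$stages[i, ]
    if (st$type == "conv") {
      fan_in <- st$kernel^2 * cin
      layers[[length(layers) + 1L]] <- list(
        type = "conv",
        W = array(rnorm(st$kernel^2 * cin * st$channels,
                        sd = sqrt(2 / fan_in)),
                  c(st$kernel, st$kernel, cin, st$channels)),
        b = rep(0, st$channels), kernel = st$kernel, stride = st$stride)
    } else {
      layers[[length(layers) + 1L]] <- list(
        type = "dw",
        W = array(rnorm(st$kernel^2 * cin, sd = sqrt(2 / st$kernel^2)),
                  c(st$kernel, st$kernel, cin)),
        b = rep(0, cin), kernel = st$kernel, stride = st$stride)
      layers[[length(layers) + 1L]] <- list(
        type = "pw",
        W = matrix(rnorm(cin * st$channels, sd = sqrt(2 / cin)),
                   cin, st$channels),
        b = rep(0, st$channels), kernel = 1L, stride = 1L)
    }
    cin <- st$channels
  }
  layers
}

#' Build an untrained patch classifier
#'
#' Initialises backbone and head weights (He-normal, zero biases)
#' deterministically from `seed`. The forward pass on a `patch_size` square
#' grayscale input yields a healthy/malignant probability pair.
#'
#' @param spec A [backbone_spec()].
#' @param seed Integer seed for weight initialisation.
#' @param patch_size Input side length in pixels; must be divisible by the
#'   backbone's total stride.
#' @return An `rcm_patch_model`.
#' @export
build_patch_model <- function(spec, seed = 1L, patch_size = 256L) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (patch_size %% spec$total_stride != 0) {
    stop_rcm("`patch_size` must be divisible by the backbone total stride.",
             "bad_spec")
  }
  withr::with_seed(seed, {
    layers <- init_layers(spec)
    # zero-initialised head: initial predictions are the uninformative
    # (0.5, 0.5) pair regardless of backbone scale
    head <- list(W = matrix(0, spec$final_channels, 2), b = rep(0, 2))
  })
  structure(
    list(spec = spec, layers = layers, head = head,
         patch_size = as.integer(patch_size), seed = as.integer(seed),
         trained = FALSE, log = NULL),
    class = "rcm_patch_model"
  )
}

#' @export
print.rcm_patch_model <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b),
                      numeric(1))) + length(x$head$W) + length(x$head$b)
  cat(sprintf("<rcm_patch_model> %s, %d parameters, patch size %d, %s\n",
              if (x$spec$aligned) "aligned kernels" else "3x3 kernels",
              as.integer(n_par), x$patch_size,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# 8-bit intensities mapped to [-0.5, 0.5]; centring keeps early layers in
# their responsive range without batch normalisation.
patch_to_tensor <- function(pixels) {
  array(pixels / 255 - 0.5, c(nrow(pixels), ncol(pixels), 1L))
}

#' Training configuration
#'
#' Defaults follow the study recipe: adaptive moment estimation (Adam) at
#' learning rate 1e-5, 20 epochs, two-class cross-entropy. Scaled-down desk
#' experiments typically pass a larger learning rate and fewer epochs (see
#' the vignette).
#'
#' @param learning_rate Adam step size.
#' @param epochs Number of passes over the training patches.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling shuffling and augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-5, epochs = 20L,
                         batch_size = 32L, seed = 1L) {
  check_scalar_num(learning_rate, "learning_rate", lower = 0)
  check_scalar_num(epochs, "epochs", lower = 1)
  check_scalar_num(batch_size, "batch_size", lower = 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the patch classifier
#'
#' Minibatch Adam on two-class cross-entropy. When an [augment_config()] is
#' given, each training patch is re-augmented on the fly every epoch
#' (labels are never touched). Requires at least one patch of each class.
#'
#' @param model An `rcm_patch_model` from [build_patch_model()].
#' @param patches A patch manifest tibble from [tile_slice()] /
#'   [tile_dataset()]: list-column `pixels` plus `label`.
#' @param config A [train_config()].
#' @param augment An [augment_config()] or `NULL` for no augmentation.
#' @return The trained model; `tidy()` on it returns the per-epoch loss log.
#' @export
train_patch_model <- function(model, patches, config = train_config(),
                              augment = NULL) {
  stopifnot(inherits(model, "rcm_patch_model"))
  labels <- patches$label
  if (length(unique(labels)) < 2L) {
    stop_rcm(paste0("Training requires both classes; got only '",
                    unique(labels), "'."), "single_class")
  }
  y <- ifelse(labels == "malignant", 2L, 1L)
  n <- length(y)
  layers <- model$layers
  head <- model$head
  opt <- adam_init(layers, head)
  lr <- config$learning_rate
  log <- vector("list", config$epochs)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        acc <- NULL
        for (i in idx) {
          px <- patches$pixels[[i]]
          if (!is.null(augment)) px <- augment_patch(px, augment)
          res <- patch_grad(layers, head, patch_to_tensor(px), y[i])
          ep_loss <- ep_loss + res$loss
          ep_correct <- ep_correct + (which.max(res$p) == y[i])
          if (is.null(acc)) {
            acc <- res
          } else {
            for (j in seq_along(layers)) {
              acc$grads[[j]]$dW <- acc$grads[[j]]$dW + res$grads[[j]]$dW
              acc$grads[[j]]$db <- acc$grads[[j]]$db + res$grads[[j]]$db
            }
            acc$head_grad$dW <- acc$head_grad$dW + res$head_grad$dW
            acc$head_grad$db <- acc$head_grad$db + res$head_grad$db
          }
        }
        bs <- length(idx)
        opt$t <- opt$t + 1L
        for (j in seq_along(layers)) {
          up <- adam_update(layers[[j]]$W, acc$grads[[j]]$dW / bs,
                            opt$layers[[j]]$W, lr, t = opt$t)
          layers[[j]]$W <- up$param; opt$layers[[j]]$W <- up$state
          up <- adam_update(layers[[j]]$b, acc$grads[[j]]$db / bs,
                            opt$layers[[j]]$b, lr, t = opt$t)
          layers[[j]]$b <- up$param; opt$layers[[j]]$b <- up$state
        }
        up <- adam_update(head$W, acc$head_grad$dW / bs, opt$head$W, lr,
                          t = opt$t)
        head$W <- up$param; opt$head$W <- up$state
        up <- adam_update(head$b, acc$head_grad$db / bs, opt$head$b, lr,
                          t = opt$t)
        head$b <- up$param; opt$head$b <- up$state
      }
      log[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss / n,
                                     accuracy = ep_correct / n)
    }
  })
  model$layers <- layers
  model$head <- head
  model$trained <- TRUE
  model$log <- dplyr::bind_rows(log)
  model
}

#' Classify one patch
#'
#' @param model A (typically trained) `rcm_patch_model`.
#' @param pixels A square integer matrix (0-255) of side `patch_size`.
#' @return Named numeric `c(p_healthy, p_malignant)`, summing to 1.
#' @export
predict_patch <- function(model, pixels) {
  stopifnot(inherits(model, "rcm_patch_model"))
  if (!is.matrix(pixels) || nrow(pixels) != model$patch_size ||
      ncol(pixels) != model$patch_size) {
    stop_rcm(sprintf("`pixels` must be a %d x %d matrix.",
                     model$patch_size, model$patch_size), "bad_shape")
  }
  f <- backbone_forward(model$layers, patch_to_tensor(pixels))$out
  g <- apply(f, 3, mean)
  logits <- drop(crossprod(model$head$W, g)) + model$head$b
  logits <- logits - max(logits)
  p <- exp(logits) / sum(exp(logits))
  c(p_healthy = p[1], p_malignant = p[2])
}

#' @export
tidy.rcm_patch_model <- function(x, ...) {
  if (is.null(x$log)) {
    tibble::tibble(epoch = integer(), loss = numeric(), accuracy = numeric())
  } else {
    x$log
  }
}

#' @export
glance.rcm_patch_model <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b),
                      numeric(1))) + length(x$head$W) + length(x$head$b)
  tibble::tibble(
    trained = x$trained,
    n_parameters = as.integer(n_par),
    final_loss = if (is.null(x$log)) NA_real_ else tail(x$log$loss, 1),
    final_accuracy = if (is.null(x$log)) NA_real_ else
      tail(x$log$accuracy, 1)
  )
}
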