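# Shared small fixtures: desk-scale generator parameters and backbones.
# Slices here are 232 x 232 so the default 24-px mirror pad lands on a
# 256-px canvas (divisible by the backbone stride of 32).

small_params <- function(seed = 11L, ...) {
  rcm_params(image_height = 232L, image_width = 232L,
             n_lesions = c(1L, 1L), lesion_axis_px = c(140, 180),
             slices_per_stack = 2L, stacks_per_case = 1L, n_cases = 2L,
             seed = seed, ...)
}

small_rule <- function() patch_rule(patch_size = 128L, stride = 104L)

small_spec <- function(kernel = "aligned") {
  tiny_backbone_spec(c(2L, 4L, 4L, 8L, 8L), kernel = kernel)
}

# A patch model with random (He-initialised) head weights standing in for a
# trained state where only the forward pass matters.
random_weight_model <- function(spec = small_spec(), seed = 1L,
                                patch_size = 128L) {
  m <- build_patch_model(spec, seed = seed, patch_size = patch_size)
  m$head$W <- withr::with_seed(seed + 1L,
    matrix(rnorm(spec$final_channels * 2, sd = 0.5),
           spec$final_channels, 2))
  m$head$b <- c(0.1, -0.1)
  m$trained <- TRUE
  m
}

# One trained-for-real tiny model on a separable task, cached per session.
.trained_cache <- new.env(parent = emptyenv())
trained_small_model <- function() {
  if (is.null(.trained_cache$model)) {
    p <- small_params(seed = 31L)
    p$n_cases <- 4L
    p$slices_per_stack <- 4L
    ds <- generate_dataset(p)
    patches <- tile_dataset(ds, small_rule())
    m <- build_patch_model(tiny_backbone_spec(c(4L, 8L, 8L, 16L, 16L)),
                           seed = 3L, patch_size = 128L)
    .trained_cache$model <- train_patch_model(
      m, patches,
      train_config(learning_rate = 1e-2, epochs = 12L, batch_size = 8L,
                   seed = 5L))
  }
  .trained_cache$model
}
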