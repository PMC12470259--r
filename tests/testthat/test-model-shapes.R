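# Shape contracts of the encoder-decoder and the forward-pass plumbing.

test_that("configuration validation rejects bad geometry and kernels", {
  expect_error(unet_config(input_height = 250L), "input_height")
  expect_error(unet_config(input_width = 100L), "input_width")
  expect_error(unet_config(sa_kernel = 4L), "sa_kernel")
  cfg <- unet_config()
  expect_equal(cfg$channel_schedule, c(32L, 64L, 128L, 256L, 512L))
})

test_that("encoder shape schedule scales with input size and width", {
  # derived by halving spatial dims four times and doubling channels
  cfg <- unet_config(input_height = 64L, input_width = 64L,
                     base_channels = 8L, seed = 2L)
  model <- build_model(cfg)
  enc <- encode(matrix(runif(64 * 64), 64, 64), model)
  expect_equal(dim(enc$bottleneck), c(4L, 4L, 128L))
  expect_equal(lapply(enc$skips, dim),
               list(c(64L, 64L, 8L), c(32L, 32L, 16L),
                    c(16L, 16L, 32L), c(8L, 8L, 64L)))
})

test_that("an all-zero input propagates zeros through the encoder", {
  cfg <- unet_config(input_height = 64L, input_width = 64L,
                     base_channels = 4L, seed = 3L)
  model <- build_model(cfg)  # biases initialize to zero
  enc <- encode(matrix(0, 64, 64), model)
  expect_true(all(enc$bottleneck == 0))
  expect_true(all(vapply(enc$skips, function(s) all(s == 0), logical(1))))
})

test_that("encoder rejects wrong sizes and non-finite input", {
  model <- build_model(unet_config(input_height = 64L, input_width = 64L,
                                   base_channels = 4L))
  expect_error(encode(matrix(0, 48, 64), model), "48x64")
  bad <- matrix(0, 64, 64); bad[5, 5] <- NaN
  expect_error(encode(bad, model), "non-finite")
})

test_that("decode(encode(x)) closes the shape contract at several sizes", {
  for (size in c(32L, 64L, 96L)) {
    cfg <- unet_config(input_height = size, input_width = size,
                       base_channels = 4L, seed = 4L)
    model <- build_model(cfg)
    enc <- encode(matrix(runif(size * size), size, size), model)
    feat <- decode(enc$bottleneck, enc$skips, model)
    expect_equal(dim(feat), c(size, size, 4L))
    p <- segmentation_head(feat, model)
    expect_equal(dim(p), c(size, size))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("decoder reports mismatched skip shapes with the level index", {
  cfg <- unet_config(input_height = 64L, input_width = 64L,
                     base_channels = 4L, seed = 5L)
  model <- build_model(cfg)
  enc <- encode(matrix(runif(64 * 64), 64, 64), model)
  skips <- enc$skips
  skips[[4]] <- skips[[4]][1:4, 1:4, , drop = FALSE]  # breaks level 1
  expect_error(decode(enc$bottleneck, skips, model), "decoder level 1")
})

test_that("zero feature map with zero head weights gives probability 0.5", {
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, seed = 6L)
  model <- build_model(cfg)
  model$weights[["head.W"]][] <- 0
  p <- segmentation_head(array(0, c(32, 32, 4)), model)
  expect_true(all(p == 0.5))
})

test_that("forward_subject is deterministic and emits one map per slice", {
  ds <- tiny_phantom()
  vol <- ds$volumes[[1]]
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, seed = 7L)
  model <- build_model(cfg)
  p1 <- forward_subject(vol, model)
  p2 <- forward_subject(vol, model)
  expect_length(p1, length(vol$slices))
  expect_identical(p1, p2)
  expect_true(all(vapply(p1, function(m) all(m > 0 & m < 1), logical(1))))
})

test_that("a single-slice volume works under the replicate boundary policy", {
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, seed = 8L)
  model <- build_model(cfg)
  vol <- subject_volume("one", list(matrix(runif(1024), 32, 32)),
                        list(matrix(0, 32, 32)))
  p <- forward_subject(vol, model)
  expect_length(p, 1L)
  expect_error(forward_subject(subject_volume("none", list(), list()), model),
               "no slices")
})

test_that("disabling both attention modules reproduces the baseline U-Net", {
  ds <- tiny_phantom()
  vol <- ds$volumes[[2]]
  off <- build_model(unet_config(input_height = 32L, input_width = 32L,
                                 base_channels = 4L, sa_enabled = FALSE,
                                 isa_enabled = FALSE, seed = 9L))
  baseline <- build_model(unet_config(input_height = 32L, input_width = 32L,
                                      base_channels = 4L, sa_enabled = FALSE,
                                      isa_enabled = FALSE, seed = 9L))
  expect_identical(off$weights, baseline$weights)
  expect_identical(forward_subject(vol, off), forward_subject(vol, baseline))
})

test_that("binarize uses a strict threshold and is monotone", {
  m <- matrix(0.5, 4, 4)
  expect_true(all(binarize(m, 0.5) == 0))  # ties go to background
  m2 <- matrix(0.1, 4, 4); m2[2, 3] <- 0.9
  expect_equal(sum(binarize(m2, 0.5)), 1)
  expect_equal(which(binarize(m2, 0.5) == 1), 10L)
  m3 <- matrix(runif(64), 8, 8)
  expect_true(all(binarize(m3, 0.7) <= binarize(m3, 0.3)))
  expect_error(binarize(m3, 1.2), "threshold")
})

test_that("interpolation upsampling and zero boundary policy also work", {
  ds <- tiny_phantom(n_subjects = 1L, seed = 12L)
  vol <- ds$volumes[[1]]
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, upsample_mode = "interp_plus_conv",
                     isa_boundary_policy = "zero", seed = 10L)
  model <- build_model(cfg)
  enc <- encode(vol$slices[[1]], model)
  feat <- decode(enc$bottleneck, enc$skips, model)
  expect_equal(dim(feat), c(32L, 32L, 4L))
  preds <- forward_subject(vol, model)
  expect_length(preds, length(vol$slices))
  # the backward pass through the interpolation path also runs and learns
  idx <- which(vapply(vol$masks, function(m) any(m > 0), logical(1)))[1:2]
  losses <- overfit_one_batch(cfg, vol$slices[idx], vol$masks[idx],
                              steps = 25L)
  expect_lt(losses[25], losses[1])
})
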