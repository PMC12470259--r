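# Training engine: loss, optimization, stopping rules, evaluation.

test_that("binary cross-entropy matches closed forms", {
  truth <- rand_mask(8, 8)
  half <- matrix(0.5, 8, 8)
  expect_equal(bce_loss(half, truth), log(2), tolerance = 1e-12)
  # 2x2 toy: p = .9,.1,.8,.2 (column-major), y = 1,0,1,0
  p <- matrix(c(0.9, 0.1, 0.8, 0.2), 2, 2)
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  hand <- -(log(0.9) + log(1 - 0.1) + log(0.8) + log(1 - 0.2)) / 4
  expect_equal(bce_loss(p, y), hand, tolerance = 1e-12)
  # near-perfect prediction drives the loss towards zero
  close <- ifelse(truth == 1, 1 - 1e-8, 1e-8)
  expect_lt(bce_loss(close, truth), 1e-6)
  expect_error(bce_loss(half, rand_mask(4, 4)), "differ in size")
})

test_that("overfitting one batch monotonically reduces the loss", {
  ds <- tiny_phantom(n_subjects = 1L, seed = 71L)
  vol <- ds$volumes[[1]]
  idx <- which(vapply(vol$masks, function(m) any(m > 0), logical(1)))[1:2]
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, sa_enabled = FALSE,
                     isa_enabled = FALSE, seed = 71L)
  losses <- overfit_one_batch(cfg, vol$slices[idx], vol$masks[idx],
                              steps = 60L)
  expect_lt(losses[60], losses[1])
  expect_lt(losses[60], 0.1)
})

test_that("training is deterministic, logs per-epoch metrics, and guards leakage", {
  ds <- tiny_phantom(n_subjects = 4L, seed = 72L)
  vols <- ds$volumes
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, seed = 72L)
  tc <- train_config(max_epochs = 2L, seed = 72L)
  fit1 <- train(cfg, vols[1:2], vols[3], tc)
  fit2 <- train(cfg, vols[1:2], vols[3], tc)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$model$weights, fit2$model$weights)
  expect_equal(nrow(fit1$log), 2L)
  expect_true(all(c("train_loss", "val_loss", "val_dice", "val_iou") %in%
                    names(fit1$log)))
  expect_equal(attr(fit1$log, "best_epoch"),
               which.min(fit1$log$val_loss))
  expect_error(train(cfg, vols[1:2], vols[2], tc), "both train and validation")
  expect_error(train(cfg, list(), vols[3], tc), "non-empty")
})

test_that("early stopping fires with zero patience on a worsening run", {
  ds <- tiny_phantom(n_subjects = 3L, seed = 73L)
  vols <- ds$volumes
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, sa_enabled = FALSE,
                     isa_enabled = FALSE, seed = 73L)
  # a wildly large learning rate makes validation loss blow up immediately
  tc <- train_config(learning_rate = 5, max_epochs = 10L,
                     early_stop_patience = 0L, seed = 73L)
  fit <- train(cfg, vols[1:2], vols[3], tc)
  expect_equal(attr(fit$log, "stop_reason"), "early_stop")
  expect_lt(nrow(fit$log), 10L)
  # returned weights come from the best epoch, not the last
  expect_equal(attr(fit$log, "best_epoch"), which.min(fit$log$val_loss))
})

test_that("evaluation round-trips checkpoints bit-for-bit", {
  ds <- tiny_phantom(n_subjects = 3L, seed = 74L)
  vols <- ds$volumes
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, seed = 74L)
  model <- build_model(cfg)
  rep1 <- evaluate(model, vols[3])
  tmp <- withr::local_tempdir()
  save_model(model, file.path(tmp, "ck.rds"))
  rep2 <- evaluate(load_model(file.path(tmp, "ck.rds")), vols[3])
  expect_identical(rep1, rep2)
})

test_that("a model scores dice 1 against its own binarized predictions", {
  ds <- tiny_phantom(n_subjects = 1L, seed = 75L)
  vol <- ds$volumes[[1]]
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, seed = 75L)
  model <- build_model(cfg)
  preds <- forward_subject(vol, model)
  self_truth <- lapply(preds, binarize)
  self_vol <- subject_volume(vol$subject_id, vol$slices, self_truth)
  rep <- evaluate(model, list(self_vol))
  expect_equal(rep$dice, 1)
  expect_equal(rep$iou, 1)
})

test_that("micro metrics are invariant to slice evaluation order", {
  ds <- tiny_phantom(n_subjects = 1L, seed = 76L)
  vol <- ds$volumes[[1]]
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 4L,
                     base_channels = 4L, sa_enabled = FALSE,
                     isa_enabled = FALSE, seed = 76L)
  model <- build_model(cfg)
  fwd <- evaluate(model, list(vol))
  rev_vol <- subject_volume(vol$subject_id, rev(vol$slices), rev(vol$masks))
  bwd <- evaluate(model, list(rev_vol))
  expect_equal(fwd$dice, bwd$dice)
  expect_equal(fwd$accuracy, bwd$accuracy)
})

test_that("the ablation harness trains four variants differing only in flags", {
  variants <- ablation_variants(input_height = 32L, input_width = 32L, depth = 4L,
                                base_channels = 4L, seed = 77L)
  flags <- t(vapply(variants, function(v) {
    c(sa = v$sa_enabled, isa = v$isa_enabled)
  }, logical(2)))
  expect_equal(unname(flags),
               matrix(c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
                      4, 2, byrow = TRUE))
  # everything else identical
  strip <- function(v) v[setdiff(names(v), c("sa_enabled", "isa_enabled"))]
  for (v in variants) expect_identical(strip(v), strip(variants$unet))

  ds <- tiny_phantom(n_subjects = 6L, seed = 77L, n_train = 3L)
  res <- suppressWarnings(
    run_ablation(ds, train_config(max_epochs = 1L, seed = 77L),
                 base_channels = 4L, depth = 4L, n_val = 1L))
  expect_equal(nrow(res$metrics), 4L)
  expect_setequal(res$metrics$model, c("unet", "unet_sa", "unet_isa", "dual"))
  expect_equal(ncol(res$metrics), 6L)  # model + five metric columns
  expect_equal(nrow(res$tests), 6L)    # dual vs 3 baselines x {dice, iou}
})
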