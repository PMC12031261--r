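# Augmentation, 1cycle schedule, training loop.

test_that("augmentation: disabled/degenerate config is the identity", {
  img <- matrix(runif(32 * 32), 32, 32)
  tgt <- matrix(runif(32 * 32), 32, 32)
  off <- augment_config(hflip_p = 0, vflip_p = 0, rotation_range = 0,
                        jitter_range = c(1, 1), crop_scale = c(1, 1))
  out <- augment_pair(img, tgt, off, draw_seed = 1)
  expect_equal(out$rough, img)
  expect_equal(out$target, tgt)

  dis <- augment_config(enabled = FALSE)
  out2 <- augment_pair(img, tgt, dis, draw_seed = 1)
  expect_identical(out2$rough, img)
})

test_that("horizontal flip is an involution and applies to both images", {
  img <- matrix(runif(16 * 16), 16, 16)
  cfg <- augment_config(hflip_p = 1, vflip_p = 0, rotation_range = 0,
                        jitter_range = c(1, 1), crop_scale = c(1, 1))
  once <- augment_pair(img, img, cfg, draw_seed = 3)
  expect_equal(once$rough, img[, 16:1])
  expect_equal(once$target, once$rough)
  twice <- augment_pair(once$rough, once$target, cfg, draw_seed = 4)
  expect_equal(twice$rough, img)
})

test_that("augmentation draws are deterministic and geometry is shared", {
  img <- matrix(runif(32 * 32), 32, 32)
  tgt <- img * 2
  cfg <- augment_config()
  a <- augment_pair(img, tgt, cfg, draw_seed = 11)
  b <- augment_pair(img, tgt, cfg, draw_seed = 11)
  expect_identical(a, b)
  # jitter touches the input only: target transform is purely geometric,
  # so target/2 must equal the geometric transform of the original image
  cfg0 <- augment_config(jitter_range = c(1, 1))
  g <- augment_pair(img, tgt, cfg0, draw_seed = 11)
  expect_equal(g$target / 2, g$rough, tolerance = 1e-12)
})

test_that("1cycle schedule hits its landmarks", {
  total <- 100; peak_step <- 30  # pct_start 0.3
  expect_equal(onecycle_lr(peak_step, total, max_lr = 3e-4), 3e-4)
  expect_equal(onecycle_lr(0, total, max_lr = 3e-4, div_factor = 25),
               3e-4 / 25)
  expect_lt(onecycle_lr(total - 1, total, max_lr = 3e-4),
            onecycle_lr(0, total, max_lr = 3e-4))
  expect_error(onecycle_lr(total, total), "range")
  # rises then falls
  lrs <- onecycle_lr(0:99, total, max_lr = 3e-4)
  expect_true(all(diff(lrs[1:31]) > 0))
  expect_true(all(diff(lrs[31:100]) < 0))
})

test_that("training reduces validation loss and is reproducible", {
  ds <- build_paired_dataset(20, 32,
                             rosette_params(n_petals = 24,
                                            samples_per_petal = 64,
                                            acceleration = 4),
                             rng_seed = 3)
  cfg <- vit_config(patch_size = 8, depth = 2, n_heads = 2, embed_dim = 16,
                    image_size = 32)
  tc <- train_config(max_epochs = 10, batch_size = 2, rng_seed = 5)
  fit1 <- vit_train(cfg, ds, tc, init_seed = 2)
  expect_lt(fit1$history$val_loss[10], fit1$history$val_loss[1])
  fit2 <- vit_train(cfg, ds, tc, init_seed = 2)
  expect_identical(fit1$history, fit2$history)
  expect_identical(rosetteRecon:::tree_flatten(fit1$weights),
                   rosetteRecon:::tree_flatten(fit2$weights))
})

test_that("triple augmentation triples the optimizer steps per epoch", {
  ds <- build_paired_dataset(10, 32,
                             rosette_params(n_petals = 24,
                                            samples_per_petal = 64,
                                            acceleration = 4),
                             rng_seed = 3)
  cfg <- vit_config(patch_size = 8, depth = 1, n_heads = 2, embed_dim = 8,
                    image_size = 32)
  tc <- train_config(max_epochs = 1, batch_size = 1, rng_seed = 5)
  f1 <- vit_train(cfg, ds, tc,
                  augment = augment_config(enabled = TRUE,
                                           multiplicity = 1))
  f3 <- vit_train(cfg, ds, tc,
                  augment = augment_config(enabled = TRUE,
                                           multiplicity = 3))
  expect_equal(f3$steps_per_epoch, 3 * f1$steps_per_epoch)
})

test_that("loss is non-negative and zero only at equality", {
  img <- matrix(runif(16 * 16), 16, 16)
  cfg <- vit_config(patch_size = 8, depth = 1, n_heads = 2, embed_dim = 8,
                    image_size = 16)
  w <- vit_init_weights(cfg, 1)
  out <- rosetteRecon:::vit_forward_core(img, cfg, w)
  expect_gte(mean((out - img)^2), 0)
  expect_equal(mean((out - out)^2), 0)
})
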