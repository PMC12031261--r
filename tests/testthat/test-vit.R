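# Vision transformer: patching, forward pass, parameter count, gradients.

tiny_cfg <- function(variant = "MHSA", window_size = 8, use_conv = TRUE) {
  vit_config(patch_size = 4, depth = 2, n_heads = 2, embed_dim = 8,
             variant = variant, window_size = window_size,
             mlp_ratio = 2, image_size = 16, use_conv = use_conv)
}

test_that("config invariants are enforced", {
  expect_error(vit_config(embed_dim = 81, n_heads = 16), "divisible")
  expect_error(vit_config(conv_stride = 2), "conv_stride")
  expect_error(vit_config(conv_kernel = 4), "conv_kernel")
})

test_that("patchify geometry and exact inversion", {
  img <- matrix(rnorm(40 * 40), 40, 40)
  rec <- patchify(img, 10)
  expect_equal(dim(rec$patches), c(16, 100))
  expect_equal(unpatchify(rec$patches, rec), img)

  # non-divisible size: symmetric zero padding, exact crop-back
  img2 <- matrix(rnorm(37 * 41), 37, 41)
  rec2 <- patchify(img2, 10)
  expect_equal(unpatchify(rec2$patches, rec2), img2)

  # full-scale geometry: 512 -> padded 520, 52^2 patches
  rec3 <- patchify(matrix(0, 512, 512), 10)
  expect_equal(rec3$grid, c(52, 52))
  expect_equal(nrow(rec3$patches), 2704)
  expect_equal(rec3$pad, c(4, 4))
})

test_that("forward pass preserves shape and is deterministic", {
  cfg <- tiny_cfg()
  w <- vit_init_weights(cfg, rng_seed = 2)
  img <- matrix(runif(16 * 16), 16, 16)
  o1 <- vit_forward(img, cfg, w)
  expect_equal(dim(o1), c(16, 16))
  expect_identical(unclass(o1), unclass(vit_forward(img, cfg, w)))
  # non-multiple size
  img2 <- matrix(runif(14 * 14), 14, 14)
  expect_equal(dim(vit_forward(img2, cfg, w)), c(14, 14))
  # finite output for extreme finite input
  img3 <- matrix(c(0, 1e6), 16, 16)
  expect_true(all(is.finite(vit_forward(img3, cfg, w))))
})

test_that("full-window WBSA reproduces MHSA exactly; windowing changes it", {
  w <- vit_init_weights(tiny_cfg(), rng_seed = 3)
  img <- matrix(runif(16 * 16), 16, 16)
  oM <- vit_forward(img, tiny_cfg("MHSA"), w)
  oW <- vit_forward(img, tiny_cfg("WBSA", window_size = 8), w)
  expect_lt(max(abs(oM - oW)), 1e-5)
  oW2 <- vit_forward(img, tiny_cfg("WBSA", window_size = 2), w)
  expect_gt(max(abs(oM - oW2)), 1e-8)
})

test_that("windows partition the patch grid and alternate layers shift", {
  cfg <- vit_config(patch_size = 4, depth = 2, n_heads = 2, embed_dim = 8,
                    variant = "WBSA", window_size = 2, image_size = 32)
  grid <- c(8, 8)
  for (layer in 1:2) {
    gs <- rosetteRecon:::attention_groups(cfg, grid, layer)
    all_idx <- sort(unlist(gs))
    expect_identical(all_idx, 1:64)          # partition: each patch once
    expect_true(all(lengths(gs) == 4))
  }
  g1 <- rosetteRecon:::attention_groups(cfg, grid, 1)
  g2 <- rosetteRecon:::attention_groups(cfg, grid, 2)
  expect_false(identical(lapply(g1, sort), lapply(g2, sort)))
})

test_that("parameter count: monotone in depth, conv adds k^2+1, audit", {
  cfg <- tiny_cfg()
  cfg2 <- tiny_cfg(); cfg2$depth <- 4L
  expect_gt(count_parameters(cfg2, 16), count_parameters(cfg, 16))

  noconv <- tiny_cfg(use_conv = FALSE)
  expect_equal(count_parameters(cfg, 16) - count_parameters(noconv, 16),
               3 * 3 + 1)

  # hand-summed ledger for depth 1, embed 8, patch 4, heads 2, mlp x2, 16px
  cfg1 <- vit_config(patch_size = 4, depth = 1, n_heads = 2, embed_dim = 8,
                     mlp_ratio = 2, image_size = 16)
  D <- 8; ps2 <- 16; P <- 16; M <- 16
  manual <- (ps2 * D + D) +            # patch embedding
    P * D +                            # position table
    (2 * D) + 4 * (D * D + D) +        # ln1 + q,k,v,o projections
    (2 * D) + (D * M + M) + (M * D + D) +  # ln2 + mlp
    2 * D +                            # final layer norm
    (D * ps2 + ps2) +                  # reconstruction head
    (9 + 1)                            # conv
  expect_equal(count_parameters(cfg1, 16), manual)
  # and the actual weight tree carries exactly that many numbers
  wt <- vit_init_weights(cfg1, rng_seed = 1)
  expect_length(rosetteRecon:::tree_flatten(wt), manual)
})

test_that("zeroed blocks leave the residual stream untouched", {
  cfg <- tiny_cfg()
  w <- vit_init_weights(cfg, rng_seed = 4)
  for (l in seq_along(w$layers)) {
    w$layers[[l]]$attn$Wo[] <- 0; w$layers[[l]]$attn$bo[] <- 0
    w$layers[[l]]$mlp$W2[] <- 0; w$layers[[l]]$mlp$b2[] <- 0
  }
  w$head$W[] <- 0; w$head$b[] <- 0
  img <- matrix(runif(16 * 16), 16, 16)
  out <- vit_forward(img, cfg, w)
  # zero head + identity conv: output is exactly the (zero) bias pattern
  expect_true(all(out == 0))
  expect_true(all(is.finite(out)))
})

test_that("analytic gradients match central finite differences", {
  for (variant in c("MHSA", "WBSA")) {
    cfg <- tiny_cfg(variant, window_size = 2)
    w <- vit_init_weights(cfg, rng_seed = 5)
    flat <- rosetteRecon:::tree_flatten(w)
    set.seed(6)
    flat <- flat + rnorm(length(flat), sd = 0.05)
    w <- rosetteRecon:::tree_unflatten(w, flat)
    img <- matrix(runif(16 * 16), 16, 16)
    tgt <- matrix(runif(16 * 16), 16, 16)
    fwd <- rosetteRecon:::vit_forward_core(img, cfg, w, cache = TRUE)
    dout <- 2 * (fwd$out - tgt) / length(tgt)
    ana <- rosetteRecon:::tree_flatten(
      rosetteRecon:::vit_backward(dout, cfg, w, fwd))
    loss_at <- function(v) {
      out <- rosetteRecon:::vit_forward_core(
        img, cfg, rosetteRecon:::tree_unflatten(w, v), cache = FALSE)
      mean((out - tgt)^2)
    }
    idx <- sort(sample(length(flat), 40))
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      up <- flat; up[i] <- up[i] + eps
      dn <- flat; dn[i] <- dn[i] - eps
      (loss_at(up) - loss_at(dn)) / (2 * eps)
    }, numeric(1))
    keep <- abs(num) > 1e-9
    expect_lt(max(abs(num - ana[idx])[keep] / abs(num[keep])), 1e-4)
  }
})

test_that("checkpoint round trip is lossless", {
  cfg <- tiny_cfg("WBSA", window_size = 2)
  w <- vit_init_weights(cfg, rng_seed = 7)
  path <- tempfile(fileext = ".rvc")
  save_checkpoint(w, cfg, path)
  ck <- load_checkpoint(path)
  expect_identical(rosetteRecon:::tree_flatten(ck$weights),
                   rosetteRecon:::tree_flatten(w))
  expect_equal(unclass(ck$config), unclass(cfg))
  img <- matrix(runif(16 * 16), 16, 16)
  expect_identical(unclass(vit_forward(img, cfg, w)),
                   unclass(vit_forward(img, ck$config, ck$weights)))
})
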