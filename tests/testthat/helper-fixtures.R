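# Shared fixtures. Everything is generated in code; heavier objects are
# memoised so several test files can reuse them within one run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# Small dense rosette + 32x32 engines used by the oracle-equivalence tests.
toy_traj <- function() {
  memo("toy_traj", function() {
    generate_rosette(rosette_params(kmax = 1000, w1 = 400, w2 = 400,
                                    n_petals = 12, samples_per_petal = 64))
  })
}

smooth_image <- function(n = 32, width = 0.05) {
  xs <- (seq_len(n) - 1 - n / 2) / n
  outer(xs, xs, function(a, b) exp(-(a^2 + b^2) / width))
}

random_complex_image <- function(n, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
}

# The scaled end-to-end study: 200 random 64x64 phantoms, a rosette scaled
# from the full acquisition (48 petals at Nyquist-edge kmax for a 64 grid),
# acceleration 4, 4 coils, and the toy refinement network (patch 8, depth 4,
# embed 32, heads 4) trained for up to 20 epochs of Adam/1cycle at
# max_lr 3e-4 with MSE loss, batch 1, under flip-only triple augmentation
# (flips preserve the trajectory-specific aliasing statistics; rotations and
# crops do not at this scale). Shared by the end-to-end, ablation and
# noise-sweep tests.
study_params <- function() {
  rosette_params(kmax = 1000, w1 = 400, w2 = 400, n_petals = 48,
                 samples_per_petal = 128, acceleration = 4)
}

study_dataset <- function() {
  memo("study_dataset", function() {
    build_paired_dataset(200, 64, study_params(), rng_seed = 11,
                         n_coils = 4)
  })
}

study_model_cfg <- function(use_conv = TRUE) {
  vit_config(patch_size = 8, depth = 4, n_heads = 4, embed_dim = 32,
             image_size = 64, use_conv = use_conv)
}

study_train_cfg <- function() {
  train_config(max_lr = 3e-4, max_epochs = 20, batch_size = 1,
               loss = "MSE", val_fraction = 0.2, rng_seed = 1)
}

study_augment <- function() {
  augment_config(hflip_p = 0.5, vflip_p = 0.5, rotation_range = 0,
                 jitter_range = c(1, 1), crop_scale = c(1, 1),
                 multiplicity = 3)
}

study_fit <- function() {
  memo("study_fit", function() {
    vit_train(study_model_cfg(), study_dataset(), study_train_cfg(),
              augment = study_augment(), init_seed = 1)
  })
}

study_fit_noconv <- function() {
  memo("study_fit_noconv", function() {
    vit_train(study_model_cfg(use_conv = FALSE), study_dataset(),
              study_train_cfg(), augment = study_augment(), init_seed = 1)
  })
}

# NRMSE against a reference image (global, range-normalized is not needed
# for relative comparisons; this is the plain relative l2 error).
rel_l2 <- function(x, ref) sqrt(sum((x - ref)^2)) / sqrt(sum(ref^2))

# strip image_grid attributes (internal helper, aliased for test bodies)
as_plain_matrix <- rosetteRecon:::as_plain_matrix

# Energy of a residual image at the patch-lattice spatial frequencies
# (multiples of 1/patch_size in either axis, DC excluded), normalized by
# total residual energy: the signature of patch-boundary artifacts.
patch_frequency_energy <- function(residual, patch_size) {
  n <- nrow(residual)
  F <- stats::fft(residual)
  P <- Mod(F)^2
  freq <- pmin(0:(n - 1), n - (0:(n - 1)))  # cycles per image, length n
  step <- n / patch_size
  on_lattice <- (freq %% step) == 0
  mask <- outer(on_lattice, on_lattice, `|`)
  mask[1, 1] <- FALSE
  sum(P[mask]) / sum(P[-1])
}
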