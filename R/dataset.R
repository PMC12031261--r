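#' Build a paired (rough, target) training set
#'
#' For each item: draw a random phantom, simulate the multi-coil rosette
#' acquisition (optionally accelerated and noisy), reconstruct the rough
#' image by density-compensated adjoint gridding + root-sum-of-squares, and
#' pair it with the noiseless ground-truth phantom magnitude (or the
#' CG-SENSE reconstruction when `target = "cg_sense"`). Both images are
#' scaled by the target's maximum so targets lie in `[0, 1]`.
#'
#' @param n_items Number of pairs (>= 1).
#' @param grid_size Image size in pixels.
#' @param params [rosette_params()] for the fully sampled trajectory; its
#'   `acceleration` field is applied via [subsample_petals()].
#' @param noise A [noise_spec()] applied to the k-space data (variance 0 for
#'   clean).
#' @param rng_seed Master seed; item phantoms, coil maps, and noise draws
#'   all derive from it.
#' @param n_coils Receive channels for the simulated array.
#' @param target `"phantom"` (ground truth) or `"cg_sense"`.
#' @param engine Forward/adjoint engine.
#' @return A `paired_dataset`: list with `rough` and `target` (lists of
#'   matrices), `maps`, `traj` (accelerated, with dcf), `params`, `rng_seed`.
#' @export
build_paired_dataset <- function(n_items, grid_size, params,
                                 noise = noise_spec(0), rng_seed = 1L,
                                 n_coils = 4L,
                                 target = c("phantom", "cg_sense"),
                                 engine = "nufft") {
  target <- match.arg(target)
  if (!is_count(n_items)) stop_field("n_items", "must be a count >= 1")
  traj <- generate_rosette(params)
  if (params$acceleration > 1) {
    traj <- subsample_petals(traj, params$acceleration, "uniform")
  }
  traj <- compute_dcf(traj, "pipe_menon", grid_size = grid_size)
  maps <- make_coil_maps(n_coils, grid_size, rng_seed = rng_seed)
  rough <- vector("list", n_items)
  tgt <- vector("list", n_items)
  for (i in seq_len(n_items)) {
    spec <- random_phantom_spec(grid_size, rng_seed = derive_seed(rng_seed, i))
    truth <- make_phantom(spec)
    kd <- forward_model(truth, maps, traj, engine)
    ns <- noise
    ns$rng_seed <- derive_seed(rng_seed, 500000L + i)
    kd <- add_kspace_noise(kd, ns)
    rough_i <- rss_combine(adjoint_recon(kd, use_dcf = TRUE, engine = engine))
    tgt_i <- if (target == "phantom") {
      truth
    } else {
      cg_sense(kd, maps, l2_reg = 1e-4, max_iters = 15, engine = engine)
    }
    sc <- max(tgt_i)
    if (sc <= 0) sc <- 1
    rough[[i]] <- as_plain_matrix(rough_i) / sc
    tgt[[i]] <- as_plain_matrix(tgt_i) / sc
  }
  structure(list(rough = rough, target = tgt, maps = maps, traj = traj,
                 params = params, noise = noise, rng_seed = rng_seed,
                 grid_size = grid_size, target_kind = target),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf(
    "paired_dataset: %d items, %dx%d, accel %d, %d coils, target '%s'\n",
    length(x$rough), x$grid_size, x$grid_size, x$params$acceleration,
    x$maps$n_coils, x$target_kind))
  invisible(x)
}
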