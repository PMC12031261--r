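#' Multi-coil k-space data container
#'
#' @param samples Complex matrix `n_coils x n_samples`.
#' @param traj The `rosette_traj` the samples live on.
#' @param grid_size Image grid size in pixels.
#' @param pixel_spacing Pixel size in m.
#' @param noise_variance Per-component Gaussian variance already added (0 if
#'   clean); metadata only.
#' @return A `kspace_data` object.
#' @export
kspace_data <- function(samples, traj, grid_size, pixel_spacing,
                        noise_variance = 0) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (ncol(samples) != n_traj_samples(traj)) {
    stop("sample count does not match trajectory length", call. = FALSE)
  }
  stopifnot(all(is.finite(Re(samples))), all(is.finite(Im(samples))))
  structure(list(samples = samples, traj = traj,
                 grid_size = as.integer(grid_size),
                 pixel_spacing = pixel_spacing,
                 noise_variance = noise_variance),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf(
    "kspace_data: %d coils x %d samples, grid %d, pixel %.4g m, noise var %.3g\n",
    nrow(x$samples), ncol(x$samples), x$grid_size, x$pixel_spacing,
    x$noise_variance))
  invisible(x)
}

#' Simulate the multi-coil rosette acquisition
#'
#' Evaluates, per coil c and sample j,
#' \eqn{S_c(k_j) = \sum_r map_c(r)\, image(r)\, e^{-2\pi i k_j \cdot r}},
#' either literally (`exact_dft`, the oracle) or by Kaiser-Bessel gridding
#' interpolation (`nufft`).
#'
#' @param image An `image_grid` (or plain matrix) of size `grid_size`.
#' @param maps A [make_coil_maps()] object of matching size.
#' @param traj A `rosette_traj`.
#' @param engine `"nufft"` (fast) or `"exact_dft"` (oracle, small grids).
#' @param pixel_spacing Pixel size in m; default places kmax at Nyquist.
#' @return A [kspace_data()].
#' @export
forward_model <- function(image, maps, traj,
                          engine = c("nufft", "exact_dft"),
                          pixel_spacing = 1 / (2 * traj$params$kmax)) {
  engine <- match.arg(engine)
  n <- nrow(image)
  if (ncol(image) != n) stop("image must be square", call. = FALSE)
  if (maps$grid_size != n) {
    stop(sprintf("grid size mismatch: image %d vs coil maps %d", n,
                 maps$grid_size), call. = FALSE)
  }
  eng <- make_engine(traj, n, pixel_spacing, engine)
  img <- as_plain_matrix(image)
  samples <- matrix(0i, maps$n_coils, n_traj_samples(traj))
  for (c in seq_len(maps$n_coils)) {
    samples[c, ] <- eng$forward(maps$maps[c, , ] * img)
  }
  kspace_data(samples, traj, n, pixel_spacing)
}

#' K-space noise specification
#'
#' Additive complex Gaussian noise for the acquisition simulator. The
#' variance applies independently to the real and imaginary part of every
#' sample, in the units of the stored samples. Because absolute scanner
#' k-space magnitudes are hardware-specific, `fraction` offers a convenience
#' mode: the per-component variance is chosen as
#' `fraction * mean(|sample|^2) / 2`, i.e. `fraction` is the noise-to-signal
#' power ratio, and the equivalent absolute variance is recorded on the
#' output.
#'
#' @param variance Non-negative per-component variance (ignored when
#'   `fraction` is given).
#' @param fraction Optional noise-to-signal power ratio.
#' @param rng_seed Integer seed; noise is deterministic given it.
#' @return A `noise_spec`.
#' @export
noise_spec <- function(variance = 0, fraction = NULL, rng_seed = 1L) {
  if (!is.null(fraction)) {
    if (!is_number(fraction) || fraction < 0) {
      stop_field("fraction", "must be >= 0")
    }
  } else if (!is_number(variance) || variance < 0) {
    stop_field("variance", "must be >= 0")
  }
  structure(list(variance = variance, fraction = fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

#' Add complex Gaussian noise to k-space samples
#'
#' @param kdata A [kspace_data()].
#' @param noise A [noise_spec()].
#' @return A new [kspace_data()] with noisy samples; `noise_variance` holds
#'   the absolute per-component variance actually applied.
#' @export
add_kspace_noise <- function(kdata, noise) {
  stopifnot(inherits(kdata, "kspace_data"), inherits(noise, "noise_spec"))
  v <- if (!is.null(noise$fraction)) {
    noise$fraction * mean(Mod(kdata$samples)^2) / 2
  } else {
    noise$variance
  }
  if (v == 0) {
    out <- kdata
    out$noise_variance <- 0
    return(out)
  }
  dims <- dim(kdata$samples)
  nn <- prod(dims)
  noise_mat <- with_seed(noise$rng_seed, {
    matrix(complex(real = stats::rnorm(nn, sd = sqrt(v)),
                   imaginary = stats::rnorm(nn, sd = sqrt(v))),
           dims[1], dims[2])
  })
  out <- kdata
  out$samples <- kdata$samples + noise_mat
  out$noise_variance <- v
  out
}
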