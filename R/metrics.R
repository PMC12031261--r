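#' Metric-suite parameters
#'
#' Controls the patch-based image-quality evaluation: six 50x50 patches with
#' centers drawn from a truncated Gaussian about the image center (to avoid
#' empty background), plus the per-metric constants.
#'
#' @param ssim_k1,ssim_k2 SSIM stabilizers (`c1 = (k1 L)^2`, `c2 = (k2 L)^2`).
#' @param dynamic_range Dynamic range `L`; `NULL` uses the reference
#'   region's maximum.
#' @param nmi_bins Joint-histogram bins for normalized mutual information.
#' @param entropy_bins Histogram bins for Shannon entropy.
#' @param patch_size Evaluation patch side in pixels.
#' @param n_patches Number of patches.
#' @param center_bias_sigma Std. dev. of the patch-center distribution as a
#'   fraction of the image side.
#' @param rng_seed Seed for patch sampling.
#' @return A `metric_params`.
#' @export
metric_params <- function(ssim_k1 = 0.01, ssim_k2 = 0.03,
                          dynamic_range = NULL, nmi_bins = 64,
                          entropy_bins = 256, patch_size = 50, n_patches = 6,
                          center_bias_sigma = 1 / 6, rng_seed = 1L) {
  if (!is_count(nmi_bins, 2)) stop_field("nmi_bins", "must be a count >= 2")
  if (!is_count(entropy_bins, 2)) {
    stop_field("entropy_bins", "must be a count >= 2")
  }
  if (!is_count(patch_size)) stop_field("patch_size", "must be a count >= 1")
  if (!is_count(n_patches)) stop_field("n_patches", "must be a count >= 1")
  structure(list(ssim_k1 = ssim_k1, ssim_k2 = ssim_k2,
                 dynamic_range = dynamic_range, nmi_bins = as.integer(nmi_bins),
                 entropy_bins = as.integer(entropy_bins),
                 patch_size = as.integer(patch_size),
                 n_patches = as.integer(n_patches),
                 center_bias_sigma = center_bias_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "metric_params")
}

#' Sample center-biased evaluation patches
#'
#' Draws `n_patches` patch origins whose centers follow a truncated Gaussian
#' about the image center (resampling until the patch lies fully inside).
#' Deterministic given the seed in `params`.
#'
#' @param image_shape Length-2 integer (rows, cols).
#' @param params A [metric_params()].
#' @return Integer matrix `n_patches x 2` of 1-based (row, col) origins.
#' @export
sample_patches <- function(image_shape, params) {
  ps <- params$patch_size
  h <- image_shape[1]; w <- image_shape[2]
  if (ps > h || ps > w) {
    stop(sprintf("patch size %d exceeds image %dx%d", ps, h, w),
         call. = FALSE)
  }
  sig_h <- params$center_bias_sigma * h
  sig_w <- params$center_bias_sigma * w
  with_seed(params$rng_seed, {
    origins <- matrix(0L, params$n_patches, 2)
    for (i in seq_len(params$n_patches)) {
      repeat {
        cr <- stats::rnorm(1, (h + 1) / 2, sig_h)
        cc <- stats::rnorm(1, (w + 1) / 2, sig_w)
        r0 <- round(cr - ps / 2); c0 <- round(cc - ps / 2)
        if (r0 >= 1 && c0 >= 1 && r0 + ps - 1 <= h && c0 + ps - 1 <= w) {
          origins[i, ] <- c(r0, c0)
          break
        }
      }
    }
    colnames(origins) <- c("row", "col")
    origins
  })
}

gaussian_window <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'valid' 2D correlation with a small window.
filter_valid <- function(img, win) {
  k <- nrow(win)
  h <- nrow(img) - k + 1; w <- ncol(img) - k + 1
  out <- matrix(0, h, w)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    out <- out + win[a, b] * img[(a - 1) + seq_len(h), (b - 1) + seq_len(w)]
  }
  out
}

#' Structural similarity index (SSIM)
#'
#' Gaussian-windowed (11x11, sigma 1.5) local SSIM
#' \deqn{SSIM = \frac{(2\mu_X\mu_Y + c_1)(2\sigma_{XY} + c_2)}
#'                   {(\mu_X^2+\mu_Y^2+c_1)(\sigma_X^2+\sigma_Y^2+c_2)}}
#' averaged over the region; regions smaller than the window fall back to a
#' single global window.
#'
#' @param X Reconstructed region. @param Y Reference region.
#' @param params A [metric_params()] (uses `ssim_k1`, `ssim_k2`,
#'   `dynamic_range`).
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(X, Y, params = metric_params()) {
  if (!all(dim(X) == dim(Y))) stop("shape mismatch", call. = FALSE)
  L <- params$dynamic_range %||% max(Y)
  c1 <- (params$ssim_k1 * L)^2
  c2 <- (params$ssim_k2 * L)^2
  if (min(dim(X)) >= 11) {
    win <- gaussian_window(11, 1.5)
    muX <- filter_valid(X, win); muY <- filter_valid(Y, win)
    sXX <- filter_valid(X * X, win) - muX^2
    sYY <- filter_valid(Y * Y, win) - muY^2
    sXY <- filter_valid(X * Y, win) - muX * muY
  } else {
    muX <- mean(X); muY <- mean(Y)
    sXX <- mean(X^2) - muX^2; sYY <- mean(Y^2) - muY^2
    sXY <- mean(X * Y) - muX * muY
  }
  mean(((2 * muX * muY + c1) * (2 * sXY + c2)) /
         ((muX^2 + muY^2 + c1) * (sXX + sYY + c2)))
}

#' Normalized root-mean-square error
#'
#' Root-mean-square difference divided by the reference region's intensity
#' range `max(Y) - min(Y)`.
#'
#' @param X Reconstructed region. @param Y Reference region.
#' @return NRMSE >= 0.
#' @export
nrmse <- function(X, Y) {
  if (!all(dim(X) == dim(Y))) stop("shape mismatch", call. = FALSE)
  rng <- max(Y) - min(Y)
  if (rng <= 0) {
    stop("undefined metric: reference region has zero intensity range",
         call. = FALSE)
  }
  sqrt(mean((X - Y)^2)) / rng
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(L^2 / MSE)`; identical regions give `Inf`.
#'
#' @param X Reconstructed region. @param Y Reference region.
#' @param L Maximum possible pixel value (dynamic range).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(X, Y, L = max(Y)) {
  if (!all(dim(X) == dim(Y))) stop("shape mismatch", call. = FALSE)
  mse <- mean((X - Y)^2)
  if (mse == 0) return(Inf)
  10 * log10(L^2 / mse)
}

shared_breaks <- function(X, Y, bins) {
  lo <- min(X, Y); hi <- max(X, Y)
  if (hi <= lo) hi <- lo + 1e-12
  seq(lo, hi, length.out = bins + 1)
}

bin_index <- function(v, breaks) {
  idx <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  idx
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized mutual information
#'
#' `2 I(X, Y) / (H(X) + H(Y))` from a joint `bins x bins` histogram with
#' shared edges over the pooled range; 1 for identical non-constant regions,
#' near 0 for independent ones.
#'
#' @param X,Y Same-shape regions.
#' @param bins Histogram bins per axis.
#' @return NMI in `[0, 1]` (up to estimation error).
#' @export
nmi <- function(X, Y, bins = 64) {
  if (!all(dim(X) == dim(Y))) stop("shape mismatch", call. = FALSE)
  if (max(X) == min(X) || max(Y) == min(Y)) {
    stop("undefined metric: constant region has zero entropy", call. = FALSE)
  }
  br <- shared_breaks(X, Y, bins)
  ix <- bin_index(as.vector(X), br)
  iy <- bin_index(as.vector(Y), br)
  joint <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  joint <- as.matrix(tab) / length(ix)
  px <- rowSums(joint); py <- colSums(joint)
  hx <- entropy_bits(px); hy <- entropy_bits(py)
  hxy <- entropy_bits(as.vector(joint))
  mi <- hx + hy - hxy
  2 * mi / (hx + hy)
}

#' Relative contrast
#'
#' `(max(X) - min(X)) / (max(X) + min(X))` of a single region.
#'
#' @param X Non-negative region with `max + min > 0`.
#' @return Relative contrast in `[0, 1]`.
#' @export
relative_contrast <- function(X) {
  s <- max(X) + min(X)
  if (s <= 0) {
    stop("undefined metric: all-zero region", call. = FALSE)
  }
  (max(X) - min(X)) / s
}

#' Shannon entropy (bits)
#'
#' Histogram entropy `-sum p_i log2 p_i` over `bins` equal-width intensity
#' bins spanning the region's own range.
#'
#' @param X Region. @param bins Histogram bins.
#' @return Entropy in bits (0 for a constant region).
#' @export
shannon_entropy <- function(X, bins = 256) {
  v <- as.vector(X)
  if (max(v) == min(v)) return(0)
  br <- seq(min(v), max(v), length.out = bins + 1)
  p <- tabulate(bin_index(v, br), nbins = bins) / length(v)
  entropy_bits(p)
}

#' Entropy focus criterion
#'
#' Energy-normalized intensity entropy
#' \deqn{E = -\sum_j \frac{x_j}{x_{max}} \ln \frac{x_j}{x_{max}},\quad
#'       x_{max} = \sqrt{\sum_j x_j^2}} with `0 ln 0 := 0`; lower values
#' indicate a sharper, less corrupted image.
#'
#' @param X Non-negative region with at least one nonzero pixel.
#' @return EFC >= 0.
#' @export
efc <- function(X) {
  xmax <- sqrt(sum(X^2))
  if (xmax == 0) {
    stop("undefined metric: all-zero region", call. = FALSE)
  }
  r <- as.vector(X) / xmax
  r <- r[r > 0]
  -sum(r * log(r))
}

#' Patch-averaged metric report
#'
#' Samples the evaluation patches once, computes every metric per patch
#' (single-image metrics on the reconstruction patch), and averages across
#' patches. Metrics undefined on some patch (e.g. zero-range reference) are
#' averaged over the remaining patches and recorded as missing if undefined
#' everywhere.
#'
#' @param recon Reconstructed image. @param reference Reference image.
#' @param params A [metric_params()].
#' @return A `metric_report`: list with `metrics` (named numeric),
#'   `per_patch` (data.frame), `origins`, `rng_seed`.
#' @export
evaluate_images <- function(recon, reference, params = metric_params()) {
  if (!all(dim(recon) == dim(reference))) {
    stop("shape mismatch", call. = FALSE)
  }
  origins <- sample_patches(dim(recon), params)
  ps <- params$patch_size
  rows <- lapply(seq_len(nrow(origins)), function(i) {
    rr <- origins[i, 1] + seq_len(ps) - 1
    cc <- origins[i, 2] + seq_len(ps) - 1
    X <- as_plain_matrix(recon)[rr, cc]
    Y <- as_plain_matrix(reference)[rr, cc]
    safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    data.frame(
      patch = i,
      ssim = safe(ssim(X, Y, params)),
      nrmse = safe(nrmse(X, Y)),
      psnr = safe(psnr(X, Y, params$dynamic_range %||% max(Y))),
      nmi = safe(nmi(X, Y, params$nmi_bins)),
      relative_contrast = safe(relative_contrast(X)),
      shannon_entropy = safe(shannon_entropy(X, params$entropy_bins)),
      efc = safe(efc(X)))
  })
  per_patch <- do.call(rbind, rows)
  metrics <- colMeans(per_patch[, -1, drop = FALSE], na.rm = TRUE)
  metrics[is.nan(metrics)] <- NA_real_
  structure(list(metrics = metrics, per_patch = per_patch,
                 origins = origins, rng_seed = params$rng_seed),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report (patch-averaged):\n")
  print(round(x$metrics, 4))
  invisible(x)
}
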