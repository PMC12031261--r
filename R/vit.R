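#' Vision transformer configuration
#'
#' Architecture hyperparameters for the refinement network: a patch-embedding
#' transformer encoder (pre-norm attention + MLP blocks with residual
#' connections), a per-patch linear reconstruction head, and a trailing
#' dimension-preserving convolution that removes patch-boundary artifacts.
#' Defaults follow the full-scale network (patch 10, depth 10, 16 heads,
#' embedding 80, conv kernel 3 stride 1); `image_size` bounds the position
#' embedding table, and smaller inputs use a cropped grid.
#'
#' @param patch_size Patch side in pixels.
#' @param depth Number of encoder layers.
#' @param n_heads Attention heads (`embed_dim` must be divisible by it).
#' @param embed_dim Feature dimension per patch token.
#' @param variant `"MHSA"` (global attention) or `"WBSA"` (window-based
#'   attention with Swin-style half-window shifts on alternating layers).
#' @param window_size Window side in patches (WBSA only).
#' @param conv_kernel Trailing convolution kernel side (odd).
#' @param conv_stride Must be 1 (dimension preserving).
#' @param mlp_ratio Hidden width of the MLP block as a multiple of
#'   `embed_dim`.
#' @param image_size Largest image side the network will see (sizes the
#'   position-embedding table).
#' @param use_conv Include the trailing convolution (`FALSE` for the
#'   ablation).
#' @return A `vit_config`.
#' @export
vit_config <- function(patch_size = 10, depth = 10, n_heads = 16,
                       embed_dim = 80, variant = c("MHSA", "WBSA"),
                       window_size = 8, conv_kernel = 3, conv_stride = 1,
                       mlp_ratio = 4, image_size = 512, use_conv = TRUE) {
  variant <- match.arg(variant)
  if (!is_count(patch_size)) stop_field("patch_size", "must be a count >= 1")
  if (!is_count(depth)) stop_field("depth", "must be a count >= 1")
  if (!is_count(n_heads)) stop_field("n_heads", "must be a count >= 1")
  if (!is_count(embed_dim)) stop_field("embed_dim", "must be a count >= 1")
  if (embed_dim %% n_heads != 0) {
    stop_field("embed_dim", "must be divisible by n_heads")
  }
  if (!is_count(window_size)) stop_field("window_size", "must be a count >= 1")
  if (!is_count(conv_kernel) || conv_kernel %% 2 != 1) {
    stop_field("conv_kernel", "must be an odd count")
  }
  if (conv_stride != 1) stop_field("conv_stride", "must be 1")
  if (!is_number(mlp_ratio) || mlp_ratio <= 0) {
    stop_field("mlp_ratio", "must be > 0")
  }
  if (!is_count(image_size, 2)) stop_field("image_size", "must be a count >= 2")
  structure(list(patch_size = as.integer(patch_size),
                 depth = as.integer(depth), n_heads = as.integer(n_heads),
                 embed_dim = as.integer(embed_dim), variant = variant,
                 window_size = as.integer(window_size),
                 conv_kernel = as.integer(conv_kernel), conv_stride = 1L,
                 mlp_ratio = mlp_ratio, image_size = as.integer(image_size),
                 use_conv = isTRUE(use_conv)),
            class = "vit_config")
}

max_patch_grid <- function(config) {
  as.integer(ceiling(config$image_size / config$patch_size))
}

#' Split an image into non-overlapping patch vectors
#'
#' Zero-pads symmetrically to the next multiple of `patch_size`, then
#' flattens each patch (column-major patch grid, column-major within patch).
#' The returned padding record makes [unpatchify()] an exact inverse.
#'
#' @param image Numeric matrix.
#' @param patch_size Patch side in pixels.
#' @return List with `patches` (`n_patches x patch_size^2`), `grid`
#'   (patch-grid rows/cols), `pad` (top/left), `size` (original dims).
#' @export
patchify <- function(image, patch_size) {
  h <- nrow(image); w <- ncol(image)
  stopifnot(h >= 1, w >= 1)
  hp <- as.integer(ceiling(h / patch_size) * patch_size)
  wp <- as.integer(ceiling(w / patch_size) * patch_size)
  top <- (hp - h) %/% 2L; left <- (wp - w) %/% 2L
  padded <- matrix(0, hp, wp)
  padded[top + seq_len(h), left + seq_len(w)] <- image
  gr <- hp %/% patch_size; gc <- wp %/% patch_size
  # reshape: dims (ps, gr, ps, gc) -> patch index (gr, gc) x pixel (ps, ps)
  arr <- array(padded, dim = c(patch_size, gr, patch_size, gc))
  patches <- matrix(aperm(arr, c(2, 4, 1, 3)), gr * gc, patch_size^2)
  list(patches = patches, grid = c(gr, gc), pad = c(top, left),
       size = c(h, w), patch_size = as.integer(patch_size))
}

#' Reassemble an image from patch vectors
#'
#' Exact inverse of [patchify()] given its record.
#'
#' @param patches `n_patches x patch_size^2` matrix.
#' @param record The list returned by [patchify()] (grid, pad, size).
#' @return Numeric matrix of the original size.
#' @export
unpatchify <- function(patches, record) {
  ps <- record$patch_size
  gr <- record$grid[1]; gc <- record$grid[2]
  arr <- array(patches, dim = c(gr, gc, ps, ps))
  padded <- matrix(aperm(arr, c(3, 1, 4, 2)), gr * ps, gc * ps)
  padded[record$pad[1] + seq_len(record$size[1]),
         record$pad[2] + seq_len(record$size[2]), drop = FALSE]
}

#' Initialize network weights
#'
#' Truncated-normal-style (sd 0.02) linear weights, zero biases, unit
#' layer-norm gains, and a delta-initialized (identity-passing) trailing
#' convolution.
#'
#' @param config A [vit_config()].
#' @param rng_seed Integer seed.
#' @return A `vit_weights` nested list.
#' @export
vit_init_weights <- function(config, rng_seed = 1L) {
  D <- config$embed_dim
  ps2 <- config$patch_size^2
  M <- as.integer(round(config$mlp_ratio * D))
  gmax <- max_patch_grid(config)
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  w <- with_seed(rng_seed, {
    layers <- lapply(seq_len(config$depth), function(l) {
      list(ln1 = list(g = rep(1, D), b = rep(0, D)),
           attn = list(Wq = rmat(D, D), bq = rep(0, D),
                       Wk = rmat(D, D), bk = rep(0, D),
                       Wv = rmat(D, D), bv = rep(0, D),
                       Wo = rmat(D, D), bo = rep(0, D)),
           ln2 = list(g = rep(1, D), b = rep(0, D)),
           mlp = list(W1 = rmat(D, M), b1 = rep(0, M),
                      W2 = rmat(M, D), b2 = rep(0, D)))
    })
    conv <- NULL
    if (config$use_conv) {
      k <- matrix(0, config$conv_kernel, config$conv_kernel)
      k[(config$conv_kernel + 1) / 2, (config$conv_kernel + 1) / 2] <- 1
      conv <- list(k = k, b = 0)
    }
    list(embed = list(W = rmat(ps2, D), b = rep(0, D)),
         pos = rmat(gmax * gmax, D),
         layers = layers,
         ln_f = list(g = rep(1, D), b = rep(0, D)),
         head = list(W = rmat(D, ps2), b = rep(0, ps2)),
         conv = conv)
  })
  structure(w, class = "vit_weights", config = config)
}

#' Count learnable parameters
#'
#' @param config A [vit_config()].
#' @param image_size Image side in pixels (sizes the position table
#'   actually used; defaults to the configured maximum).
#' @return Integer parameter count.
#' @export
count_parameters <- function(config, image_size = config$image_size) {
  D <- config$embed_dim
  ps2 <- config$patch_size^2
  M <- as.integer(round(config$mlp_ratio * D))
  g <- as.integer(ceiling(image_size / config$patch_size))
  per_layer <- 2 * D + 4 * (D * D + D) + 2 * D + (D * M + M) + (M * D + D)
  total <- (ps2 * D + D) + g * g * D + config$depth * per_layer +
    2 * D + (D * ps2 + ps2)
  if (config$use_conv) total <- total + config$conv_kernel^2 + 1
  as.integer(total)
}

layer_norm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  P <- nrow(X)
  list(out = xhat * matrix(g, P, length(g), byrow = TRUE) +
         matrix(b, P, length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Window partition of the patch grid: list of integer index vectors, one per
# attention group. MHSA: one global group. WBSA: w x w windows of the
# (cyclically shifted) grid; alternating layers shift by floor(w/2).
attention_groups <- function(config, grid, layer) {
  gr <- grid[1]; gc <- grid[2]
  P <- gr * gc
  if (config$variant == "MHSA") return(list(seq_len(P)))
  w <- config$window_size
  if (w >= gr && w >= gc) return(list(seq_len(P)))
  s <- if (layer %% 2 == 0) w %/% 2L else 0L
  Pidx <- matrix(seq_len(P), gr, gc)
  ri <- ((seq_len(gr) - 1 + s) %% gr) + 1
  ci <- ((seq_len(gc) - 1 + s) %% gc) + 1
  rolled <- Pidx[ri, ci, drop = FALSE]
  wid_r <- ceiling(seq_len(gr) / w)
  wid_c <- ceiling(seq_len(gc) / w)
  wid <- outer(wid_r, wid_c, function(a, b) a + b * 10000)
  unname(split(as.vector(rolled), as.vector(wid)))
}

# Core forward pass. Returns the output image and, when cache = TRUE, all
# intermediates needed by the backward pass.
vit_forward_core <- function(image, config, weights, cache = FALSE) {
  ps <- config$patch_size
  D <- config$embed_dim
  H <- config$n_heads
  dh <- D %/% H
  rec <- patchify(image, ps)
  P <- nrow(rec$patches)
  gmax <- max_patch_grid(config)
  if (any(rec$grid > gmax)) {
    stop(sprintf(
      "image %dx%d exceeds the configured maximum image size %d",
      nrow(image), ncol(image), config$image_size), call. = FALSE)
  }
  # crop the position table to the current patch grid (column-major)
  pos_idx <- as.vector(outer(seq_len(rec$grid[1]),
                             (seq_len(rec$grid[2]) - 1) * gmax, `+`))
  E <- rec$patches %*% weights$embed$W +
    matrix(weights$embed$b, P, D, byrow = TRUE)
  X <- E + weights$pos[pos_idx, , drop = FALSE]
  L <- vector("list", config$depth)
  for (l in seq_len(config$depth)) {
    lw <- weights$layers[[l]]
    groups <- attention_groups(config, rec$grid, l)
    ln1 <- layer_norm_fwd(X, lw$ln1$g, lw$ln1$b)
    Y <- ln1$out
    Q <- Y %*% lw$attn$Wq + matrix(lw$attn$bq, P, D, byrow = TRUE)
    K <- Y %*% lw$attn$Wk + matrix(lw$attn$bk, P, D, byrow = TRUE)
    V <- Y %*% lw$attn$Wv + matrix(lw$attn$bv, P, D, byrow = TRUE)
    O <- matrix(0, P, D)
    A_list <- if (cache) vector("list", length(groups)) else NULL
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      Ah <- if (cache) vector("list", H) else NULL
      for (h in seq_len(H)) {
        ix <- (h - 1) * dh + seq_len(dh)
        S <- tcrossprod(Q[g, ix, drop = FALSE],
                        K[g, ix, drop = FALSE]) / sqrt(dh)
        A <- softmax_rows(S)
        O[g, ix] <- A %*% V[g, ix, drop = FALSE]
        if (cache) Ah[[h]] <- A
      }
      if (cache) A_list[[gi]] <- Ah
    }
    attn_out <- O %*% lw$attn$Wo + matrix(lw$attn$bo, P, D, byrow = TRUE)
    X1 <- X + attn_out
    ln2 <- layer_norm_fwd(X1, lw$ln2$g, lw$ln2$b)
    Z <- ln2$out
    M1 <- Z %*% lw$mlp$W1 + matrix(lw$mlp$b1, P, ncol(lw$mlp$W1), byrow = TRUE)
    H1 <- gelu(M1)
    M2 <- H1 %*% lw$mlp$W2 + matrix(lw$mlp$b2, P, D, byrow = TRUE)
    X2 <- X1 + M2
    if (cache) {
      L[[l]] <- list(Xin = X, ln1 = ln1, Y = Y, Q = Q, K = K, V = V, O = O,
                     groups = groups, A = A_list, X1 = X1, ln2 = ln2, Z = Z,
                     M1 = M1, H1 = H1)
    }
    X <- X2
  }
  lnf <- layer_norm_fwd(X, weights$ln_f$g, weights$ln_f$b)
  Fh <- lnf$out
  R <- Fh %*% weights$head$W +
    matrix(weights$head$b, P, ps * ps, byrow = TRUE)
  pre_conv <- unpatchify(R, rec)
  out <- pre_conv
  conv_pad <- NULL
  if (config$use_conv && !is.null(weights$conv)) {
    cv <- conv2d_fwd(pre_conv, weights$conv$k, weights$conv$b)
    out <- cv$out
    conv_pad <- cv
  }
  if (!cache) return(out)
  list(out = out, rec = rec, pos_idx = pos_idx, X_final = X, lnf = lnf,
       Fh = Fh, R = R, pre_conv = pre_conv, conv = conv_pad, layers = L)
}

# Dimension-preserving single-channel convolution with zero padding.
conv2d_fwd <- function(img, k, bias) {
  kk <- nrow(k)
  r <- (kk - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  padded <- matrix(0, h + 2 * r, w + 2 * r)
  padded[r + seq_len(h), r + seq_len(w)] <- img
  out <- matrix(bias, h, w)
  for (a in seq_len(kk)) for (b in seq_len(kk)) {
    out <- out + k[a, b] * padded[(a - 1) + seq_len(h), (b - 1) + seq_len(w)]
  }
  list(out = out, padded = padded, r = r)
}

#' Refine an image with the vision transformer
#'
#' Full forward pass: patch embedding with learned position embeddings (no
#' classification token), `depth` pre-norm encoder layers (attention + MLP,
#' residual connections), a final layer norm, a per-patch linear
#' reconstruction head, exact unpadding, and (optionally) the trailing
#' convolution. Deterministic given weights.
#'
#' @param image Numeric matrix (magnitude image, typically scaled to
#'   `[0, 1]`) or `image_grid`.
#' @param config A [vit_config()].
#' @param weights Matching [vit_init_weights()] / trained weights.
#' @return An `image_grid` with provenance `"refined"`, same shape as the
#'   input.
#' @export
vit_forward <- function(image, config, weights) {
  check_weight_shapes(config, weights)
  out <- vit_forward_core(as_plain_matrix(image), config, weights,
                          cache = FALSE)
  image_grid(pmax(out, 0), pixel_spacing = attr(image, "pixel_spacing") %||%
               NA_real_, provenance = "refined")
}

check_weight_shapes <- function(config, weights) {
  D <- config$embed_dim
  ps2 <- config$patch_size^2
  if (!all(dim(weights$embed$W) == c(ps2, D)) ||
      length(weights$layers) != config$depth ||
      !all(dim(weights$head$W) == c(D, ps2))) {
    stop("weights do not match the configuration (shape mismatch)",
         call. = FALSE)
  }
  if (config$use_conv && is.null(weights$conv)) {
    stop("configuration requires the trailing conv but weights lack it",
         call. = FALSE)
  }
  invisible(TRUE)
}
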