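# Kaiser-Bessel gridding NUFFT (type-2 forward / type-1 adjoint) and the
# explicit-DFT oracle. Conventions: image pixels live at centered integer
# coordinates x in {-N/2, ..., N/2-1}; non-uniform frequencies nu are in
# cycles/pixel on [-0.5, 0.5); the oversampled grid has G = N + 2*ceil((os-1)N/2)
# cells and grid coordinates p = nu * G. Spreading wraps indices mod G, which
# is exact for the periodic discrete spectrum.

kb_beta <- function(width, os) {
  # Beatty et al. aliasing-optimal shape parameter.
  pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)
}

kb_kernel <- function(u, width, beta) {
  t <- 1 - (2 * u / width)^2
  out <- array(0, dim = dim(u) %||% length(u))
  ok <- t > 0
  out[ok] <- besselI(beta * sqrt(t[ok]), 0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Continuous Fourier transform of the KB kernel, evaluated at frequency f
# (pixels^-1 relative to the oversampled grid): the deapodization function.
kb_ft <- function(f, width, beta) {
  t <- beta^2 - (pi * width * f)^2
  out <- numeric(length(t))
  pos <- t > 1e-12
  neg <- t < -1e-12
  mid <- !pos & !neg
  out[pos] <- sinh(sqrt(t[pos])) / sqrt(t[pos])
  out[neg] <- sin(sqrt(-t[neg])) / sqrt(-t[neg])
  out[mid] <- 1
  width * out / besselI(0, 0)  # besselI(0,0)=1; keep explicit unit scale
}

# Plan holding everything reusable for a fixed (trajectory, grid) pair.
nufft_plan <- function(nx, ny, grid_size, os = 1.5, width = 6) {
  N <- as.integer(grid_size)
  stopifnot(N %% 2 == 0, width %% 2 == 0)
  G <- N + 2L * as.integer(ceiling((os - 1) * N / 2))
  beta <- kb_beta(width, G / N)
  px <- nx * G
  py <- ny * G
  offs <- seq_len(width) - (width / 2)   # e.g. -1,0,1,2 for width 4
  mk_idx <- function(p) {
    m0 <- floor(p)
    m <- outer(m0, offs, `+`)                   # n x width integer freqs
    w <- kb_kernel(p - m, width, beta)          # kernel weights
    idx <- ((m + G / 2) %% G) + 1               # 1-based centered array index
    list(idx = idx, w = w)
  }
  ix <- mk_idx(px); iy <- mk_idx(py)
  xs <- centered_coords(N)
  dea <- outer(kb_ft(xs / G, width, beta), kb_ft(xs / G, width, beta))
  emb <- (G - N) / 2 + seq_len(N)
  # flatten the width^2 neighbor stencil: linear grid indices and kernel
  # weight products, n_samples x width^2, so forward/adjoint are single
  # vectorized gathers/scatters
  n <- length(nx)
  lin <- matrix(0L, n, width * width)
  wprod <- matrix(0, n, width * width)
  k <- 0L
  for (a in seq_len(width)) for (b in seq_len(width)) {
    k <- k + 1L
    lin[, k] <- ix$idx[, a] + (iy$idx[, b] - 1L) * G
    wprod[, k] <- ix$w[, a] * iy$w[, b]
  }
  list(N = N, G = G, width = width, beta = beta,
       lin = lin, wprod = wprod, dea = dea, emb = emb, n_samples = n)
}

# Forward (type-2): image (N x N, possibly complex) -> samples at (nx, ny).
nufft_forward <- function(plan, img) {
  padded <- matrix(0 + 0i, plan$G, plan$G)
  padded[plan$emb, plan$emb] <- img / plan$dea
  Fg <- fft2c(padded)
  vals <- matrix(Fg[plan$lin], plan$n_samples) * plan$wprod
  rowSums(vals)
}

# Adjoint (type-1): weighted samples -> N x N image; exact transpose of
# nufft_forward (same kernel, conjugate FFT), so the inner-product identity
# holds to rounding error.
nufft_adjoint <- function(plan, samples, weights = NULL) {
  G <- plan$G; W <- plan$width
  v <- if (is.null(weights)) samples else samples * weights
  vv <- as.vector(v * plan$wprod)          # recycles v down columns
  li <- as.vector(plan$lin)
  sr <- rowsum(cbind(Re(vv), Im(vv)), li)
  at <- as.integer(rownames(sr))
  acc_re <- numeric(G * G); acc_im <- numeric(G * G)
  acc_re[at] <- sr[, 1]; acc_im[at] <- sr[, 2]
  grid <- matrix(complex(real = acc_re, imaginary = acc_im), G, G)
  full <- ifft2c_adj(grid)
  full[plan$emb, plan$emb] / plan$dea
}

# Explicit-DFT oracle operators (small grids only).
dft_matrices <- function(nx, ny, grid_size) {
  xs <- centered_coords(grid_size)
  list(Ex = exp(-2i * pi * outer(nx, xs)),
       Ey = exp(-2i * pi * outer(ny, xs)))
}

dft_forward <- function(mats, img) {
  rowSums((mats$Ex %*% img) * mats$Ey)
}

dft_adjoint <- function(mats, samples, weights = NULL) {
  v <- if (is.null(weights)) samples else samples * weights
  t(Conj(mats$Ex)) %*% (v * Conj(mats$Ey))
}

# Shared entry point: build the engine for a trajectory + grid.
make_engine <- function(traj, grid_size, pixel_spacing = NULL,
                        engine = c("nufft", "exact_dft")) {
  engine <- match.arg(engine)
  if (is.null(pixel_spacing)) pixel_spacing <- 1 / (2 * traj$params$kmax)
  # No band check: the discrete spectrum is 1-periodic in cycles/pixel, and
  # both engines (complex exponentials / mod-G index wrap) treat frequencies
  # beyond the Nyquist band exactly as their aliases, so corner-covering
  # acquisitions (|nu| up to 0.5*sqrt(2)) are valid.
  nc <- normalized_coords(traj, pixel_spacing)
  if (engine == "nufft") {
    plan <- nufft_plan(nc$nx, nc$ny, grid_size)
    list(engine = engine, pixel_spacing = pixel_spacing,
         forward = function(img) nufft_forward(plan, img),
         adjoint = function(s, w = NULL) nufft_adjoint(plan, s, w))
  } else {
    mats <- dft_matrices(nc$nx, nc$ny, grid_size)
    list(engine = engine, pixel_spacing = pixel_spacing,
         forward = function(img) dft_forward(mats, img),
         adjoint = function(s, w = NULL) dft_adjoint(mats, s, w))
  }
}
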