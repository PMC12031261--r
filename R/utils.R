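# Internal numerical helpers shared across modules.

# Quadrant swap for even-sized matrices. For even dimensions fftshift and
# ifftshift coincide, so a single helper suffices; even sizes are enforced
# at grid construction.
fftshift2 <- function(m) {
  g1 <- nrow(m); g2 <- ncol(m)
  stopifnot(g1 %% 2 == 0, g2 %% 2 == 0)
  m[c((g1 / 2 + 1):g1, 1:(g1 / 2)), c((g2 / 2 + 1):g2, 1:(g2 / 2)), drop = FALSE]
}

# Centered 2D DFT: F(m) = sum_x f(x) exp(-2*pi*i*m.x/G) with pixel and
# frequency indices both centered (DC at index G/2+1, 1-based).
fft2c <- function(x) fftshift2(stats::fft(fftshift2(x)))

# Unnormalized adjoint (= conjugate transpose) of fft2c.
ifft2c_adj <- function(x) fftshift2(stats::fft(fftshift2(x), inverse = TRUE))

# Centered pixel coordinates for an even grid of size n: -n/2 .. n/2-1.
centered_coords <- function(n) seq_len(n) - 1 - n / 2

is_count <- function(x, min = 1L) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

stop_field <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

# Evaluate a function under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child RNG seed from a master seed and a stream index, staying
# within 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000003 + as.double(stream)) %%
               .Machine$integer.max)
}

# Bilinear resampling of a matrix at (possibly fractional) row/col positions.
# Positions outside [1, nrow]x[1, ncol] evaluate to `fill`.
bilinear_sample <- function(img, rows, cols, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0;   fc <- cols - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out <- numeric(length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out[!ok] <- fill
    out
  }
  v00 <- val(r0, c0); v01 <- val(r0, c0 + 1)
  v10 <- val(r0 + 1, c0); v11 <- val(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Resize a matrix to out_h x out_w by bilinear interpolation (align centers).
bilinear_resize <- function(img, out_h, out_w, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  rr <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  cc <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  grid <- expand.grid(r = rr, c = cc)
  matrix(bilinear_sample(img, grid$r, grid$c, fill = fill), out_h, out_w)
}

# Root-mean-square relative error helper used in tests and diagnostics.
rel_err <- function(x, ref) {
  sqrt(sum(Mod(x - ref)^2)) / sqrt(sum(Mod(ref)^2))
}
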