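#' Adjoint (gridding/IFFT) reconstruction per coil
#'
#' Phase-1 reconstruction: per coil,
#' \eqn{image(r) = \sum_j w_j S(k_j) e^{+2\pi i k_j \cdot r}}, with
#' `w = dcf` when density compensation is requested and 1 otherwise,
#' realized either exactly (oracle) or by Kaiser-Bessel gridding onto an
#' oversampled Cartesian grid, inverse FFT, and deapodization.
#'
#' @param kdata A [kspace_data()].
#' @param use_dcf Apply the trajectory's density compensation weights
#'   (default `TRUE`; requires [compute_dcf()] to have been run).
#' @param engine `"nufft"` or `"exact_dft"`.
#' @return A `coil_images` object (complex array `n_coils x H x W`).
#' @export
adjoint_recon <- function(kdata, use_dcf = TRUE,
                          engine = c("nufft", "exact_dft")) {
  engine <- match.arg(engine)
  stopifnot(inherits(kdata, "kspace_data"))
  w <- NULL
  if (use_dcf) {
    if (is.null(kdata$traj$dcf)) {
      stop("use_dcf = TRUE but the trajectory has no dcf; run compute_dcf()",
           call. = FALSE)
    }
    w <- kdata$traj$dcf
  }
  n <- kdata$grid_size
  eng <- make_engine(kdata$traj, n, kdata$pixel_spacing, engine)
  nc <- nrow(kdata$samples)
  imgs <- array(0i, dim = c(nc, n, n))
  for (c in seq_len(nc)) {
    imgs[c, , ] <- eng$adjoint(kdata$samples[c, ], w)
  }
  structure(list(images = imgs, n_coils = nc, grid_size = n,
                 pixel_spacing = kdata$pixel_spacing),
            class = "coil_images")
}

#' Root-sum-of-squares coil combination
#'
#' Pixelwise \eqn{\sqrt{\sum_c |image_c|^2}}; invariant to per-coil global
#' phase.
#'
#' @param coil_images A `coil_images` from [adjoint_recon()].
#' @return An `image_grid` with provenance `"rough"`.
#' @export
rss_combine <- function(coil_images) {
  stopifnot(inherits(coil_images, "coil_images"))
  rss <- sqrt(apply(Mod(coil_images$images)^2, c(2, 3), sum))
  image_grid(rss, pixel_spacing = coil_images$pixel_spacing,
             provenance = "rough")
}

#' Iterative SENSE reconstruction (conjugate residual)
#'
#' Solves the regularized normal equations
#' \eqn{(A^H W A + \lambda I) x = A^H W b} by the conjugate residual
#' variant of the conjugate-gradient family, where `A` stacks coil-weighted
#' forward transforms (`A_c x = F(map_c x)`) and `W` is the optional
#' density-compensation preconditioner. Conjugate residual minimizes the
#' normal-equation residual norm over the Krylov space at each step, so the
#' logged residual is non-increasing by construction. This is the package's
#' reference reconstructor, standing in for an l1-regularized
#' parallel-imaging solver; l2 regularization only.
#'
#' @param kdata A [kspace_data()].
#' @param maps Coil maps matching the grid.
#' @param l2_reg Tikhonov weight lambda (>= 0).
#' @param max_iters Maximum CG iterations.
#' @param tol Relative residual tolerance for early stopping.
#' @param use_dcf Use the trajectory dcf as preconditioning weights.
#' @param engine `"nufft"` or `"exact_dft"`.
#' @return An `image_grid` (magnitude of the solution, provenance
#'   `"reference"`) with attributes `cg_log` (data.frame of iteration,
#'   normal-equation residual norm) and `converged`.
#' @export
cg_sense <- function(kdata, maps, l2_reg = 0, max_iters = 30, tol = 1e-6,
                     use_dcf = TRUE, engine = c("nufft", "exact_dft")) {
  engine <- match.arg(engine)
  stopifnot(inherits(kdata, "kspace_data"), inherits(maps, "coil_maps"))
  if (max_iters < 1) stop_field("max_iters", "must be >= 1")
  n <- kdata$grid_size
  if (maps$grid_size != n) stop("coil maps do not cover the grid", call. = FALSE)
  eng <- make_engine(kdata$traj, n, kdata$pixel_spacing, engine)
  w <- if (use_dcf && !is.null(kdata$traj$dcf)) kdata$traj$dcf else NULL
  nc <- maps$n_coils
  AHW <- function(smat) {
    out <- matrix(0i, n, n)
    for (c in seq_len(nc)) {
      out <- out + Conj(maps$maps[c, , ]) * eng$adjoint(smat[c, ], w)
    }
    out
  }
  AHA <- function(x) {
    out <- matrix(0i, n, n)
    for (c in seq_len(nc)) {
      s <- eng$forward(maps$maps[c, , ] * x)
      out <- out + Conj(maps$maps[c, , ]) * eng$adjoint(s, w)
    }
    out + l2_reg * x
  }
  b <- AHW(kdata$samples)
  x <- matrix(0i, n, n)
  r <- b
  rs0 <- sum(Mod(r)^2)
  if (rs0 == 0) {
    out <- image_grid(Mod(x), pixel_spacing = kdata$pixel_spacing,
                      provenance = "reference")
    attr(out, "cg_log") <- data.frame(iteration = integer(0),
                                      residual = numeric(0))
    attr(out, "converged") <- TRUE
    return(out)
  }
  log_res <- numeric(0)
  converged <- FALSE
  Mr <- AHA(r)
  p <- r
  Mp <- Mr
  rMr <- Re(sum(Conj(r) * Mr))
  rs <- rs0
  for (it in seq_len(max_iters)) {
    alpha <- rMr / Re(sum(Conj(Mp) * Mp))
    x <- x + alpha * p
    r <- r - alpha * Mp
    rs <- sum(Mod(r)^2)
    log_res <- c(log_res, sqrt(rs))
    if (sqrt(rs / rs0) < tol) {
      converged <- TRUE
      break
    }
    Mr <- AHA(r)
    rMr_new <- Re(sum(Conj(r) * Mr))
    beta <- rMr_new / rMr
    rMr <- rMr_new
    p <- r + beta * p
    Mp <- Mr + beta * Mp
  }
  if (!converged && max_iters > 1) {
    warning(sprintf("cg_sense: not converged within %d iterations (rel res %.3g)",
                    max_iters, sqrt(rs / rs0)), call. = FALSE)
  }
  out <- image_grid(Mod(x), pixel_spacing = kdata$pixel_spacing,
                    provenance = "reference")
  attr(out, "cg_log") <- data.frame(iteration = seq_along(log_res),
                                    residual = log_res)
  attr(out, "converged") <- converged
  out
}

# Density-weighted SENSE adjoint A^H W b (the right-hand side of the
# normal equations); used in the large-lambda limit check.
sense_adjoint_dcf <- function(kdata, maps, engine = "nufft") {
  n <- kdata$grid_size
  eng <- make_engine(kdata$traj, n, kdata$pixel_spacing, engine)
  w <- kdata$traj$dcf
  out <- matrix(0i, n, n)
  for (c in seq_len(maps$n_coils)) {
    out <- out + Conj(maps$maps[c, , ]) * eng$adjoint(kdata$samples[c, ], w)
  }
  out
}

# SENSE adjoint used in tests of the inner-product identity:
# A^H y = sum_c conj(map_c) * adjoint(y_c) (no dcf weighting).
sense_adjoint <- function(kdata, maps, engine = "nufft") {
  n <- kdata$grid_size
  eng <- make_engine(kdata$traj, n, kdata$pixel_spacing, engine)
  out <- matrix(0i, n, n)
  for (c in seq_len(maps$n_coils)) {
    out <- out + Conj(maps$maps[c, , ]) * eng$adjoint(kdata$samples[c, ])
  }
  out
}
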