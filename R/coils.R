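#' Simulated complex coil sensitivity maps
#'
#' Emulates a receive array: each coil is a smooth Gaussian magnitude lobe
#' centered on a point just outside the field-of-view perimeter, with a
#' smooth low-order phase (linear ramp towards the coil plus a small
#' seeded quadratic term). Optionally normalized so the root-sum-of-squares
#' across coils is exactly 1 on the support.
#'
#' @param n_coils Number of receive channels (>= 1).
#' @param grid_size Image size in pixels.
#' @param rng_seed Seed for the small random perturbations of lobe width,
#'   center and phase; identical seeds give identical maps.
#' @param normalize If `TRUE`, divide by the RSS wherever it exceeds
#'   `1e-6` of its maximum so that `sum_c |map_c|^2 = 1` on the support.
#' @return A `coil_maps` object: list with `maps` (complex array
#'   `n_coils x H x W`) and `n_coils`.
#' @export
make_coil_maps <- function(n_coils, grid_size, rng_seed = 1L,
                           normalize = TRUE) {
  if (!is_count(n_coils)) stop_field("n_coils", "must be a count >= 1")
  n <- as.integer(grid_size)
  xs <- (centered_coords(n) + 0.5) / (n / 2)
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  maps <- array(0i, dim = c(n_coils, n, n))
  pars <- with_seed(rng_seed, {
    data.frame(jit_ang = runif(n_coils, -0.15, 0.15),
               sigma = runif(n_coils, 0.55, 0.75),
               phase_a = runif(n_coils, -0.5, 0.5),
               phase_b = runif(n_coils, -0.5, 0.5))
  })
  for (c in seq_len(n_coils)) {
    ang <- 2 * pi * (c - 1) / n_coils + pars$jit_ang[c]
    cx <- 1.15 * cos(ang); cy <- 1.15 * sin(ang)
    d2 <- (X - cx)^2 + (Y - cy)^2
    mag <- exp(-d2 / (2 * pars$sigma[c]^2))
    # linear phase towards the coil plus a mild seeded quadratic
    ph <- pi * (X * cos(ang) + Y * sin(ang)) +
      pars$phase_a[c] * X^2 + pars$phase_b[c] * Y^2
    maps[c, , ] <- mag * exp(1i * ph)
  }
  if (normalize) {
    rss <- sqrt(apply(Mod(maps)^2, c(2, 3), sum))
    support <- rss > 1e-6 * max(rss)
    for (c in seq_len(n_coils)) {
      m <- maps[c, , ]
      m[support] <- m[support] / rss[support]
      maps[c, , ] <- m
    }
  }
  structure(list(maps = maps, n_coils = as.integer(n_coils),
                 grid_size = n, rng_seed = as.integer(rng_seed),
                 normalized = normalize),
            class = "coil_maps")
}

#' @export
print.coil_maps <- function(x, ...) {
  cat(sprintf("coil_maps: %d coils, %dx%d, %snormalized\n", x$n_coils,
              x$grid_size, x$grid_size, if (x$normalized) "RSS-" else "un"))
  invisible(x)
}
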