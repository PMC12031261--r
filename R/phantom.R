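#' Phantom specification
#'
#' Describes a piecewise-constant 2D phantom as a sum of ellipses on the
#' `[-1, 1]^2` square, in the tradition of the Shepp-Logan head phantom.
#' Intensities may be negative per ellipse but must be non-negative after
#' summation.
#'
#' @param ellipses Matrix or data.frame with columns
#'   `cx, cy, a, b, angle, intensity` (centers and semi-axes in `[-1,1]`
#'   units, angle in degrees counter-clockwise).
#' @param grid_size Image size in pixels (even, >= 16).
#' @param rng_seed Seed recorded with the spec (used by [random_phantom_spec()]).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(ellipses, grid_size = 64, rng_seed = 0L) {
  if (!is_count(grid_size, 16) || grid_size %% 2 != 0) {
    stop_field("grid_size", "must be an even count >= 16")
  }
  e <- as.data.frame(ellipses)
  if (nrow(e) > 0) {
    names(e) <- c("cx", "cy", "a", "b", "angle", "intensity")[seq_len(ncol(e))]
    if (any(abs(e$cx) > 1 | abs(e$cy) > 1)) {
      stop_field("ellipses", "centers must lie within the unit square")
    }
    if (any(e$a <= 0 | e$b <= 0)) {
      stop_field("ellipses", "semi-axes must be positive")
    }
  }
  structure(list(ellipses = e, grid_size = as.integer(grid_size),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Modified Shepp-Logan ellipse set (high-contrast variant).
shepp_logan_ellipses <- function() {
  data.frame(
    cx = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    cy = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.605, -0.605),
    a = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    angle = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0),
    intensity = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  )
}

#' Brain-like default phantom specification
#'
#' @param grid_size Image size in pixels.
#' @return A `phantom_spec` with the modified Shepp-Logan ellipse set.
#' @export
shepp_logan_spec <- function(grid_size = 64) {
  phantom_spec(shepp_logan_ellipses(), grid_size)
}

#' Randomized phantom specification
#'
#' A head-like outer ellipse plus `n_inner` random interior ellipses with
#' signed intensities (clipped to non-negative at rasterization), giving a
#' family of piecewise-smooth magnitude images for training and evaluation.
#'
#' @param grid_size Image size in pixels.
#' @param rng_seed Integer seed; the spec is fully determined by it.
#' @param n_inner Number of interior ellipses.
#' @return A `phantom_spec`.
#' @export
random_phantom_spec <- function(grid_size = 64, rng_seed = 1L, n_inner = 6L) {
  ell <- with_seed(rng_seed, {
    outer_a <- runif(1, 0.6, 0.8)
    outer_b <- runif(1, 0.75, 0.92)
    inner <- data.frame(
      cx = runif(n_inner, -0.4, 0.4),
      cy = runif(n_inner, -0.5, 0.5),
      a = runif(n_inner, 0.05, 0.35),
      b = runif(n_inner, 0.05, 0.35),
      angle = runif(n_inner, -90, 90),
      intensity = runif(n_inner, -0.4, 0.5)
    )
    rbind(data.frame(cx = 0, cy = 0, a = outer_a, b = outer_b,
                     angle = runif(1, -20, 20), intensity = 1),
          inner)
  })
  phantom_spec(ell, grid_size, rng_seed)
}

#' Rasterize a phantom
#'
#' Renders the ellipse sum on the pixel grid, clips at zero, and rescales to
#' `[0, 1]`. Deterministic given the spec.
#'
#' @param spec A [phantom_spec()].
#' @return An `image_grid` (real non-negative matrix with attributes
#'   `pixel_spacing` and `provenance = "phantom"`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  xs <- (centered_coords(n) + 0.5) / (n / 2)   # pixel centers in [-1, 1)
  img <- matrix(0, n, n)
  e <- spec$ellipses
  if (nrow(e) > 0) {
    X <- matrix(xs, n, n)        # row coordinate -> x
    Y <- matrix(xs, n, n, byrow = TRUE)
    for (i in seq_len(nrow(e))) {
      th <- e$angle[i] * pi / 180
      u <- cos(th) * (X - e$cx[i]) + sin(th) * (Y - e$cy[i])
      v <- -sin(th) * (X - e$cx[i]) + cos(th) * (Y - e$cy[i])
      img <- img + e$intensity[i] * ((u / e$a[i])^2 + (v / e$b[i])^2 <= 1)
    }
  }
  img <- pmax(img, 0)
  if (max(img) > 0 && max(img) > 1) img <- img / max(img)
  image_grid(img, provenance = "phantom")
}

#' Image container
#'
#' Light wrapper marking a real non-negative matrix as an image with pixel
#' spacing and provenance.
#'
#' @param pixels Numeric matrix (finite, square for the pipeline).
#' @param pixel_spacing Pixel size in m.
#' @param provenance One of `"phantom"`, `"rough"`, `"reference"`, `"refined"`.
#' @return An `image_grid`.
#' @export
image_grid <- function(pixels, pixel_spacing = NA_real_,
                       provenance = c("phantom", "rough", "reference",
                                      "refined")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  structure(pixels, pixel_spacing = pixel_spacing, provenance = provenance,
            class = c("image_grid", "matrix", "array"))
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid %dx%d (%s), range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "provenance"), min(x), max(x)))
  invisible(x)
}

# Strip image_grid attributes back to a plain matrix.
as_plain_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
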