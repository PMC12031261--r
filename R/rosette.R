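#' Rosette trajectory parameters
#'
#' Bundles the analytic parameters of a 2D rosette k-space trajectory
#' \eqn{k(t) = k_{max} \sin(2\pi w_1 t)\, e^{i 2\pi w_2 t}}: the radial
#' oscillation frequency `w1` sets how fast the readout swings between the
#' k-space origin and the rim, the angular frequency `w2` rotates the lobe,
#' and each petal covers one radial half-period `t in [0, 1/(2 w1))` so it
#' leaves and returns to the origin.
#'
#' @param kmax Maximum spatial frequency in 1/m (defines the resolution).
#' @param w1 Radial oscillation frequency in Hz.
#' @param w2 Angular rotation frequency in Hz (0 allowed: pure radial lobes).
#' @param n_petals Number of petals in the fully sampled trajectory.
#' @param samples_per_petal Readout points per petal (half-open in time, so
#'   sample 1 of every petal sits exactly on the k-space origin). Even counts
#'   place a sample exactly on the `kmax` rim.
#' @param dwell_time Seconds per sample (metadata only; the sampling times are
#'   implied by `w1` and `samples_per_petal`).
#' @param acceleration Positive integer petal-subsampling factor recorded with
#'   the parameters; applied by [subsample_petals()].
#' @param phase_schedule `"uniform"` (default) spaces the per-petal rotation
#'   offsets evenly over `[0, pi)`, emulating a multi-shot acquisition in
#'   which every petal is a separately rotated shot; `"continuous"` rotates
#'   petal p by the angle the carrier `w2` accumulates up to the petal's
#'   start time (`phi_p = pi * w2/w1 * p`), so `w2 = 0` gives collinear
#'   petals but integer `w2/w1` ratios retrace earlier petals.
#' @return An object of class `rosette_params`.
#' @examples
#' p <- rosette_params(kmax = 1000, w1 = 400, w2 = 400, n_petals = 189,
#'                     samples_per_petal = 64, acceleration = 4)
#' @export
rosette_params <- function(kmax = 1000, w1 = 400, w2 = 400, n_petals = 189,
                           samples_per_petal = 128,
                           dwell_time = 1 / (2 * w1 * samples_per_petal),
                           acceleration = 1L,
                           phase_schedule = c("uniform", "continuous")) {
  phase_schedule <- match.arg(phase_schedule)
  if (!is_number(kmax) || kmax <= 0) stop_field("kmax", "must be > 0")
  if (!is_number(w1) || w1 <= 0) stop_field("w1", "must be > 0")
  if (!is_number(w2) || w2 < 0) stop_field("w2", "must be >= 0")
  if (!is_count(n_petals)) stop_field("n_petals", "must be a count >= 1")
  if (!is_count(samples_per_petal, 2)) {
    stop_field("samples_per_petal", "must be a count >= 2")
  }
  if (!is_number(dwell_time) || dwell_time <= 0) {
    stop_field("dwell_time", "must be > 0")
  }
  if (!is_count(acceleration)) stop_field("acceleration", "must be a count >= 1")
  if (acceleration > n_petals) {
    stop_field("acceleration", "must not exceed n_petals")
  }
  structure(list(kmax = kmax, w1 = w1, w2 = w2,
                 n_petals = as.integer(n_petals),
                 samples_per_petal = as.integer(samples_per_petal),
                 dwell_time = dwell_time,
                 acceleration = as.integer(acceleration),
                 phase_schedule = phase_schedule),
            class = "rosette_params")
}

#' Generate a rosette k-space trajectory
#'
#' Samples the analytic rosette curve petal by petal. Petal `p` (0-based) is
#' the signed-radius half-period rotated by its phase offset:
#' \eqn{k_p(t) = k_{max}\sin(2\pi w_1 t)\,e^{i(2\pi w_2 t + \phi_p)}},
#' `t` on the half-open interval `[0, 1/(2 w1))`, so every petal starts at
#' the origin, touches the `kmax` rim (exactly, for even sample counts), and
#' returns towards the origin.
#'
#' @param params A [rosette_params()] object.
#' @return A `rosette_traj` object with fields `kx`, `ky` (1/m, length
#'   `n_petals * samples_per_petal`), `petal` (1-based petal id per sample),
#'   `params`, and `dcf` (`NULL` until [compute_dcf()]).
#' @export
generate_rosette <- function(params) {
  stopifnot(inherits(params, "rosette_params"))
  S <- params$samples_per_petal
  tt <- (seq_len(S) - 1) / S * (1 / (2 * params$w1))
  radius <- params$kmax * sin(2 * pi * params$w1 * tt)
  carrier <- 2 * pi * params$w2 * tt
  p <- seq_len(params$n_petals) - 1
  phi <- switch(params$phase_schedule,
    continuous = pi * params$w2 / params$w1 * p,
    uniform    = pi * p / params$n_petals
  )
  ang <- outer(carrier, phi, `+`)        # S x n_petals
  kx <- as.vector(radius * cos(ang))
  ky <- as.vector(radius * sin(ang))
  structure(list(kx = kx, ky = ky,
                 petal = rep(seq_len(params$n_petals), each = S),
                 params = params, dcf = NULL),
            class = "rosette_traj")
}

#' @export
print.rosette_traj <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "rosette trajectory: %d petals x %d samples (%d total), kmax %.6g 1/m\n",
    length(unique(x$petal)), p$samples_per_petal, length(x$kx), p$kmax))
  cat(sprintf("  w1 %.6g Hz, w2 %.6g Hz, phase schedule '%s', dcf %s\n",
              p$w1, p$w2, p$phase_schedule,
              if (is.null(x$dcf)) "unset" else "set"))
  invisible(x)
}

n_traj_samples <- function(traj) length(traj$kx)

#' Retain a subset of petals (acceleration)
#'
#' Realizes the acquisition's acceleration factor as petal subsampling:
#' `ceiling(n_petals / acceleration)` petals are kept, either at evenly
#' spaced fractional positions (`uniform`) or every `acceleration`-th petal
#' (`stride`).
#'
#' @param traj A `rosette_traj`.
#' @param acceleration Positive integer, at most the petal count.
#' @param scheme Petal selection scheme.
#' @return A `rosette_traj` containing only the retained petals (any `dcf` is
#'   dropped, since density changes).
#' @export
subsample_petals <- function(traj, acceleration,
                             scheme = c("uniform", "stride")) {
  stopifnot(inherits(traj, "rosette_traj"))
  scheme <- match.arg(scheme)
  petals <- unique(traj$petal)
  np <- length(petals)
  if (!is_count(acceleration)) stop_field("acceleration", "must be a count >= 1")
  if (acceleration > np) {
    stop_field("acceleration", sprintf("exceeds petal count (%d)", np))
  }
  nkeep <- ceiling(np / acceleration)
  keep_idx <- switch(scheme,
    stride  = seq(1L, np, by = acceleration),
    uniform = unique(as.integer(floor((seq_len(nkeep) - 1) * np / nkeep)) + 1L)
  )
  keep <- traj$petal %in% petals[keep_idx]
  out <- traj
  out$kx <- traj$kx[keep]; out$ky <- traj$ky[keep]
  out$petal <- traj$petal[keep]
  out$dcf <- NULL
  out
}

#' Build a trajectory from explicit sample coordinates
#'
#' Wraps raw k-space sample coordinates (1/m) in the trajectory container
#' used throughout the package, e.g. when reading a k-space container from
#' disk or constructing toy trajectories in tests.
#'
#' @param kx,ky Sample coordinates in 1/m.
#' @param kmax Nominal maximum spatial frequency; defaults to the largest
#'   sample radius.
#' @param petal Optional per-sample petal id.
#' @param dcf Optional per-sample density weights.
#' @return A `rosette_traj`.
#' @export
manual_trajectory <- function(kx, ky, kmax = NULL, petal = NULL, dcf = NULL) {
  stopifnot(length(kx) == length(ky), all(is.finite(kx)), all(is.finite(ky)))
  r <- sqrt(kx^2 + ky^2)
  if (is.null(kmax)) kmax <- max(r)
  if (max(r) > kmax * (1 + 1e-9)) {
    stop_field("kmax", "samples lie outside the kmax disk")
  }
  if (is.null(petal)) petal <- rep(1L, length(kx))
  params <- list(kmax = kmax, w1 = NA_real_, w2 = NA_real_,
                 n_petals = length(unique(petal)),
                 samples_per_petal = NA_integer_, dwell_time = NA_real_,
                 acceleration = 1L, phase_schedule = "manual")
  class(params) <- "rosette_params"
  structure(list(kx = as.numeric(kx), ky = as.numeric(ky),
                 petal = as.integer(petal), params = params, dcf = dcf),
            class = "rosette_traj")
}

#' Merge coincident trajectory samples
#'
#' Rosette petals all start at the k-space origin, so a multi-petal
#' trajectory carries coincident samples that make Voronoi cells degenerate.
#' This keeps the first of each group of (numerically) coincident points.
#'
#' @param traj A `rosette_traj`.
#' @param digits Significant digits used to detect coincidence.
#' @return The deduplicated trajectory (dcf dropped).
#' @export
dedupe_trajectory <- function(traj, digits = 12) {
  key <- paste(signif(traj$kx, digits), signif(traj$ky, digits))
  keep <- !duplicated(key)
  out <- traj
  out$kx <- traj$kx[keep]; out$ky <- traj$ky[keep]
  out$petal <- traj$petal[keep]; out$dcf <- NULL
  out
}

# Map physical k coordinates (1/m) to normalized frequencies in cycles/pixel.
# Default pixel spacing puts kmax at the Nyquist edge (|nu| = 0.5).
normalized_coords <- function(traj, pixel_spacing = 1 / (2 * traj$params$kmax)) {
  list(nx = traj$kx * pixel_spacing, ny = traj$ky * pixel_spacing,
       pixel_spacing = pixel_spacing)
}
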