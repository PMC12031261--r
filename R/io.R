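# K-space container, checkpoints, and image writers.
#
# The k-space container is a single self-describing binary file: an 8-byte
# magic ("RKSC0001"), a 4-byte little-endian header length, a JSON header
# describing datasets (name, dtype, shape) and scalar attributes, then the
# raw little-endian float64 payload in header order (complex data stored as
# interleaved re/im). The round trip is lossless at full float64 precision.

CONTAINER_MAGIC <- "RKSC0001"

write_dataset <- function(con, x) {
  if (is.complex(x)) {
    v <- as.vector(x)
    writeBin(as.double(rbind(Re(v), Im(v))), con, size = 8,
             endian = "little")
  } else {
    writeBin(as.double(as.vector(x)), con, size = 8, endian = "little")
  }
}

read_dataset <- function(con, dtype, shape) {
  n <- prod(shape)
  if (dtype == "complex128") {
    raw <- readBin(con, "double", n = 2 * n, size = 8, endian = "little")
    v <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  } else {
    v <- readBin(con, "double", n = n, size = 8, endian = "little")
  }
  if (length(shape) > 1) array(v, dim = shape) else v
}

#' Write a k-space container
#'
#' Serializes multi-coil k-space samples, the trajectory, optional density
#' weights and coil maps, plus the acquisition attributes needed to
#' regenerate the simulation, into the package's binary container format.
#'
#' @param kdata A [kspace_data()].
#' @param path Output file path.
#' @param maps Optional [make_coil_maps()] object.
#' @param extra_attrs Named list of additional scalar attributes.
#' @return `path`, invisibly.
#' @export
write_kspace_container <- function(kdata, path, maps = NULL,
                                   extra_attrs = list()) {
  stopifnot(inherits(kdata, "kspace_data"))
  traj <- kdata$traj
  datasets <- list(
    kdata = list(dtype = "complex128", shape = dim(kdata$samples)),
    traj = list(dtype = "float64", shape = c(n_traj_samples(traj), 2L))
  )
  if (!is.null(traj$dcf)) {
    datasets$dcf <- list(dtype = "float64",
                         shape = n_traj_samples(traj))
  }
  if (!is.null(maps)) {
    datasets$maps <- list(dtype = "complex128", shape = dim(maps$maps))
  }
  p <- traj$params
  attrs <- c(list(grid_size = kdata$grid_size,
                  pixel_spacing_m = kdata$pixel_spacing,
                  kmax = p$kmax, w1 = p$w1, w2 = p$w2,
                  n_petals = p$n_petals,
                  acceleration = p$acceleration,
                  noise_variance = kdata$noise_variance),
             extra_attrs)
  header <- jsonlite::toJSON(list(datasets = datasets, attrs = attrs),
                             auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(CONTAINER_MAGIC, con, eos = NULL)
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  write_dataset(con, kdata$samples)
  write_dataset(con, cbind(traj$kx, traj$ky))
  if (!is.null(traj$dcf)) write_dataset(con, as.numeric(traj$dcf))
  if (!is.null(maps)) write_dataset(con, maps$maps)
  invisible(path)
}

#' Read a k-space container
#'
#' Lossless inverse of [write_kspace_container()].
#'
#' @param path Container file path.
#' @return List with `kdata` ([kspace_data()], trajectory rebuilt from the
#'   stored coordinates with any dcf attached), `maps` (or `NULL`), and
#'   `attrs` (named list).
#' @export
read_kspace_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(CONTAINER_MAGIC), useBytes = TRUE)
  if (!identical(magic, CONTAINER_MAGIC)) {
    stop("schema error: not a k-space container (bad magic)", call. = FALSE)
  }
  hlen <- readBin(con, "integer", size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  ds <- header$datasets
  for (req in c("kdata", "traj")) {
    if (is.null(ds[[req]])) {
      stop(sprintf("schema error: container missing mandatory dataset '%s'",
                   req), call. = FALSE)
    }
  }
  data <- list()
  for (nm in names(ds)) {
    data[[nm]] <- read_dataset(con, ds[[nm]]$dtype, ds[[nm]]$shape)
  }
  attrs <- header$attrs
  traj <- manual_trajectory(data$traj[, 1], data$traj[, 2],
                            kmax = attrs$kmax, dcf = data$dcf)
  kdata <- kspace_data(data$kdata, traj, attrs$grid_size,
                       attrs$pixel_spacing_m,
                       noise_variance = attrs$noise_variance)
  maps <- NULL
  if (!is.null(data$maps)) {
    maps <- structure(list(maps = data$maps, n_coils = dim(data$maps)[1],
                           grid_size = dim(data$maps)[2],
                           rng_seed = NA_integer_, normalized = NA),
                      class = "coil_maps")
  }
  list(kdata = kdata, maps = maps, attrs = attrs)
}

#' Save a network checkpoint
#'
#' Single binary file: JSON-encoded configuration and weight-tree shape
#' followed by every parameter as little-endian float64; the round trip is
#' lossless.
#'
#' @param weights `vit_weights` (or the `weights` element of a
#'   [vit_train()] fit).
#' @param config The matching [vit_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(weights, config, path) {
  flat <- tree_flatten(weights)
  header <- jsonlite::toJSON(list(format = "rosette-vit-checkpoint-1",
                                  config = unclass(config),
                                  n_params = length(flat)),
                             auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  writeBin(flat, con, size = 8, endian = "little")
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path Checkpoint path from [save_checkpoint()].
#' @return List with `weights` and `config`.
#' @export
load_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  if (!identical(header$format, "rosette-vit-checkpoint-1")) {
    stop("schema error: not a checkpoint file", call. = FALSE)
  }
  cfgl <- header$config
  config <- vit_config(patch_size = cfgl$patch_size, depth = cfgl$depth,
                       n_heads = cfgl$n_heads, embed_dim = cfgl$embed_dim,
                       variant = cfgl$variant,
                       window_size = cfgl$window_size,
                       conv_kernel = cfgl$conv_kernel,
                       conv_stride = cfgl$conv_stride,
                       mlp_ratio = cfgl$mlp_ratio,
                       image_size = cfgl$image_size,
                       use_conv = cfgl$use_conv)
  flat <- readBin(con, "double", n = header$n_params, size = 8,
                  endian = "little")
  template <- vit_init_weights(config, rng_seed = 0L)
  weights <- tree_unflatten(template, flat)
  list(weights = weights, config = config)
}

#' Write an image as NIfTI-1
#'
#' @param image An `image_grid` (pixel spacing, if known, goes into the
#'   header) or plain matrix.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param pixel_spacing Override spacing in m (stored in mm, the NIfTI
#'   convention).
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(image, path,
                              pixel_spacing = attr(image, "pixel_spacing")) {
  m <- as_plain_matrix(image)
  sp_mm <- if (is.null(pixel_spacing) || is.na(pixel_spacing)) 1 else {
    pixel_spacing * 1000
  }
  img <- RNifti::asNifti(m)
  RNifti::pixdim(img) <- c(sp_mm, sp_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an 8-bit PNG preview
#'
#' Min-max scaled preview for visual inspection only (never used for
#' metrics).
#'
#' @param image Matrix or `image_grid`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  m <- as_plain_matrix(image)
  rng <- range(m)
  if (diff(rng) == 0) m[] <- 0 else m <- (m - rng[1]) / diff(rng)
  png::writePNG(m, path)
  invisible(path)
}
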