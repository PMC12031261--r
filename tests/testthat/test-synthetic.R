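# Phantoms, coil maps, forward model, noise, paired dataset.

test_that("phantom rasterization: empty, binary circle, determinism", {
  expect_true(all(make_phantom(phantom_spec(data.frame()[0, ], 16)) == 0))

  circ <- phantom_spec(data.frame(cx = 0, cy = 0, a = 0.5, b = 0.5,
                                  angle = 0, intensity = 1), 32)
  img <- make_phantom(circ)
  expect_setequal(unique(as.vector(img)), c(0, 1))
  expect_equal(img[16, 16], 1)

  spec <- random_phantom_spec(32, rng_seed = 9)
  expect_identical(make_phantom(spec), make_phantom(spec))
  expect_true(min(make_phantom(spec)) >= 0)
})

test_that("phantom spec validation", {
  expect_error(phantom_spec(data.frame(cx = 2, cy = 0, a = 1, b = 1,
                                       angle = 0, intensity = 1), 32),
               "unit square")
  expect_error(phantom_spec(data.frame(), 8), "grid_size")
})

test_that("coil maps: RSS normalization, reproducibility, single coil", {
  m1 <- make_coil_maps(1, 32, rng_seed = 4)
  rss1 <- sqrt(apply(Mod(m1$maps)^2, c(2, 3), sum))
  sup <- rss1 > 1e-6 * max(rss1)
  expect_true(all(abs(rss1[sup] - 1) < 1e-6))

  m8 <- make_coil_maps(8, 32, rng_seed = 4)
  rss8 <- sqrt(apply(Mod(m8$maps)^2, c(2, 3), sum))
  expect_true(all(abs(rss8 - 1) < 1e-6))  # 8 lobes cover the full FOV

  expect_identical(make_coil_maps(3, 16, rng_seed = 7),
                   make_coil_maps(3, 16, rng_seed = 7))
})

test_that("forward model matches its definition on trivial inputs", {
  tr <- toy_traj()
  n <- 32
  maps1 <- make_coil_maps(1, n, normalize = FALSE)
  maps1$maps[1, , ] <- 1 + 0i  # uniform coil
  zero <- image_grid(matrix(0, n, n))
  expect_true(all(forward_model(zero, maps1, tr)$samples == 0))

  # unit pixel at the phase origin (centered coordinate 0 = index n/2+1)
  delta <- matrix(0, n, n)
  delta[n / 2 + 1, n / 2 + 1] <- 1
  kd <- forward_model(image_grid(delta), maps1, tr, engine = "exact_dft")
  expect_true(all(abs(Mod(kd$samples) - 1) < 1e-12))
})

test_that("gridding forward/adjoint match the explicit-DFT oracle", {
  tr <- toy_traj()
  n <- 32
  img <- random_complex_image(n, seed = 3)
  en <- rosetteRecon:::make_engine(tr, n, engine = "nufft")
  ed <- rosetteRecon:::make_engine(tr, n, engine = "exact_dft")
  sf <- en$forward(img); sd <- ed$forward(img)
  expect_lt(max(Mod(sf - sd)) / max(Mod(sd)), 1e-3)
  y <- complex(real = rnorm(length(sf)), imaginary = rnorm(length(sf)))
  af <- en$adjoint(y); ad <- ed$adjoint(y)
  expect_lt(max(Mod(af - ad)) / max(Mod(ad)), 1e-3)
})

test_that("exact-DFT forward model is linear", {
  tr <- toy_traj()
  n <- 16
  maps <- make_coil_maps(2, n)
  x <- image_grid(matrix(runif(n * n), n, n))
  y <- image_grid(matrix(runif(n * n), n, n))
  a <- 1.7; b <- -0.4
  sx <- forward_model(x, maps, tr, engine = "exact_dft")$samples
  sy <- forward_model(y, maps, tr, engine = "exact_dft")$samples
  combo <- image_grid(matrix(a * as.vector(x) + b * as.vector(y), n, n))
  lin <- forward_model(combo, maps, tr, engine = "exact_dft")$samples
  expect_lt(max(Mod(lin - (a * sx + b * sy))), 1e-10 * max(Mod(lin)))
})

test_that("adjoint inner-product identity holds for the multi-coil nufft pair", {
  tr <- toy_traj()
  n <- 32
  maps <- make_coil_maps(3, n, rng_seed = 2)
  set.seed(10)
  x <- matrix(runif(n * n), n, n)
  kd <- forward_model(image_grid(x), maps, tr)
  y <- matrix(complex(real = rnorm(length(kd$samples)),
                      imaginary = rnorm(length(kd$samples))),
              nrow(kd$samples), ncol(kd$samples))
  lhs <- sum(kd$samples * Conj(y))
  kdy <- kd; kdy$samples <- y
  rhs <- sum(x * Conj(rosetteRecon:::sense_adjoint(kdy, maps)))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
})

test_that("k-space noise: variance 0 identity, empirical variance, paper levels", {
  tr <- generate_rosette(rosette_params(n_petals = 100,
                                        samples_per_petal = 256))
  n <- 16
  maps <- make_coil_maps(4, n)
  kd <- forward_model(make_phantom(shepp_logan_spec(n)), maps, tr)
  expect_identical(add_kspace_noise(kd, noise_spec(0))$samples, kd$samples)

  v <- 0.003
  noisy <- add_kspace_noise(kd, noise_spec(v, rng_seed = 8))
  d <- noisy$samples - kd$samples
  expect_gt(length(d), 1e5)
  expect_lt(abs(stats::var(Re(as.vector(d))) / v - 1), 0.05)
  expect_lt(abs(stats::var(Im(as.vector(d))) / v - 1), 0.05)

  # reference sweep levels are accepted and recorded in metadata
  for (lev in c(1e-12, 5e-12, 1e-11, 5e-11)) {
    out <- add_kspace_noise(kd, noise_spec(lev, rng_seed = 1))
    expect_equal(out$noise_variance, lev)
  }

  # fractional mode records the equivalent absolute variance
  fr <- add_kspace_noise(kd, noise_spec(fraction = 0.01, rng_seed = 2))
  expect_equal(fr$noise_variance, 0.01 * mean(Mod(kd$samples)^2) / 2)

  # determinism
  expect_identical(add_kspace_noise(kd, noise_spec(v, rng_seed = 3))$samples,
                   add_kspace_noise(kd, noise_spec(v, rng_seed = 3))$samples)
})

test_that("paired dataset: shapes, determinism, gridding error, acceleration cost", {
  p1 <- rosette_params(n_petals = 48, samples_per_petal = 64,
                       acceleration = 1)
  ds <- build_paired_dataset(4, 32, p1, rng_seed = 5)
  expect_length(ds$rough, 4)
  expect_true(all(vapply(ds$rough, function(m) all(dim(m) == 32),
                         logical(1))))
  ds2 <- build_paired_dataset(4, 32, p1, rng_seed = 5)
  expect_identical(ds$rough, ds2$rough)
  expect_identical(ds$target, ds2$target)

  # noiseless dense acquisition: rough is close to but never equal to truth
  err1 <- vapply(seq_len(4), function(i) rel_l2(ds$rough[[i]],
                                                ds$target[[i]]),
                 numeric(1))
  expect_true(all(err1 > 0))

  # acceleration strictly degrades the rough approximation, same phantoms
  p4 <- rosette_params(n_petals = 48, samples_per_petal = 64,
                       acceleration = 4)
  ds4 <- build_paired_dataset(4, 32, p4, rng_seed = 5)
  err4 <- vapply(seq_len(4), function(i) rel_l2(ds4$rough[[i]],
                                                ds4$target[[i]]),
                 numeric(1))
  expect_true(all(err4 > err1))
})
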