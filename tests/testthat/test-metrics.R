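# Image-quality metric suite: closed-form cases and naive-loop oracles.

naive_oracles <- list(
  nrmse = function(X, Y) {
    s <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
      s <- s + (X[i, j] - Y[i, j])^2
    }
    sqrt(s / length(X)) / (max(Y) - min(Y))
  },
  psnr = function(X, Y, L) {
    s <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
      s <- s + (X[i, j] - Y[i, j])^2
    }
    10 * log10(L^2 / (s / length(X)))
  },
  entropy = function(X, bins) {
    v <- as.vector(X)
    br <- seq(min(v), max(v), length.out = bins + 1)
    counts <- numeric(bins)
    for (x in v) {
      b <- min(bins, max(1, findInterval(x, br, rightmost.closed = TRUE,
                                         all.inside = TRUE)))
      counts[b] <- counts[b] + 1
    }
    p <- counts / sum(counts)
    -sum(ifelse(p > 0, p * log2(p), 0))
  },
  efc = function(X) {
    xmax <- sqrt(sum(X^2))
    s <- 0
    for (x in as.vector(X)) {
      if (x > 0) s <- s - (x / xmax) * log(x / xmax)
    }
    s
  },
  nmi = function(X, Y, bins) {
    lo <- min(X, Y); hi <- max(X, Y)
    br <- seq(lo, hi, length.out = bins + 1)
    joint <- matrix(0, bins, bins)
    for (k in seq_along(X)) {
      i <- min(bins, max(1, findInterval(X[k], br, rightmost.closed = TRUE,
                                         all.inside = TRUE)))
      j <- min(bins, max(1, findInterval(Y[k], br, rightmost.closed = TRUE,
                                         all.inside = TRUE)))
      joint[i, j] <- joint[i, j] + 1
    }
    joint <- joint / sum(joint)
    H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
    hx <- H(rowSums(joint)); hy <- H(colSums(joint))
    2 * (hx + hy - H(as.vector(joint))) / (hx + hy)
  }
)

test_that("metrics match naive double-loop oracles on random regions", {
  set.seed(21)
  for (rep in 1:3) {
    X <- matrix(runif(64), 8, 8)
    Y <- matrix(runif(64), 8, 8)
    expect_equal(nrmse(X, Y), naive_oracles$nrmse(X, Y), tolerance = 1e-10)
    expect_equal(psnr(X, Y, 1), naive_oracles$psnr(X, Y, 1),
                 tolerance = 1e-10)
    expect_equal(shannon_entropy(X, 16), naive_oracles$entropy(X, 16),
                 tolerance = 1e-10)
    expect_equal(efc(X), naive_oracles$efc(X), tolerance = 1e-10)
    expect_equal(nmi(X, Y, 8), naive_oracles$nmi(X, Y, 8),
                 tolerance = 1e-10)
  }
})

test_that("ssim closed-form cases", {
  set.seed(4)
  X <- matrix(runif(400), 20, 20)
  expect_equal(ssim(X, X, metric_params(dynamic_range = 1)), 1,
               tolerance = 1e-12)
  # inverted binary image scores badly
  B <- matrix(rep(c(0, 1), 200), 20, 20)
  expect_lt(ssim(1 - B, B, metric_params(dynamic_range = 1)), 0.5)
  # windowless evaluation matches the formula on constant-statistics pairs
  mp <- metric_params(dynamic_range = 1)
  Xs <- matrix(rep(c(0.2, 0.4), 32), 8, 8)   # small region: global window
  Ys <- matrix(rep(c(0.3, 0.6), 32), 8, 8)
  muX <- mean(Xs); muY <- mean(Ys)
  sX <- mean(Xs^2) - muX^2; sY <- mean(Ys^2) - muY^2
  sXY <- mean(Xs * Ys) - muX * muY
  c1 <- 1e-4; c2 <- 9e-4
  ref <- ((2 * muX * muY + c1) * (2 * sXY + c2)) /
    ((muX^2 + muY^2 + c1) * (sX + sY + c2))
  expect_equal(ssim(Xs, Ys, mp), ref, tolerance = 1e-6)
})

test_that("nrmse: identity, constant offset, zero-range error", {
  X <- matrix(runif(64), 8, 8)
  expect_equal(nrmse(X, X), 0)
  R <- max(X) - min(X)
  expect_equal(nrmse(X + 0.05, X), 0.05 / R, tolerance = 1e-12)
  expect_error(nrmse(X, matrix(1, 8, 8)), "range")
})

test_that("psnr landmarks: infinity, 0 dB, 20 dB", {
  X <- matrix(runif(64), 8, 8)
  expect_equal(psnr(X, X, 1), Inf)
  expect_equal(psnr(matrix(0, 4, 4), matrix(1, 4, 4), 1), 0)
  # MSE = L^2/100 -> 20 dB
  Y <- matrix(0.5, 10, 10)
  X2 <- Y + 0.1  # MSE = 0.01 = 1^2/100
  expect_equal(psnr(X2, Y, 1), 20, tolerance = 1e-12)
})

test_that("nmi: identity, monotone remap, independence, constant error", {
  set.seed(9)
  X <- matrix(runif(10000), 100, 100)
  expect_equal(nmi(X, X, 16), 1, tolerance = 1e-12)
  # monotone bijective remap aligned with the bin grid (each level maps to
  # a distinct bin of the shared 4-bin histogram): exactly 1
  xl <- c(0, 1 / 3, 2 / 3, 1)
  yl <- c(0, 0.3, 0.55, 1)
  idx <- sample(rep(1:4, 16))
  Xd <- matrix(xl[idx], 8, 8)
  Yd <- matrix(yl[idx], 8, 8)
  expect_equal(nmi(Xd, Yd, 4), 1, tolerance = 1e-12)
  Y <- matrix(runif(10000), 100, 100)
  expect_lt(nmi(X, Y, 16), 0.05)
  expect_error(nmi(matrix(1, 4, 4), X[1:4, 1:4]), "constant")
})

test_that("relative contrast closed forms", {
  expect_equal(relative_contrast(matrix(2, 4, 4)), 0)
  expect_equal(relative_contrast(matrix(c(0, 3), 4, 4)), 1)
  expect_equal(relative_contrast(matrix(c(1, 3), 4, 4)), 0.5)
  expect_error(relative_contrast(matrix(0, 4, 4)), "all-zero")
})

test_that("shannon entropy closed forms", {
  expect_equal(shannon_entropy(matrix(5, 4, 4)), 0)
  expect_equal(shannon_entropy(matrix(c(0, 1), 4, 4), 256), 1)
  lv <- matrix(rep(0:255, 4) / 255, 32, 32)
  expect_equal(shannon_entropy(lv, 256), 8)
})

test_that("efc closed forms and dispersal monotonicity", {
  one <- matrix(0, 4, 4); one[2, 2] <- 7
  expect_equal(efc(one), 0)
  expect_equal(efc(matrix(1, 2, 2)), log(4), tolerance = 1e-12)
  spread <- matrix(1, 4, 4)
  expect_gt(efc(spread), efc(one))
  expect_error(efc(matrix(0, 4, 4)), "all-zero")
})

test_that("patch sampling respects bounds, count and seed", {
  mp <- metric_params(rng_seed = 13)
  o <- sample_patches(c(512, 512), mp)
  expect_equal(dim(o), c(6, 2))
  expect_true(all(o >= 1) && all(o <= 512 - 50 + 1))
  expect_identical(o, sample_patches(c(512, 512), mp))
  expect_error(sample_patches(c(40, 40), mp), "patch size")
})

test_that("evaluate: perfect reconstruction, decomposition, reproducibility", {
  set.seed(2)
  img <- matrix(runif(128 * 128), 128, 128)
  mp <- metric_params(patch_size = 30, rng_seed = 3)
  rep1 <- evaluate_images(img, img, mp)
  expect_equal(rep1$metrics[["ssim"]], 1, tolerance = 1e-12)
  expect_equal(rep1$metrics[["nrmse"]], 0)
  expect_equal(rep1$metrics[["psnr"]], Inf)
  expect_equal(rep1$metrics[["nmi"]], 1, tolerance = 1e-12)

  other <- matrix(runif(128 * 128), 128, 128)
  rep2 <- evaluate_images(other, img, mp)
  expect_identical(rep2$metrics, evaluate_images(other, img, mp)$metrics)
  # patch-average equals the mean of the per-patch values
  expect_equal(rep2$metrics[["nrmse"]], mean(rep2$per_patch$nrmse),
               tolerance = 1e-12)
  manual <- vapply(seq_len(6), function(i) {
    rr <- rep2$origins[i, 1] + 0:29; cc <- rep2$origins[i, 2] + 0:29
    nrmse(other[rr, cc], img[rr, cc])
  }, numeric(1))
  expect_equal(rep2$metrics[["nrmse"]], mean(manual), tolerance = 1e-12)
})

test_that("ssim and nmi are invariant to a common positive rescale", {
  set.seed(30)
  X <- matrix(runif(3600), 60, 60)
  Y <- matrix(runif(3600), 60, 60)
  s <- 37.5
  expect_equal(ssim(X, Y, metric_params(dynamic_range = 1)),
               ssim(s * X, s * Y, metric_params(dynamic_range = s)),
               tolerance = 1e-12)
  expect_equal(nmi(X, Y, 16), nmi(s * X, s * Y, 16), tolerance = 1e-12)
})

test_that("psnr and nrmse are mutually consistent", {
  set.seed(31)
  X <- matrix(runif(64), 8, 8); Y <- matrix(runif(64), 8, 8)
  L <- 1
  rng <- max(Y) - min(Y)
  expect_equal(psnr(X, Y, L), 20 * log10(L / (nrmse(X, Y) * rng)),
               tolerance = 1e-10)
})
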