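#' Augmentation configuration
#'
#' The training-set augmentations: random horizontal/vertical flips,
#' rotation, random resized crop, and brightness/contrast jitter. One random
#' geometric transform is applied identically to the rough input and the
#' target; intensity jitter perturbs the rough input only, since the target
#' is the reference to be predicted. Saturation has no meaning on
#' single-channel magnitude images and is omitted.
#'
#' @param hflip_p,vflip_p Flip probabilities.
#' @param rotation_range Max rotation in degrees (angle drawn uniformly from
#'   `[0, rotation_range]`, with a random sign).
#' @param jitter_range Length-2 multiplicative brightness/contrast range.
#' @param crop_scale Length-2 area-scale range of the random resized crop
#'   (values > 1 zoom out with zero padding).
#' @param multiplicity Augmented copies of the dataset per epoch (1 or 3).
#' @param enabled Master switch.
#' @return An `augment_config`.
#' @export
augment_config <- function(hflip_p = 0.5, vflip_p = 0.5, rotation_range = 180,
                           jitter_range = c(0.8, 1.2),
                           crop_scale = c(0.3, 1.1), multiplicity = 1L,
                           enabled = TRUE) {
  for (p in c(hflip_p, vflip_p)) {
    if (!is_number(p) || p < 0 || p > 1) {
      stop_field("hflip_p/vflip_p", "must be probabilities in [0, 1]")
    }
  }
  if (!is_number(rotation_range) || rotation_range < 0 ||
      rotation_range > 180) {
    stop_field("rotation_range", "must lie in [0, 180] degrees")
  }
  if (length(jitter_range) != 2 || diff(jitter_range) < 0) {
    stop_field("jitter_range", "must be an ordered length-2 range")
  }
  if (length(crop_scale) != 2 || diff(crop_scale) < 0 ||
      crop_scale[1] <= 0) {
    stop_field("crop_scale", "must be an ordered positive range")
  }
  if (!is_count(multiplicity)) stop_field("multiplicity", "must be a count")
  structure(list(hflip_p = hflip_p, vflip_p = vflip_p,
                 rotation_range = rotation_range,
                 jitter_range = jitter_range, crop_scale = crop_scale,
                 multiplicity = as.integer(multiplicity),
                 enabled = isTRUE(enabled)),
            class = "augment_config")
}

#' Training configuration
#'
#' Adam with the 1cycle learning-rate policy; defaults follow the reference
#' training setup (max learning rate 3e-4, up to 20 epochs with
#' best-validation checkpointing, one validation set in five).
#'
#' @param max_lr Peak learning rate of the 1cycle schedule.
#' @param max_epochs Epoch cap (training keeps the best-validation weights).
#' @param batch_size Items per gradient step.
#' @param loss `"MSE"` or `"L1"` pixelwise loss.
#' @param val_fraction Fraction of items held out for validation.
#' @param pct_start,div_factor,final_div 1cycle shape parameters (fraction
#'   of steps spent warming up, initial and final lr divisors).
#' @param rng_seed Seed governing the split, shuffling and augmentation.
#' @return A `train_config`.
#' @export
train_config <- function(max_lr = 3e-4, max_epochs = 20, batch_size = 8,
                         loss = c("MSE", "L1"), val_fraction = 0.2,
                         pct_start = 0.3, div_factor = 25, final_div = 1e4,
                         rng_seed = 1L) {
  loss <- match.arg(loss)
  if (!is_number(max_lr) || max_lr <= 0) stop_field("max_lr", "must be > 0")
  if (!is_count(max_epochs)) stop_field("max_epochs", "must be a count >= 1")
  if (!is_count(batch_size)) stop_field("batch_size", "must be a count >= 1")
  if (!is_number(val_fraction) || val_fraction <= 0 || val_fraction >= 1) {
    stop_field("val_fraction", "must lie in (0, 1)")
  }
  structure(list(max_lr = max_lr, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 val_fraction = val_fraction, pct_start = pct_start,
                 div_factor = div_factor, final_div = final_div,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' 1cycle learning rate
#'
#' Cosine-annealed warmup from `max_lr / div_factor` to `max_lr` over the
#' first `pct_start` fraction of steps, then cosine annealing down to
#' `max_lr / final_div`.
#'
#' @param step 0-based step index, `0 <= step < total_steps`.
#' @param total_steps Total optimizer steps in the run.
#' @param max_lr Peak learning rate.
#' @param pct_start Warmup fraction.
#' @param div_factor Initial divisor (`lr_0 = max_lr / div_factor`).
#' @param final_div Final divisor (`lr_end = max_lr / final_div`).
#' @return The learning rate at `step`.
#' @export
onecycle_lr <- function(step, total_steps, max_lr = 3e-4, pct_start = 0.3,
                        div_factor = 25, final_div = 1e4) {
  if (any(step < 0 | step >= total_steps)) {
    stop("step out of range [0, total_steps)", call. = FALSE)
  }
  up <- pct_start * total_steps
  lr0 <- max_lr / div_factor
  lr_end <- max_lr / final_div
  cos_interp <- function(a, b, t) b + (a - b) * (1 + cos(pi * t)) / 2
  t_up <- if (up > 0) step / up else rep(1, length(step))
  ifelse(step <= up,
         cos_interp(lr0, max_lr, t_up),
         cos_interp(max_lr, lr_end,
                    (step - up) / pmax(total_steps - 1 - up, 1)))
}

# --- augmentation primitives -------------------------------------------------

rotate_image <- function(img, angle_deg) {
  if (angle_deg == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  th <- angle_deg * pi / 180
  cr <- (n + 1) / 2; cc <- (m + 1) / 2
  grid <- expand.grid(r = seq_len(n), c = seq_len(m))
  dr <- grid$r - cr; dc <- grid$c - cc
  src_r <- cos(th) * dr + sin(th) * dc + cr
  src_c <- -sin(th) * dr + cos(th) * dc + cc
  matrix(bilinear_sample(img, src_r, src_c), n, m)
}

resized_crop <- function(img, scale, off_r, off_c) {
  n <- nrow(img); m <- ncol(img)
  side_r <- max(4L, round(n * sqrt(scale)))
  side_c <- max(4L, round(m * sqrt(scale)))
  # window top-left (possibly outside the image for zoom-out)
  r0 <- round(off_r * (n - side_r)); c0 <- round(off_c * (m - side_c))
  rr <- r0 + seq_len(side_r); cc <- c0 + seq_len(side_c)
  win <- matrix(0, side_r, side_c)
  ok_r <- rr >= 1 & rr <= n; ok_c <- cc >= 1 & cc <= m
  win[ok_r, ok_c] <- img[rr[ok_r], cc[ok_c]]
  bilinear_resize(win, n, m)
}

#' Augment a (rough, target) pair
#'
#' Draws one geometric transform (flips, rotation, resized crop) and applies
#' it identically to both images, then applies brightness/contrast jitter to
#' the rough input only. Deterministic given `draw_seed`.
#'
#' @param rough,target Same-shape matrices.
#' @param cfg An [augment_config()].
#' @param draw_seed Integer seed for this draw.
#' @return List with elements `rough` and `target`.
#' @export
augment_pair <- function(rough, target, cfg, draw_seed = 1L) {
  stopifnot(all(dim(rough) == dim(target)))
  if (!cfg$enabled) return(list(rough = rough, target = target))
  draws <- with_seed(draw_seed, {
    list(hf = stats::runif(1) < cfg$hflip_p,
         vf = stats::runif(1) < cfg$vflip_p,
         ang = stats::runif(1, 0, cfg$rotation_range) * sample(c(-1, 1), 1),
         scale = stats::runif(1, cfg$crop_scale[1], cfg$crop_scale[2]),
         off_r = stats::runif(1), off_c = stats::runif(1),
         bright = stats::runif(1, cfg$jitter_range[1], cfg$jitter_range[2]),
         contrast = stats::runif(1, cfg$jitter_range[1], cfg$jitter_range[2]))
  })
  geo <- function(img) {
    if (draws$hf) img <- img[, rev(seq_len(ncol(img)))]
    if (draws$vf) img <- img[rev(seq_len(nrow(img))), ]
    if (cfg$rotation_range > 0) img <- rotate_image(img, draws$ang)
    if (cfg$crop_scale[1] != 1 || cfg$crop_scale[2] != 1) {
      img <- resized_crop(img, draws$scale, draws$off_r, draws$off_c)
    }
    img
  }
  r <- geo(rough); t <- geo(target)
  r <- r * draws$bright
  m <- mean(r)
  r <- pmax((r - m) * draws$contrast + m, 0)
  list(rough = r, target = t)
}

# --- Adam / training loop ----------------------------------------------------

adam_init <- function(weights) {
  list(m = tree_map(function(x) x * 0, weights),
       v = tree_map(function(x) x * 0, weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(weights = tree_map2(`-`, weights, upd), state = state)
}

loss_and_grad <- function(img, tgt, config, weights, loss) {
  fwd <- vit_forward_core(img, config, weights, cache = TRUE)
  diff <- fwd$out - tgt
  if (loss == "MSE") {
    l <- mean(diff^2)
    dout <- 2 * diff / length(diff)
  } else {
    l <- mean(abs(diff))
    dout <- sign(diff) / length(diff)
  }
  list(loss = l, grads = vit_backward(dout, config, weights, fwd))
}

#' Train the refinement network
#'
#' Minimizes the configured pixelwise loss between the network output on the
#' rough input and the target, using Adam under the 1cycle schedule, with
#' per-epoch augmentation draws and best-validation checkpointing. Fully
#' reproducible given the seeds in the configs.
#'
#' @param model_cfg A [vit_config()].
#' @param dataset A [build_paired_dataset()] result, or any list with
#'   `rough` and `target` lists of same-shape matrices (>= 2 items).
#' @param cfg A [train_config()].
#' @param augment An [augment_config()]; `augment_config(enabled = FALSE)`
#'   trains on the raw pairs.
#' @param init_seed Seed for weight initialization.
#' @param verbose Print per-epoch losses.
#' @return List with `weights` (best-validation), `history` (data.frame:
#'   epoch, train_loss, val_loss, lr), `best_epoch`, `config`.
#' @export
vit_train <- function(model_cfg, dataset, cfg = train_config(),
                      augment = augment_config(enabled = FALSE),
                      init_seed = 1L, verbose = FALSE) {
  n <- length(dataset$rough)
  if (n < 2) stop("dataset must contain at least 2 items", call. = FALSE)
  n_val <- max(1L, round(cfg$val_fraction * n))
  idx <- with_seed(derive_seed(cfg$rng_seed, 1L), sample.int(n))
  val_idx <- idx[seq_len(n_val)]
  train_idx <- idx[-seq_len(n_val)]
  mult <- if (augment$enabled) augment$multiplicity else 1L
  steps_per_epoch <- ceiling(mult * length(train_idx) / cfg$batch_size)
  total_steps <- cfg$max_epochs * steps_per_epoch
  weights <- vit_init_weights(model_cfg, rng_seed = init_seed)
  state <- adam_init(weights)
  best <- list(val = Inf, weights = weights, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  step <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    order_items <- with_seed(derive_seed(cfg$rng_seed, 100L + ep), {
      sample(rep(train_idx, mult))
    })
    ep_loss <- 0
    nb <- 0L
    for (bs in split(order_items,
                     ceiling(seq_along(order_items) / cfg$batch_size))) {
      lr <- onecycle_lr(step, total_steps, cfg$max_lr, cfg$pct_start,
                        cfg$div_factor, cfg$final_div)
      gsum <- NULL
      lsum <- 0
      for (j in seq_along(bs)) {
        i <- bs[j]
        if (augment$enabled) {
          pair <- augment_pair(dataset$rough[[i]], dataset$target[[i]],
                               augment,
                               draw_seed = derive_seed(cfg$rng_seed,
                                                       1000L * ep + i))
        } else {
          pair <- list(rough = dataset$rough[[i]],
                       target = dataset$target[[i]])
        }
        lg <- loss_and_grad(pair$rough, pair$target, model_cfg, weights,
                            cfg$loss)
        lsum <- lsum + lg$loss
        gsum <- if (is.null(gsum)) lg$grads else {
          tree_map2(`+`, gsum, lg$grads)
        }
      }
      if (!is.finite(lsum)) {
        stop(sprintf(
          "training diverged (non-finite loss) at epoch %d step %d", ep,
          step), call. = FALSE)
      }
      gmean <- tree_map(function(g) g / length(bs), gsum)
      st <- adam_step(weights, gmean, state, lr)
      weights <- st$weights
      state <- st$state
      step <- step + 1L
      ep_loss <- ep_loss + lsum / length(bs)
      nb <- nb + 1L
    }
    val_loss <- mean(vapply(val_idx, function(i) {
      out <- vit_forward_core(dataset$rough[[i]], model_cfg, weights,
                              cache = FALSE)
      if (cfg$loss == "MSE") mean((out - dataset$target[[i]])^2)
      else mean(abs(out - dataset$target[[i]]))
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val_loss,
                                   lr = onecycle_lr(step - 1L, total_steps,
                                                    cfg$max_lr,
                                                    cfg$pct_start,
                                                    cfg$div_factor,
                                                    cfg$final_div)))
    if (verbose) {
      message(sprintf("epoch %2d  train %.5g  val %.5g", ep, ep_loss / nb,
                      val_loss))
    }
    if (val_loss < best$val) {
      best <- list(val = val_loss, weights = weights, epoch = ep)
    }
  }
  list(weights = best$weights, history = hist, best_epoch = best$epoch,
       config = model_cfg, train_idx = train_idx, val_idx = val_idx,
       steps_per_epoch = steps_per_epoch)
}
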