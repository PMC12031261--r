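#' Compare reconstruction methods statistically
#'
#' One-way repeated-measures ANOVA per metric across methods (items as the
#' repeated-measures unit), followed by all pairwise paired t-tests with a
#' Bonferroni-corrected significance threshold `0.05 / k` for the `k`
#' pairwise comparisons (6 comparisons give 0.00833).
#'
#' @param scores Named list, one element per method, each a data.frame (or
#'   matrix) of per-item metric scores with identical column names and row
#'   counts, rows paired by item.
#' @return A `method_comparison`: list with `anova` (data.frame: metric, F,
#'   p), `pairwise` (data.frame: metric, method_a, method_b, p,
#'   significant), `threshold`, `n_comparisons`.
#' @export
compare_methods <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 methods", call. = FALSE)
  if (is.null(names(scores)) || any(names(scores) == "")) {
    names(scores) <- paste0("method", seq_along(scores))
  }
  scores <- lapply(scores, as.data.frame)
  metrics <- colnames(scores[[1]])
  n <- nrow(scores[[1]])
  for (s in scores) {
    if (!identical(colnames(s), metrics) || nrow(s) != n) {
      stop("unpaired inputs: methods must share metrics and item counts",
           call. = FALSE)
    }
  }
  methods <- names(scores)
  pairs <- utils::combn(methods, 2)
  k <- ncol(pairs)
  threshold <- 0.05 / k
  anova_rows <- list()
  pair_rows <- list()
  for (m in metrics) {
    long <- data.frame(
      value = unlist(lapply(scores, function(s) s[[m]]), use.names = FALSE),
      method = factor(rep(methods, each = n)),
      item = factor(rep(seq_len(n), times = length(methods))))
    if (stats::var(long$value) == 0) {
      Fv <- 0; pv <- 1
    } else {
      fit <- stats::aov(value ~ method + Error(item), data = long)
      tab <- summary(fit)[["Error: Within"]][[1]]
      Fv <- tab["method", "F value"]
      pv <- tab["method", "Pr(>F)"]
      if (is.na(Fv)) { Fv <- 0; pv <- 1 }
    }
    anova_rows[[m]] <- data.frame(metric = m, F = Fv, p = pv)
    for (j in seq_len(k)) {
      a <- scores[[pairs[1, j]]][[m]]
      b <- scores[[pairs[2, j]]][[m]]
      d <- a - b
      p <- if (stats::sd(d) == 0) {
        if (mean(d) == 0) 1 else 0  # constant nonzero difference
      } else {
        # an (essentially) constant nonzero difference is off-scale
        # significant; the paired t-test cannot evaluate it
        tryCatch(stats::t.test(a, b, paired = TRUE)$p.value,
                 error = function(e) if (mean(d) == 0) 1 else 0)
      }
      if (is.na(p)) p <- 1
      pair_rows[[paste(m, j)]] <- data.frame(
        metric = m, method_a = pairs[1, j], method_b = pairs[2, j], p = p,
        significant = p < threshold)
    }
  }
  structure(list(anova = do.call(rbind, c(anova_rows,
                                          make.row.names = FALSE)),
                 pairwise = do.call(rbind, c(pair_rows,
                                             make.row.names = FALSE)),
                 threshold = threshold, n_comparisons = k),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("method comparison: %d pairwise tests, Bonferroni alpha %.5f\n",
              x$n_comparisons, x$threshold))
  print(x$anova)
  print(x$pairwise)
  invisible(x)
}

#' K-space noise robustness sweep
#'
#' For each noise variance: re-simulates the k-space data of a fixed
#' evaluation set, adds complex Gaussian noise, reconstructs the rough
#' image, refines it with the trained network, and evaluates against the
#' clean targets. Emits one row per variance with the patch-averaged
#' metrics.
#'
#' @param weights Trained weights from [vit_train()].
#' @param model_cfg The matching [vit_config()].
#' @param dataset A [build_paired_dataset()] result built WITHOUT noise; its
#'   phantoms, maps and trajectory define the evaluation set.
#' @param variances Numeric vector of per-component Gaussian variances, or
#'   noise-to-signal power fractions when `fractional = TRUE`.
#' @param params [metric_params()] for the evaluation.
#' @param fractional Interpret `variances` as noise-to-signal power ratios.
#' @param items Indices of dataset items to evaluate (default all).
#' @return Data.frame: one row per variance, columns `variance`,
#'   `abs_variance`, and the patch-averaged metrics of the refined (and
#'   rough) reconstructions.
#' @export
noise_sweep <- function(weights, model_cfg, dataset, variances,
                        params = metric_params(), fractional = TRUE,
                        items = NULL) {
  stopifnot(inherits(dataset, "paired_dataset"))
  if (is.null(items)) items <- seq_along(dataset$rough)
  maps <- dataset$maps
  traj <- dataset$traj
  gs <- dataset$grid_size
  rows <- list()
  for (vi in seq_along(variances)) {
    v <- variances[vi]
    met_ref <- NULL
    met_rough <- NULL
    abs_v <- numeric(0)
    for (i in items) {
      spec <- random_phantom_spec(gs, rng_seed = derive_seed(dataset$rng_seed,
                                                             i))
      truth <- make_phantom(spec)
      kd <- forward_model(truth, maps, traj)
      ns <- if (fractional) {
        noise_spec(fraction = v, rng_seed = derive_seed(dataset$rng_seed,
                                                        900000L + 1000L * vi + i))
      } else {
        noise_spec(variance = v, rng_seed = derive_seed(dataset$rng_seed,
                                                        900000L + 1000L * vi + i))
      }
      kd <- add_kspace_noise(kd, ns)
      abs_v <- c(abs_v, kd$noise_variance)
      rough <- rss_combine(adjoint_recon(kd))
      sc <- max(truth)
      rough <- as_plain_matrix(rough) / sc
      tgt <- as_plain_matrix(truth) / sc
      refined <- as_plain_matrix(vit_forward(rough, model_cfg, weights))
      mr <- evaluate_images(refined, tgt, params)$metrics
      mo <- evaluate_images(rough, tgt, params)$metrics
      met_ref <- rbind(met_ref, mr)
      met_rough <- rbind(met_rough, mo)
    }
    avg <- colMeans(met_ref, na.rm = TRUE)
    avg_rough <- colMeans(met_rough, na.rm = TRUE)
    rows[[vi]] <- data.frame(variance = v, abs_variance = mean(abs_v),
                             t(avg),
                             rough_ssim = avg_rough[["ssim"]],
                             rough_psnr = avg_rough[["psnr"]])
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
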