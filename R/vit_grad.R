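# Analytic backward pass for the vision transformer. Mirrors
# vit_forward_core(cache = TRUE) layer by layer in reverse; verified against
# central finite differences in the test suite.

layer_norm_bwd <- function(dout, ln, g) {
  P <- nrow(dout)
  G <- matrix(g, P, length(g), byrow = TRUE)
  dg <- colSums(dout * ln$xhat)
  db <- colSums(dout)
  dxhat <- dout * G
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * ln$xhat)
  dx <- ln$inv * (dxhat - m1 - ln$xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

linear_bwd <- function(dY, X, W) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = tcrossprod(dY, W))
}

conv2d_bwd <- function(dout, cv, k) {
  kk <- nrow(k)
  r <- cv$r
  h <- nrow(dout); w <- ncol(dout)
  dk <- matrix(0, kk, kk)
  dpad <- matrix(0, h + 2 * r, w + 2 * r)
  for (a in seq_len(kk)) for (b in seq_len(kk)) {
    sub <- cv$padded[(a - 1) + seq_len(h), (b - 1) + seq_len(w)]
    dk[a, b] <- sum(dout * sub)
    dpad[(a - 1) + seq_len(h), (b - 1) + seq_len(w)] <-
      dpad[(a - 1) + seq_len(h), (b - 1) + seq_len(w)] + k[a, b] * dout
  }
  list(dk = dk, db = sum(dout),
       din = dpad[r + seq_len(h), r + seq_len(w)])
}

# Gradient of a scalar loss w.r.t. every weight, given d(loss)/d(output).
# fwd is the cache list from vit_forward_core(cache = TRUE).
vit_backward <- function(dout, config, weights, fwd) {
  ps <- config$patch_size
  D <- config$embed_dim
  H <- config$n_heads
  dh <- D %/% H
  gw <- list()  # gradient tree, same shape as weights

  if (config$use_conv && !is.null(weights$conv)) {
    cb <- conv2d_bwd(dout, fwd$conv, weights$conv$k)
    gw$conv <- list(k = cb$dk, b = cb$db)
    d_pre <- cb$din
  } else {
    gw$conv <- NULL
    d_pre <- dout
  }
  # unpatchify backward: re-embed the gradient into the padded canvas and
  # split into patch vectors
  dR <- patchify_grad(d_pre, fwd$rec)
  hb <- linear_bwd(dR, fwd$Fh, weights$head$W)
  gw$head <- list(W = hb$dW, b = hb$db)
  lb <- layer_norm_bwd(hb$dX, fwd$lnf, weights$ln_f$g)
  gw$ln_f <- list(g = lb$dg, b = lb$db)
  dX <- lb$dx

  gw$layers <- vector("list", config$depth)
  for (l in rev(seq_len(config$depth))) {
    lw <- weights$layers[[l]]
    cc <- fwd$layers[[l]]
    P <- nrow(dX)
    # MLP block: X2 = X1 + gelu(LN2(X1) W1 + b1) W2 + b2
    dM2 <- dX
    mb2 <- linear_bwd(dM2, cc$H1, lw$mlp$W2)
    dH1 <- mb2$dX
    dM1 <- dH1 * gelu_grad(cc$M1)
    mb1 <- linear_bwd(dM1, cc$Z, lw$mlp$W1)
    ln2b <- layer_norm_bwd(mb1$dX, cc$ln2, lw$ln2$g)
    dX1 <- dX + ln2b$dx
    # attention block: X1 = Xin + O Wo + bo
    ob <- linear_bwd(dX1, cc$O, lw$attn$Wo)
    dO <- ob$dX
    dQ <- matrix(0, P, D); dK <- matrix(0, P, D); dV <- matrix(0, P, D)
    for (gi in seq_along(cc$groups)) {
      g <- cc$groups[[gi]]
      for (h in seq_len(H)) {
        ix <- (h - 1) * dh + seq_len(dh)
        A <- cc$A[[gi]][[h]]
        dOg <- dO[g, ix, drop = FALSE]
        Vg <- cc$V[g, ix, drop = FALSE]
        dA <- tcrossprod(dOg, Vg)
        dV[g, ix] <- dV[g, ix] + crossprod(A, dOg)
        dS <- (dA - rowSums(dA * A)) * A / sqrt(dh)
        dQ[g, ix] <- dQ[g, ix] + dS %*% cc$K[g, ix, drop = FALSE]
        dK[g, ix] <- dK[g, ix] + crossprod(dS, cc$Q[g, ix, drop = FALSE])
      }
    }
    qb <- linear_bwd(dQ, cc$Y, lw$attn$Wq)
    kb <- linear_bwd(dK, cc$Y, lw$attn$Wk)
    vb <- linear_bwd(dV, cc$Y, lw$attn$Wv)
    dY <- qb$dX + kb$dX + vb$dX
    ln1b <- layer_norm_bwd(dY, cc$ln1, lw$ln1$g)
    dXin <- dX1 + ln1b$dx
    gw$layers[[l]] <- list(
      ln1 = list(g = ln1b$dg, b = ln1b$db),
      attn = list(Wq = qb$dW, bq = qb$db, Wk = kb$dW, bk = kb$db,
                  Wv = vb$dW, bv = vb$db, Wo = ob$dW, bo = ob$db),
      ln2 = list(g = ln2b$dg, b = ln2b$db),
      mlp = list(W1 = mb1$dW, b1 = mb1$db, W2 = mb2$dW, b2 = mb2$db))
    dX <- dXin
  }
  gw$pos <- matrix(0, nrow(weights$pos), D)
  gw$pos[fwd$pos_idx, ] <- dX
  eb <- linear_bwd(dX, fwd$rec$patches, weights$embed$W)
  gw$embed <- list(W = eb$dW, b = eb$db)
  gw[c("embed", "pos", "layers", "ln_f", "head", "conv")]
}

# patchify applied to a gradient image: same reshape, but keeps the padded
# frame (gradient of unpatchify w.r.t. its patch-matrix input).
patchify_grad <- function(dimg, rec) {
  ps <- rec$patch_size
  gr <- rec$grid[1]; gc <- rec$grid[2]
  padded <- matrix(0, gr * ps, gc * ps)
  padded[rec$pad[1] + seq_len(rec$size[1]),
         rec$pad[2] + seq_len(rec$size[2])] <- dimg
  arr <- array(padded, dim = c(ps, gr, ps, gc))
  matrix(aperm(arr, c(2, 4, 1, 3)), gr * gc, ps^2)
}

# Elementwise binary map over two parallel weight trees.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (!is.null(a[[nm]])) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    }
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (!is.null(a[[nm]])) out[[nm]] <- tree_map(f, a[[nm]])
    }
    out
  } else {
    f(a)
  }
}

# Flatten a weight tree to a single numeric vector (for checkpoints and
# finite-difference checks) and rebuild it.
tree_flatten <- function(a) {
  if (is.list(a)) {
    unlist(lapply(a, tree_flatten), use.names = FALSE)
  } else {
    as.numeric(a)
  }
}

tree_unflatten <- function(template, values) {
  pos <- 0L
  rebuild <- function(a) {
    if (is.list(a)) {
      for (nm in seq_along(a)) {
        if (!is.null(a[[nm]])) a[[nm]] <- rebuild(a[[nm]])
      }
      a
    } else {
      n <- length(a)
      v <- values[pos + seq_len(n)]
      pos <<- pos + n
      if (is.matrix(a)) matrix(v, nrow(a), ncol(a)) else v
    }
  }
  out <- rebuild(template)
  stopifnot(pos == length(values))
  out
}
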