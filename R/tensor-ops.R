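# Structural ops on (batch, channel, row, col) feature maps: convolution,
# pooling, normalisation, upsampling and the broadcast products the gating
# paths need. All are tape nodes with hand-derived backward rules; the unit
# tests check every rule against central finite differences.

# view of x as a (N*H*W) x C matrix, channels as columns
to_cm <- function(xv) {
  d <- dim(xv)
  matrix(aperm(xv, c(1L, 3L, 4L, 2L)), d[1] * d[3] * d[4], d[2])
}

from_cm <- function(m, d) {
  aperm(array(m, c(d[1], d[3], d[4], d[2])), c(1L, 4L, 2L, 3L))
}

pad_nchw <- function(xv, p) {
  if (p == 0) return(xv)
  d <- dim(xv)
  out <- array(0, c(d[1], d[2], d[3] + 2 * p, d[4] + 2 * p))
  out[, , p + seq_len(d[3]), p + seq_len(d[4])] <- xv
  out
}

# 2-D convolution, stride 1, zero padding (k-1)/2 so spatial dims are kept.
# W: (Cout, Cin, k, k), b: length Cout. Implemented as k^2 BLAS products on a
# channel-last padded copy (one permutation each way, not one per offset).
tn_conv2d <- function(x, W, b) {
  xv <- x$value; Wv <- W$value; bv <- b$value
  d <- dim(xv); N <- d[1]; C <- d[2]; H <- d[3]; Wd <- d[4]
  k <- dim(Wv)[3]; Cout <- dim(Wv)[1]
  M <- N * H * Wd
  if (k == 1L) {
    Xm <- to_cm(xv)
    Wk <- matrix(Wv, Cout, C)
    out_m <- tcrossprod(Xm, Wk)
    out_m <- out_m + matrix(bv, M, Cout, byrow = TRUE)
    out <- from_cm(out_m, c(N, Cout, H, Wd))
    return(tn(out, list(x, W, b), function(g) {
      g_m <- to_cm(g)
      list(from_cm(g_m %*% Wk, d),
           array(crossprod(g_m, Xm), dim(Wv)), colSums(g_m))
    }))
  }
  p <- (k - 1L) %/% 2L
  Xq <- array(0, c(N, H + 2L * p, Wd + 2L * p, C))
  Xq[, p + seq_len(H), p + seq_len(Wd), ] <- aperm(xv, c(1L, 3L, 4L, 2L))
  out_m <- matrix(bv, M, Cout, byrow = TRUE)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    Sm <- matrix(Xq[, di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE],
                 M, C)
    Wk <- matrix(Wv[, , di, dj], Cout, C)
    out_m <- out_m + tcrossprod(Sm, Wk)
  }
  out <- from_cm(out_m, c(N, Cout, H, Wd))
  tn(out, list(x, W, b), function(g) {
    g_m <- to_cm(g)
    dW <- array(0, dim(Wv))
    dXq <- array(0, dim(Xq))
    for (di in seq_len(k)) for (dj in seq_len(k)) {
      ri <- di:(di + H - 1L); ci <- dj:(dj + Wd - 1L)
      Sm <- matrix(Xq[, ri, ci, , drop = FALSE], M, C)
      Wk <- matrix(Wv[, , di, dj], Cout, C)
      dW[, , di, dj] <- crossprod(g_m, Sm)
      dXq[, ri, ci, ] <- dXq[, ri, ci, , drop = FALSE] +
        array(g_m %*% Wk, c(N, H, Wd, C))
    }
    dx <- aperm(dXq[, p + seq_len(H), p + seq_len(Wd), , drop = FALSE],
                c(1L, 4L, 2L, 3L))
    list(dx, dW, colSums(g_m))
  })
}

# 2x2 max pooling, stride 2. Ties route the gradient to the first claimant
# (row-major scan order), keeping the op deterministic.
tn_maxpool2 <- function(x) {
  xv <- x$value
  d <- dim(xv); H <- d[3]; W <- d[4]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  ri <- seq(1L, H, 2L); ci <- seq(1L, W, 2L)
  v <- list(
    xv[, , ri, ci, drop = FALSE], xv[, , ri, ci + 1L, drop = FALSE],
    xv[, , ri + 1L, ci, drop = FALSE], xv[, , ri + 1L, ci + 1L, drop = FALSE]
  )
  m <- pmax(v[[1]], v[[2]], v[[3]], v[[4]])
  tn(m, list(x), function(g) {
    dx <- array(0, d)
    claimed <- array(FALSE, dim(m))
    slots <- list(list(ri, ci), list(ri, ci + 1L), list(ri + 1L, ci),
                  list(ri + 1L, ci + 1L))
    for (i in 1:4) {
      sel <- (v[[i]] == m) & !claimed
      claimed <- claimed | sel
      dx[, , slots[[i]][[1]], slots[[i]][[2]]] <- g * sel
    }
    list(dx)
  })
}

# Bilinear x2 upsampling as two 1-D interpolation matrices (half-pixel
# centers, edge-clamped), so the backward pass is just the transposes.
upsample_matrix <- function(H) {
  A <- matrix(0, 2L * H, H)
  for (o in seq_len(2L * H)) {
    src <- (o - 1) / 2 - 0.25          # 0-based source coordinate
    f <- floor(src)
    w <- src - f
    i0 <- min(max(f, 0), H - 1)
    i1 <- min(max(f + 1, 0), H - 1)
    A[o, i0 + 1] <- A[o, i0 + 1] + (1 - w)
    A[o, i1 + 1] <- A[o, i1 + 1] + w
  }
  A
}

apply_rows <- function(xv, A) {
  d <- dim(xv)
  Xm <- matrix(aperm(xv, c(3L, 1L, 2L, 4L)), d[3], d[1] * d[2] * d[4])
  Y <- A %*% Xm
  aperm(array(Y, c(nrow(A), d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
}

apply_cols <- function(xv, B) {
  d <- dim(xv)
  Xm <- matrix(aperm(xv, c(4L, 1L, 2L, 3L)), d[4], d[1] * d[2] * d[3])
  Y <- B %*% Xm
  aperm(array(Y, c(nrow(B), d[1], d[2], d[3])), c(2L, 3L, 4L, 1L))
}

tn_upsample2 <- function(x) {
  xv <- x$value
  d <- dim(xv)
  A <- upsample_matrix(d[3]); B <- upsample_matrix(d[4])
  out <- apply_cols(apply_rows(xv, A), B)
  tn(out, list(x), function(g) {
    list(apply_rows(apply_cols(g, t(B)), t(A)))
  })
}

# Batch normalisation over (N, H, W) per channel. `layer` is an environment
# carrying gamma/beta params plus running statistics; `train` selects batch
# statistics (and updates the running ones) versus the stored ones.
tn_batchnorm <- function(x, layer, train = TRUE) {
  xv <- x$value
  d <- dim(xv); C <- d[2]
  eps <- layer$eps
  Xc <- to_cm(xv)
  M <- nrow(Xc)
  gv <- layer$gamma$value; bv <- layer$beta$value
  if (train) {
    mu <- colMeans(Xc)
    xm <- sweep(Xc, 2L, mu, `-`)
    v <- colMeans(xm^2)
    layer$run_mean <- (1 - layer$mom) * layer$run_mean + layer$mom * mu
    layer$run_var <- (1 - layer$mom) * layer$run_var + layer$mom * v
  } else {
    mu <- layer$run_mean
    xm <- sweep(Xc, 2L, mu, `-`)
    v <- layer$run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xm, 2L, ivar, `*`)
  Y <- sweep(sweep(xhat, 2L, gv, `*`), 2L, bv, `+`)
  tn(from_cm(Y, d), list(x, layer$gamma, layer$beta), function(g) {
    Gc <- to_cm(g)
    dgamma <- colSums(Gc * xhat)
    dbeta <- colSums(Gc)
    dxhat <- sweep(Gc, 2L, gv, `*`)
    if (train) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dX <- sweep(
        M * dxhat - matrix(s1, M, C, byrow = TRUE) -
          xhat * matrix(s2, M, C, byrow = TRUE),
        2L, ivar / M, `*`)
    } else {
      dX <- sweep(dxhat, 2L, ivar, `*`)
    }
    list(from_cm(dX, d), dgamma, dbeta)
  })
}

# Layer normalisation over the last axis of (N, T, D) token arrays.
tn_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv); D <- d[length(d)]
  Xm <- matrix(xv, ncol = D)
  mu <- rowMeans(Xm)
  xm <- Xm - mu
  v <- rowMeans(xm^2)
  ivar <- 1 / sqrt(v + eps)
  xhat <- xm * ivar
  gv <- gamma$value; bv <- beta$value
  Y <- sweep(sweep(xhat, 2L, gv, `*`), 2L, bv, `+`)
  tn(array(Y, d), list(x, gamma, beta), function(g) {
    Gm <- matrix(g, ncol = D)
    dgamma <- colSums(Gm * xhat)
    dbeta <- colSums(Gm)
    dxhat <- sweep(Gm, 2L, gv, `*`)
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * xhat)
    dX <- (ivar / D) * (D * dxhat - s1 - xhat * s2)
    list(array(dX, d), dgamma, dbeta)
  })
}

# y[n,c,h,w] = x[n,c,h,w] * gate[n,c]
tn_scale_by_channel <- function(x, gate) {
  xv <- x$value; gv <- gate$value
  d <- dim(xv)
  garr <- array(gv, d)  # column-major recycling over (H, W)
  tn(xv * garr, list(x, gate), function(g) {
    dgate <- matrix(rowSums(matrix(g * xv, d[1] * d[2], d[3] * d[4])),
                    d[1], d[2])
    list(g * garr, dgate)
  })
}

# y[n,c,h,w] = x[n,c,h,w] * s[n,1,h,w]
tn_scale_by_spatial <- function(x, s) {
  xv <- x$value; sv <- s$value
  d <- dim(xv); C <- d[2]
  sarr <- sv[, rep(1L, C), , , drop = FALSE]
  tn(xv * sarr, list(x, s), function(g) {
    m <- g * xv
    ds <- array(colSums(matrix(aperm(m, c(2L, 1L, 3L, 4L)), C)),
                c(d[1], 1L, d[3], d[4]))
    list(g * sarr, ds)
  })
}

# broadcast a per-channel vector (N, C) to a full map
tn_channel_to_map <- function(gate, d) {
  gv <- gate$value
  tn(array(gv, d), list(gate), function(g) {
    list(matrix(rowSums(matrix(g, d[1] * d[2], d[3] * d[4])), d[1], d[2]))
  })
}

# broadcast a 1-channel map (N, 1, H, W) to C channels
tn_spatial_to_map <- function(s, C) {
  sv <- s$value
  d <- dim(sv)
  tn(sv[, rep(1L, C), , , drop = FALSE], list(s), function(g) {
    list(array(colSums(matrix(aperm(g, c(2L, 1L, 3L, 4L)), C)),
               c(d[1], 1L, d[3], d[4])))
  })
}

# spatial global average pool -> (N, C)
tn_gap <- function(x) {
  xv <- x$value
  d <- dim(xv); HW <- d[3] * d[4]
  out <- matrix(rowSums(matrix(xv, d[1] * d[2], HW)) / HW, d[1], d[2])
  tn(out, list(x), function(g) {
    list(array(g / HW, d))
  })
}

# max over the channel axis -> (N, 1, H, W); ties to the lowest channel
tn_channel_max <- function(x) {
  xv <- x$value
  d <- dim(xv); C <- d[2]
  m <- xv[, 1L, , , drop = FALSE]
  if (C > 1L) for (c in 2:C) m <- pmax(m, xv[, c, , , drop = FALSE])
  tn(m, list(x), function(g) {
    dx <- array(0, d)
    claimed <- array(FALSE, dim(m))
    for (c in seq_len(C)) {
      sel <- (xv[, c, , , drop = FALSE] == m) & !claimed
      claimed <- claimed | sel
      dx[, c, , ] <- g * sel
    }
    list(dx)
  })
}

# mean over the channel axis -> (N, 1, H, W)
tn_channel_mean <- function(x) {
  xv <- x$value
  d <- dim(xv); C <- d[2]
  out <- array(colSums(matrix(aperm(xv, c(2L, 1L, 3L, 4L)), C)) / C,
               c(d[1], 1L, d[3], d[4]))
  tn(out, list(x), function(g) {
    list(g[, rep(1L, C), , , drop = FALSE] / C)
  })
}

# concatenate along the channel axis
tn_concat_channels <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  out <- array(0, c(da[1], da[2] + db[2], da[3], da[4]))
  out[, seq_len(da[2]), , ] <- av
  out[, da[2] + seq_len(db[2]), , ] <- bv
  tn(out, list(a, b), function(g) {
    list(g[, seq_len(da[2]), , , drop = FALSE],
         g[, da[2] + seq_len(db[2]), , , drop = FALSE])
  })
}

# add a (T, D) positional table to every sample of an (N, T, D) sequence
tn_add_pos <- function(x, pos) {
  xv <- x$value; pv <- pos$value
  d <- dim(xv)
  parr <- aperm(array(pv, c(d[2], d[3], d[1])), c(3L, 1L, 2L))
  tn(xv + parr, list(x, pos), function(g) {
    list(g, matrix(colSums(matrix(g, d[1], d[2] * d[3])), d[2], d[3]))
  })
}
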