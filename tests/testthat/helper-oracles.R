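# Independent brute-force oracles. These deliberately use naive loops and a
# formulation separate from the package internals, so agreement is evidence
# of correctness rather than shared code.

oracle_dice <- function(p, t) {
  inter <- 0; np <- 0; nt <- 0
  for (i in seq_along(p)) {
    pi <- p[i] != 0; ti <- t[i] != 0
    if (pi && ti) inter <- inter + 1
    if (pi) np <- np + 1
    if (ti) nt <- nt + 1
  }
  if (np + nt == 0) return(1)
  2 * inter / (np + nt)
}

oracle_boundary <- function(m) {
  m <- m != 0
  H <- nrow(m); W <- ncol(m)
  pts <- NULL
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!m[r, c]) next
    nb <- c(
      if (r > 1) m[r - 1, c] else FALSE,
      if (r < H) m[r + 1, c] else FALSE,
      if (c > 1) m[r, c - 1] else FALSE,
      if (c < W) m[r, c + 1] else FALSE
    )
    if (!all(nb)) pts <- rbind(pts, c(r, c))
  }
  pts
}

oracle_hausdorff <- function(a, b, spacing = c(1, 1)) {
  A <- oracle_boundary(a); B <- oracle_boundary(b)
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    dmat[i, j] <- sqrt(sum(((A[i, ] - B[j, ]) * spacing)^2))
  }
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

oracle_confusion <- function(p, t) {
  TP <- TN <- FP <- FN <- 0
  for (i in seq_along(p)) {
    pi <- p[i] != 0; ti <- t[i] != 0
    if (pi && ti) TP <- TP + 1
    if (!pi && !ti) TN <- TN + 1
    if (pi && !ti) FP <- FP + 1
    if (!pi && ti) FN <- FN + 1
  }
  c(TP = TP, TN = TN, FP = FP, FN = FN)
}

# reference spatial self-attention: explicit affinity softmax over positions
oracle_position_attention <- function(x, Wq, Wk, Wv, gamma) {
  # x: (1, C, H, W); W*: (Cout, C) 1x1 projections
  d <- dim(x)
  C <- d[2]; H <- d[3]; W <- d[4]
  HW <- H * W
  feat <- matrix(0, HW, C)  # token t = (h, w), h fastest
  for (w in seq_len(W)) for (h in seq_len(H)) {
    feat[(w - 1) * H + h, ] <- x[1, , h, w]
  }
  Q <- feat %*% t(Wq); K <- feat %*% t(Wk); V <- feat %*% t(Wv)
  E <- matrix(0, HW, HW)
  for (i in seq_len(HW)) for (j in seq_len(HW)) E[i, j] <- sum(Q[i, ] * K[j, ])
  A <- matrix(0, HW, HW)
  for (i in seq_len(HW)) A[i, ] <- exp(E[i, ] - max(E[i, ])) /
      sum(exp(E[i, ] - max(E[i, ])))
  O <- A %*% V
  out <- x
  for (w in seq_len(W)) for (h in seq_len(H)) {
    out[1, , h, w] <- gamma * O[(w - 1) * H + h, ] + x[1, , h, w]
  }
  out
}

# reference channel self-attention: C x C Gram affinity softmax
oracle_channel_attention <- function(x, gamma) {
  d <- dim(x)
  C <- d[2]; HW <- d[3] * d[4]
  feat <- matrix(0, C, HW)
  for (c in seq_len(C)) feat[c, ] <- as.vector(x[1, c, , ])
  E <- feat %*% t(feat)
  A <- matrix(0, C, C)
  for (i in seq_len(C)) A[i, ] <- exp(E[i, ] - max(E[i, ])) /
      sum(exp(E[i, ] - max(E[i, ])))
  O <- A %*% feat
  out <- x
  for (c in seq_len(C)) out[1, c, , ] <- gamma * O[c, ] + as.vector(x[1, c, , ])
  out
}

random_mask <- function(size, p = 0.4) {
  matrix(stats::runif(size * size) < p, size, size) * 1L
}

# a random mask guaranteed nonempty
random_mask_nonempty <- function(size, p = 0.4) {
  repeat {
    m <- random_mask(size, p)
    if (sum(m) > 0) return(m)
  }
}
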