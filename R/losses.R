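# Compound training loss: equal-weight sum of pixelwise cross-entropy and a
# soft Dice loss on the class probability maps,
#   L = 1/2 CE + 1/2 (1 - mean_k softDice_k),
# with additive smoothing eps in the Dice numerator and denominator. For a
# single-channel head the cross-entropy term is the binary (logistic)
# cross-entropy and the Dice term is computed on the foreground map.

loss_eps <- 1e-5

# custom tape op: returns scalar tn with analytic gradient wrt logits
tn_compound_loss <- function(logits, labels, K) {
  lv <- logits$value
  d <- dim(lv)
  labv <- as.integer(labels)
  if (any(labv < 0L) || any(labv > max(K - 1L, 1L))) {
    stop("labels outside [0, K-1]")
  }
  M <- d[1] * d[3] * d[4]
  if (length(labv) != M) stop("label array shape mismatch with logits")
  if (K == 1L) {
    z <- as.numeric(to_cm(lv))
    t <- labv
    p <- 1 / (1 + exp(-z))
    ce <- mean(log1p(exp(-abs(z))) + pmax(z, 0) - z * t)
    sp <- sum(p); st <- sum(t); spt <- sum(p * t)
    dice <- (2 * spt + loss_eps) / (sp + st + loss_eps)
    val <- 0.5 * ce + 0.5 * (1 - dice)
    tn(val, list(logits), function(g) {
      g <- as.numeric(g)
      ddice_dp <- (2 * t * (sp + st + loss_eps) - (2 * spt + loss_eps)) /
        (sp + st + loss_eps)^2
      dz <- 0.5 * (p - t) / M - 0.5 * ddice_dp * p * (1 - p)
      list(from_cm(matrix(g * dz, M, 1L), d))
    })
  } else {
    Lm <- to_cm(lv)                     # M x K, rows ordered like labels
    mx <- apply(Lm, 1L, max)
    Ls <- Lm - mx
    lse <- log(rowSums(exp(Ls)))
    P <- exp(Ls - lse)
    idx <- cbind(seq_len(M), labv + 1L)
    ce <- -mean(Ls[idx] - lse)
    Tm <- matrix(0, M, K)
    Tm[idx] <- 1
    sp <- colSums(P); st <- colSums(Tm); spt <- colSums(P * Tm)
    dice_k <- (2 * spt + loss_eps) / (sp + st + loss_eps)
    val <- 0.5 * ce + 0.5 * (1 - mean(dice_k))
    tn(val, list(logits), function(g) {
      g <- as.numeric(g)
      dLdp <- sweep(Tm, 2L,
                    2 * (sp + st + loss_eps) / (sp + st + loss_eps)^2, `*`)
      dLdp <- sweep(dLdp, 2L,
                    (2 * spt + loss_eps) / (sp + st + loss_eps)^2, `-`)
      dLdp <- -0.5 / K * dLdp           # d(0.5*(1-mean dice))/dP
      dCE <- 0.5 * (P - Tm) / M
      dLm <- dCE + P * (dLdp - rowSums(dLdp * P))
      list(from_cm(g * dLm, d))
    })
  }
}

#' Compound segmentation loss
#'
#' Equal-weight cross-entropy plus soft-Dice loss.
#'
#' @param logits numeric `(batch, K, row, col)` array of raw class scores
#'   (`K = 1` for a binary logistic head).
#' @param labels integer `(batch, row, col)` array of class labels in
#'   `[0, K-1]` (`0/1` for the binary head).
#' @return scalar loss value.
#' @examples
#' logits <- array(0, c(1, 9, 4, 4))
#' labels <- array(0L, c(1, 4, 4))
#' compound_loss(logits, labels)  # 0.5 * log(9) + 0.5 * dice term
#' @export
compound_loss <- function(logits, labels) {
  if (length(dim(logits)) != 4L) stop("logits must be (batch, K, row, col)")
  K <- dim(logits)[2]
  as.numeric(tn_compound_loss(tn_const(logits), labels, K)$value)
}

#' Cross-entropy and Dice components of the compound loss
#'
#' @inheritParams compound_loss
#' @return named numeric vector with `ce`, `dice_loss` and `total`.
#' @export
compound_loss_parts <- function(logits, labels) {
  d <- dim(logits)
  K <- d[2]
  M <- d[1] * d[3] * d[4]
  labv <- as.integer(labels)
  if (K == 1L) {
    z <- as.numeric(to_cm(logits))
    p <- 1 / (1 + exp(-z))
    ce <- mean(log1p(exp(-abs(z))) + pmax(z, 0) - z * labv)
    dice <- (2 * sum(p * labv) + loss_eps) /
      (sum(p) + sum(labv) + loss_eps)
  } else {
    Lm <- to_cm(logits)
    mx <- apply(Lm, 1L, max)
    Ls <- Lm - mx
    lse <- log(rowSums(exp(Ls)))
    P <- exp(Ls - lse)
    idx <- cbind(seq_len(M), labv + 1L)
    ce <- -mean(Ls[idx] - lse)
    Tm <- matrix(0, M, K); Tm[idx] <- 1
    dice <- mean((2 * colSums(P * Tm) + loss_eps) /
                   (colSums(P) + colSums(Tm) + loss_eps))
  }
  c(ce = ce, dice_loss = 1 - dice, total = 0.5 * ce + 0.5 * (1 - dice))
}
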