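# -- Tape-based reverse-mode autodiff on dense numeric arrays ------------------
#
# Every differentiable quantity is a "tn" node: an environment holding the
# forward value, an accumulated gradient, the parent nodes and a backward
# closure mapping the upstream gradient to per-parent gradients.  The engine
# is deliberately minimal: dense arrays, stride-1 convolutions expressed as
# BLAS matrix products, no broadcasting beyond what the layers need.
# Array layout everywhere is (batch, channel, row, col) for feature maps and
# (batch, token, dim) for token sequences.

.tn_env <- new.env(parent = emptyenv())
.tn_env$id <- 0L

tn_next_id <- function() {
  .tn_env$id <- .tn_env$id + 1L
  .tn_env$id
}

#' Create an autodiff node
#'
#' Wraps a numeric array as a node on the differentiation tape. Users of the
#' package normally never call this directly; layers and models do.
#'
#' @param value numeric array (any dimensionality).
#' @param parents list of parent `tn` nodes this value was computed from.
#' @param backward function mapping the upstream gradient (array shaped like
#'   `value`) to a list of gradients, one per parent (NULL entries allowed).
#' @param requires logical; whether gradients should flow into this node.
#' @param name optional label used in parameter listings.
#' @return an object of class `tn`.
#' @keywords internal
tn <- function(value, parents = list(), backward = NULL, requires = NULL,
               name = "") {
  if (is.null(requires)) {
    requires <- length(parents) > 0 &&
      any(vapply(parents, function(p) p$requires, logical(1)))
  }
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- if (requires) parents else list()
  e$backward <- if (requires) backward else NULL
  e$requires <- requires
  e$is_param <- FALSE
  e$name <- name
  e$id <- tn_next_id()
  class(e) <- "tn"
  e
}

#' Create a trainable parameter node
#' @param value initial numeric array.
#' @param name parameter label.
#' @keywords internal
tn_param <- function(value, name = "") {
  p <- tn(value, requires = TRUE, name = name)
  p$is_param <- TRUE
  p$momentum <- NULL
  p
}

tn_const <- function(value) tn(value, requires = FALSE)

is_tn <- function(x) inherits(x, "tn")

as_tn <- function(x) if (is_tn(x)) x else tn_const(x)

#' @export
print.tn <- function(x, ...) {
  d <- dim(x$value)
  cat(sprintf("<tn%s %s [%s]%s>\n",
              if (x$is_param) " param" else "",
              x$name,
              paste(if (is.null(d)) length(x$value) else d, collapse = "x"),
              if (x$requires) " grad" else ""))
  invisible(x)
}

# Topological order via iterative DFS (the graph can be a few hundred deep).
tn_topo <- function(root) {
  topo <- vector("list", 256L)
  n_topo <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  assign(as.character(root$id), TRUE, envir = visited)
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    node <- top$node
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      child <- node$parents[[top$i + 1L]]
      key <- as.character(child$id)
      if (child$requires && !exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
      }
    } else {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  topo[seq_len(n_topo)]
}

#' Run backpropagation from a scalar node
#'
#' Accumulates gradients into every reachable node with `requires = TRUE`
#' (parameters keep them until [tn_zero_grad()]).
#' @param root scalar `tn` node (typically a loss).
#' @keywords internal
tn_backward <- function(root) {
  stopifnot(length(root$value) == 1L)
  topo <- tn_topo(root)
  root$grad <- array(1, dim = dim(root$value) %||% 1L)
  for (k in rev(seq_along(topo))) {
    node <- topo[[k]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (i in seq_along(node$parents)) {
      p <- node$parents[[i]]
      if (!p$requires || is.null(gs[[i]])) next
      if (is.null(p$grad)) p$grad <- gs[[i]] else p$grad <- p$grad + gs[[i]]
    }
    if (!node$is_param) node$grad <- NULL  # free as we go
  }
  invisible(root)
}

tn_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- elementwise ops -----------------------------------------------------------

tn_add <- function(a, b) {
  a <- as_tn(a); b <- as_tn(b)
  tn(a$value + b$value, list(a, b), function(g) list(g, g))
}

tn_sub <- function(a, b) {
  a <- as_tn(a); b <- as_tn(b)
  tn(a$value - b$value, list(a, b), function(g) list(g, -g))
}

tn_mul <- function(a, b) {
  a <- as_tn(a); b <- as_tn(b)
  av <- a$value; bv <- b$value
  tn(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

tn_scale <- function(a, s) {
  stopifnot(is.numeric(s), length(s) == 1L)
  tn(a$value * s, list(a), function(g) list(g * s))
}

# y = s * a where s is a scalar *parameter* (attention scale gamma)
tn_scale_param <- function(a, s) {
  av <- a$value; sv <- as.numeric(s$value)
  tn(av * sv, list(a, s),
     function(g) list(g * sv, array(sum(g * av), dim = dim(s$value) %||% 1L)))
}

tn_relu <- function(a) {
  m <- a$value > 0
  tn(a$value * m, list(a), function(g) list(g * m))
}

tn_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  tn(s, list(a), function(g) list(g * s * (1 - s)))
}

tn_gelu <- function(a) {
  av <- a$value
  ph <- stats::pnorm(av)
  tn(av * ph, list(a),
     function(g) list(g * (ph + av * stats::dnorm(av))))
}

tn_sum <- function(a) {
  d <- dim(a$value)
  tn(sum(a$value), list(a), function(g) list(array(as.numeric(g), dim = d)))
}

tn_mean <- function(a) {
  d <- dim(a$value); n <- length(a$value)
  tn(mean(a$value), list(a),
     function(g) list(array(as.numeric(g) / n, dim = d)))
}

# -- linear algebra ------------------------------------------------------------

tn_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  tn(av %*% bv, list(a, b),
     function(g) list(g %*% t(bv), t(av) %*% g))
}

# y = X W + b over the last axis of X (X: (..., D), W: D x Dout, b: Dout)
tn_linear <- function(x, W, b) {
  xv <- x$value
  d <- dim(xv)
  D <- d[length(d)]
  Xm <- matrix(xv, ncol = D)
  Wv <- W$value
  out <- Xm %*% Wv
  out <- sweep(out, 2L, b$value, `+`)
  od <- c(d[-length(d)], ncol(Wv))
  tn(array(out, od), list(x, W, b), function(g) {
    Gm <- matrix(g, ncol = ncol(Wv))
    list(array(Gm %*% t(Wv), d), t(Xm) %*% Gm, colSums(Gm))
  })
}

# Regroup an array: reshape to `split_dim`, permute axes by `perm`, then
# flatten to `final_dim`. Exactly invertible, so the backward pass is the
# reverse regroup. Handles patch extraction, token (un)gridding and
# attention-head splitting.
tn_arrange <- function(x, split_dim, perm, final_dim) {
  xv <- x$value
  d0 <- dim(xv)
  pv <- aperm(array(xv, split_dim), perm)
  out <- array(pv, final_dim)
  permuted_dim <- split_dim[perm]
  invperm <- order(perm)
  tn(out, list(x), function(g) {
    gv <- array(g, permuted_dim)
    list(array(aperm(gv, invperm), d0))
  })
}

# softmax over rows of a matrix, returning value only (helper, not a node)
row_softmax <- function(E) {
  mx <- E[cbind(seq_len(nrow(E)), max.col(E, ties.method = "first"))]
  P <- exp(E - mx)
  P / rowSums(P)
}

# dE from dA for row softmax A
row_softmax_back <- function(A, dA) {
  A * (dA - rowSums(dA * A))
}

# Batched scaled dot-product attention.
# q,k: (B, T, Dk), v: (B, T, Dv). Returns (B, T, Dv).
tn_attend <- function(q, k, v, scale = 1) {
  qv <- q$value; kv <- k$value; vv <- v$value
  B <- dim(qv)[1]; Tn <- dim(qv)[2]
  Dv <- dim(vv)[3]
  # sample-last copies so per-sample slices are contiguous
  qp <- aperm(qv, c(2L, 3L, 1L))
  kp <- aperm(kv, c(2L, 3L, 1L))
  vp <- aperm(vv, c(2L, 3L, 1L))
  outp <- array(0, c(Tn, Dv, B))
  As <- vector("list", B)
  for (n in seq_len(B)) {
    A <- row_softmax(tcrossprod(qp[, , n], kp[, , n]) * scale)
    As[[n]] <- A
    outp[, , n] <- A %*% vp[, , n]
  }
  tn(aperm(outp, c(3L, 1L, 2L)), list(q, k, v), function(g) {
    gp <- aperm(g, c(2L, 3L, 1L))
    dq <- array(0, dim(qp)); dk <- array(0, dim(kp)); dv <- array(0, dim(vp))
    for (n in seq_len(B)) {
      G <- gp[, , n]
      A <- As[[n]]
      dA <- tcrossprod(G, vp[, , n])
      dv[, , n] <- crossprod(A, G)
      dE <- row_softmax_back(A, dA) * scale
      dq[, , n] <- dE %*% kp[, , n]
      dk[, , n] <- crossprod(dE, qp[, , n])
    }
    list(aperm(dq, c(3L, 1L, 2L)), aperm(dk, c(3L, 1L, 2L)),
         aperm(dv, c(3L, 1L, 2L)))
  })
}

# Channel self-attention core: for each sample, affinity softmax over the
# C x C Gram matrix of channel descriptors, applied back to the channels.
# x: (N, C, H, W) -> (N, C, H, W).
tn_channel_attend <- function(x) {
  xv <- x$value
  d <- dim(xv); N <- d[1]; C <- d[2]; HW <- d[3] * d[4]
  xp <- array(aperm(xv, c(2L, 3L, 4L, 1L)), c(C, HW, N))
  outp <- array(0, c(C, HW, N))
  As <- vector("list", N)
  for (n in seq_len(N)) {
    Xf <- xp[, , n]
    A <- row_softmax(tcrossprod(Xf))
    As[[n]] <- A
    outp[, , n] <- A %*% Xf
  }
  out <- aperm(array(outp, c(C, d[3], d[4], N)), c(4L, 1L, 2L, 3L))
  tn(out, list(x), function(g) {
    gp <- array(aperm(g, c(2L, 3L, 4L, 1L)), c(C, HW, N))
    dxp <- array(0, c(C, HW, N))
    for (n in seq_len(N)) {
      G <- gp[, , n]
      Xf <- xp[, , n]
      A <- As[[n]]
      dA <- tcrossprod(G, Xf)
      dXf <- crossprod(A, G)
      dE <- row_softmax_back(A, dA)
      dXf <- dXf + (dE + t(dE)) %*% Xf
      dxp[, , n] <- dXf
    }
    list(aperm(array(dxp, c(C, d[3], d[4], N)), c(4L, 1L, 2L, 3L)))
  })
}
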