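# central finite differences on a scalar-valued function of an array
numeric_grad <- function(fn, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_fast_config <- function(...) {
  tiny_config(input_size = 32L, base_channels = 4L, num_classes = 3L,
              embed_dim = 16L, mlp_dim = 32L, transformer_heads = 2L, ...)
}

tiny_fast_phantoms <- function(n = 4L, seed = 11L, ...) {
  generate_phantoms(phantom_spec(n_images = n, image_size = 32L,
                                 n_classes = 3L, radius_range = c(4, 7),
                                 seed = seed, ...))
}
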