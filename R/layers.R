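# Layer constructors. A "layer" is a plain list (or environment where mutable
# running state is needed) holding tn_param nodes; forward passes are explicit
# functions. Weight initialisation draws from the current RNG stream, so
# builders wrap construction in with_seed() for reproducibility.

with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# bias = FALSE for convolutions feeding batch norm (a mean shift would be
# removed by the normalisation, leaving the bias without gradient)
layer_conv2d <- function(cin, cout, k, name = "conv", bias = TRUE) {
  list(
    kind = "conv2d",
    W = tn_param(he_init(c(cout, cin, k, k), cin * k * k), paste0(name, ".W")),
    b = if (bias) {
      tn_param(numeric(cout), paste0(name, ".b"))
    } else tn_const(numeric(cout))
  )
}

conv_fwd <- function(layer, x) tn_conv2d(x, layer$W, layer$b)

layer_linear <- function(din, dout, name = "fc") {
  list(
    kind = "linear",
    W = tn_param(array(stats::rnorm(din * dout, sd = sqrt(1 / din)),
                       c(din, dout)), paste0(name, ".W")),
    b = tn_param(numeric(dout), paste0(name, ".b"))
  )
}

linear_fwd <- function(layer, x) tn_linear(x, layer$W, layer$b)

layer_bn <- function(C, name = "bn") {
  e <- new.env(parent = emptyenv())
  e$kind <- "batchnorm"
  e$gamma <- tn_param(rep(1, C), paste0(name, ".gamma"))
  e$beta <- tn_param(numeric(C), paste0(name, ".beta"))
  e$run_mean <- numeric(C)
  e$run_var <- rep(1, C)
  e$eps <- 1e-5
  e$mom <- 0.1
  e
}

layer_ln <- function(D, name = "ln") {
  list(
    kind = "layernorm",
    gamma = tn_param(rep(1, D), paste0(name, ".gamma")),
    beta = tn_param(numeric(D), paste0(name, ".beta"))
  )
}

ln_fwd <- function(layer, x) tn_layernorm(x, layer$gamma, layer$beta)

# conv -> batchnorm -> relu unit
layer_cbr <- function(cin, cout, k = 3L, name = "cbr") {
  list(kind = "cbr",
       conv = layer_conv2d(cin, cout, k, paste0(name, ".conv"), bias = FALSE),
       bn = layer_bn(cout, paste0(name, ".bn")))
}

cbr_fwd <- function(layer, x, train) {
  tn_relu(tn_batchnorm(conv_fwd(layer$conv, x), layer$bn, train))
}

# -- parameter bookkeeping -----------------------------------------------------

#' Collect trainable parameters from a layer or model
#'
#' Recursively walks nested lists/environments and returns every trainable
#' parameter node found, named by its label.
#' @param obj a layer, block or model object.
#' @return named list of parameter nodes.
#' @export
collect_params <- function(obj) {
  out <- list()
  walk <- function(o) {
    if (is_tn(o)) {
      if (o$is_param) out[[length(out) + 1L]] <<- o
      return(invisible())
    }
    if (is.environment(o)) {
      for (nm in ls(o)) {
        v <- get(nm, envir = o)
        if (is_tn(v) || is.list(v) || is.environment(v)) walk(v)
      }
      return(invisible())
    }
    if (is.list(o)) for (el in o) {
      if (is_tn(el) || is.list(el) || is.environment(el)) walk(el)
    }
    invisible()
  }
  walk(obj)
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

#' Total number of scalar parameters
#' @param obj a layer, block or model object.
#' @return integer count of scalar weights.
#' @export
n_parameters <- function(obj) {
  sum(vapply(collect_params(obj), function(p) length(p$value), numeric(1)))
}

#' Set every trainable parameter of a block to zero
#'
#' Test and diagnostics hook: with all weights (including attention scales)
#' at zero, the attention blocks collapse to analytically known maps.
#' @param obj a layer, block or model object.
#' @return the object, invisibly (parameters are modified in place).
#' @export
zero_params <- function(obj) {
  for (p in collect_params(obj)) p$value[] <- 0
  invisible(obj)
}
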