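# Model assembly: a U-shaped encoder-decoder with a transformer bottleneck.
# Three convolutional stages halve the resolution and double the width, a
# MIPC block purifies the deepest features before patch embedding and the
# transformer, and the decoder fuses upsampled features with (optionally
# dual-attention-purified) skips, with an optional skip-residue path that
# re-injects a MIPC-purified decoder feature into configured skip levels.

#' Model configuration
#'
#' Validates and stores every architectural knob, including the ablation
#' flags that reproduce the variant grids of the ablation study.
#'
#' @param input_size square input resolution in pixels; must be divisible by
#'   8 (three halvings) and then by `patch_size`.
#' @param patch_size token patch edge on the 1/8-resolution bottleneck map;
#'   the effective input-pixel patch is `8 * patch_size` (the default 2 on a
#'   224-pixel input corresponds to an effective 16-pixel patch).
#' @param in_channels image channels (1 grayscale, 3 RGB).
#' @param num_classes number of segmentation classes K including background;
#'   `1` selects a binary logistic head.
#' @param base_channels width of the first convolutional stage; stages use
#'   `base_channels * c(1, 2, 4)`.
#' @param transformer_depth,transformer_heads,embed_dim,mlp_dim transformer
#'   bottleneck shape. Defaults are desk-scale; a published-scale preset
#'   would be depth 12, embed 768.
#' @param attention an [attention_params()] object shared by all blocks.
#' @param use_encoder_mipc place a MIPC block before the patch embedding.
#' @param mutual_inclusion `FALSE` builds the "PC" baseline in which the
#'   attention paths are independent (no cross-gating).
#' @param mix_variant which branch of each attention pair is primary; see
#'   [mipc_layer()].
#' @param da_skip purify every skip connection with a dual-attention block.
#' @param skip_residue_layers integer subset of `c(1, 2, 3)` (1 = highest
#'   resolution skip) receiving the skip-residue injection; default `1`.
#' @param seed integer seed for weight initialisation.
#' @return a validated `model_config` object.
#' @export
model_config <- function(input_size = 224L, patch_size = 2L, in_channels = 1L,
                         num_classes = 9L, base_channels = 64L,
                         transformer_depth = 2L, transformer_heads = 4L,
                         embed_dim = 128L, mlp_dim = 2L * embed_dim,
                         attention = attention_params(),
                         use_encoder_mipc = TRUE, mutual_inclusion = TRUE,
                         mix_variant = "pam_cpool.cam_ppool", da_skip = TRUE,
                         skip_residue_layers = 1L, seed = 1L) {
  input_size <- as.integer(input_size)
  patch_size <- as.integer(patch_size)
  if (input_size %% 8L != 0L) {
    stop("input_size must be divisible by 2^3 = 8 (three conv stages)")
  }
  bottleneck <- input_size %/% 8L
  if (bottleneck %% patch_size != 0L) {
    stop("input_size / 8 must be divisible by patch_size")
  }
  if (num_classes < 1L) stop("num_classes must be >= 1")
  if (embed_dim %% transformer_heads != 0L) {
    stop("embed_dim must be divisible by transformer_heads")
  }
  skip_residue_layers <- sort(unique(as.integer(skip_residue_layers)))
  if (length(skip_residue_layers) > 0 &&
      !all(skip_residue_layers %in% 1:3)) {
    stop("skip_residue_layers must be a subset of {1, 2, 3}")
  }
  if (!mix_variant %in% mix_variants()) {
    stop("mix_variant must be one of: ",
         paste(mix_variants(), collapse = ", "),
         " (primary_auxiliary for Part A . Part C)")
  }
  structure(list(
    input_size = input_size, patch_size = patch_size,
    in_channels = as.integer(in_channels),
    num_classes = as.integer(num_classes),
    base_channels = as.integer(base_channels),
    num_conv_stages = 3L,
    transformer_depth = as.integer(transformer_depth),
    transformer_heads = as.integer(transformer_heads),
    embed_dim = as.integer(embed_dim), mlp_dim = as.integer(mlp_dim),
    attention = attention,
    use_encoder_mipc = isTRUE(use_encoder_mipc),
    mutual_inclusion = isTRUE(mutual_inclusion),
    mix_variant = mix_variant,
    da_skip = isTRUE(da_skip),
    skip_residue_layers = skip_residue_layers,
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Desk-scale configuration preset
#'
#' A small configuration (64-pixel inputs, 8 base channels, depth-2
#' transformer) that trains in minutes on one CPU; used throughout the
#' tests and examples.
#' @param ... overrides passed to [model_config()].
#' @export
tiny_config <- function(...) {
  args <- list(input_size = 64L, patch_size = 2L, in_channels = 1L,
               num_classes = 4L, base_channels = 8L, transformer_depth = 2L,
               transformer_heads = 4L, embed_dim = 32L, mlp_dim = 64L,
               attention = attention_params(reduction_ratio = 4L))
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "<model_config %dpx K=%d base=%d depth=%d embed=%d%s%s mix=%s da=%s sr={%s}>\n",
    x$input_size, x$num_classes, x$base_channels, x$transformer_depth,
    x$embed_dim,
    if (x$use_encoder_mipc) " enc-mipc" else "",
    if (x$mutual_inclusion) "" else " PC-variant",
    x$mix_variant, x$da_skip,
    paste(x$skip_residue_layers, collapse = ",")))
  invisible(x)
}

new_transformer_block <- function(D, heads, mlp_dim, name = "tf") {
  list(kind = "transformer_block", heads = heads,
       ln1 = layer_ln(D, paste0(name, ".ln1")),
       q = layer_linear(D, D, paste0(name, ".q")),
       k = layer_linear(D, D, paste0(name, ".k")),
       v = layer_linear(D, D, paste0(name, ".v")),
       proj = layer_linear(D, D, paste0(name, ".proj")),
       ln2 = layer_ln(D, paste0(name, ".ln2")),
       fc1 = layer_linear(D, mlp_dim, paste0(name, ".fc1")),
       fc2 = layer_linear(mlp_dim, D, paste0(name, ".fc2")))
}

split_heads <- function(x, h) {
  d <- dim(x$value)  # (N, T, D)
  dh <- d[3] %/% h
  tn_arrange(x, c(d[1], d[2], dh, h), c(1L, 4L, 2L, 3L),
             c(d[1] * h, d[2], dh))
}

merge_heads <- function(x, h, N) {
  d <- dim(x$value)  # (N*h, T, dh)
  tn_arrange(x, c(N, h, d[2], d[3]), c(1L, 3L, 4L, 2L),
             c(N, d[2], d[3] * h))
}

transformer_block_fwd <- function(blk, x) {
  d <- dim(x$value); N <- d[1]; h <- blk$heads
  xn <- ln_fwd(blk$ln1, x)
  q <- split_heads(linear_fwd(blk$q, xn), h)
  k <- split_heads(linear_fwd(blk$k, xn), h)
  v <- split_heads(linear_fwd(blk$v, xn), h)
  dh <- d[3] %/% h
  att <- merge_heads(tn_attend(q, k, v, scale = 1 / sqrt(dh)), h, N)
  x <- tn_add(x, linear_fwd(blk$proj, att))
  xn <- ln_fwd(blk$ln2, x)
  tn_add(x, linear_fwd(blk$fc2, tn_gelu(linear_fwd(blk$fc1, xn))))
}

#' Build a segmentation model
#'
#' Assembles the full network described by a [model_config()], with seeded
#' weight initialisation: three convolutional stages emitting skip features
#' at 1/2, 1/4 and 1/8 resolution, an optional MIPC block, patch embedding
#' plus a pre-norm transformer, and a decoder with dual-attention skip
#' purification and skip-residue injection.
#'
#' @param cfg a [model_config()] object.
#' @return an object of class `mipc_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  base <- cfg$base_channels
  widths <- base * c(1L, 2L, 4L)
  bneck_px <- cfg$input_size %/% 8L
  tokens_side <- bneck_px %/% cfg$patch_size
  n_tokens <- tokens_side^2
  D <- cfg$embed_dim
  layers <- with_seed(cfg$seed, function() {
    l <- list()
    ins <- c(cfg$in_channels, widths[1], widths[2])
    for (s in 1:3) {
      l[[paste0("stage", s)]] <- list(
        cbr1 = layer_cbr(ins[s], widths[s], 3L, paste0("enc", s, ".cbr1")),
        cbr2 = layer_cbr(widths[s], widths[s], 3L, paste0("enc", s, ".cbr2")))
    }
    if (cfg$use_encoder_mipc) {
      l$enc_mipc <- mipc_layer(widths[3], cfg$attention,
                               mutual_inclusion = cfg$mutual_inclusion,
                               mix_variant = cfg$mix_variant)
    }
    l$patch_embed <- layer_linear(cfg$patch_size^2 * widths[3], D, "embed")
    l$pos <- tn_param(array(stats::rnorm(n_tokens * D, sd = 0.02),
                            c(n_tokens, D)), "pos")
    l$tf <- lapply(seq_len(cfg$transformer_depth), function(i) {
      new_transformer_block(D, cfg$transformer_heads, cfg$mlp_dim,
                            paste0("tf", i))
    })
    l$tf_ln <- layer_ln(D, "tf.ln")
    l$bneck_proj <- layer_conv2d(D, widths[3], 1L, "bneck")
    if (cfg$da_skip) {
      l$da <- lapply(1:3, function(s) da_layer(widths[s], cfg$attention))
    }
    for (s in cfg$skip_residue_layers) {
      l[[paste0("sr_mipc", s)]] <-
        mipc_layer(widths[s], cfg$attention,
                   mutual_inclusion = cfg$mutual_inclusion,
                   mix_variant = cfg$mix_variant)
      l[[paste0("sr_proj", s)]] <-
        layer_conv2d(widths[s], widths[s], 1L, paste0("srproj", s))
    }
    # decoder: level 3 -> 1; up-conv keeps the skip width, fusion halves it
    fuse_out <- c(base, base, 2L * base)  # indexed by level
    for (s in 3:1) {
      cin_up <- if (s == 3) widths[3] else fuse_out[s + 1]
      l[[paste0("up", s)]] <- layer_cbr(cin_up, widths[s], 3L,
                                        paste0("up", s))
      l[[paste0("fuse", s)]] <- layer_cbr(2L * widths[s], fuse_out[s], 3L,
                                          paste0("fuse", s))
    }
    l$final_up <- layer_cbr(base, base, 3L, "final_up")
    l$head <- layer_conv2d(base, cfg$num_classes, 1L, "head")
    l
  })
  model <- list(cfg = cfg, layers = layers)
  class(model) <- "mipc_model"
  model$params <- collect_params(layers)
  model
}

#' @export
print.mipc_model <- function(x, ...) {
  cat(sprintf("<mipc_model: %s params>\n",
              format(n_parameters(x$layers), big.mark = ",")))
  print(x$cfg)
  invisible(x)
}

check_input_images <- function(model, img) {
  d <- dim(img)
  cfg <- model$cfg
  if (length(d) != 4L) stop("images must be (batch, channel, row, col)")
  if (d[2] != cfg$in_channels) stop("channel count mismatch with config")
  if (d[3] != cfg$input_size || d[4] != cfg$input_size) {
    stop(sprintf("image spatial dims must be %d x %d",
                 cfg$input_size, cfg$input_size))
  }
  invisible(d)
}

enc_fwd <- function(model, x, train = FALSE) {
  l <- model$layers
  cfg <- model$cfg
  skips <- vector("list", 3L)
  f <- x
  for (s in 1:3) {
    st <- l[[paste0("stage", s)]]
    f <- cbr_fwd(st$cbr2, cbr_fwd(st$cbr1, f, train), train)
    f <- tn_maxpool2(f)
    skips[[s]] <- f
  }
  if (cfg$use_encoder_mipc) f <- mipc_fwd(l$enc_mipc, f, train)
  d <- dim(f$value)  # (N, 4base, s8, s8)
  p <- cfg$patch_size
  hp <- d[3] %/% p
  tokens <- tn_arrange(f, c(d[1], d[2], p, hp, p, hp),
                       c(1L, 4L, 6L, 3L, 5L, 2L),
                       c(d[1], hp * hp, p * p * d[2]))
  tok <- tn_add_pos(linear_fwd(l$patch_embed, tokens), l$pos)
  for (blk in l$tf) tok <- transformer_block_fwd(blk, tok)
  tok <- ln_fwd(l$tf_ln, tok)
  dt <- dim(tok$value)
  grid <- tn_arrange(tok, c(dt[1], hp, hp, dt[3]), c(1L, 4L, 2L, 3L),
                     c(dt[1], dt[3], hp, hp))
  bneck <- conv_fwd(l$bneck_proj, grid)
  list(bottleneck = bneck, skips = skips)
}

sr_inject_tn <- function(model, level, dec_f, skip_f, train = FALSE) {
  if (!(level %in% model$cfg$skip_residue_layers)) return(skip_f)
  l <- model$layers
  purified <- mipc_fwd(l[[paste0("sr_mipc", level)]], dec_f, train)
  tn_add(skip_f, conv_fwd(l[[paste0("sr_proj", level)]], purified))
}

dec_fwd <- function(model, bottleneck, skips, train = FALSE) {
  l <- model$layers
  cfg <- model$cfg
  f <- bottleneck
  for (s in 3:1) {
    f <- cbr_fwd(l[[paste0("up", s)]], tn_upsample2(f), train)
    sk <- skips[[s]]
    if (dim(sk$value)[3] != dim(f$value)[3]) {
      stop("skip/decoder spatial dims mismatch")
    }
    if (cfg$da_skip) sk <- da_fwd(l$da[[s]], sk)
    sk <- sr_inject_tn(model, s, f, sk, train)
    f <- cbr_fwd(l[[paste0("fuse", s)]], tn_concat_channels(f, sk), train)
  }
  f <- cbr_fwd(l$final_up, tn_upsample2(f), train)
  conv_fwd(l$head, f)
}

model_fwd <- function(model, x, train = FALSE) {
  enc <- enc_fwd(model, x, train)
  dec_fwd(model, enc$bottleneck, enc$skips, train)
}

#' Run one encoder convolution stage
#'
#' Applies stage `stage_index` of the encoder (conv-BN-ReLU twice, then 2x2
#' max pooling): spatial dims halve and channels double relative to the
#' stage input (stage 1 maps the image channels to `base_channels`).
#'
#' @param model an `mipc_model`.
#' @param f numeric `(batch, channel, row, col)` array with the channel
#'   width this stage expects and even spatial dims.
#' @param stage_index stage number, 1 to 3.
#' @param train logical; batch-statistics mode.
#' @return array with halved spatial dims and this stage's output width.
#' @export
conv_stage <- function(model, f, stage_index, train = FALSE) {
  check_fmap(f)
  stopifnot(stage_index %in% 1:3)
  base <- model$cfg$base_channels
  exp_in <- c(model$cfg$in_channels, base, 2L * base)[stage_index]
  if (dim(f)[2] != exp_in) {
    stop(sprintf("stage %d expects %d input channels, got %d",
                 stage_index, exp_in, dim(f)[2]))
  }
  if (any(dim(f)[3:4] %% 2L != 0L)) stop("spatial dims must be even")
  st <- model$layers[[paste0("stage", stage_index)]]
  tn_maxpool2(cbr_fwd(st$cbr2, cbr_fwd(st$cbr1, tn_const(f), train),
                      train))$value
}

#' Encoder forward pass
#'
#' Runs images through the convolutional stages, optional MIPC block and
#' transformer bottleneck.
#' @param model an `mipc_model`.
#' @param images numeric `(batch, channel, row, col)` array at the configured
#'   input size.
#' @param train logical; batch-statistics mode for normalisation layers.
#' @return list with `bottleneck` (`(batch, 4*base, S/8/patch... )` map at
#'   token resolution) and `skips` (list of three arrays at 1/2, 1/4, 1/8
#'   resolution, highest resolution first).
#' @export
encoder_forward <- function(model, images, train = FALSE) {
  check_input_images(model, images)
  enc <- enc_fwd(model, tn_const(images), train)
  list(bottleneck = enc$bottleneck$value,
       skips = lapply(enc$skips, function(s) s$value))
}

#' Decoder forward pass
#' @param model an `mipc_model`.
#' @param bottleneck,skips arrays as returned by [encoder_forward()].
#' @param train logical; batch-statistics mode.
#' @return logits array `(batch, num_classes, input_size, input_size)`.
#' @export
decoder_forward <- function(model, bottleneck, skips, train = FALSE) {
  dec_fwd(model, tn_const(bottleneck), lapply(skips, tn_const), train)$value
}

#' Skip-residue injection
#'
#' Adds a MIPC-purified, 1x1-projected decoder feature to the skip feature at
#' `level`, if that level is configured in `skip_residue_layers`; otherwise
#' returns the skip feature unchanged.
#' @param model an `mipc_model`.
#' @param level skip level, 1 (highest resolution) to 3.
#' @param decoder_feature,skip_feature arrays with matching shapes.
#' @param train logical; batch-statistics mode.
#' @return array shaped like `skip_feature`.
#' @export
skip_residue_inject <- function(model, level, decoder_feature, skip_feature,
                                train = FALSE) {
  if (level %in% model$cfg$skip_residue_layers &&
      !identical(dim(decoder_feature)[3:4], dim(skip_feature)[3:4])) {
    stop("decoder and skip features must share spatial dims")
  }
  sr_inject_tn(model, level, tn_const(decoder_feature),
               tn_const(skip_feature), train)$value
}

#' Model prediction
#'
#' @param object an `mipc_model`.
#' @param images numeric `(batch, channel, row, col)` array; a single
#'   `(row, col)` matrix or `(batch, row, col)` array of grayscale images is
#'   promoted automatically.
#' @param type `"class"` for integer label masks (argmax over classes, or
#'   thresholded sigmoid for the binary head), `"prob"` for class
#'   probabilities, `"logits"` for the raw head output.
#' @param ... unused.
#' @return label array `(batch, row, col)` or array of
#'   probabilities/logits `(batch, K, row, col)`.
#' @export
predict.mipc_model <- function(object, images, type = c("class", "prob",
                                                        "logits"), ...) {
  type <- match.arg(type)
  images <- promote_images(object$cfg, images)
  check_input_images(object, images)
  logits <- model_fwd(object, tn_const(images), train = FALSE)$value
  if (type == "logits") return(logits)
  K <- object$cfg$num_classes
  if (type == "prob") {
    if (K == 1L) return(1 / (1 + exp(-logits)))
    d <- dim(logits)
    P <- row_softmax(to_cm(logits))
    return(from_cm(P, d))
  }
  logits_to_labels(logits, K)
}

logits_to_labels <- function(logits, K) {
  d <- dim(logits)
  if (K == 1L) {
    lab <- (logits[, 1L, , , drop = FALSE] > 0) * 1L
    return(array(as.integer(lab), c(d[1], d[3], d[4])))
  }
  m <- to_cm(logits)
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), c(d[1], d[3], d[4]))
}

promote_images <- function(cfg, images) {
  d <- dim(images)
  if (is.null(d) || length(d) == 2L) {
    images <- array(images, c(1L, 1L, dim(images)))
  } else if (length(d) == 3L) {
    images <- array(images, c(d[1], 1L, d[2], d[3]))
  }
  images
}
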