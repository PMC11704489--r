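# Mutual-inclusion attention blocks.
#
# The MIPC block combines three parallel parts computed from one shared input:
#  * Part A (position-dominant): a position self-attention map (PAM) gated
#    channel-wise by a squeeze-excitation summary (ChannelPool -> FC -> sigmoid).
#  * Part C (channel-dominant): a channel self-attention map (CAM) gated
#    pixel-wise by a spatial summary (PositionPool -> conv -> sigmoid).
#  * Part B (residual): two 3x3 convolutions of the input multiplied
#    elementwise, refined by a third convolution.
# The three outputs are added elementwise and passed through a basic residual
# tail (conv-BN-ReLU-conv-BN + identity, final ReLU).
#
# In every part the *auxiliary* branch passes through a sigmoid and gates the
# *primary* branch, which stays linear. The four mix variants permute which
# branch of each pair is primary.

#' Attention hyper-parameters
#'
#' Hyper-parameters shared by the gating paths of the attention blocks.
#'
#' @param reduction_ratio channel-gate bottleneck ratio; the hidden width is
#'   `max(1, floor(channels / reduction_ratio))`.
#' @param spatial_kernel odd kernel size of the spatial-gate convolution.
#' @param scale_init initial value of the learnable scale on the PAM/CAM
#'   attended output. Zero makes both modules exact identities at
#'   initialisation; the default is a small positive value so that the
#'   attention projections receive gradient from the first step.
#' @return an object of class `attention_params`.
#' @export
attention_params <- function(reduction_ratio = 16L, spatial_kernel = 7L,
                             scale_init = 0.1) {
  stopifnot(reduction_ratio >= 1, spatial_kernel >= 1,
            spatial_kernel %% 2L == 1L)
  structure(list(reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 scale_init = scale_init),
            class = "attention_params")
}

mix_variants <- function() {
  c("pam_cpool.cam_ppool", "pam_cpool.ppool_cam",
    "cpool_pam.cam_ppool", "cpool_pam.ppool_cam")
}

check_fmap <- function(f) {
  if (!is.numeric(f) && !is_tn(f)) stop("feature map must be numeric")
  v <- if (is_tn(f)) f$value else f
  if (length(dim(v)) != 4L) {
    stop("feature map must be a 4-axis (batch, channel, row, col) array")
  }
  if (!all(is.finite(v))) stop("feature map contains non-finite entries")
  if (any(dim(v)[3:4] < 1L)) stop("spatial dims must be positive")
  invisible(v)
}

# -- layer constructors --------------------------------------------------------

#' @rdname attention_ops
#' @export
channel_gate_layer <- function(channels, params = attention_params(),
                               seed = NULL) {
  build <- function() {
    hidden <- max(1L, channels %/% params$reduction_ratio)
    list(kind = "channel_gate",
         fc1 = layer_linear(channels, hidden, "cgate.fc1"),
         fc2 = layer_linear(hidden, channels, "cgate.fc2"))
  }
  if (is.null(seed)) build() else with_seed(seed, build)
}

channel_gate_logits <- function(layer, x) {
  pooled <- tn_gap(x)                       # (N, C)
  linear_fwd(layer$fc2, tn_relu(linear_fwd(layer$fc1, pooled)))
}

#' @rdname attention_ops
#' @export
spatial_gate_layer <- function(params = attention_params(), seed = NULL) {
  build <- function() {
    list(kind = "spatial_gate",
         conv = layer_conv2d(2L, 1L, params$spatial_kernel, "sgate.conv"))
  }
  if (is.null(seed)) build() else with_seed(seed, build)
}

spatial_gate_logits <- function(layer, x) {
  pooled <- tn_concat_channels(tn_channel_max(x), tn_channel_mean(x))
  conv_fwd(layer$conv, pooled)              # (N, 1, H, W)
}

#' @rdname attention_ops
#' @export
pam_layer <- function(channels, params = attention_params(), seed = NULL) {
  build <- function() {
    ck <- max(1L, channels %/% 8L)
    list(kind = "pam",
         q = layer_conv2d(channels, ck, 1L, "pam.q"),
         k = layer_conv2d(channels, ck, 1L, "pam.k"),
         v = layer_conv2d(channels, channels, 1L, "pam.v"),
         gamma = tn_param(params$scale_init, "pam.gamma"))
  }
  if (is.null(seed)) build() else with_seed(seed, build)
}

# tokens (N, H*W, C) view of an (N, C, H, W) map
map_to_tokens <- function(x) {
  d <- dim(x$value)
  tn_arrange(x, d, c(1L, 3L, 4L, 2L), c(d[1], d[3] * d[4], d[2]))
}

tokens_to_map <- function(x, d) {
  dt <- dim(x$value)
  tn_arrange(x, c(dt[1], d[3], d[4], dt[3]), c(1L, 4L, 2L, 3L), d)
}

pam_fwd <- function(layer, x) {
  d <- dim(x$value)
  if (d[3] * d[4] < 1L) stop("spatial size must be positive")
  q <- map_to_tokens(conv_fwd(layer$q, x))
  k <- map_to_tokens(conv_fwd(layer$k, x))
  v <- map_to_tokens(conv_fwd(layer$v, x))
  att <- tokens_to_map(tn_attend(q, k, v), d)
  tn_add(tn_scale_param(att, layer$gamma), x)
}

#' @rdname attention_ops
#' @export
cam_layer <- function(params = attention_params(), seed = NULL) {
  list(kind = "cam", gamma = tn_param(params$scale_init, "cam.gamma"))
}

cam_fwd <- function(layer, x) {
  tn_add(tn_scale_param(tn_channel_attend(x), layer$gamma), x)
}

#' @rdname attention_ops
#' @export
part_b_layer <- function(channels, seed = NULL) {
  build <- function() {
    list(kind = "part_b",
         conv_a = layer_conv2d(channels, channels, 3L, "partb.conv_a"),
         conv_c = layer_conv2d(channels, channels, 3L, "partb.conv_c"),
         conv_out = layer_conv2d(channels, channels, 3L, "partb.conv_out"))
  }
  if (is.null(seed)) build() else with_seed(seed, build)
}

part_b_fwd <- function(layer, x) {
  conv_fwd(layer$conv_out,
           tn_mul(conv_fwd(layer$conv_a, x), conv_fwd(layer$conv_c, x)))
}

#' @rdname attention_ops
#' @export
residual_tail_layer <- function(channels, seed = NULL) {
  build <- function() {
    list(kind = "residual_tail",
         conv1 = layer_conv2d(channels, channels, 3L, "tail.conv1",
                              bias = FALSE),
         bn1 = layer_bn(channels, "tail.bn1"),
         conv2 = layer_conv2d(channels, channels, 3L, "tail.conv2",
                              bias = FALSE),
         bn2 = layer_bn(channels, "tail.bn2"))
  }
  if (is.null(seed)) build() else with_seed(seed, build)
}

residual_tail_fwd <- function(layer, x, train = FALSE) {
  h <- tn_relu(tn_batchnorm(conv_fwd(layer$conv1, x), layer$bn1, train))
  h <- tn_batchnorm(conv_fwd(layer$conv2, h), layer$bn2, train)
  tn_relu(tn_add(h, x))
}

#' Construct a MIPC block
#'
#' Creates the full mutual-inclusion block: channel gate, position attention,
#' spatial gate, channel attention, residual part and residual tail. With
#' `mutual_inclusion = FALSE` the cross-gating paths are dropped, leaving
#' independent PAM and CAM branches (the "PC" baseline variant).
#'
#' @param channels number of feature channels the block operates on.
#' @param params an [attention_params()] object.
#' @param seed optional integer seed for weight initialisation.
#' @param mutual_inclusion logical; gate each attention path by the pooled
#'   summary of the other.
#' @param mix_variant one of `"pam_cpool.cam_ppool"` (default),
#'   `"pam_cpool.ppool_cam"`, `"cpool_pam.cam_ppool"`,
#'   `"cpool_pam.ppool_cam"`: which branch of each pair is primary (linear
#'   carrier) versus auxiliary (sigmoid gate), for Part A and Part C
#'   respectively.
#' @return a `mipc_layer` list usable with [mipc_block()] and the part-level
#'   operations.
#' @export
mipc_layer <- function(channels, params = attention_params(), seed = NULL,
                       mutual_inclusion = TRUE,
                       mix_variant = "pam_cpool.cam_ppool") {
  if (!mix_variant %in% mix_variants()) {
    stop("mix_variant must be one of: ", paste(mix_variants(), collapse = ", "))
  }
  build <- function() {
    l <- list(kind = "mipc", channels = channels, params = params,
              mutual_inclusion = mutual_inclusion, mix_variant = mix_variant,
              pam = pam_layer(channels, params),
              cam = cam_layer(params),
              part_b = part_b_layer(channels),
              tail = residual_tail_layer(channels))
    if (mutual_inclusion) {
      l$channel_gate <- channel_gate_layer(channels, params)
      l$spatial_gate <- spatial_gate_layer(params)
    }
    l
  }
  if (is.null(seed)) build() else with_seed(seed, build)
}

# Part A on the tape. gate_override: numeric (N, C) matrix or scalar that
# replaces the learned gate (test hook for forcing the gate to 1).
part_a_tn <- function(layer, x, gate_override = NULL) {
  if (!layer$mutual_inclusion) return(pam_fwd(layer$pam, x))
  roles <- strsplit(layer$mix_variant, ".", fixed = TRUE)[[1]][1]
  carrier_first <- startsWith(roles, "pam")
  if (carrier_first) {
    carrier <- pam_fwd(layer$pam, x)
    gate <- if (is.null(gate_override)) {
      tn_sigmoid(channel_gate_logits(layer$channel_gate, x))
    } else {
      d <- dim(x$value)
      tn_const(matrix(gate_override, d[1], d[2]))
    }
    tn_scale_by_channel(carrier, gate)
  } else {
    # pooled summary is the carrier, attended map is the gate
    d <- dim(x$value)
    carrier <- tn_channel_to_map(channel_gate_logits(layer$channel_gate, x), d)
    gate <- if (is.null(gate_override)) {
      tn_sigmoid(pam_fwd(layer$pam, x))
    } else tn_const(array(gate_override, d))
    tn_mul(carrier, gate)
  }
}

part_c_tn <- function(layer, x, gate_override = NULL) {
  if (!layer$mutual_inclusion) return(cam_fwd(layer$cam, x))
  roles <- strsplit(layer$mix_variant, ".", fixed = TRUE)[[1]][2]
  carrier_first <- startsWith(roles, "cam")
  d <- dim(x$value)
  if (carrier_first) {
    carrier <- cam_fwd(layer$cam, x)
    gate <- if (is.null(gate_override)) {
      tn_sigmoid(spatial_gate_logits(layer$spatial_gate, x))
    } else tn_const(array(gate_override, c(d[1], 1L, d[3], d[4])))
    tn_scale_by_spatial(carrier, gate)
  } else {
    carrier <- tn_spatial_to_map(spatial_gate_logits(layer$spatial_gate, x),
                                 d[2])
    gate <- if (is.null(gate_override)) {
      tn_sigmoid(cam_fwd(layer$cam, x))
    } else tn_const(array(gate_override, d))
    tn_mul(carrier, gate)
  }
}

mipc_fwd <- function(layer, x, train = FALSE) {
  s <- tn_add(tn_add(part_a_tn(layer, x), part_b_fwd(layer$part_b, x)),
              part_c_tn(layer, x))
  residual_tail_fwd(layer$tail, s, train)
}

#' Construct a dual-attention purification block
#'
#' Two parallel branches (1x1 conv -> position attention -> 1x1 conv and
#' 1x1 conv -> channel attention -> 1x1 conv) whose outputs are summed;
#' used to purify skip-connection features.
#'
#' @inheritParams mipc_layer
#' @return a `da_layer` list usable with [da_block()].
#' @export
da_layer <- function(channels, params = attention_params(), seed = NULL) {
  build <- function() {
    list(kind = "da", channels = channels,
         p_in = layer_conv2d(channels, channels, 1L, "da.p_in"),
         pam = pam_layer(channels, params),
         p_out = layer_conv2d(channels, channels, 1L, "da.p_out"),
         c_in = layer_conv2d(channels, channels, 1L, "da.c_in"),
         cam = cam_layer(params),
         c_out = layer_conv2d(channels, channels, 1L, "da.c_out"))
  }
  if (is.null(seed)) build() else with_seed(seed, build)
}

da_fwd <- function(layer, x) {
  p <- conv_fwd(layer$p_out, pam_fwd(layer$pam, conv_fwd(layer$p_in, x)))
  c <- conv_fwd(layer$c_out, cam_fwd(layer$cam, conv_fwd(layer$c_in, x)))
  tn_add(p, c)
}

# -- functional surface on plain arrays ---------------------------------------

#' Attention block operations
#'
#' Functional forms of the attention-block forward passes. Each takes a
#' feature map as a plain numeric `(batch, channel, row, col)` array plus a
#' layer object created by the matching constructor, and returns a plain
#' array (or gate object). Shapes are always preserved.
#'
#' @param f numeric 4-axis array `(batch, channel, row, col)`.
#' @param layer layer object from [mipc_layer()], [da_layer()] or one of the
#'   sub-layer constructors documented here.
#' @param gate_override optional numeric value(s) replacing the learned gate
#'   (diagnostic hook; e.g. `1` disables gating).
#' @param train logical; use batch statistics in the residual tail's
#'   normalisation layers and update running statistics.
#' @param channels,params,seed passed to the layer constructors.
#' @return `channel_pool_gate()` returns a list with `gate` and `logits`
#'   matrices `(batch, channel)`; `position_pool_map()` a list with `gate`
#'   and `logits` arrays `(batch, 1, row, col)`; all other operations return
#'   an array shaped like `f`.
#' @name attention_ops
NULL

#' @rdname attention_ops
#' @export
channel_pool_gate <- function(f, layer) {
  check_fmap(f)
  if (identical(layer$kind, "mipc")) layer <- layer$channel_gate
  logits <- channel_gate_logits(layer, tn_const(f))
  structure(list(gate = 1 / (1 + exp(-logits$value)), logits = logits$value),
            class = "channel_gate")
}

#' @rdname attention_ops
#' @export
position_pool_map <- function(f, layer) {
  check_fmap(f)
  if (identical(layer$kind, "mipc")) layer <- layer$spatial_gate
  logits <- spatial_gate_logits(layer, tn_const(f))
  structure(list(gate = 1 / (1 + exp(-logits$value)), logits = logits$value),
            class = "spatial_gate")
}

#' @rdname attention_ops
#' @export
position_attention <- function(f, layer) {
  check_fmap(f)
  if (identical(layer$kind, "mipc")) layer <- layer$pam
  pam_fwd(layer, tn_const(f))$value
}

#' @rdname attention_ops
#' @export
channel_attention <- function(f, layer) {
  check_fmap(f)
  if (identical(layer$kind, "mipc")) layer <- layer$cam
  cam_fwd(layer, tn_const(f))$value
}

#' @rdname attention_ops
#' @export
part_a <- function(f, layer, gate_override = NULL) {
  check_fmap(f)
  part_a_tn(layer, tn_const(f), gate_override)$value
}

#' @rdname attention_ops
#' @export
part_b <- function(f, layer) {
  check_fmap(f)
  if (identical(layer$kind, "mipc")) layer <- layer$part_b
  part_b_fwd(layer, tn_const(f))$value
}

#' @rdname attention_ops
#' @export
part_c <- function(f, layer, gate_override = NULL) {
  check_fmap(f)
  part_c_tn(layer, tn_const(f), gate_override)$value
}

#' @rdname attention_ops
#' @export
residual_tail <- function(f, layer, train = FALSE) {
  check_fmap(f)
  if (identical(layer$kind, "mipc")) layer <- layer$tail
  residual_tail_fwd(layer, tn_const(f), train)$value
}

#' @rdname attention_ops
#' @export
mipc_block <- function(f, layer, train = FALSE) {
  check_fmap(f)
  mipc_fwd(layer, tn_const(f), train)$value
}

#' @rdname attention_ops
#' @export
da_block <- function(f, layer) {
  check_fmap(f)
  da_fwd(layer, tn_const(f))$value
}
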