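# The stage-2 segmentation network: a Deeplabv3-style architecture with a
# ResNet34-block encoder at output stride 8, a multi-scale fusion head (AMFF
# by default, plain ASPP as the ablation baseline), and a light decoder that
# reduces to one channel per vessel and upsamples 8x bilinearly.

#' Network configuration
#'
#' Builds the hyperparameter list for [vessel_net()]. The defaults reproduce
#' the full-size architecture: a 7x7 stride-2 stem, four cascaded residual
#' groups (each two basic blocks, i.e. four 3x3 convolutions) with strides
#' 2,2,1,1 ending at 512 channels and 1/8 resolution, a four-branch fusion
#' head with dilation rates 1,6,12,18 producing a 2048-channel fused feature,
#' and a 256-channel intermediate decode convolution. `base_channels` scales
#' every width by `base_channels/64`, which is how the desk-scale test
#' configurations are built.
#'
#' @param base_channels stem width; block widths are `base_channels *
#'   c(2, 4, 8, 8)` and the encoder output has `base_channels * 8` channels.
#' @param branch_count number of dilated branches in the fusion head.
#' @param dilations strictly increasing dilation rates, one per branch.
#' @param decode_channels width of the first decode convolution.
#' @param head `"amff"` (hierarchical connections + spatial attention) or
#'   `"aspp"` (independent parallel branches, no attention).
#' @param in_channels channels the stem expects; grayscale input is
#'   replicated to this many channels.
#' @return a `net_config` list.
#' @export
net_config <- function(base_channels = 64L, branch_count = 4L,
                       dilations = c(1L, 6L, 12L, 18L),
                       decode_channels = 4L * base_channels,
                       head = c("amff", "aspp"), in_channels = 3L) {
  head <- match.arg(head)
  if (length(dilations) != branch_count)
    stop_v3("need one dilation rate per branch (%d branches, %d rates)",
            "vessel3_config_error", branch_count, length(dilations))
  if (any(diff(dilations) <= 0))
    stop_v3("dilation rates must be strictly increasing", "vessel3_config_error")
  if (base_channels < 1) stop_v3("base_channels must be >= 1", "vessel3_config_error")
  structure(list(base_channels = as.integer(base_channels),
                 branch_count = as.integer(branch_count),
                 dilations = as.integer(dilations),
                 branch_channels = 8L * as.integer(base_channels),
                 fused_channels = as.integer(branch_count) * 8L * as.integer(base_channels),
                 decode_channels = as.integer(decode_channels),
                 head = head, in_channels = as.integer(in_channels),
                 n_classes = 3L),
            class = "net_config")
}

make_basic_block <- function(cin, cout, stride) {
  blk <- list(conv1 = layer_conv(3, 3, cin, cout, stride = stride, pad = 1),
              bn1 = layer_bn(cout),
              conv2 = layer_conv(3, 3, cout, cout, pad = 1),
              bn2 = layer_bn(cout))
  if (stride != 1 || cin != cout) {
    blk$convd <- layer_conv(1, 1, cin, cout, stride = stride)
    blk$bnd <- layer_bn(cout)
  }
  blk
}

fwd_basic_block <- function(tape, x, blk, training) {
  h <- op_relu(tape, op_bn(tape, op_conv(tape, x, blk$conv1), blk$bn1, training))
  h <- op_bn(tape, op_conv(tape, h, blk$conv2), blk$bn2, training)
  s <- if (!is.null(blk$convd))
    op_bn(tape, op_conv(tape, x, blk$convd), blk$bnd, training) else x
  op_relu(tape, op_add(tape, h, s))
}

make_encoder <- function(cfg) {
  b <- cfg$base_channels
  widths <- b * c(2L, 4L, 8L, 8L)
  strides <- c(2L, 2L, 1L, 1L)
  enc <- list(stem_conv = layer_conv(7, 7, cfg$in_channels, b, stride = 2, pad = 3),
              stem_bn = layer_bn(b))
  cin <- b
  for (i in 1:4) {
    enc[[paste0("block", i, "a")]] <- make_basic_block(cin, widths[i], strides[i])
    enc[[paste0("block", i, "b")]] <- make_basic_block(widths[i], widths[i], 1L)
    cin <- widths[i]
  }
  enc
}

fwd_encoder <- function(tape, x, enc, training) {
  h <- op_relu(tape, op_bn(tape, op_conv(tape, x, enc$stem_conv), enc$stem_bn, training))
  for (i in 1:4) {
    h <- fwd_basic_block(tape, h, enc[[paste0("block", i, "a")]], training)
    h <- fwd_basic_block(tape, h, enc[[paste0("block", i, "b")]], training)
  }
  h
}

make_head <- function(cfg) {
  cb <- cfg$branch_channels
  head <- list()
  for (i in seq_len(cfg$branch_count)) {
    d <- cfg$dilations[i]
    head[[paste0("branch", i, "_conv")]] <- layer_conv(3, 3, cb, cb, dil = d, pad = d)
    head[[paste0("branch", i, "_bn")]] <- layer_bn(cb)
    if (cfg$head == "amff")
      head[[paste0("branch", i, "_att")]] <- layer_conv(7, 7, 2, 1, pad = 3)
  }
  head
}

fwd_head <- function(tape, enc_feat, head, cfg, training) {
  outs <- vector("list", cfg$branch_count)
  prev <- NULL
  for (i in seq_len(cfg$branch_count)) {
    inp <- if (cfg$head == "amff" && !is.null(prev)) op_add(tape, enc_feat, prev) else enc_feat
    pre <- op_relu(tape, op_bn(tape, op_conv(tape, inp, head[[paste0("branch", i, "_conv")]]),
                               head[[paste0("branch", i, "_bn")]], training))
    if (cfg$head == "amff") {
      att <- head[[paste0("branch", i, "_att")]]
      pooled <- op_concat(tape, list(op_chan_mean(tape, pre), op_chan_max(tape, pre)))
      amap <- op_sigmoid(tape, op_conv(tape, pooled, att))
      outs[[i]] <- op_mul_map(tape, pre, amap)
      prev <- pre  # hierarchical connection feeds the pre-attention feature
    } else {
      outs[[i]] <- pre
    }
  }
  op_concat(tape, outs)
}

make_decoder <- function(cfg) {
  list(conv1 = layer_conv(3, 3, cfg$fused_channels, cfg$decode_channels, pad = 1),
       bn1 = layer_bn(cfg$decode_channels),
       conv2 = layer_conv(3, 3, cfg$decode_channels, cfg$n_classes, pad = 1))
}

fwd_decoder <- function(tape, fused, dec, training, out_h, out_w) {
  h <- op_relu(tape, op_bn(tape, op_conv(tape, fused, dec$conv1), dec$bn1, training))
  logits_lr <- op_conv(tape, h, dec$conv2)
  op_upsample_bilinear(tape, logits_lr, out_h, out_w)
}

#' Construct the stage-2 segmentation network
#'
#' Assembles encoder, multi-scale fusion head and decoder with freshly
#' initialized (He-normal) weights. All randomness is governed by `seed`.
#'
#' @param config a [net_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `vessel_net`.
#' @examples
#' net <- vessel_net(net_config(base_channels = 4), seed = 1)
#' count_params(net)
#' @export
vessel_net <- function(config = net_config(), seed = 0L) {
  stopifnot(inherits(config, "net_config"))
  model <- with_seed(seed, {
    list(encoder = make_encoder(config),
         head = make_head(config),
         decoder = make_decoder(config))
  })
  structure(list(modules = model, config = config, seed = seed),
            class = "vessel_net")
}

net_layers <- function(model) collect_layers(model$modules)

#' Number of trainable parameters
#' @param model a `vessel_net`, or a bare module list.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  layers <- if (inherits(model, "vessel_net")) net_layers(model) else collect_layers(model)
  sum(vapply(layers, layer_n_params, numeric(1)))
}

# Full forward pass on the tape; x is (H,W,1,N) or (H,W) grayscale in [0,1].
net_forward_tape <- function(model, x, training = FALSE) {
  x <- as_tensor4(x)
  d <- dim(x)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop_v3("input size %dx%d is not divisible by 8", "vessel3_shape_error", d[1], d[2])
  if (d[3] == 1L && model$config$in_channels > 1L)
    x <- x[, , rep(1L, model$config$in_channels), , drop = FALSE]
  else if (d[3] != model$config$in_channels)
    stop_v3("input has %d channels, network expects 1 or %d", "vessel3_shape_error",
            d[3], model$config$in_channels)
  tape <- new_tape()
  xin <- op_input(tape, x)
  feat <- fwd_encoder(tape, xin, model$modules$encoder, training)
  fused <- fwd_head(tape, feat, model$modules$head, model$config, training)
  logits <- fwd_decoder(tape, fused, model$modules$decoder, training, d[1], d[2])
  prob <- op_sigmoid(tape, logits)
  list(tape = tape, input = xin, feature = feat, fused = fused,
       logits = logits, prob = prob)
}

#' Encoder features for an image
#'
#' Runs only the encoder: for an `HxW` input the feature map has spatial size
#' `H/8 x W/8` and `8 * base_channels` channels (512 at full size).
#'
#' @param model a `vessel_net`.
#' @param image grayscale matrix or (H,W,1,N) array, values in \[0,1\].
#' @return feature array (H/8, W/8, C, N).
#' @export
net_encode <- function(model, image) {
  x <- as_tensor4(image)
  d <- dim(x)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop_v3("input size %dx%d is not divisible by 8", "vessel3_shape_error", d[1], d[2])
  if (d[3] == 1L && model$config$in_channels > 1L)
    x <- x[, , rep(1L, model$config$in_channels), , drop = FALSE]
  tape <- new_tape()
  fwd_encoder(tape, op_input(tape, x), model$modules$encoder, FALSE)$value
}

#' Multi-scale fusion head (AMFF or ASPP) applied to encoder features
#'
#' Each branch applies a 3x3 convolution at its dilation rate (padding equal
#' to the rate, so spatial size is preserved). With the AMFF head, branch i
#' receives the encoder feature plus branch i-1's pre-attention output, and a
#' per-branch spatial attention map rescales the result before concatenation;
#' the ASPP head runs the branches independently with no attention. Branch
#' outputs are concatenated along channels into the fused feature
#' (`branch_count * branch_channels` channels; 2048 at full size).
#'
#' @param model a `vessel_net`.
#' @param feature encoder feature array (h, w, C, N) with
#'   `C = 8 * base_channels`.
#' @return fused feature array (h, w, fused_channels, N).
#' @export
net_head <- function(model, feature) {
  x <- as_tensor4(feature)
  if (dim(x)[3] != model$config$branch_channels)
    stop_v3("head expects %d channels, got %d", "vessel3_shape_error",
            model$config$branch_channels, dim(x)[3])
  tape <- new_tape()
  fwd_head(tape, op_input(tape, x), model$modules$head, model$config, FALSE)$value
}

#' Decode fused features to per-class probability maps
#'
#' Two convolutions reduce the fused feature to one channel per vessel class,
#' the low-resolution logits are upsampled 8x by bilinear interpolation, and a
#' per-channel sigmoid maps them to \[0,1\].
#'
#' @param model a `vessel_net`.
#' @param fused fused feature array (h, w, fused_channels, N).
#' @return probability array (8h, 8w, 3, N); logits kept in attribute
#'   `"logits"`.
#' @export
net_decode <- function(model, fused) {
  x <- as_tensor4(fused)
  if (dim(x)[3] != model$config$fused_channels)
    stop_v3("decoder expects %d channels, got %d", "vessel3_shape_error",
            model$config$fused_channels, dim(x)[3])
  tape <- new_tape()
  logits <- fwd_decoder(tape, op_input(tape, x), model$modules$decoder, FALSE,
                        8L * dim(x)[1], 8L * dim(x)[2])
  structure(1 / (1 + exp(-logits$value)), logits = logits$value)
}

#' Segment an image with a trained network
#'
#' @param object a `vessel_net`.
#' @param image grayscale matrix (values in \[0,1\]), or an (H,W,1,N) array.
#' @param type `"prob"` for the (H,W,3,N) per-class probability maps,
#'   `"mask"` for the labeled mask (0 background, 1 PA, 2 Ao, 3 SVC).
#' @param threshold per-channel probability threshold used for `type="mask"`.
#' @param ... unused.
#' @return probabilities or an integer mask matrix (list of matrices for N>1).
#' @export
predict.vessel_net <- function(object, image, type = c("prob", "mask"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  out <- net_forward_tape(object, image, training = FALSE)
  prob <- out$prob$value
  if (type == "prob") return(structure(prob, logits = out$logits$value))
  n <- dim(prob)[4]
  masks <- lapply(seq_len(n), function(i) prob_to_mask(prob[, , , i], threshold))
  if (n == 1L) masks[[1]] else masks
}

#' Convert per-class probability maps to a labeled mask
#'
#' A pixel is assigned the class with the highest probability among channels
#' exceeding `threshold` (ties to the lower class index), else background.
#'
#' @param prob array (H, W, 3).
#' @param threshold probability cut-off per channel.
#' @return integer matrix with labels 0-3.
#' @export
prob_to_mask <- function(prob, threshold = 0.5) {
  d <- dim(prob)
  pm <- matrix(prob, d[1] * d[2], d[3])
  best <- max.col(pm, ties.method = "first")
  bestp <- pm[cbind(seq_len(nrow(pm)), best)]
  lab <- ifelse(bestp >= threshold, best, 0L)
  matrix(as.integer(lab), d[1], d[2])
}

#' Standalone spatial attention
#'
#' The attention operator used inside each AMFF branch: channel-wise mean and
#' max maps are stacked, passed through a 7x7 convolution and a sigmoid, and
#' the resulting one-channel map in (0,1) rescales the feature. Output
#' magnitude therefore never exceeds the input's.
#'
#' @param feature array (H, W, C) or (H, W, C, N).
#' @param att_conv optionally a pre-built 7x7 `layer_conv(7,7,2,1)`; a fresh
#'   seeded one is created when `NULL`.
#' @param seed seed for the fresh attention convolution.
#' @return attended feature, same shape as the input, with the attention map
#'   in attribute `"attention_map"`.
#' @export
spatial_attention <- function(feature, att_conv = NULL, seed = 0L) {
  x <- as_tensor4(feature)
  if (is.null(att_conv)) att_conv <- with_seed(seed, layer_conv(7, 7, 2, 1, pad = 3))
  tape <- new_tape()
  xin <- op_input(tape, x)
  pooled <- op_concat(tape, list(op_chan_mean(tape, xin), op_chan_max(tape, xin)))
  amap <- op_sigmoid(tape, op_conv(tape, pooled, att_conv))
  out <- op_mul_map(tape, xin, amap)
  res <- out$value
  dim(res) <- dim(feature)
  structure(res, attention_map = amap$value)
}

#' Replace the fusion head of a network
#'
#' Builds a new network sharing the encoder and decoder parameter
#' environments but with a freshly initialized head of the requested kind, so
#' AMFF and ASPP variants are drop-in interchangeable.
#'
#' @param model a `vessel_net`.
#' @param head `"amff"` or `"aspp"`.
#' @param seed seed for the new head's weights.
#' @return a `vessel_net`.
#' @export
swap_head <- function(model, head = c("amff", "aspp"), seed = 0L) {
  head <- match.arg(head)
  cfg <- model$config
  cfg$head <- head
  model$config <- cfg
  model$modules$head <- with_seed(seed, make_head(cfg))
  model
}

#' Extract / restore all network parameters
#'
#' `net_state()` returns a flat named list of numeric arrays (names are
#' namespaced `encoder.*`, `head.*`, `decoder.*`); `net_load_state()` writes
#' such a list back into a compatible network.
#'
#' @param model a `vessel_net`.
#' @return named list of parameter arrays.
#' @export
net_state <- function(model) {
  layers <- net_layers(model)
  out <- list()
  for (nm in names(layers)) {
    l <- layers[[nm]]
    for (p in layer_param_names(l)) out[[paste0(nm, ".", p)]] <- l[[p]]
    if (l$type == "bn") {
      out[[paste0(nm, ".running_mean")]] <- l$running_mean
      out[[paste0(nm, ".running_var")]] <- l$running_var
    }
  }
  out
}

#' @rdname net_state
#' @param state a list produced by `net_state()`.
#' @export
net_load_state <- function(model, state) {
  layers <- net_layers(model)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    for (p in c(layer_param_names(l),
                if (l$type == "bn") c("running_mean", "running_var"))) {
      key <- paste0(nm, ".", p)
      if (is.null(state[[key]]))
        stop_v3("checkpoint is missing parameter '%s'", "vessel3_state_error", key)
      if (length(state[[key]]) != length(l[[p]]))
        stop_v3("parameter '%s' has wrong size", "vessel3_state_error", key)
      val <- state[[key]]
      if (!is.null(dim(l[[p]]))) dim(val) <- dim(l[[p]])
      l[[p]] <- val
    }
  }
  invisible(model)
}

#' @export
print.vessel_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<vessel_net> head=%s base=%d branches=%d dilations=%s params=%s\n",
              cfg$head, cfg$base_channels, cfg$branch_count,
              paste(cfg$dilations, collapse = ","),
              format(count_params(x), big.mark = ",")))
  invisible(x)
}
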