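#' Architecture specification for experts, generalists and the DSN
#'
#' The expert (and baseline generalist) is a V-net style 3D encoder/decoder:
#' `n_scales` lateral/axial downsampling stages of ceil-mode 2x max pooling
#' with two convolution blocks (3x3x3 conv, instance norm with learnable
#' affine, ReLU) per stage, skip connections at every scale, a bottleneck
#' block, and a 1x1x1 sigmoid head. With the default 128 x 128 x 100 patch
#' and 4 stages the bottleneck spatial size is 8 x 8 x 7
#' (lateral 128-64-32-16-8, axial 100-50-25-13-7 under ceil-mode pooling).
#'
#' The gating network (GTN) is a small VGG-style 2D CNN on the 128 x 128
#' hologram patch: conv/ReLU/maxpool stages, global average pooling, two
#' dense layers and a softmax over the `n_experts` synthesis weights.
#'
#' The dynamic synthesis network (DSN) holds `n_experts` expert
#' encoder/decoders plus the GTN, so its trainable parameter count is about
#' 3x the expert's (the GTN is comparatively tiny). The "wide generalist"
#' preset instead widens a single V-net's channels by ~sqrt(3) to match the
#' DSN parameter count with a monolithic network.
#'
#' @param patch Integer length-3 input sub-volume size (px, py, pz).
#' @param n_experts Number of experts (>= 2).
#' @param n_scales Number of pooling stages.
#' @param base_channels Channels at the finest scale; doubled per stage.
#' @param kernel Convolution kernel size (odd).
#' @param gtn_channels Channels of the GTN conv stages.
#' @param gtn_hidden Width of the GTN's hidden dense layer.
#' @return A `dsn_architecture` list.
#' @export
dsn_architecture <- function(patch = c(128L, 128L, 100L), n_experts = 3L,
                             n_scales = 4L, base_channels = 16L, kernel = 3L,
                             gtn_channels = c(8L, 16L, 32L, 64L),
                             gtn_hidden = 32L) {
  stopifnot(length(patch) == 3L, all(patch >= 2^n_scales * c(1, 1, 0) + c(0, 0, 2)),
            n_experts >= 2L, n_scales >= 1L, base_channels >= 1L,
            kernel %% 2L == 1L)
  structure(list(patch = as.integer(patch), n_experts = as.integer(n_experts),
                 n_scales = as.integer(n_scales),
                 base_channels = as.integer(base_channels),
                 kernel = as.integer(kernel),
                 gtn_channels = as.integer(gtn_channels),
                 gtn_hidden = as.integer(gtn_hidden)),
            class = "dsn_architecture")
}

#' Desk-scale architecture for CPU tests and examples
#' @param patch Input sub-volume size.
#' @param ... Overrides forwarded to [dsn_architecture()].
#' @return A `dsn_architecture`.
#' @export
dsn_mini_architecture <- function(patch = c(32L, 32L, 16L), ...) {
  args <- list(patch = patch, n_experts = 3L, n_scales = 2L,
               base_channels = 2L, gtn_channels = c(4L, 8L), gtn_hidden = 8L)
  over <- list(...)
  args[names(over)] <- over
  do.call(dsn_architecture, args)
}

#' Named architecture presets
#'
#' `"expert"` and `"generalist"` share one V-net; `"wide_generalist"`
#' widens the channels by ~sqrt(3) so a single V-net carries roughly the
#' DSN's parameter count; `"dsn"` is the expert spec (the DSN holds
#' `n_experts` of them plus the GTN).
#'
#' @param name Preset name.
#' @param patch Input sub-volume size.
#' @return A `dsn_architecture`.
#' @export
architecture_preset <- function(name = c("expert", "generalist",
                                         "wide_generalist", "dsn"),
                                patch = c(128L, 128L, 100L)) {
  name <- match.arg(name)
  base <- 16L
  if (name == "wide_generalist") base <- as.integer(round(16 * sqrt(3)))
  dsn_architecture(patch = patch, base_channels = base)
}

#' Spatial size of the bottleneck feature map
#' @param spec A [dsn_architecture()].
#' @return Integer length-3 spatial dims after `n_scales` ceil-mode poolings.
#' @export
bottleneck_shape <- function(spec) {
  d <- spec$patch
  for (s in seq_len(spec$n_scales)) d <- ceiling(d / 2)
  as.integer(d)
}

scale_channels <- function(spec, s) {
  # s in 1..n_scales gives the per-scale width; s = n_scales + 1 the bottleneck
  as.integer(spec$base_channels * 2^(s - 1L))
}

conv_block_shapes <- function(ci, co, k) {
  layer <- function(ci, co) list(w = c(k, k, k, ci, co), b = co,
                                 gamma = co, beta = co)
  list(conv1 = layer(ci, co), conv2 = layer(co, co))
}

#' Parameter shapes of every learnable tensor
#'
#' @param spec A [dsn_architecture()].
#' @param part `"expert"` (one encoder/decoder), `"gtn"`, or `"dsn"`
#'   (`n_experts` experts plus the GTN).
#' @return Nested list mirroring the parameter tree, dim vectors at leaves.
#' @keywords internal
param_shapes <- function(spec, part = c("expert", "gtn", "dsn")) {
  part <- match.arg(part)
  k <- spec$kernel
  S <- spec$n_scales
  if (part == "expert") {
    enc <- list(scales = lapply(seq_len(S), function(s) {
      ci <- if (s == 1L) 1L else scale_channels(spec, s - 1L)
      conv_block_shapes(ci, scale_channels(spec, s), k)
    }))
    enc$bottleneck <- conv_block_shapes(scale_channels(spec, S),
                                        scale_channels(spec, S + 1L), k)
    dec <- list(scales = lapply(seq_len(S), function(s) {
      cs <- scale_channels(spec, s)
      conv_block_shapes(cs + scale_channels(spec, s + 1L), cs, k)
    }))
    dec$head <- list(w = c(1L, 1L, 1L, spec$base_channels, 1L), b = 1L)
    return(list(encoder = enc, decoder = dec))
  }
  if (part == "gtn") {
    ch <- c(1L, spec$gtn_channels)
    convs <- lapply(seq_along(spec$gtn_channels), function(i) {
      list(w = c(3L, 3L, ch[i], ch[i + 1L]), b = ch[i + 1L])
    })
    return(list(convs = convs,
                fc1 = list(W = c(spec$gtn_hidden, ch[length(ch)]),
                           b = spec$gtn_hidden),
                fc2 = list(W = c(spec$n_experts, spec$gtn_hidden),
                           b = spec$n_experts)))
  }
  list(experts = replicate(spec$n_experts, param_shapes(spec, "expert"),
                           simplify = FALSE),
       gtn = param_shapes(spec, "gtn"))
}

#' Count the trainable parameters of a model
#'
#' @param spec A [dsn_architecture()].
#' @param part `"expert"`, `"gtn"` or `"dsn"`.
#' @return Total number of learnable scalars.
#' @examples
#' spec <- dsn_architecture()
#' count_parameters(spec, "dsn") / count_parameters(spec, "expert") # ~3
#' @export
count_parameters <- function(spec, part = "dsn") {
  shapes <- param_shapes(spec, part)
  sum(vapply(flatten_leaves(shapes), prod, numeric(1)))
}

flatten_leaves <- function(p) {
  if (is.numeric(p)) return(list(p))
  if (!length(p)) return(list())
  do.call(c, lapply(p, flatten_leaves))
}

unflatten_leaves <- function(skeleton, leaves) {
  i <- 0L
  rec <- function(s) {
    if (is.numeric(s)) {
      i <<- i + 1L
      return(leaves[[i]])
    }
    lapply(s, rec)
  }
  rec(skeleton)
}

ptree_map <- function(f, a, b = NULL) {
  if (is.numeric(a)) {
    return(if (is.null(b)) f(a) else f(a, b))
  }
  out <- lapply(seq_along(a), function(i) {
    ptree_map(f, a[[i]], if (is.null(b)) NULL else b[[i]])
  })
  names(out) <- names(a)
  out
}

ptree_weighted_sum <- function(trees, weights) {
  stopifnot(length(trees) == length(weights))
  first <- trees[[1L]]
  if (is.numeric(first)) {
    acc <- weights[1L] * first
    for (i in seq_along(trees)[-1L]) acc <- acc + weights[i] * trees[[i]]
    return(acc)
  }
  out <- lapply(seq_along(first), function(j) {
    ptree_weighted_sum(lapply(trees, `[[`, j), weights)
  })
  names(out) <- names(first)
  out
}

ptree_dot <- function(a, b) {
  if (is.numeric(a)) return(sum(a * b))
  s <- 0
  for (i in seq_along(a)) s <- s + ptree_dot(a[[i]], b[[i]])
  s
}

xavier_leaf <- function(dims, name) {
  n <- prod(dims)
  if (name %in% c("b", "beta")) {
    out <- numeric(n)
  } else if (name == "gamma") {
    out <- rep(1, n)
  } else if (name == "W") {
    a <- sqrt(6 / (dims[2] + dims[1]))
    out <- stats::runif(n, -a, a)
  } else { # conv weight: fan over kernel taps x channels
    nd <- length(dims)
    recept <- prod(dims[seq_len(nd - 2L)])
    a <- sqrt(6 / (recept * dims[nd - 1L] + recept * dims[nd]))
    out <- stats::runif(n, -a, a)
  }
  if (length(dims) > 1L) dim(out) <- dims
  out
}

#' Xavier-initialize a parameter tree
#'
#' Weights are drawn uniformly on `(-a, a)` with
#' `a = sqrt(6 / (fan_in + fan_out))`; biases and instance-norm shifts are
#' zero, instance-norm gains one.
#'
#' @param spec A [dsn_architecture()].
#' @param part `"expert"`, `"gtn"` or `"dsn"`.
#' @param seed RNG seed; a fixed seed gives bit-identical parameters.
#' @return Nested parameter list.
#' @export
init_parameters <- function(spec, part = "dsn", seed = 1L) {
  set.seed(seed)
  shapes <- param_shapes(spec, part)
  rec <- function(node) {
    if (!is.list(node)) stop("bad shape node")
    nms <- names(node)
    out <- lapply(seq_along(node), function(i) {
      child <- node[[i]]
      nm <- if (!is.null(nms)) nms[i] else ""
      if (is.numeric(child)) xavier_leaf(child, nm) else rec(child)
    })
    names(out) <- nms
    out
  }
  rec(shapes)
}

# ---- forward / backward passes ------------------------------------------

conv_layer3d_fw <- function(x, lp) {
  y1 <- conv3d_fw_cpp(x, lp$w, lp$b)
  nc <- instnorm_fw(y1, lp$gamma, lp$beta)
  rc <- relu_fw(nc$y)
  list(y = rc$y, x = x, norm = nc, relu = rc)
}

conv_layer3d_bw <- function(cache, lp, gy) {
  g <- relu_bw(cache$relu, gy)
  nb <- instnorm_bw(cache$norm, g)
  cb <- conv3d_bw_cpp(cache$x, lp$w, nb$gx)
  list(gx = cb$gx,
       gp = list(w = cb$gw, b = cb$gb, gamma = nb$ggamma, gbeta = nb$gbeta))
}

conv_block3d_fw <- function(x, bp) {
  c1 <- conv_layer3d_fw(x, bp$conv1)
  c2 <- conv_layer3d_fw(c1$y, bp$conv2)
  list(y = c2$y, c1 = c1, c2 = c2)
}

conv_block3d_bw <- function(cache, bp, gy) {
  b2 <- conv_layer3d_bw(cache$c2, bp$conv2, gy)
  b1 <- conv_layer3d_bw(cache$c1, bp$conv1, b2$gx)
  list(gx = b1$gx,
       gp = list(conv1 = list(w = b1$gp$w, b = b1$gp$b,
                              gamma = b1$gp$gamma, beta = b1$gp$gbeta),
                 conv2 = list(w = b2$gp$w, b = b2$gp$b,
                              gamma = b2$gp$gamma, beta = b2$gp$gbeta)))
}

as_input_tensor <- function(subvolume, spec) {
  d <- dim(subvolume)
  if (length(d) == 3L) {
    if (!identical(as.integer(d), spec$patch)) {
      stop("sub-volume size (", paste(d, collapse = " x "),
           ") does not match the architecture patch (",
           paste(spec$patch, collapse = " x "), ")", call. = FALSE)
    }
    dim(subvolume) <- c(d, 1L)
  } else if (!identical(as.integer(d), c(spec$patch, 1L))) {
    stop("sub-volume size does not match the architecture patch", call. = FALSE)
  }
  subvolume
}

#' Multi-scale feature extraction by one expert encoder
#'
#' Runs the encoder half of a V-net: per-scale conv blocks whose pre-pool
#' outputs form the skip-connection feature pyramid, ceil-mode 2x pooling
#' between scales, and a bottleneck block at the coarsest scale.
#'
#' @param subvolume Input array `(px, py, pz)` (normalized amplitude).
#' @param encoder_params Encoder half of an expert parameter tree.
#' @param spec A [dsn_architecture()].
#' @return A list with `features` (`skips` per scale and `bottleneck`) and
#'   `cache` for the backward pass.
#' @export
expert_encode <- function(subvolume, encoder_params, spec) {
  x <- as_input_tensor(subvolume, spec)
  S <- spec$n_scales
  skips <- vector("list", S)
  blocks <- vector("list", S)
  pools <- vector("list", S)
  cur <- x
  for (s in seq_len(S)) {
    bc <- conv_block3d_fw(cur, encoder_params$scales[[s]])
    skips[[s]] <- bc$y
    blocks[[s]] <- bc
    pc <- maxpool3d_fw_cpp(bc$y)
    pools[[s]] <- pc
    cur <- pc$y
  }
  bott <- conv_block3d_fw(cur, encoder_params$bottleneck)
  list(features = list(skips = skips, bottleneck = bott$y),
       cache = list(blocks = blocks, pools = pools, bott = bott))
}

expert_encode_bw <- function(cache, encoder_params, gfeatures, spec) {
  S <- spec$n_scales
  bb <- conv_block3d_bw(cache$bott, encoder_params$bottleneck,
                        gfeatures$bottleneck)
  gscales <- vector("list", S)
  gpooled <- bb$gx
  for (s in rev(seq_len(S))) {
    gpre <- maxpool_bw_cpp(cache$pools[[s]]$idx, gpooled,
                           dim(cache$blocks[[s]]$y)) + gfeatures$skips[[s]]
    sb <- conv_block3d_bw(cache$blocks[[s]], encoder_params$scales[[s]], gpre)
    gscales[[s]] <- sb$gp
    gpooled <- sb$gx
  }
  list(scales = gscales, bottleneck = bb$gp)
}

#' Decode a feature pyramid into a probability volume
#'
#' Decoder half of the V-net: starting from the bottleneck, each stage
#' upsamples (nearest-neighbour), concatenates the same-scale skip features
#' and applies a conv block; a 1x1x1 convolution and sigmoid produce the
#' per-voxel particle probability.
#'
#' @param features A pyramid as returned by [expert_encode()] (or the
#'   synthesized pyramid from [synthesize_features()]).
#' @param decoder_params Decoder half of a parameter tree (possibly
#'   synthesized by [synthesize_decoder()]).
#' @param spec A [dsn_architecture()].
#' @return A list with `prob` (`(px, py, pz)` array in (0,1)), `logits`,
#'   and `cache`.
#' @export
decode <- function(features, decoder_params, spec) {
  S <- spec$n_scales
  cur <- features$bottleneck
  ups <- vector("list", S)
  blocks <- vector("list", S)
  for (s in rev(seq_len(S))) {
    skip <- features$skips[[s]]
    up <- upsample3d_fw(cur, dim(skip)[1:3])
    ups[[s]] <- up
    cat_in <- array(c(skip, up$y),
                    dim = c(dim(skip)[1:3], dim(skip)[4] + dim(up$y)[4]))
    bc <- conv_block3d_fw(cat_in, decoder_params$scales[[s]])
    blocks[[s]] <- list(block = bc, skip_channels = dim(skip)[4])
    cur <- bc$y
  }
  logits <- conv3d_fw_cpp(cur, decoder_params$head$w, decoder_params$head$b)
  prob <- sigmoid(logits)
  dims <- dim(prob)
  out <- prob
  dim(out) <- dims[1:3]
  list(prob = out, logits = logits,
       cache = list(ups = ups, blocks = blocks, head_in = cur))
}

decode_bw <- function(cache, decoder_params, glogits, spec) {
  S <- spec$n_scales
  hb <- conv3d_bw_cpp(cache$head_in, decoder_params$head$w, glogits)
  gcur <- hb$gx
  gscales <- vector("list", S)
  gskips <- vector("list", S)
  for (s in seq_len(S)) {
    entry <- cache$blocks[[s]]
    bb <- conv_block3d_bw(entry$block, decoder_params$scales[[s]], gcur)
    gscales[[s]] <- bb$gp
    csk <- entry$skip_channels
    gcat <- bb$gx
    gskips[[s]] <- gcat[, , , seq_len(csk), drop = FALSE]
    gup <- gcat[, , , csk + seq_len(dim(gcat)[4] - csk), drop = FALSE]
    gcur <- upsample3d_bw(cache$ups[[s]], gup)
  }
  list(gparams = list(scales = gscales, head = list(w = hb$gw, b = hb$gb)),
       gfeatures = list(skips = gskips, bottleneck = gcur))
}

#' Forward pass of a single expert (or generalist) V-net
#'
#' @param subvolume Input array `(px, py, pz)`.
#' @param expert_params A parameter tree with `encoder` and `decoder`.
#' @param spec A [dsn_architecture()].
#' @param with_cache Keep intermediate activations for a backward pass.
#' @return List with `prob`, `logits` and (optionally) `cache`.
#' @export
expert_forward <- function(subvolume, expert_params, spec, with_cache = FALSE) {
  enc <- expert_encode(subvolume, expert_params$encoder, spec)
  dec <- decode(enc$features, expert_params$decoder, spec)
  out <- list(prob = dec$prob, logits = dec$logits)
  if (with_cache) out$cache <- list(enc = enc, dec = dec)
  out
}

expert_backward <- function(cache, expert_params, glogits, spec) {
  db <- decode_bw(cache$dec$cache, expert_params$decoder, glogits, spec)
  ge <- expert_encode_bw(cache$enc$cache, expert_params$encoder,
                         db$gfeatures, spec)
  list(encoder = ge, decoder = db$gparams)
}

#' Synthesis weights from the gating network
#'
#' VGG-style conv stages on the normalized hologram patch, global average
#' pooling, two dense layers and a softmax. The resulting weights are
#' nonnegative and sum to one; one alpha vector gates all feature scales
#' and the whole decoder for that input.
#'
#' @param hologram_patch Normalized hologram patch, `(px, py)` matrix.
#' @param gtn_params GTN parameter tree.
#' @param spec A [dsn_architecture()].
#' @param with_cache Keep activations for the backward pass.
#' @return List with `alpha` (length `n_experts`) and optionally `cache`.
#' @export
gtn_forward <- function(hologram_patch, gtn_params, spec, with_cache = FALSE) {
  d <- dim(hologram_patch)
  if (is.null(d) || length(d) != 2L ||
      !identical(as.integer(d), spec$patch[1:2])) {
    stop("hologram patch size does not match the architecture patch",
         call. = FALSE)
  }
  x <- hologram_patch
  dim(x) <- c(d, 1L)
  convs <- vector("list", length(gtn_params$convs))
  for (i in seq_along(gtn_params$convs)) {
    cp <- gtn_params$convs[[i]]
    y <- conv2d_fw_cpp(x, cp$w, cp$b)
    rc <- relu_fw(y)
    pc <- maxpool2d_fw_cpp(rc$y)
    convs[[i]] <- list(x = x, relu = rc, pool = pc, pre_pool_dims = dim(rc$y))
    x <- pc$y
  }
  sp <- prod(dim(x)[1:2])
  pooled <- colMeans(matrix(x, sp, dim(x)[3]))
  f1 <- dense_fw(pooled, gtn_params$fc1$W, gtn_params$fc1$b)
  r1 <- relu_fw(f1$y)
  f2 <- dense_fw(r1$y, gtn_params$fc2$W, gtn_params$fc2$b)
  alpha <- softmax(f2$y)
  out <- list(alpha = alpha)
  if (with_cache) {
    out$cache <- list(convs = convs, gap_dims = dim(x), f1 = f1, r1 = r1,
                      f2 = f2, alpha = alpha)
  }
  out
}

gtn_backward <- function(cache, gtn_params, galpha, spec) {
  gz <- softmax_bw(cache$alpha, galpha)
  d2 <- dense_bw(cache$f2, gtn_params$fc2$W, gz)
  gr1 <- relu_bw(cache$r1, d2$gx)
  d1 <- dense_bw(cache$f1, gtn_params$fc1$W, gr1)
  gd <- cache$gap_dims
  sp <- prod(gd[1:2])
  gx <- array(rep(d1$gx / sp, each = sp), dim = gd)
  gconvs <- vector("list", length(gtn_params$convs))
  for (i in rev(seq_along(gtn_params$convs))) {
    entry <- cache$convs[[i]]
    gpre <- maxpool_bw_cpp(entry$pool$idx, gx, entry$pre_pool_dims)
    grelu <- relu_bw(entry$relu, gpre)
    cb <- conv2d_bw_cpp(entry$x, gtn_params$convs[[i]]$w, grelu)
    gconvs[[i]] <- list(w = cb$gw, b = cb$gb)
    gx <- cb$gx
  }
  list(convs = gconvs,
       fc1 = list(W = d1$gW, b = d1$gb),
       fc2 = list(W = d2$gW, b = d2$gb))
}

#' Blend expert feature pyramids with synthesis weights
#'
#' Element-wise weighted sum of the expert feature maps at every scale
#' including the bottleneck: `F_s = sum_i alpha_i F_i`.
#'
#' @param pyramids List of feature pyramids (one per expert).
#' @param alpha Synthesis weights (nonnegative, summing to 1).
#' @return A synthesized feature pyramid.
#' @export
synthesize_features <- function(pyramids, alpha) {
  stopifnot(length(pyramids) == length(alpha))
  S <- length(pyramids[[1]]$skips)
  for (p in pyramids[-1L]) {
    if (length(p$skips) != S ||
        !identical(dim(p$bottleneck), dim(pyramids[[1]]$bottleneck))) {
      stop("feature pyramids are not shape-compatible", call. = FALSE)
    }
  }
  skips <- lapply(seq_len(S), function(s) {
    acc <- alpha[1L] * pyramids[[1L]]$skips[[s]]
    for (i in seq_along(pyramids)[-1L]) {
      if (!identical(dim(pyramids[[i]]$skips[[s]]), dim(acc))) {
        stop("feature pyramids are not shape-compatible", call. = FALSE)
      }
      acc <- acc + alpha[i] * pyramids[[i]]$skips[[s]]
    }
    acc
  })
  bott <- alpha[1L] * pyramids[[1L]]$bottleneck
  for (i in seq_along(pyramids)[-1L]) {
    bott <- bott + alpha[i] * pyramids[[i]]$bottleneck
  }
  list(skips = skips, bottleneck = bott)
}

#' Blend expert decoder parameters with synthesis weights
#'
#' Every learnable decoder parameter (conv kernels, biases, instance-norm
#' gains and shifts) of the synthesized decoder is the weighted sum of the
#' corresponding expert parameters: `D_s = sum_i alpha_i D_i`.
#'
#' @param decoders List of decoder parameter trees (one per expert), with
#'   identical key sets.
#' @param alpha Synthesis weights.
#' @return A synthesized decoder parameter tree.
#' @export
synthesize_decoder <- function(decoders, alpha) {
  stopifnot(length(decoders) == length(alpha))
  sig <- function(p) paste(names(flatten_leaves_names(p)), collapse = "|")
  ref <- sig(decoders[[1L]])
  for (d in decoders[-1L]) {
    if (!identical(sig(d), ref)) {
      stop("decoder parameter key sets differ between experts", call. = FALSE)
    }
  }
  ptree_weighted_sum(decoders, alpha)
}

flatten_leaves_names <- function(p, prefix = "") {
  if (is.numeric(p)) {
    out <- list(p)
    names(out) <- prefix
    return(out)
  }
  nm <- names(p)
  if (is.null(nm)) nm <- seq_along(p)
  do.call(c, lapply(seq_along(p), function(i) {
    flatten_leaves_names(p[[i]], paste0(prefix, "/", nm[i]))
  }))
}

#' Forward pass of the dynamic synthesis network
#'
#' The GTN predicts synthesis weights from the hologram patch; each expert
#' encoder extracts its feature pyramid from the sub-volume; the pyramids
#' are blended into synthesized features, the expert decoder parameters are
#' blended into a synthesized decoder, and the synthesized decoder maps the
#' synthesized features to the descattered probability volume.
#'
#' @param subvolume Normalized amplitude sub-volume `(px, py, pz)`.
#' @param hologram_patch Matching normalized hologram patch `(px, py)`.
#' @param params DSN parameter tree (`experts`, `gtn`).
#' @param spec A [dsn_architecture()].
#' @param with_cache Keep everything needed for the backward pass.
#' @return List with `prob`, `logits`, `alpha`, optionally `cache`.
#' @export
dsn_forward <- function(subvolume, hologram_patch, params, spec,
                        with_cache = FALSE) {
  gt <- gtn_forward(hologram_patch, params$gtn, spec, with_cache = with_cache)
  encs <- lapply(params$experts, function(ep) {
    expert_encode(subvolume, ep$encoder, spec)
  })
  pyramids <- lapply(encs, `[[`, "features")
  feats <- synthesize_features(pyramids, gt$alpha)
  dec_params <- synthesize_decoder(lapply(params$experts, `[[`, "decoder"),
                                   gt$alpha)
  dc <- decode(feats, dec_params, spec)
  out <- list(prob = dc$prob, logits = dc$logits, alpha = gt$alpha)
  if (with_cache) {
    out$cache <- list(gtn = gt$cache, encs = encs, pyramids = pyramids,
                      dec = dc$cache, dec_params = dec_params,
                      alpha = gt$alpha)
  }
  out
}

#' Backward pass of the DSN (gradients for all parameters)
#'
#' Gradients reach the synthesis weights through both blending paths:
#' `dL/dalpha_i = <dL/dD_s, D_i> + sum_scales <dL/dF_s, F_i>`, then flow
#' through the softmax into the GTN; expert gradients are the alpha-scaled
#' synthesized gradients.
#'
#' @param fw Result of [dsn_forward()] with `with_cache = TRUE`.
#' @param params DSN parameter tree.
#' @param glogits Gradient of the loss w.r.t. the output logits.
#' @param spec A [dsn_architecture()].
#' @return Gradient tree matching `params`.
#' @export
dsn_backward <- function(fw, params, glogits, spec) {
  cache <- fw$cache
  alpha <- cache$alpha
  db <- decode_bw(cache$dec, cache$dec_params, glogits, spec)
  gfeat_s <- db$gfeatures
  n <- length(params$experts)
  galpha <- numeric(n)
  gexperts <- vector("list", n)
  for (i in seq_len(n)) {
    galpha[i] <- ptree_dot(db$gparams, params$experts[[i]]$decoder) +
      ptree_dot(gfeat_s, cache$pyramids[[i]])
    gfeat_i <- ptree_map(function(g) alpha[i] * g, gfeat_s)
    genc <- expert_encode_bw(cache$encs[[i]]$cache,
                             params$experts[[i]]$encoder, gfeat_i, spec)
    gdec <- ptree_map(function(g) alpha[i] * g, db$gparams)
    gexperts[[i]] <- list(encoder = genc, decoder = gdec)
  }
  ggtn <- gtn_backward(cache$gtn, params$gtn, galpha, spec)
  list(experts = gexperts, gtn = ggtn)
}
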