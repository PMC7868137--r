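#' Generator configuration
#'
#' Describes the U-shaped generator: two weight-independent contracting paths
#' (one for the image, one for the attention map) of `depth` blocks each, a
#' bottleneck fusion, and an expansive path of `depth` up-convolution blocks.
#' Each contracting block halves the spatial side (kernel 4, stride 2); the
#' first `dilation_blocks` blocks use dilation 2 (effective kernel 7) to
#' enlarge the receptive field while the maps are still larger than 32x32.
#' The canonical configuration is input 512, depth 9, channel schedule
#' 64,128,...,1024 capped at 1024, four dilated blocks, dropout 0.5.
#'
#' @param input_size Pixels per side; must equal `2^depth`.
#' @param depth Blocks per contracting path (default `log2(input_size)`).
#' @param base_channels First-block channel count, doubled per block.
#' @param max_channels Channel cap (1024 canonically).
#' @param dilation_blocks Leading contracting blocks using dilated convolution.
#' @param dropout_rate Dropout probability in the three coarsest decoder
#'   blocks (training mode only).
#' @param attention_max_side Decoder scales with side up to this value fuse
#'   the two encoder streams through mask attention; finer scales use plain
#'   additive skip connections.
#' @return A `generator_config` list.
#' @export
generator_config <- function(input_size = 512L,
                             depth = as.integer(round(log2(input_size))),
                             base_channels = 64L,
                             max_channels = 1024L,
                             dilation_blocks = 4L,
                             dropout_rate = 0.5,
                             attention_max_side = 32L) {
  input_size <- as.integer(input_size); depth <- as.integer(depth)
  if (input_size < 16 || bitwAnd(input_size, input_size - 1L) != 0L)
    err_config("input_size must be a power of two, at least 16")
  if (input_size != 2L^depth)
    err_config("input_size must equal 2^depth so the bottleneck is 1x1")
  if (dilation_blocks > depth || dilation_blocks < 0)
    err_config("dilation_blocks must lie in [0, depth]")
  if (base_channels < 1 || max_channels < base_channels)
    err_config("channel schedule must satisfy 1 <= base_channels <= max_channels")
  if (dropout_rate < 0 || dropout_rate >= 1)
    err_config("dropout_rate must be in [0, 1)")
  structure(list(input_size = input_size, depth = depth,
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 dilation_blocks = as.integer(dilation_blocks),
                 dropout_rate = dropout_rate,
                 attention_max_side = as.integer(attention_max_side)),
            class = "generator_config")
}

#' Desk-scale generator configuration
#'
#' A reduced configuration for 64x64 phantoms: depth 6, channel schedule
#' 16,32,64,128,128,128, attention fusion at decoder sides up to 16. Keeps
#' the canonical architecture shape (halving chain, dilated first four
#' blocks, 1x1 bottleneck) at a parameter budget a single CPU trains in
#' minutes.
#'
#' @param input_size Pixels per side (default 64).
#' @return A `generator_config`.
#' @export
toy_generator_config <- function(input_size = 64L) {
  generator_config(input_size = input_size, base_channels = 16L,
                   max_channels = 128L, attention_max_side = 16L)
}

gen_channels <- function(config)
  pmin(config$base_channels * 2L^(seq_len(config$depth) - 1L),
       config$max_channels)

#' Build a generator
#'
#' Instantiates all layer parameters with a deterministic initialization.
#' Block ordering is pre-activation: ReLU, convolution, batch normalization,
#' with the leading ReLU omitted in the first block (raw inputs) and batch
#' normalization omitted at the 1x1 bottleneck (a single spatial position has
#' no variance). Decoder blocks are up-convolution (transposed convolution,
#' kernel 4, stride 2), batch normalization, dropout in the three coarsest
#' blocks, plus a residual skip from the encoders: mask-attention fusion at
#' coarse scales, plain addition at fine scales.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for the parameter initialization.
#' @return A `generator_state` environment.
#' @export
build_generator <- function(config, seed = 1L) {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  ch <- gen_channels(config)
  depth <- config$depth
  with_seed(seed, {
    make_enc <- function() lapply(seq_len(depth), function(d) {
      dilated <- d <= config$dilation_blocks
      list(conv = layer_conv(if (d == 1) 1L else ch[d - 1], ch[d], k = 4,
                             stride = 2, pad = if (dilated) 3 else 1,
                             dil = if (dilated) 2 else 1),
           bn = if (2L^(depth - d) > 1) layer_bn(ch[d]) else NULL,
           relu_before = d > 1)
    })
    enc_a <- make_enc()
    enc_b <- make_enc()
    fuse <- layer_conv(2L * ch[depth], ch[depth], k = 1, stride = 1, pad = 0)
    dec <- lapply(seq_len(depth), function(j) {
      in_ch <- if (j == 1) ch[depth] else ch[depth - j + 1]
      out_ch <- if (j < depth) ch[depth - j] else 1L
      side_out <- 2L^j
      list(convt = layer_convt(in_ch, out_ch, k = 4, stride = 2, pad = 1),
           bn = if (j < depth) layer_bn(out_ch) else NULL,
           dropout = j <= 3 && j < depth,
           attention = if (j < depth && side_out <= config$attention_max_side)
             layer_attention(out_ch) else NULL)
    })
  })
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$enc_a <- enc_a; st$enc_b <- enc_b; st$fuse <- fuse; st$dec <- dec
  st$layers <- c(unlist(lapply(c(enc_a, enc_b), function(b) list(b$conv, b$bn)),
                        recursive = FALSE),
                 list(fuse),
                 unlist(lapply(dec, function(b)
                   list(b$convt, b$bn, b$attention)), recursive = FALSE))
  st$layers <- Filter(Negate(is.null), st$layers)
  class(st) <- "generator_state"
  st
}

as_input_column <- function(x, size, what) {
  px <- if (inherits(x, c("normalized_slice", "attention_map", "ct_slice")))
    x$pixels else as_pixel_matrix(x)
  if (nrow(px) != size || ncol(px) != size)
    err_shape(sprintf("%s is %dx%d but the generator expects %dx%d",
                      what, nrow(px), ncol(px), size, size))
  matrix(px, size * size, 1)
}

enc_pass <- function(blocks, x, size, training) {
  h <- size; w <- size
  feats <- vector("list", length(blocks))
  for (d in seq_along(blocks)) {
    blk <- blocks[[d]]
    if (blk$relu_before) {
      mask <- x > 0
      if (training) blk$conv$relu_mask <- mask
      x <- x * mask
    }
    out <- conv_fwd(blk$conv, x, h, w, training)
    x <- out$y; h <- out$h; w <- out$w
    if (!is.null(blk$bn)) x <- bn_fwd(blk$bn, x, training)
    feats[[d]] <- x
  }
  feats
}

#' Run the generator forward
#'
#' Both inputs are standardized slices (see [normalize_slice()]); the
#' attention-map input is expected to be normalized with the same statistics
#' as its source slice so the white marker stays maximal. In evaluation mode
#' the pass is deterministic (no dropout, batch-norm running averages).
#'
#' @param state A `generator_state` from [build_generator()].
#' @param image Standardized image input (matrix or `normalized_slice`).
#' @param attention Standardized attention-map input.
#' @param training Logical; enables dropout, batch statistics and caching for
#'   the backward pass.
#' @return `input_size x input_size` matrix of synthesized (standardized)
#'   intensities.
#' @export
generator_forward <- function(state, image, attention, training = FALSE) {
  cfg <- state$config
  size <- cfg$input_size
  depth <- cfg$depth
  xa <- as_input_column(image, size, "image")
  xb <- as_input_column(attention, size, "attention map")
  fa <- enc_pass(state$enc_a, xa, size, training)
  fb <- enc_pass(state$enc_b, xb, size, training)
  state$feature_summary <- list(
    enc_sides = as.integer(sqrt(vapply(fa, nrow, numeric(1)))),
    enc_channels = vapply(fa, ncol, integer(1)))
  z <- conv_fwd(state$fuse, cbind(fa[[depth]], fb[[depth]]), 1L, 1L, training)$y
  x <- z; h <- 1L; w <- 1L
  for (j in seq_len(depth)) {
    blk <- state$dec[[j]]
    mask <- x > 0
    if (training) blk$convt$relu_mask <- mask
    x <- x * mask
    out <- convt_fwd(blk$convt, x, h, w, training)
    x <- out$y; h <- out$h; w <- out$w
    if (!is.null(blk$bn)) x <- bn_fwd(blk$bn, x, training)
    if (blk$dropout && training && cfg$dropout_rate > 0) {
      dm <- (stats::runif(length(x)) >= cfg$dropout_rate) /
        (1 - cfg$dropout_rate)
      blk$convt$drop_mask <- dm
      x <- x * dm
    }
    if (j < depth) {
      d_enc <- depth - j
      if (!is.null(blk$attention))
        x <- x + att_fwd(blk$attention, fa[[d_enc]], fb[[d_enc]], training)
      else
        x <- x + fa[[d_enc]] + fb[[d_enc]]
    }
  }
  if (training) state$fwd_feats <- list(fa = fa, fb = fb)
  matrix(x, size, size)
}

# Backward pass; d_out is an input_size x input_size matrix of gradients
# w.r.t. the synthesized output. Accumulates parameter gradients in place.
generator_backward <- function(state, d_out) {
  cfg <- state$config
  depth <- cfg$depth
  dy <- matrix(d_out, cfg$input_size^2, 1)
  dfa <- vector("list", depth)
  dfb <- vector("list", depth)
  add_to <- function(lst, d, val) {
    lst[[d]] <- if (is.null(lst[[d]])) val else lst[[d]] + val
    lst
  }
  for (j in rev(seq_len(depth))) {
    blk <- state$dec[[j]]
    if (j < depth) {
      if (!is.null(blk$attention)) {
        dd <- att_bwd(blk$attention, dy)
        dfa <- add_to(dfa, depth - j, dd$dfa)
        dfb <- add_to(dfb, depth - j, dd$dfb)
      } else {
        dfa <- add_to(dfa, depth - j, dy)
        dfb <- add_to(dfb, depth - j, dy)
      }
    }
    if (blk$dropout && !is.null(blk$convt$drop_mask))
      dy <- dy * blk$convt$drop_mask
    if (!is.null(blk$bn)) dy <- bn_bwd(blk$bn, dy)
    dy <- convt_bwd(blk$convt, dy)
    dy <- dy * blk$convt$relu_mask
  }
  dz <- conv_bwd(state$fuse, dy)
  cbot <- ncol(dz) / 2
  dfa <- add_to(dfa, depth, dz[, seq_len(cbot), drop = FALSE])
  dfb <- add_to(dfb, depth, dz[, cbot + seq_len(cbot), drop = FALSE])
  enc_bwd <- function(blocks, dfeats) {
    for (d in rev(seq_along(blocks))) {
      blk <- blocks[[d]]
      dy <- dfeats[[d]]
      if (!is.null(blk$bn)) dy <- bn_bwd(blk$bn, dy)
      dx <- conv_bwd(blk$conv, dy)
      if (blk$relu_before) dx <- dx * blk$conv$relu_mask
      if (d > 1) dfeats <- add_to(dfeats, d - 1, dx)
    }
    invisible(NULL)
  }
  enc_bwd(state$enc_a, dfa)
  enc_bwd(state$enc_b, dfb)
  invisible(state)
}

#' Mean-absolute-error reconstruction loss
#'
#' The generator's reconstruction objective: the mean absolute difference
#' between the real and synthesized slices.
#'
#' @param real,synthesized Matrices (or slice objects) of equal shape.
#' @return Scalar loss.
#' @export
generator_l1_loss <- function(real, synthesized) {
  a <- as_pixel_matrix(real)
  b <- as_pixel_matrix(synthesized)
  if (!identical(dim(a), dim(b)))
    err_shape("real and synthesized slices must share shape")
  mean(abs(a - b))
}
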