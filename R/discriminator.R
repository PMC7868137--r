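#' Discriminator configuration
#'
#' A six-block patch discriminator: it consumes a channel-concatenated
#' (image, attention map) pairing and emits a grid of real/fake
#' probabilities, each judging one overlapping input patch. The canonical
#' geometry — four blocks of kernel 4 / stride 2 / padding 1 followed by two
#' of kernel 4 / stride 1 / padding 1, channels 64,128,256,512,512,1 — maps a
#' 512x512 pairing to a 30x30 map (900 patches) with a 142x142 receptive
#' field. Batch normalization is omitted from the first and last blocks; the
#' final activation is a sigmoid.
#'
#' @param input_size Pixels per side of the pairing images.
#' @param block_specs Optional list of six lists with fields `kernel`,
#'   `stride`, `pad`, `channels`, `activation` (`"relu"`, `"sigmoid"`,
#'   `"none"`), `batchnorm`, `dilation`. Defaults to the canonical geometry.
#' @return A `discriminator_config`.
#' @export
discriminator_config <- function(input_size = 512L, block_specs = NULL) {
  if (is.null(block_specs)) {
    chans <- c(64L, 128L, 256L, 512L, 512L, 1L)
    block_specs <- lapply(1:6, function(i) list(
      kernel = 4L, stride = if (i <= 4) 2L else 1L, pad = 1L,
      channels = chans[i],
      activation = if (i < 6) "relu" else "sigmoid",
      batchnorm = i %in% 2:5, dilation = 1L))
  }
  if (length(block_specs) != 6)
    err_config("the discriminator has exactly six blocks")
  block_specs <- lapply(block_specs, function(b) {
    b$dilation <- b$dilation %||% 1L
    if (any(vapply(c("kernel", "stride", "pad", "channels"), function(f)
      is.null(b[[f]]) || b[[f]] < ifelse(f == "pad", 0, 1), TRUE)))
      err_config("each block needs kernel/stride >= 1, pad >= 0, channels >= 1")
    b$activation <- match.arg(b$activation, c("relu", "sigmoid", "none"))
    b$batchnorm <- isTRUE(b$batchnorm)
    b
  })
  if (block_specs[[6]]$activation != "sigmoid")
    err_config("the final block must end in a sigmoid")
  sides <- disc_side_chain(input_size, block_specs)
  if (any(sides < 1))
    err_config("block geometry collapses the map below 1x1 for this input size")
  structure(list(input_size = as.integer(input_size),
                 block_specs = block_specs, side_chain = sides),
            class = "discriminator_config")
}

#' Desk-scale discriminator configuration
#'
#' Same six-block geometry as the canonical patch discriminator (four
#' stride-2 blocks then two stride-1 blocks, kernel 4, so the 142-pixel
#' receptive field is preserved) with a narrow channel schedule
#' 16,32,64,128,128,1 suited to small phantom inputs.
#'
#' @param input_size Pixels per side (default 64).
#' @return A `discriminator_config`.
#' @export
toy_discriminator_config <- function(input_size = 64L) {
  chans <- c(16L, 32L, 64L, 128L, 128L, 1L)
  discriminator_config(input_size, lapply(1:6, function(i) list(
    kernel = 4L, stride = if (i <= 4) 2L else 1L, pad = 1L,
    channels = chans[i],
    activation = if (i < 6) "relu" else "sigmoid",
    batchnorm = i %in% 2:5, dilation = 1L)))
}

disc_side_chain <- function(input_size, block_specs) {
  s <- as.integer(input_size)
  vapply(block_specs, function(b) {
    s <<- as.integer(conv_out_side(s, b$kernel, b$stride, b$pad, b$dilation))
    s
  }, integer(1))
}

#' Build a discriminator
#'
#' @param config A [discriminator_config()].
#' @param seed Integer seed for deterministic parameter initialization.
#' @return A `discriminator_state` environment.
#' @export
build_discriminator <- function(config, seed = 1L) {
  if (!inherits(config, "discriminator_config"))
    err_config("config must be a discriminator_config")
  with_seed(seed, {
    in_ch <- 2L  # image and attention map, channel-concatenated
    blocks <- lapply(config$block_specs, function(b) {
      blk <- list(conv = layer_conv(in_ch, b$channels, k = b$kernel,
                                    stride = b$stride, pad = b$pad,
                                    dil = b$dilation),
                  bn = if (b$batchnorm) layer_bn(b$channels) else NULL,
                  activation = b$activation)
      in_ch <<- b$channels
      blk
    })
  })
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$blocks <- blocks
  st$layers <- Filter(Negate(is.null),
                      unlist(lapply(blocks, function(b) list(b$conv, b$bn)),
                             recursive = FALSE))
  class(st) <- "discriminator_state"
  st
}

# x: (input_size^2) x 2 matrix (image || attention map, standardized).
# Block order follows conv -> activation -> batch norm.
disc_fwd <- function(state, x, training = FALSE) {
  h <- w <- state$config$input_size
  for (blk in state$blocks) {
    out <- conv_fwd(blk$conv, x, h, w, training)
    x <- out$y; h <- out$h; w <- out$w
    if (blk$activation == "relu") {
      mask <- x > 0
      if (training) blk$conv$relu_mask <- mask
      x <- x * mask
    } else if (blk$activation == "sigmoid") {
      x <- 1 / (1 + exp(-x))
      if (training) blk$conv$sig_out <- x
    }
    if (!is.null(blk$bn)) x <- bn_fwd(blk$bn, x, training)
  }
  list(map = matrix(x, h, w), h = h, w = w)
}

# dmap: gradient w.r.t. the probability map; returns gradient w.r.t. the
# 2-channel input.
disc_bwd <- function(state, dmap) {
  dy <- matrix(dmap, length(dmap), 1)
  for (blk in rev(state$blocks)) {
    if (!is.null(blk$bn)) dy <- bn_bwd(blk$bn, dy)
    if (blk$activation == "relu") dy <- dy * blk$conv$relu_mask
    else if (blk$activation == "sigmoid") {
      s <- blk$conv$sig_out
      dy <- dy * s * (1 - s)
    }
    dy <- conv_bwd(blk$conv, dy)
  }
  dy
}

#' Score a pairing with the discriminator
#'
#' Runs the pairing through the six blocks and returns the patch probability
#' map together with its arithmetic mean, the scalar verdict.
#'
#' @param state A `discriminator_state`.
#' @param x A [pairing()] object.
#' @return List with `map` (probability matrix) and `score` (mean).
#' @export
discriminator_score <- function(state, x) {
  if (!inherits(x, "pairing")) ct_error("invalid_input", "x must be a pairing")
  size <- state$config$input_size
  if (!identical(dim(x$image), c(size, size)))
    err_shape(sprintf("pairing is %dx%d but the discriminator expects %dx%d",
                      nrow(x$image), ncol(x$image), size, size))
  inp <- cbind(as.vector(x$image), as.vector(x$attention))
  out <- disc_fwd(state, inp, training = FALSE)
  list(map = out$map, score = mean(out$map))
}

#' Receptive field of a discriminator configuration
#'
#' Side length, in input pixels, of the region influencing one output unit,
#' by the standard recursion: starting from `rf = 1`, `jump = 1`, each block
#' contributes `rf <- rf + (k_eff - 1) * jump; jump <- jump * stride`, with
#' `k_eff = (kernel - 1) * dilation + 1`.
#'
#' @param config A [discriminator_config()].
#' @return Receptive-field side length in pixels.
#' @export
receptive_field <- function(config) {
  if (!inherits(config, "discriminator_config"))
    err_config("config must be a discriminator_config")
  rf <- 1; jump <- 1
  for (b in config$block_specs) {
    keff <- (b$kernel - 1) * b$dilation + 1
    rf <- rf + (keff - 1) * jump
    jump <- jump * b$stride
  }
  as.integer(rf)
}

#' Patch-discriminator log loss
#'
#' The discriminator's maximization objective: the mean over map entries of
#' `log D_real + log(1 - D_fake)`, with entries clipped to
#' `[eps, 1 - eps]` to avoid `log(0)`. The trainer minimizes its negation.
#'
#' @param real_score_map,fake_score_map Probability maps of equal shape.
#' @param eps Clipping constant (default `1e-7`).
#' @return Scalar objective value (0 at perfect discrimination, negative
#'   otherwise).
#' @export
discriminator_loss <- function(real_score_map, fake_score_map, eps = 1e-7) {
  if (!identical(dim(real_score_map), dim(fake_score_map)))
    err_shape("score maps must share shape")
  r <- pmin(pmax(real_score_map, eps), 1 - eps)
  f <- pmin(pmax(fake_score_map, eps), 1 - eps)
  mean(log(r)) + mean(log(1 - f))
}
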