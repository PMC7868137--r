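# Minimal convolutional-network toolkit backing the generator and
# discriminator. Feature maps travel as (h*w) x channels matrices whose
# columns are column-major image planes; spatial geometry is tracked by the
# network code. Layers are environments so parameters, gradients and Adam
# moments update in place.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# broadcast a per-channel vector across n spatial positions (column-major)
colbc <- function(v, n) rep(v, each = n)

INIT_SD <- 0.02  # weight-initialization scale, the usual conditional-GAN value

new_layer <- function(type, params, buffers = character()) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  ly$params <- params
  ly$buffers <- buffers
  class(ly) <- c(paste0("ctnn_", type), "ctnn_layer")
  ly
}

layer_conv <- function(in_ch, out_ch, k = 4, stride = 2, pad = 1, dil = 1) {
  ly <- new_layer("conv", c("W", "b"))
  ly$W <- matrix(stats::rnorm(k * k * in_ch * out_ch, 0, INIT_SD),
                 k * k * in_ch, out_ch)
  ly$b <- numeric(out_ch)
  ly$k <- k; ly$stride <- stride; ly$pad <- pad; ly$dil <- dil
  ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly
}

conv_out_side <- function(n, k, stride, pad, dil = 1) {
  keff <- (k - 1) * dil + 1
  (n + 2 * pad - keff) %/% stride + 1
}

conv_fwd <- function(ly, x, h, w, training = FALSE) {
  cols <- im2col_cpp(x, h, w, ly$k, ly$stride, ly$pad, ly$dil)
  y <- cols %*% ly$W
  y <- y + colbc(ly$b, nrow(y))
  if (training) ly$cache <- list(cols = cols, h = h, w = w)
  list(y = y,
       h = conv_out_side(h, ly$k, ly$stride, ly$pad, ly$dil),
       w = conv_out_side(w, ly$k, ly$stride, ly$pad, ly$dil))
}

conv_bwd <- function(ly, dy) {
  cc <- ly$cache
  ly$gW <- ly$gW + crossprod(cc$cols, dy)
  ly$gb <- ly$gb + colSums(dy)
  col2im_cpp(tcrossprod(dy, ly$W), cc$h, cc$w, ly$in_ch,
             ly$k, ly$stride, ly$pad, ly$dil)
}

# Transposed convolution: the adjoint of layer_conv's geometry, used by the
# expansive path. Weight shape (k*k*out_ch) x in_ch.
layer_convt <- function(in_ch, out_ch, k = 4, stride = 2, pad = 1) {
  ly <- new_layer("convt", c("W", "b"))
  ly$W <- matrix(stats::rnorm(k * k * out_ch * in_ch, 0, INIT_SD),
                 k * k * out_ch, in_ch)
  ly$b <- numeric(out_ch)
  ly$k <- k; ly$stride <- stride; ly$pad <- pad
  ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly
}

convt_out_side <- function(n, k, stride, pad) (n - 1) * stride - 2 * pad + k

convt_fwd <- function(ly, x, h, w, training = FALSE) {
  oh <- convt_out_side(h, ly$k, ly$stride, ly$pad)
  ow <- convt_out_side(w, ly$k, ly$stride, ly$pad)
  y <- col2im_cpp(tcrossprod(x, ly$W), oh, ow, ly$out_ch,
                  ly$k, ly$stride, ly$pad, 1L)
  y <- y + colbc(ly$b, nrow(y))
  if (training) ly$cache <- list(x = x, oh = oh, ow = ow)
  list(y = y, h = oh, w = ow)
}

convt_bwd <- function(ly, dy) {
  cc <- ly$cache
  dcols <- im2col_cpp(dy, cc$oh, cc$ow, ly$k, ly$stride, ly$pad, 1L)
  ly$gW <- ly$gW + crossprod(dcols, cc$x)
  ly$gb <- ly$gb + colSums(dy)
  dcols %*% ly$W
}

# Batch normalization at batch size 1: statistics are per channel over the
# spatial positions of the single item; running averages serve evaluation.
layer_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  ly <- new_layer("bn", c("gamma", "beta"),
                  buffers = c("running_mean", "running_var"))
  ly$gamma <- 1 + stats::rnorm(ch, 0, INIT_SD)
  ly$beta <- numeric(ch)
  ly$running_mean <- numeric(ch)
  ly$running_var <- rep(1, ch)
  ly$momentum <- momentum; ly$eps <- eps; ly$ch <- ch
  ly
}

bn_fwd <- function(ly, x, training = FALSE) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - colbc(mu, n)
    v <- colMeans(xc * xc)
    ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
    ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * v
    istd <- 1 / sqrt(v + ly$eps)
    xhat <- xc * colbc(istd, n)
    ly$cache <- list(xhat = xhat, istd = istd)
    xhat * colbc(ly$gamma, n) + colbc(ly$beta, n)
  } else {
    istd <- 1 / sqrt(ly$running_var + ly$eps)
    (x - colbc(ly$running_mean, n)) * colbc(istd * ly$gamma, n) +
      colbc(ly$beta, n)
  }
}

bn_bwd <- function(ly, dy) {
  cc <- ly$cache
  n <- nrow(dy)
  xhat <- cc$xhat
  ly$ggamma <- ly$ggamma + colSums(dy * xhat)
  ly$gbeta <- ly$gbeta + colSums(dy)
  dxhat <- dy * colbc(ly$gamma, n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  (dxhat - colbc(s1 / n, n) - xhat * colbc(s2 / n, n)) * colbc(cc$istd, n)
}

# Mask-attention fusion over two feature streams (image path a, attention-map
# path b): 1x1 projections, inner-product similarity, column softmax, and
# attention-weighted aggregation of a value projection of the image stream.
layer_attention <- function(ch, proj_ch = max(ch %/% 8L, 1L)) {
  ly <- new_layer("attention", c("Wa", "Wb", "Wv"))
  ly$Wa <- matrix(stats::rnorm(ch * proj_ch, 0, INIT_SD), ch, proj_ch)
  ly$Wb <- matrix(stats::rnorm(ch * proj_ch, 0, INIT_SD), ch, proj_ch)
  ly$Wv <- matrix(stats::rnorm(ch * ch, 0, INIT_SD), ch, ch)
  ly$ch <- ch; ly$proj_ch <- proj_ch
  ly
}

softmax_cols <- function(s) {
  m <- apply(s, 2, max)
  e <- exp(s - matrix(m, nrow(s), ncol(s), byrow = TRUE))
  e / matrix(colSums(e), nrow(s), ncol(s), byrow = TRUE)
}

att_fwd <- function(ly, fa, fb, training = FALSE) {
  A <- fa %*% ly$Wa
  B <- fb %*% ly$Wb
  V <- fa %*% ly$Wv
  S <- tcrossprod(A, B)          # S[i, j] = <A_i, B_j>
  D <- softmax_cols(S)
  out <- crossprod(D, V)         # out_j = sum_i D[i, j] V_i
  if (training) ly$cache <- list(fa = fa, fb = fb, A = A, B = B, V = V, D = D)
  out
}

att_bwd <- function(ly, dout) {
  cc <- ly$cache
  D <- cc$D
  dV <- D %*% dout
  dD <- tcrossprod(cc$V, dout)
  s <- colSums(D * dD)
  dS <- D * (dD - matrix(s, nrow(D), ncol(D), byrow = TRUE))
  dA <- dS %*% cc$B
  dB <- crossprod(dS, cc$A)
  ly$gWa <- ly$gWa + crossprod(cc$fa, dA)
  ly$gWb <- ly$gWb + crossprod(cc$fb, dB)
  ly$gWv <- ly$gWv + crossprod(cc$fa, dV)
  list(dfa = tcrossprod(dA, ly$Wa) + tcrossprod(dV, ly$Wv),
       dfb = tcrossprod(dB, ly$Wb))
}

relu <- function(x) pmax(x, 0)

# ---- optimizer --------------------------------------------------------------

zero_grads <- function(layers) {
  for (ly in layers)
    for (nm in ly$params) {
      gn <- paste0("g", nm)
      if (is.null(ly[[gn]]) || length(ly[[gn]]) != length(ly[[nm]]))
        ly[[gn]] <- ly[[nm]] * 0
      else ly[[gn]][] <- 0
    }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(layers, lr, beta1, beta2, eps, t) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (ly in layers) {
    for (nm in ly$params) {
      mn <- paste0("m_", nm); vn <- paste0("v_", nm)
      if (is.null(ly[[mn]])) {
        ly[[mn]] <- ly[[nm]] * 0
        ly[[vn]] <- ly[[nm]] * 0
      }
      adam_update_cpp(ly[[nm]], ly[[mn]], ly[[vn]], ly[[paste0("g", nm)]],
                      lr, beta1, beta2, eps, c1, c2)
    }
  }
  invisible(NULL)
}

# serializable parameter dump / restore (flat layer order is deterministic)
layers_dump <- function(layers)
  lapply(layers, function(ly) mget(c(ly$params, ly$buffers), envir = ly))

layers_restore <- function(layers, dump) {
  stopifnot(length(layers) == length(dump))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    # copy (+ 0) so in-place optimizer updates never alias the dump
    for (nm in c(ly$params, ly$buffers)) ly[[nm]] <- dump[[i]][[nm]] + 0
  }
  invisible(NULL)
}
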