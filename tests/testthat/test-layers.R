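# Finite-difference gradient checks for the network primitives. These are
# the foundation the adversarial training rests on.

test_that("convolution forward/backward match finite differences", {
  ns <- asNamespace("ctinpaint")
  with_seed_local(11, {
    ly <- ns$layer_conv(2, 3, k = 3, stride = 2, pad = 1, dil = 1)
    x <- matrix(rnorm(36 * 2), 36, 2)  # 6x6, 2 channels
    tgt <- matrix(rnorm(9 * 3), 9, 3)
  })
  obj <- function(xm, W = ly$W, b = ly$b)
    sum((ns$im2col_cpp(xm, 6L, 6L, 3L, 2L, 1L, 1L) %*% W +
           rep(b, each = 9)) * tgt)
  ns$zero_grads(list(ly))
  out <- ns$conv_fwd(ly, x, 6, 6, training = TRUE)
  expect_equal(dim(out$y), c(9, 3))
  dx <- ns$conv_bwd(ly, tgt)
  expect_lt(max_rel_err(dx, num_grad(obj, x)), 1e-6)
  expect_lt(max_rel_err(ly$gW,
                        num_grad(function(W) obj(x, W = matrix(W, nrow(ly$W))),
                                 ly$W)), 1e-6)
  expect_lt(max_rel_err(as.numeric(ly$gb),
                        num_grad(function(b) obj(x, b = b), ly$b)), 1e-6)
})

test_that("dilated convolution halves the side and backpropagates correctly", {
  ns <- asNamespace("ctinpaint")
  with_seed_local(12, {
    ly <- ns$layer_conv(1, 2, k = 4, stride = 2, pad = 3, dil = 2)
    x <- matrix(rnorm(64), 64, 1)
  })
  out <- ns$conv_fwd(ly, x, 8, 8, training = TRUE)
  expect_equal(out$h, 4)  # effective kernel 7 still halves the side
  tgt <- with_seed_local(13, matrix(rnorm(16 * 2), 16, 2))
  ns$zero_grads(list(ly))
  dx <- ns$conv_bwd(ly, tgt)
  obj <- function(z)
    sum((ns$im2col_cpp(z, 8L, 8L, 4L, 2L, 3L, 2L) %*% ly$W +
           rep(ly$b, each = 16)) * tgt)
  expect_lt(max_rel_err(dx, num_grad(obj, x)), 1e-6)
})

test_that("transposed convolution is the exact adjoint of convolution", {
  ns <- asNamespace("ctinpaint")
  with_seed_local(14, {
    lt <- ns$layer_convt(3, 2, k = 4, stride = 2, pad = 1)
    x <- matrix(rnorm(4 * 3), 4, 3)  # 2x2 in -> 4x4 out
    tgt <- matrix(rnorm(16 * 2), 16, 2)
  })
  out <- ns$convt_fwd(lt, x, 2, 2, training = TRUE)
  expect_equal(out$h, 4)
  # adjointness: <conv^T(x), y> == <x, conv(y)> for the underlying linear maps
  y <- with_seed_local(15, matrix(rnorm(16 * 2), 16, 2))
  lhs <- sum((out$y - rep(lt$b, each = 16)) * y)
  rhs <- sum(x * (ns$im2col_cpp(y, 4L, 4L, 4L, 2L, 1L, 1L) %*% lt$W))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  ns$zero_grads(list(lt))
  dx <- ns$convt_bwd(lt, tgt)
  obj <- function(z, W = lt$W)
    sum((ns$col2im_cpp(z %*% t(W), 4L, 4L, 2L, 4L, 2L, 1L, 1L) +
           rep(lt$b, each = 16)) * tgt)
  expect_lt(max_rel_err(dx, num_grad(obj, x)), 1e-6)
  expect_lt(max_rel_err(lt$gW,
                        num_grad(function(W) obj(x, W = matrix(W, nrow(lt$W))),
                                 lt$W)), 1e-6)
})

test_that("batch normalization at batch size one matches finite differences", {
  ns <- asNamespace("ctinpaint")
  with_seed_local(16, {
    lb <- ns$layer_bn(3)
    x <- matrix(rnorm(30), 10, 3)
    tgt <- matrix(rnorm(30), 10, 3)
  })
  obj <- function(z, g = lb$gamma) {
    mu <- colMeans(z)
    zc <- z - rep(mu, each = 10)
    v <- colMeans(zc^2)
    xh <- zc * rep(1 / sqrt(v + lb$eps), each = 10)
    sum((xh * rep(g, each = 10) + rep(lb$beta, each = 10)) * tgt)
  }
  ns$zero_grads(list(lb))
  y <- ns$bn_fwd(lb, x, training = TRUE)
  expect_lt(max(abs(colMeans(y - rep(lb$beta, each = 10)))), 1e-8)
  dx <- ns$bn_bwd(lb, tgt)
  expect_lt(max_rel_err(dx, num_grad(function(z) obj(z), x)), 1e-5)
  expect_lt(max_rel_err(as.numeric(lb$ggamma),
                        num_grad(function(g) obj(x, g = g), lb$gamma)), 1e-6)
  # evaluation mode uses running averages: deterministic and different from
  # batch statistics on fresh data
  y1 <- ns$bn_fwd(lb, x, training = FALSE)
  y2 <- ns$bn_fwd(lb, x, training = FALSE)
  expect_identical(y1, y2)
})

test_that("attention fusion layer backpropagates to both streams and weights", {
  ns <- asNamespace("ctinpaint")
  with_seed_local(17, {
    la <- ns$layer_attention(4, 2)
    fa <- matrix(rnorm(24), 6, 4)
    fb <- matrix(rnorm(24), 6, 4)
    tgt <- matrix(rnorm(24), 6, 4)
  })
  obj <- function(fa_, fb_, Wv = la$Wv) {
    A <- fa_ %*% la$Wa; B <- fb_ %*% la$Wb; V <- fa_ %*% Wv
    S <- tcrossprod(A, B)
    D <- apply(S, 2, function(s) { e <- exp(s - max(s)); e / sum(e) })
    sum(crossprod(D, V) * tgt)
  }
  ns$zero_grads(list(la))
  out <- ns$att_fwd(la, fa, fb, training = TRUE)
  expect_equal(dim(out), c(6, 4))
  d <- ns$att_bwd(la, tgt)
  expect_lt(max_rel_err(d$dfa,
                        num_grad(function(z) obj(matrix(z, 6, 4), fb), fa)),
            1e-5)
  expect_lt(max_rel_err(d$dfb,
                        num_grad(function(z) obj(fa, matrix(z, 6, 4)), fb)),
            1e-5)
  expect_lt(max_rel_err(la$gWv,
                        num_grad(function(W) obj(fa, fb, Wv = matrix(W, 4, 4)),
                                 la$Wv)), 1e-6)
})

test_that("the Adam step matches the reference update rule", {
  ns <- asNamespace("ctinpaint")
  ly <- ns$new_layer("conv", "W")
  ly$W <- matrix(c(1, -2, 0.5, 3), 2, 2)
  ly$gW <- matrix(c(0.1, -0.2, 0, 1), 2, 2)
  ns$adam_step(list(ly), lr = 0.1, beta1 = 0.5, beta2 = 0.999,
               eps = 1e-8, t = 1)
  m <- 0.5 * ly$gW  # first step from zero moments
  v <- 0.001 * ly$gW^2
  want <- matrix(c(1, -2, 0.5, 3), 2, 2) -
    0.1 * (m / 0.5) / (sqrt(v / 0.001) + 1e-8)
  expect_equal(ly$W, want, tolerance = 1e-12)
})
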