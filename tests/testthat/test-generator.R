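test_that("generator configs validate the power-of-two contract", {
  expect_error(generator_config(input_size = 48),
               class = "ctinpaint_invalid_config")
  expect_error(generator_config(input_size = 64, depth = 5),
               class = "ctinpaint_invalid_config")
  cfg <- generator_config()
  expect_equal(cfg$input_size, 512L)
  expect_equal(cfg$depth, 9L)
  expect_equal(max(ctinpaint:::gen_channels(cfg)), 1024L)
})

test_that("contracting path halves and expansive path doubles exactly", {
  # scaled configuration: size 16, depth 4; bottleneck must reach 1x1
  cfg <- generator_config(input_size = 16, base_channels = 4,
                          max_channels = 16, dilation_blocks = 2,
                          dropout_rate = 0, attention_max_side = 4)
  g <- build_generator(cfg, seed = 2)
  x <- with_seed_local(3, matrix(rnorm(256), 16, 16))
  y <- generator_forward(g, x, x)
  expect_equal(dim(y), c(16, 16))
  fs <- g$feature_summary
  expect_equal(fs$enc_sides, 2L^((cfg$depth - 1):0))     # 8, 4, 2, 1
  expect_equal(fs$enc_channels, c(4L, 8L, 16L, 16L))
  expect_true(all(is.finite(y)))
})

test_that("evaluation-mode forward is deterministic", {
  cfg <- toy_generator_config(64)
  g <- build_generator(cfg, seed = 5)
  x <- with_seed_local(6, matrix(rnorm(64 * 64), 64, 64))
  expect_identical(generator_forward(g, x, x), generator_forward(g, x, x))
  # identical seeds build identical parameters
  g2 <- build_generator(cfg, seed = 5)
  expect_identical(generator_forward(g2, x, x), generator_forward(g, x, x))
})

test_that("every generator parameter receives gradient on a random batch", {
  cfg <- toy_generator_config(64)
  g <- build_generator(cfg, seed = 7)
  with_seed_local(8, {
    img <- matrix(rnorm(64 * 64), 64, 64)
    att <- matrix(rnorm(64 * 64), 64, 64)
    tgt <- matrix(rnorm(64 * 64), 64, 64)
  })
  ctinpaint:::zero_grads(g$layers)
  out <- generator_forward(g, img, att, training = TRUE)
  ctinpaint:::generator_backward(g, sign(out - tgt) / length(out))
  for (ly in g$layers)
    for (nm in ly$params)
      expect_gt(max(abs(ly[[paste0("g", nm)]])), 0)
})

test_that("generator parameter gradients match finite differences end to end", {
  cfg <- generator_config(input_size = 16, base_channels = 4,
                          max_channels = 16, dilation_blocks = 2,
                          dropout_rate = 0, attention_max_side = 4)
  g <- build_generator(cfg, seed = 9)
  with_seed_local(10, {
    img <- matrix(rnorm(256), 16, 16)
    att <- matrix(rnorm(256), 16, 16)
    tgt <- matrix(rnorm(256), 16, 16)
  })
  ctinpaint:::zero_grads(g$layers)
  generator_forward(g, img, att, training = TRUE)
  ctinpaint:::generator_backward(g, tgt)
  # probe a handful of weights in distinct places: first conv of each
  # encoder, an attention projection, a decoder up-convolution
  probes <- list(g$enc_a[[1]]$conv, g$enc_b[[2]]$conv,
                 g$dec[[2]]$convt, g$fuse)
  for (ly in probes) {
    W0 <- ly$W
    ii <- with_seed_local(11, sample(length(W0), 3))
    for (i in ii) {
      e <- 1e-5
      ly$W[i] <- W0[i] + e
      v1 <- sum(generator_forward(g, img, att, training = TRUE) * tgt)
      ly$W[i] <- W0[i] - e
      v2 <- sum(generator_forward(g, img, att, training = TRUE) * tgt)
      ly$W <- W0
      expect_equal(ly$gW[i], (v1 - v2) / (2 * e), tolerance = 1e-4)
    }
  }
})

test_that("generator_l1_loss matches hand arithmetic", {
  expect_equal(generator_l1_loss(matrix(1, 3, 3), matrix(1, 3, 3)), 0)
  expect_equal(generator_l1_loss(matrix(1, 4, 4), matrix(0, 4, 4)), 1)
  # 2x2 hand case
  expect_equal(generator_l1_loss(matrix(c(0, 4, 2, 6), 2, 2),
                                 matrix(c(1, 5, 1, 5), 2, 2)), 1)
  expect_error(generator_l1_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "ctinpaint_shape_mismatch")
})
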