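test_that("normalize_slice standardizes with the population convention and inverts", {
  # frozen oracle: pixels {0, 100, 200} -> mean 100, population sd 81.6497
  n <- normalize_slice(matrix(c(0, 100, 200), 1, 3))
  expect_equal(n$source_mean, 100)
  expect_equal(n$source_sd, 81.649658, tolerance = 1e-6)
  expect_equal(as.vector(n$pixels), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)

  # identity case: an already standardized slice passes through (up to its
  # own statistics being ~0/~1)
  z <- with_seed_local(4, matrix(rnorm(64), 8, 8))
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  expect_equal(normalize_slice(z)$pixels, z, tolerance = 1e-10)

  # per-slice statistics obey the type invariants, and round trips recover
  # the source for a spread of random slices
  for (s in 1:5) {
    px <- tiny_slice(8, seed = s)
    nz <- normalize_slice(px)
    expect_lt(abs(mean(nz$pixels)), 1e-5)
    expect_lt(abs(sqrt(mean((nz$pixels - mean(nz$pixels))^2)) - 1), 1e-5)
    expect_equal(denormalize_slice(nz), px, tolerance = 1e-4)
  }

  expect_error(normalize_slice(matrix(500, 4, 4)),
               class = "ctinpaint_degenerate_image")
})

test_that("make_attention_map whitens exactly the masked pixels and is idempotent", {
  px <- tiny_slice(10, seed = 2)
  mk <- block_mask(10, 3, 4, 2, 5)  # 10 pixels
  am <- make_attention_map(px, mk)
  expect_s3_class(am, "attention_map")
  expect_equal(sum(am$pixels != px), 10)
  expect_true(all(am$pixels[mk == 1] == 4096))
  expect_equal(am$pixels[mk == 0], px[mk == 0])

  # idempotence
  am2 <- make_attention_map(am$pixels, mk)
  expect_identical(am2$pixels, am$pixels)

  # empty and saturating masks
  expect_identical(make_attention_map(px, matrix(0, 10, 10))$pixels, px)
  expect_true(all(make_attention_map(px, matrix(1, 10, 10))$pixels == 4096))

  expect_error(make_attention_map(px, matrix(0, 4, 4)),
               class = "ctinpaint_shape_mismatch")
})

test_that("ct_slice and tumor_mask enforce their invariants", {
  expect_error(ct_slice(matrix(-5, 2, 2)), class = "ctinpaint_invalid_input")
  expect_error(ct_slice(matrix(5000, 2, 2)), class = "ctinpaint_invalid_input")
  expect_error(tumor_mask(matrix(2, 2, 2)), class = "ctinpaint_invalid_input")
  s <- ct_slice(tiny_slice(6), spacing = c(0.7, 0.7))
  expect_equal(s$height, 6)
  expect_equal(s$spacing, c(0.7, 0.7))
})

test_that("16-bit containers round-trip integer slices exactly", {
  px <- with_seed_local(9, matrix(sample(0:4096, 64, replace = TRUE), 8, 8))
  for (ext in c(".tif", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_slice(px, f)
    expect_equal(read_slice(f)$pixels, px, ignore_attr = TRUE)
    unlink(f)
  }
})

test_that("8-bit PNG input maps linearly onto the 12-bit range", {
  f <- tempfile(fileext = ".png")
  px8 <- matrix(c(0, 51, 102, 255), 2, 2)
  png::writePNG(px8 / 255, f)
  r <- read_slice(f)
  expect_equal(r$pixels, px8 * 4096 / 255, ignore_attr = TRUE)
  unlink(f)
})

test_that("unreadable inputs raise classed errors", {
  f <- tempfile(fileext = ".tif")
  writeLines("not an image", f)
  expect_error(read_slice(f), class = "ctinpaint_corrupt_file")
  expect_error(read_slice(tempfile(fileext = ".tif")),
               class = "ctinpaint_corrupt_file")
  expect_error(read_slice(f, format = "bmp"),
               class = "ctinpaint_unsupported_format")
  unlink(f)
})

test_that("pairings validate shape and carry their label", {
  px <- tiny_slice(6)
  am <- make_attention_map(px, block_mask(6, 2, 2))
  p <- pairing(px, am, "A_real")
  expect_equal(p$label, "A_real")
  expect_error(pairing(matrix(0, 3, 3), am),
               class = "ctinpaint_shape_mismatch")
})
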