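test_that("harvest_patches crops one patch per connected component", {
  px <- tiny_slice(16, seed = 3)
  mk <- block_mask(16, 2, 2, 3, 3) + block_mask(16, 10, 11, 2, 2)
  pats <- harvest_patches(px, mk, margin = 1)
  expect_length(pats, 2)
  # single 3x3 blob with margin 1 -> 5x5 patch
  expect_equal(dim(pats[[1]]$pixels), c(5, 5))
  expect_equal(sum(pats[[1]]$mask), 9)
  expect_error(harvest_patches(px, matrix(0, 16, 16)),
               class = "ctinpaint_empty_mask")
})

test_that("patches touching the border are clipped to image bounds", {
  n <- 12
  px <- tiny_slice(n, seed = 5)
  mk <- matrix(0, n, n)
  mk[1:3, 10:12] <- 1  # touches top and right borders
  pats <- harvest_patches(px, mk, margin = 2)
  expect_length(pats, 1)
  # brute-force bounding-box oracle
  idx <- which(mk == 1, arr.ind = TRUE)
  r <- range(idx[, 1]); cc <- range(idx[, 2])
  exp_rows <- max(r[1] - 2, 1):min(r[2] + 2, n)
  exp_cols <- max(cc[1] - 2, 1):min(cc[2] + 2, n)
  expect_identical(pats[[1]]$pixels, px[exp_rows, exp_cols])
  expect_equal(unname(pats[[1]]$offset), c(exp_rows[1], exp_cols[1]))
})

test_that("right-angle transforms reproduce the dihedral orbit exactly", {
  p <- structure(list(pixels = matrix(c(1, 2, 3, 4), 2, 2),
                      mask = matrix(c(1, 0, 0, 1), 2, 2),
                      offset = c(row = 1, col = 1)), class = "tumor_patch")
  got <- list()
  for (hf in c(FALSE, TRUE)) for (ang in c(0, 90, 180, 270))
    got <- c(got, list(patch_transform(p, hflip = hf, angle = ang)$pixels))
  got <- unique(got)
  want <- dihedral_orbit(p$pixels)
  expect_length(got, 8)
  expect_length(want, 8)
  for (w in want)
    expect_true(any(vapply(got, identical, TRUE, y = w)))
})

test_that("masks stay binary and aligned under arbitrary rotation and scale", {
  ph <- generate_phantom(phantom_spec(seed = 41))
  pats <- harvest_patches(ph$slice, ph$mask)
  for (i in 1:6) {
    tp <- patch_transform(pats[[1]], hflip = i %% 2 == 0,
                          angle = i * 53.7, scale = 0.8 + i * 0.08)
    expect_true(all(tp$mask %in% c(0, 1)))
    expect_gt(sum(tp$mask), 0)
    expect_identical(dim(tp$pixels), dim(tp$mask))
    expect_true(all(tp$pixels >= 0 & tp$pixels <= 4096))
  }
})

test_that("augment_patches hits the target count deterministically with a manifest", {
  ph <- generate_phantom(phantom_spec(seed = 43, lesion_count_range = c(2, 3)))
  pats <- harvest_patches(ph$slice, ph$mask)
  aug <- augment_patches(pats, 37, seed = 7)
  expect_length(aug, 37)
  man <- attr(aug, "manifest")
  expect_equal(nrow(man), 37)
  expect_true(all(man$source %in% seq_along(pats)))
  # the first length(pats) outputs are the identity originals
  for (i in seq_along(pats))
    expect_identical(aug[[i]]$pixels, pats[[i]]$pixels)
  # target == input count returns the originals
  same <- augment_patches(pats, length(pats), seed = 7)
  expect_identical(lapply(same, `[[`, "pixels"), lapply(pats, `[[`, "pixels"))
  # determinism
  aug2 <- augment_patches(pats, 37, seed = 7)
  expect_identical(lapply(aug, `[[`, "pixels"), lapply(aug2, `[[`, "pixels"))
  expect_false(identical(
    lapply(augment_patches(pats, 37, seed = 8), `[[`, "pixels"),
    lapply(aug, `[[`, "pixels")))
  expect_error(augment_patches(list(), 5), class = "ctinpaint_empty_input")
  expect_error(augment_patches(pats, 1), class = "ctinpaint_invalid_input")
})

test_that("implant_mask whitens the union of placed stencils", {
  px <- tiny_slice(20, seed = 6)
  s1 <- matrix(1, 3, 3)
  s2 <- matrix(1, 2, 4)
  am <- implant_mask(px, s1, c(2, 2))
  am <- implant_mask(am, s2, c(12, 9))
  expect_equal(sum(am$mask$pixels), 9 + 8)
  expect_true(all(am$pixels[am$mask$pixels == 1] == 4096))
  expect_equal(am$pixels[am$mask$pixels == 0], px[am$mask$pixels == 0])
  # empty stencil changes nothing
  am0 <- implant_mask(px, matrix(0, 3, 3), c(5, 5))
  expect_identical(am0$pixels, px)
  expect_equal(sum(am0$mask$pixels), 0)
  expect_error(implant_mask(px, s1, c(19, 19)),
               class = "ctinpaint_out_of_bounds")
})

test_that("re-implanting a harvested mask reproduces the attention map", {
  ph <- generate_phantom(phantom_spec(seed = 47, lesion_count_range = c(1, 1)))
  p <- harvest_patches(ph$slice, ph$mask, margin = 2)[[1]]
  am_direct <- make_attention_map(ph$slice, ph$mask)
  am_implant <- implant_mask(ph$slice, p$mask, p$offset)
  expect_identical(am_implant$pixels, am_direct$pixels)
  expect_identical(am_implant$mask$pixels, am_direct$mask$pixels)
})
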