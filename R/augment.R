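#' Harvest tumor patches from a labeled slice
#'
#' Extracts one patch per connected component of the mask, cropped to the
#' component bounding box plus `margin` pixels and clipped at the image
#' borders. Each patch records its top-left offset in the source slice so a
#' harvested mask can be re-implanted at its original location.
#'
#' @param slice A [ct_slice()] (or matrix).
#' @param mask A [tumor_mask()] aligned with `slice`.
#' @param margin Pixels added around the bounding box.
#' @return List of `tumor_patch` objects (fields `pixels`, `mask`, `offset`).
#' @export
harvest_patches <- function(slice, mask, margin = 2L) {
  px <- as_pixel_matrix(slice)
  if (!inherits(mask, "tumor_mask")) mask <- tumor_mask(mask)
  if (!identical(dim(px), dim(mask$pixels)))
    err_shape("slice and mask must share shape")
  if (sum(mask$pixels) == 0)
    ct_error("empty_mask", "mask has no lesion pixels")
  labels <- EBImage::imageData(EBImage::bwlabel(mask$pixels))
  out <- lapply(seq_len(max(labels)), function(L) {
    idx <- which(labels == L, arr.ind = TRUE)
    r1 <- max(min(idx[, 1]) - margin, 1L)
    r2 <- min(max(idx[, 1]) + margin, nrow(px))
    c1 <- max(min(idx[, 2]) - margin, 1L)
    c2 <- min(max(idx[, 2]) + margin, ncol(px))
    structure(list(pixels = px[r1:r2, c1:c2, drop = FALSE],
                   mask = (labels[r1:r2, c1:c2, drop = FALSE] == L) * 1,
                   offset = c(row = r1, col = c1)),
              class = "tumor_patch")
  })
  out
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Transform a tumor patch
#'
#' Applies, in order: horizontal flip, vertical flip, rotation, isotropic
#' scale. Right-angle rotations are exact grid operations; other angles use
#' bilinear resampling for pixels and nearest-neighbour for the mask, which
#' is re-binarized at 0.5. Pixels are clamped to the raw range.
#'
#' @param patch A `tumor_patch`.
#' @param hflip,vflip Logical flips (columns / rows reversed).
#' @param angle Rotation in degrees.
#' @param scale Isotropic scale factor.
#' @return A transformed `tumor_patch`.
#' @export
patch_transform <- function(patch, hflip = FALSE, vflip = FALSE,
                            angle = 0, scale = 1) {
  px <- patch$pixels
  mk <- patch$mask
  if (hflip) { px <- px[, ncol(px):1, drop = FALSE]
               mk <- mk[, ncol(mk):1, drop = FALSE] }
  if (vflip) { px <- px[nrow(px):1, , drop = FALSE]
               mk <- mk[nrow(mk):1, , drop = FALSE] }
  angle <- angle %% 360
  if (angle %% 90 == 0) {
    for (q in seq_len((angle %/% 90) %% 4)) {
      px <- rot90cw(px); mk <- rot90cw(mk)
    }
  } else if (angle != 0) {
    px <- EBImage::imageData(EBImage::rotate(px, angle, filter = "bilinear",
                                             bg.col = 0))
    mk <- EBImage::imageData(EBImage::rotate(mk, angle, filter = "none",
                                             bg.col = 0))
  }
  if (scale != 1) {
    nr <- max(1L, as.integer(round(nrow(px) * scale)))
    nc <- max(1L, as.integer(round(ncol(px) * scale)))
    px <- EBImage::imageData(EBImage::resize(px, w = nr, h = nc,
                                             filter = "bilinear"))
    mk <- EBImage::imageData(EBImage::resize(mk, w = nr, h = nc,
                                             filter = "none"))
  }
  mk <- (mk > 0.5) * 1
  if (sum(mk) == 0) mk[which.max(patch_center_weight(mk))] <- 1
  px[px < 0] <- 0
  px[px > RAW_MAX] <- RAW_MAX
  structure(list(pixels = px, mask = mk, offset = patch$offset),
            class = "tumor_patch")
}

# tie-break helper used only when resampling erases a tiny mask: prefer the
# center pixel
patch_center_weight <- function(m) {
  rr <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cc <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  -( (rr - (nrow(m) + 1) / 2)^2 + (cc - (ncol(m) + 1) / 2)^2 )
}

#' Expand a patch set to a target count by random flips, rotations and scales
#'
#' The first `length(patches)` outputs are the originals (identity
#' transform); the remainder are drawn with replacement over (patch,
#' transform) pairs, with continuous rotation angles in `[0, 360)` and scales
#' uniform in `scale_range`. Deterministic given `seed`. The transform of
#' every output is recorded in the `manifest` attribute (a data frame).
#'
#' @param patches Nonempty list of `tumor_patch` objects.
#' @param target_count Desired output count (`>= length(patches)`).
#' @param seed Integer seed.
#' @param scale_range Uniform range of isotropic scale factors.
#' @return List of `target_count` patches with a `manifest` attribute.
#' @export
augment_patches <- function(patches, target_count, seed = 1L,
                            scale_range = c(0.75, 1.25)) {
  if (length(patches) == 0) ct_error("empty_input", "no patches to augment")
  n0 <- length(patches)
  if (target_count < n0)
    ct_error("invalid_input", "target_count must be at least length(patches)")
  k <- target_count - n0
  with_seed(seed, {
    manifest <- data.frame(
      index = seq_len(target_count),
      source = c(seq_len(n0), if (k > 0) sample.int(n0, k, replace = TRUE)),
      hflip = c(rep(FALSE, n0), if (k > 0) stats::runif(k) < 0.5),
      vflip = c(rep(FALSE, n0), if (k > 0) stats::runif(k) < 0.5),
      angle = c(rep(0, n0), if (k > 0) stats::runif(k, 0, 360)),
      scale = c(rep(1, n0), if (k > 0) stats::runif(k, scale_range[1],
                                                    scale_range[2])))
  })
  out <- vector("list", target_count)
  out[seq_len(n0)] <- patches
  for (i in seq_len(k)) {
    row <- manifest[n0 + i, ]
    out[[n0 + i]] <- patch_transform(patches[[row$source]], row$hflip,
                                     row$vflip, row$angle, row$scale)
  }
  attr(out, "manifest") <- manifest
  out
}

#' Whiten a stencil region on a healthy slice
#'
#' Places a binary stencil (for example a harvested, augmented tumor-patch
#' mask) at `location` on a healthy slice and whitens those pixels, producing
#' the attention map that asks the generator to synthesize a tumor there.
#' Calling it again on the returned attention map accumulates regions.
#'
#' @param healthy A [ct_slice()] or an `attention_map` from a previous call.
#' @param stencil Binary matrix (or `tumor_mask` / `tumor_patch`).
#' @param location `(row, col)` of the stencil's top-left corner, 1-based.
#' @return An `attention_map` whose `mask` field is the accumulated
#'   implanted [tumor_mask()].
#' @export
implant_mask <- function(healthy, stencil, location) {
  if (inherits(stencil, "tumor_patch")) stencil <- stencil$mask
  if (inherits(stencil, "tumor_mask")) stencil <- stencil$pixels
  stencil <- as_pixel_matrix(stencil)
  if (!all(stencil %in% c(0, 1)))
    ct_error("invalid_input", "stencil must be binary")
  if (inherits(healthy, "attention_map")) {
    base_mask <- healthy$mask$pixels
    base_px <- healthy$pixels
  } else {
    base_px <- as_pixel_matrix(healthy)
    base_mask <- matrix(0, nrow(base_px), ncol(base_px))
  }
  r1 <- location[1]; c1 <- location[2]
  r2 <- r1 + nrow(stencil) - 1L
  c2 <- c1 + ncol(stencil) - 1L
  if (r1 < 1 || c1 < 1 || r2 > nrow(base_px) || c2 > ncol(base_px))
    ct_error("out_of_bounds",
             "stencil placed at this location exceeds the image extent")
  base_mask[r1:r2, c1:c2] <- pmax(base_mask[r1:r2, c1:c2], stencil)
  make_attention_map(base_px, tumor_mask(base_mask))
}
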