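#' @useDynLib ctinpaint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# White value used to mark tumor pixels in an attention map. The raw CT
# representation spans [0, 4096]; the marker is stored literally and only
# clamped when exporting to integer containers.
WHITE_VALUE <- 4096
RAW_MAX <- 4096

#' Construct a CT slice
#'
#' A `ct_slice` holds one 2D grayscale slice of raw scanner intensities in
#' `[0, 4096]` plus optional pixel-spacing metadata. Pixels are stored as a
#' numeric matrix, row-major semantics with origin at the top-left.
#'
#' @param pixels Numeric matrix of intensities.
#' @param spacing Optional numeric length-2 vector, physical (row, col) pixel
#'   size in mm.
#' @return An object of class `ct_slice` with fields `pixels`, `height`,
#'   `width`, `spacing`.
#' @export
ct_slice <- function(pixels, spacing = NULL) {
  pixels <- as_pixel_matrix(pixels)
  if (!all(is.finite(pixels)))
    ct_error("invalid_input", "slice pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > RAW_MAX)
    ct_error("invalid_input",
             sprintf("raw slice intensities must lie in [0, %d]", RAW_MAX))
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0))
      ct_error("invalid_input", "spacing must be two positive numbers (mm)")
  }
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
                 spacing = spacing),
            class = "ct_slice")
}

#' Construct a binary tumor mask
#'
#' @param pixels Matrix with values in `{0, 1}`; 1 marks lesion pixels.
#' @return An object of class `tumor_mask`.
#' @export
tumor_mask <- function(pixels) {
  pixels <- as_pixel_matrix(pixels)
  if (!all(pixels %in% c(0, 1)))
    ct_error("invalid_input", "mask values must be 0 or 1")
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels)),
            class = "tumor_mask")
}

as_pixel_matrix <- function(x) {
  if (inherits(x, c("ct_slice", "tumor_mask", "attention_map",
                    "normalized_slice")))
    return(x$pixels)
  if (!is.matrix(x)) {
    if (is.array(x) && length(dim(x)) == 2) x <- as.matrix(x)
    else ct_error("invalid_input", "pixels must be a 2D matrix")
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice %dx%d, range [%.0f, %.0f]%s>\n",
              x$height, x$width, min(x$pixels), max(x$pixels),
              if (is.null(x$spacing)) ""
              else sprintf(", spacing %.2fx%.2f mm", x$spacing[1], x$spacing[2])))
  invisible(x)
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask %dx%d, %d lesion pixels>\n",
              x$height, x$width, sum(x$pixels)))
  invisible(x)
}

#' Standardize a slice to zero mean and unit variance
#'
#' Applies the per-slice standardization
#' `value_normalized = (value_original - mean) / std`, with the standard
#' deviation computed under the population convention (divide by the pixel
#' count). The slice statistics are stored so [denormalize_slice()] can invert
#' the transform.
#'
#' @param slice A [ct_slice()] (or plain matrix).
#' @return A `normalized_slice` with fields `pixels`, `source_mean`,
#'   `source_sd`.
#' @export
normalize_slice <- function(slice) {
  px <- as_pixel_matrix(slice)
  if (length(px) < 2)
    ct_error("degenerate_image", "slice must have at least 2 pixels")
  m <- mean(px)
  s <- sqrt(mean((px - m)^2))
  if (s == 0)
    ct_error("degenerate_image",
             "constant slice: standard deviation is zero, cannot standardize")
  structure(list(pixels = (px - m) / s, source_mean = m, source_sd = s),
            class = "normalized_slice")
}

#' Invert [normalize_slice()]
#'
#' @param norm A `normalized_slice`, or a plain matrix together with explicit
#'   `mean` and `sd`.
#' @param mean,sd Statistics to invert with; default taken from `norm`.
#' @return A numeric matrix of raw-scale intensities.
#' @export
denormalize_slice <- function(norm, mean = NULL, sd = NULL) {
  if (inherits(norm, "normalized_slice")) {
    if (is.null(mean)) mean <- norm$source_mean
    if (is.null(sd)) sd <- norm$source_sd
    px <- norm$pixels
  } else {
    px <- as_pixel_matrix(norm)
    if (is.null(mean) || is.null(sd))
      ct_error("invalid_input", "mean and sd required for a plain matrix")
  }
  px * sd + mean
}

#' Build an attention map by whitening masked pixels
#'
#' Copies the slice and sets every pixel where the mask is 1 to the white
#' value 4096, signalling the region the generator must synthesize. The
#' operation is idempotent for a fixed mask.
#'
#' @param slice A [ct_slice()] or matrix.
#' @param mask A [tumor_mask()] or binary matrix of the same shape.
#' @return An `attention_map` with fields `pixels` and `mask`.
#' @export
make_attention_map <- function(slice, mask) {
  px <- as_pixel_matrix(slice)
  if (!inherits(mask, "tumor_mask")) mask <- tumor_mask(mask)
  if (!identical(dim(px), dim(mask$pixels)))
    err_shape(sprintf("slice is %dx%d but mask is %dx%d",
                      nrow(px), ncol(px), mask$height, mask$width))
  px[mask$pixels == 1] <- WHITE_VALUE
  structure(list(pixels = px, mask = mask), class = "attention_map")
}

#' Pair an image with its attention map
#'
#' Pairing A couples the real image with the attention map; pairing B couples
#' the synthesized image with the same attention map. The discriminator judges
#' both.
#'
#' @param image A slice (real or synthesized); `ct_slice` or matrix.
#' @param attention An `attention_map` (or matrix).
#' @param label `"A_real"` or `"B_synth"`.
#' @return A `pairing` object.
#' @export
pairing <- function(image, attention, label = c("A_real", "B_synth")) {
  label <- match.arg(label)
  img <- as_pixel_matrix(image)
  att <- as_pixel_matrix(attention)
  if (!identical(dim(img), dim(att)))
    err_shape("image and attention map must share shape")
  structure(list(image = img, attention = att, label = label),
            class = "pairing")
}

# ---- file I/O ---------------------------------------------------------------

SUPPORTED_FORMATS <- c("nifti", "png", "tiff")

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
         nii = "nifti", png = "png", tif = "tiff", tiff = "tiff",
         ct_error("unsupported_format",
                  sprintf("cannot infer format from extension '.%s'", ext)))
}

#' Read a CT slice from disk
#'
#' Supports NIfTI volumes (one axial slice extracted via `slice_index`),
#' and 8- or 16-bit grayscale PNG/TIFF. 16-bit containers round-trip integer
#' intensities in `[0, 4096]` exactly; 8-bit input is rescaled by the fixed
#' factor 4096/255 (documented linear map onto the 12-bit range).
#'
#' @param path File path.
#' @param format One of `"auto"`, `"nifti"`, `"png"`, `"tiff"`.
#' @param slice_index Axial index for NIfTI volumes (default 1).
#' @return A [ct_slice()].
#' @export
read_slice <- function(path, format = "auto", slice_index = 1L) {
  if (!file.exists(path))
    ct_error("corrupt_file", sprintf("file not found: %s", path))
  if (identical(format, "auto")) format <- guess_format(path)
  if (!format %in% SUPPORTED_FORMATS)
    ct_error("unsupported_format", sprintf("unsupported format '%s'", format))
  px <- tryCatch(switch(format,
    nifti = {
      vol <- RNifti::asNifti(RNifti::readNifti(path))
      arr <- as.array(vol)
      if (length(dim(arr)) == 2) arr
      else arr[, , slice_index]
    },
    png = {
      img <- png::readPNG(path, info = TRUE)
      depth <- attr(img, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      if (length(dim(img)) == 3) img <- img[, , 1]  # first channel of RGB(A)
      if (depth >= 16) round(img * 65535) else round(img * 255) * RAW_MAX / 255
    },
    tiff = {
      img <- tiff::readTIFF(path)
      if (length(dim(img)) == 3) img <- img[, , 1]
      round(img * 65535)
    }),
    error = function(e) {
      if (inherits(e, "ctinpaint_error")) stop(e)
      ct_error("corrupt_file", sprintf("failed to read %s: %s",
                                       path, conditionMessage(e)))
    })
  px[px > RAW_MAX] <- RAW_MAX
  px[px < 0] <- 0
  ct_slice(px)
}

#' Write a CT slice to disk
#'
#' The default container is 16-bit TIFF, which round-trips integer intensities
#' in `[0, 4096]` bit-exactly; NIfTI is likewise lossless. PNG export is 8-bit
#' (the inverse of the fixed 4096/255 read factor) because the installed PNG
#' writer has no 16-bit mode. Intensities are clamped to `[0, 4096]` on export.
#'
#' @param slice A [ct_slice()] or matrix.
#' @param path Output path.
#' @param format One of `"auto"`, `"tiff"`, `"png"`, `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_slice <- function(slice, path, format = "auto") {
  px <- as_pixel_matrix(slice)
  px[px > RAW_MAX] <- RAW_MAX
  px[px < 0] <- 0
  if (identical(format, "auto")) format <- guess_format(path)
  if (!format %in% SUPPORTED_FORMATS)
    ct_error("unsupported_format", sprintf("unsupported format '%s'", format))
  switch(format,
    tiff = tiff::writeTIFF(round(px) / 65535, path, bits.per.sample = 16L),
    png = png::writePNG(round(px * 255 / RAW_MAX) / 255, path),
    nifti = RNifti::writeNifti(RNifti::asNifti(round(px)), path))
  invisible(path)
}
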