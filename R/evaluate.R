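#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels, with MSE the mean squared
#' pixel difference. Identical images return `Inf` (zero-MSE sentinel). The
#' default range 4095 is the 12-bit CT convention matching the raw `[0, 4096]`
#' representation. With `mask` given, only masked pixels are scored
#' (whitened-region evaluation).
#'
#' @param real,synth Slices ([ct_slice()] or matrices) of equal shape.
#' @param data_range Peak intensity span (must be positive).
#' @param mask Optional binary matrix / [tumor_mask()] restricting the score.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(real, synth, data_range = 4095, mask = NULL) {
  a <- as_pixel_matrix(real)
  b <- as_pixel_matrix(synth)
  if (!identical(dim(a), dim(b)))
    err_shape("images must share shape")
  if (!is.numeric(data_range) || data_range <= 0)
    ct_error("invalid_input", "data_range must be positive")
  if (!is.null(mask)) {
    m <- as_pixel_matrix(mask) == 1
    if (!identical(dim(m), dim(a)))
      err_shape("mask must share the image shape")
    if (!any(m)) ct_error("empty_mask", "mask selects no pixels")
    a <- a[m]; b <- b[m]
  }
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Per-pixel absolute difference map with a color rendering
#'
#' @param real,synth Slices of equal shape.
#' @param palette Name of a [grDevices::hcl.colors()] palette.
#' @return A `difference_map`: `values` (absolute differences), `rgb`
#'   (`h x w x 3` rendering), `scale` (value mapped to the top color),
#'   `palette`.
#' @export
difference_map <- function(real, synth, palette = "viridis") {
  a <- as_pixel_matrix(real)
  b <- as_pixel_matrix(synth)
  if (!identical(dim(a), dim(b)))
    err_shape("images must share shape")
  v <- abs(a - b)
  sc <- max(v)
  cols <- grDevices::hcl.colors(256, palette)
  idx <- if (sc == 0) matrix(1L, nrow(v), ncol(v))
         else matrix(pmin(255L, as.integer(v / sc * 255)) + 1L, nrow(v), ncol(v))
  rgbv <- grDevices::col2rgb(cols[idx]) / 255
  rgb <- array(0, c(nrow(v), ncol(v), 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(rgbv[ch, ], nrow(v), ncol(v))
  structure(list(values = v, rgb = rgb, scale = sc, palette = palette),
            class = "difference_map")
}

#' Aggregate PSNR over a dataset of (real, synthesized) pairs
#'
#' Infinite per-pair values (bit-identical pairs) are excluded from the
#' summary statistics and reported as a count; with no finite value the
#' statistics are `NA`.
#'
#' @param pairs Nonempty list of `list(real, synth)` pairs.
#' @param data_range Passed to [psnr()].
#' @param mask Optional shared mask passed to [psnr()].
#' @return List with `mean`, `median`, `min`, `max`, `n`, `n_infinite`,
#'   `psnr` (per-pair values).
#' @export
evaluate_dataset <- function(pairs, data_range = 4095, mask = NULL) {
  if (length(pairs) == 0) ct_error("empty_input", "no pairs to evaluate")
  vals <- vapply(pairs, function(p)
    psnr(p$real %||% p[[1]], p$synth %||% p[[2]], data_range, mask),
    numeric(1))
  fin <- vals[is.finite(vals)]
  stat <- function(f) if (length(fin)) f(fin) else NA_real_
  list(mean = stat(mean), median = stat(stats::median),
       min = stat(min), max = stat(max),
       n = length(vals), n_infinite = sum(is.infinite(vals)), psnr = vals)
}
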