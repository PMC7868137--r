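#' Phantom specification
#'
#' Describes a procedurally generated CT-like slice: a smooth elliptical
#' organ with band-limited (smoothed white-noise) texture on a darker
#' background, containing one or more compact lesions with an intensity
#' offset and finer texture, plus their binary mask. Intensities span the
#' 12-bit raw range `[0, 4096]`. Phantoms let every other module train and
#' run without any external dataset.
#'
#' @param size Pixels per side; a power of two, at least 16.
#' @param organ_intensity_band `(low, high)` intensities the organ mean must
#'   lie in; defaults emulate contrast-enhanced liver parenchyma on an
#'   offset 12-bit scale.
#' @param lesion_count_range `(min, max)` lesions per slice.
#' @param lesion_radius_range `(min, max)` nominal lesion radius in pixels;
#'   must stay below `size / 4`.
#' @param texture_scale Correlation length of the organ texture in pixels.
#' @param noise_std Texture standard deviation in intensity units.
#' @param lesion_intensity_offset Added to lesion pixels (negative =
#'   hypodense lesions, the common contrast-CT appearance).
#' @param background_intensity Mean background level.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(size = 64L, organ_intensity_band = c(1000, 1400),
                         lesion_count_range = c(1L, 3L),
                         lesion_radius_range = c(3, 8),
                         texture_scale = 4, noise_std = 40,
                         lesion_intensity_offset = -250,
                         background_intensity = 150, seed = 1L) {
  size <- as.integer(size)
  if (size < 16 || bitwAnd(size, size - 1L) != 0L)
    err_config("size must be a power of two, at least 16")
  if (length(organ_intensity_band) != 2 ||
      organ_intensity_band[1] >= organ_intensity_band[2] ||
      organ_intensity_band[1] < 0 || organ_intensity_band[2] > RAW_MAX)
    err_config("organ_intensity_band must be an increasing pair within [0, 4096]")
  if (max(lesion_radius_range) >= size / 4)
    err_config("lesion radii must stay below size / 4")
  if (min(lesion_radius_range) < 1 ||
      lesion_radius_range[1] > lesion_radius_range[2])
    err_config("lesion_radius_range must be an increasing pair, at least 1 pixel")
  if (lesion_count_range[1] < 0 ||
      lesion_count_range[1] > lesion_count_range[2])
    err_config("lesion_count_range must be a nondecreasing pair")
  structure(list(size = size, organ_intensity_band = organ_intensity_band,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = lesion_radius_range,
                 texture_scale = texture_scale, noise_std = noise_std,
                 lesion_intensity_offset = lesion_intensity_offset,
                 background_intensity = background_intensity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

smooth_noise <- function(size, sigma, sd_target) {
  z <- matrix(stats::rnorm(size * size), size, size)
  z <- as.matrix(EBImage::gblur(z, sigma = max(sigma, 0.5)))
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s * sd_target
  z
}

#' Generate one phantom slice with its tumor mask
#'
#' @param spec A [phantom_spec()].
#' @return List with `slice` (a [ct_slice()]) and `mask` (a [tumor_mask()]).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) err_config("spec must be a phantom_spec")
  n <- spec$size
  band <- spec$organ_intensity_band
  with_seed(spec$seed, {
    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    # organ: random ellipse around the center
    ctr <- n / 2 + stats::runif(2, -n / 16, n / 16)
    ax <- stats::runif(2, 0.28, 0.40) * n
    th <- stats::runif(1, 0, pi)
    xr <- (rr - ctr[1]) * cos(th) + (cc - ctr[2]) * sin(th)
    yr <- -(rr - ctr[1]) * sin(th) + (cc - ctr[2]) * cos(th)
    edist <- (xr / ax[1])^2 + (yr / ax[2])^2
    organ <- edist <= 1
    # keep the mean inside the band: draw the base level from the central
    # half of the band and center the texture exactly over the organ
    base <- stats::runif(1, band[1] + 0.25 * diff(band),
                         band[2] - 0.25 * diff(band))
    tex <- smooth_noise(n, spec$texture_scale, spec$noise_std)
    tex <- tex - mean(tex[organ])
    bg <- spec$background_intensity +
      smooth_noise(n, spec$texture_scale, spec$noise_std / 2)
    px <- bg
    px[organ] <- base + tex[organ]
    # lesions: compact blobs strictly inside the organ
    k <- if (spec$lesion_count_range[1] == spec$lesion_count_range[2])
      spec$lesion_count_range[1]
    else sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1)
    mask <- matrix(0, n, n)
    lesion_tex <- smooth_noise(n, max(spec$texture_scale / 4, 0.5),
                               spec$noise_std * 1.5)
    organ_idx <- which(organ, arr.ind = TRUE)
    for (l in seq_len(k)) {
      placed <- FALSE
      for (attempt in seq_len(400)) {
        r <- stats::runif(1, spec$lesion_radius_range[1],
                          spec$lesion_radius_range[2])
        ci <- organ_idx[sample.int(nrow(organ_idx), 1), ]
        cr <- ci[1] + stats::runif(1, -0.5, 0.5)
        cl <- ci[2] + stats::runif(1, -0.5, 0.5)
        # blob boundary: radius modulated by low-order harmonics
        ph <- stats::runif(2, 0, 2 * pi)
        d <- sqrt((rr - cr)^2 + (cc - cl)^2)
        ang <- atan2(cc - cl, rr - cr)
        rad <- r * (1 + 0.2 * sin(3 * ang + ph[1]) + 0.15 * sin(5 * ang + ph[2]))
        blob <- d <= rad
        # strict containment: the blob plus a 1-pixel rim must sit inside
        # the organ and clear of previously placed lesions
        rim <- d <= rad + 1
        if (any(blob) && all(organ[rim]) && !any(mask[rim] == 1)) {
          mask[blob] <- 1
          px[blob] <- px[blob] + spec$lesion_intensity_offset +
            lesion_tex[blob]
          placed <- TRUE
          break
        }
      }
      if (!placed)
        ct_error("infeasible_spec",
                 "could not place a lesion strictly inside the organ")
    }
    px[px < 0] <- 0
    px[px > RAW_MAX] <- RAW_MAX
    list(slice = ct_slice(px), mask = tumor_mask(mask))
  })
}

# counter-based per-item seed so dataset items are independent of order
derive_seed <- function(master, i)
  as.integer((as.double(master) + as.double(i) * 1000003) %% 2147483647)

#' Generate a reproducible phantom dataset
#'
#' Item `i` is generated from a per-item seed derived deterministically from
#' the master seed by a counter scheme, so items are independent of
#' generation order.
#'
#' @param spec A [phantom_spec()] (its own seed field is ignored here).
#' @param n Number of phantoms.
#' @param seed Master seed (defaults to the spec seed).
#' @return List of `list(slice, mask)` pairs.
#' @export
generate_dataset <- function(spec, n, seed = spec$seed) {
  if (!inherits(spec, "phantom_spec")) err_config("spec must be a phantom_spec")
  if (n < 1) ct_error("invalid_input", "n must be at least 1")
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- derive_seed(seed, i)
    generate_phantom(s)
  })
}
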