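#' Min-max normalize a patch channel to [0, 255]
#'
#' Affine map of the channel's observed range onto [0, 255], applied per
#' patch. A constant channel maps to all zeros (documented degenerate
#' convention, avoiding a divide-by-zero). Because the map absorbs any gain
#' or offset in the raw intensities, the downstream quantization is invariant
#' to affine rescaling of the input.
#'
#' @param channel 3D numeric array with finite values.
#' @return Array of the same shape with values in [0, 255].
#' @export
normalize_0_255 <- function(channel) {
  if (length(channel) == 0) abort("empty array")
  if (!all(is.finite(channel))) abort("non-finite values in channel")
  rng <- range(channel)
  if (rng[1] == rng[2]) {
    out <- array(0, dim(channel) %||% length(channel))
    return(out)
  }
  (channel - rng[1]) / (rng[2] - rng[1]) * 255
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantize a 0-255 channel into discrete gray levels
#'
#' Uniform bins on [0, 256): `level = floor(v * n_levels / 256) + 1`, clamped
#' to `[1, n_levels]`. With the default 64 levels this reproduces the
#' customary 64-bin discretization with voxel values 1..64.
#'
#' @param channel Array with values in [0, 255] (see [normalize_0_255()]).
#' @param n_levels Number of gray levels (>= 2), default 64.
#' @return Integer array of class `vt_quantized` with attribute `n_levels`.
#' @export
quantize <- function(channel, n_levels = 64L) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) abort("n_levels must be >= 2")
  if (any(channel < 0 | channel > 255)) abort("values must lie in [0, 255]")
  lev <- floor(channel * n_levels / 256) + 1
  lev <- pmin(pmax(lev, 1), n_levels)
  out <- array(as.integer(lev), dim(channel) %||% length(channel))
  structure(out, n_levels = n_levels, class = "vt_quantized")
}

# normalize + quantize both channels of a patch
quantize_patch <- function(patch, n_levels = 64L) {
  list(t2w = quantize(normalize_0_255(patch$t2w), n_levels),
       adc = quantize(normalize_0_255(patch$adc), n_levels))
}
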