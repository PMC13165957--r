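# Closed-form FLOP accounting for partial convolution (PConv).

#' Partial-convolution specification
#'
#' PConv applies a k x k convolution to only `channels_active` (c_p) of the
#' `channels_total` (c) channels and passes the remainder through
#' unchanged; the separation ratio is `r = c_p / c`.
#'
#' @param channels_total Total channels c (> 0).
#' @param channels_active Convolved channels c_p (0 < c_p <= c).
#' @param kernel Kernel size k.
#' @param height,width Spatial dims of the feature map.
#' @return A `pconv_spec` list (includes `r`).
#' @export
pconv_spec <- function(channels_total, channels_active, kernel = 3,
                       height = 1, width = 1) {
  if (channels_active <= 0 || channels_active > channels_total) {
    abort("Need 0 < `channels_active` <= `channels_total`.")
  }
  if (kernel < 1 || height < 1 || width < 1) {
    abort("Kernel and spatial dims must be positive.")
  }
  structure(
    list(channels_total = channels_total, channels_active = channels_active,
         kernel = kernel, height = height, width = width,
         r = channels_active / channels_total),
    class = "pconv_spec"
  )
}

#' FLOPs of the standard and partial convolution
#'
#' Multiply–accumulates of the convolution proper (bias and pass-through
#' channels cost zero): a standard k x k convolution mapping c channels to c
#' channels costs `h * w * k^2 * c^2`; PConv convolves only the c_p active
#' channels, costing `h * w * k^2 * c_p^2`.
#'
#' @param spec A [pconv_spec()].
#' @return A one-row tibble: `flops_standard`, `flops_partial`, `ratio`.
#' @export
pconv_flops <- function(spec) {
  hw <- spec$height * spec$width * spec$kernel^2
  std <- hw * spec$channels_total^2
  part <- hw * spec$channels_active^2
  tibble::tibble(flops_standard = std, flops_partial = part,
                 ratio = std / part)
}

#' Theoretical PConv speed-up ratio
#'
#' `FLOPs(standard) / FLOPs(partial) = (c / c_p)^2 = 1 / r^2`, independent
#' of the spatial dims and kernel size. At the reference separation ratio
#' r = 1/4 the speed-up is exactly 16.
#'
#' @param spec A [pconv_spec()], or a bare separation ratio r in (0, 1\].
#' @return The dimensionless speed-up ratio.
#' @examples
#' pconv_flop_ratio(pconv_spec(64, 16)) # 16
#' pconv_flop_ratio(1 / 2) # 4
#' @export
pconv_flop_ratio <- function(spec) {
  if (is.numeric(spec)) {
    if (any(spec <= 0) || any(spec > 1)) {
      abort("A bare separation ratio must lie in (0, 1].")
    }
    return(1 / spec^2)
  }
  pconv_flops(spec)$ratio
}

#' Speed-up table across separation ratios
#'
#' @param r Vector of separation ratios in (0, 1\].
#' @return A tibble with `r` and `speedup`.
#' @export
pconv_table <- function(r = c(1, 1 / 2, 1 / 4, 1 / 8)) {
  tibble::tibble(r = r, speedup = pconv_flop_ratio(r))
}
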