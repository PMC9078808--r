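#' MSRCP image enhancement
#'
#' Multiscale Retinex with chromaticity preservation. The intensity channel
#' (the mean of the channels for RGB input, the image itself for gray input)
#' is processed by log-domain multiscale Retinex with Gaussian surrounds at
#' the given scales and equal weights, stretched by simplest color balance
#' (percentile clipping) back onto the original intensity range, and the
#' resulting per-pixel gain is applied to every channel equally — so the
#' per-pixel channel ratios (chromaticity) of the input are preserved.
#'
#' @param frame a `rows x cols` matrix or `rows x cols x 3` array, gray levels
#'   in `[0, 255]`.
#' @param scales Gaussian surround sigmas in pixels; default `c(15, 80, 250)`,
#'   the classic small/medium/large surround triple.
#' @param clip_percentiles lower/upper clip fractions of the simplest color
#'   balance step (default 1% / 99%).
#' @param out_range output intensity range.
#' @param clip_range optional fixed `c(low, high)` clip bounds in the
#'   multiscale-Retinex log domain, as returned in the `msrcp_range`
#'   attribute of a previous call. Enhancing every frame of a sequence with
#'   the first frame's range keeps the mapping identical across frames
#'   (no temporal flicker), which matters when frame differences feed an
#'   optical-flow solver.
#' @return enhanced image, same shape and range as the input.
#' @details A spatially uniform image carries no illumination structure for
#'   Retinex to remove; the percentile stretch would be degenerate, so such
#'   images (and all-zero images, whose gain is undefined) are returned
#'   unchanged.
#' @export
msrcp_enhance <- function(frame, scales = c(15, 80, 250),
                          clip_percentiles = c(0.01, 0.99),
                          out_range = c(0, 255), clip_range = NULL) {
  if (length(scales) < 1) stop("need at least one surround scale")
  if (min(frame) < 0) stop("intensities must be nonnegative")
  rgb <- !is.matrix(frame)
  intensity <- if (rgb) (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3 else frame

  if (all(intensity == 0)) return(frame)            # gain undefined -> identity

  # log-domain multiscale retinex on the intensity channel
  li <- log1p(intensity)
  msr <- 0
  for (s in scales) msr <- msr + (li - log1p(gaussian_blur(intensity, s)))
  msr <- msr / length(scales)

  # simplest color balance: clip at percentiles, stretch to out_range
  q <- if (is.null(clip_range))
    stats::quantile(msr, clip_percentiles, names = FALSE) else clip_range
  if (q[2] - q[1] < 1e-12) return(frame)            # uniform image -> identity
  enhanced <- (pmin(pmax(msr, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  enhanced <- out_range[1] + enhanced * (out_range[2] - out_range[1])

  gain <- ifelse(intensity > 0, enhanced / intensity, 1)
  out <- if (rgb) {
    # apply the intensity gain to all channels; where the brightest channel
    # would clip, rescale the whole pixel so channel ratios stay exact
    r <- frame[, , 1] * gain; g <- frame[, , 2] * gain; b <- frame[, , 3] * gain
    mx <- pmax(r, g, b)
    scale <- ifelse(mx > out_range[2], out_range[2] / mx, 1)
    out <- frame
    out[, , 1] <- r * scale; out[, , 2] <- g * scale; out[, , 3] <- b * scale
    out
  } else {
    pmin(pmax(frame * gain, out_range[1]), out_range[2])
  }
  attr(out, "msrcp_range") <- q
  out
}

#' RGB to HSV feature conversion
#'
#' Converts a 3-channel frame to the hue/saturation/value feature space used
#' for tracking: `V = max(R, G, B)`, `S = (max - min) / max` (0 where the
#' maximum is 0), and `H` in degrees from the branch matching the maximal
#' channel — `60 (G-B)/d` when `V = R`, `120 + 60 (B-R)/d` when `V = G`,
#' `240 + 60 (R-G)/d` when `V = B`, with `d = max - min`; negative hues are
#' wrapped by +360 and `H` is 0 by convention wherever `S = 0`.
#'
#' @param frame a `rows x cols x 3` array.
#' @return list of class `hsv_image` with matrices `h` (degrees, `[0, 360)`),
#'   `s` (`[0, 1]`) and `v` (input intensity scale).
#' @export
rgb_to_hsv_img <- function(frame) {
  if (is.matrix(frame) || length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("rgb_to_hsv_img needs a rows x cols x 3 array; ",
         "generate frames with channels = 3 for a replicated-gray RGB stack")
  d2 <- dim(frame)[1:2]
  r <- array(frame[, , 1], d2); g <- array(frame[, , 2], d2)
  b <- array(frame[, , 3], d2)
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  s <- ifelse(mx > 0, d / mx, 0)
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  # branch priority R, G, B on ties
  br <- nz & (mx == r)
  bg <- nz & (mx == g) & !br
  bb <- nz & (mx == b) & !br & !bg
  h[br] <- 60 * (g[br] - b[br]) / d[br]
  h[bg] <- 120 + 60 * (b[bg] - r[bg]) / d[bg]
  h[bb] <- 240 + 60 * (r[bb] - g[bb]) / d[bb]
  h <- h %% 360
  structure(list(h = h, s = s, v = mx), class = "hsv_image")
}
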