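#' MSRCR parameter set
#'
#' Parameters of multi-scale retinex with color restoration. The defaults
#' are the canonical values from the retinex literature: three surround
#' scales spanning fine to near-global context, equal weights, and a
#' 1%/99% percentile clip for dynamic-range restoration.
#'
#' @param scales Gaussian surround standard deviations in pixels.
#' @param weights per-scale weights; must sum to 1.
#' @param alpha color-restoration strength (dimensionless).
#' @param beta color-restoration gain (dimensionless).
#' @param stretch_low,stretch_high percentile clip bounds (fractions in
#'   `[0, 1]`) of the retinex response used for the linear map to 0..255.
#' @param stretch_mode `"per-channel"` computes clip bounds per channel;
#'   `"luminance"` derives one pair of bounds from the luma of the
#'   response and applies the same linear map to all channels.
#' @return a `retinex_params` list.
#' @export
retinex_params <- function(scales = c(15, 80, 250),
                           weights = rep(1 / length(scales), length(scales)),
                           alpha = 125, beta = 46,
                           stretch_low = 0.01, stretch_high = 0.99,
                           stretch_mode = c("per-channel", "luminance")) {
  stretch_mode <- match.arg(stretch_mode)
  if (length(scales) == 0L || any(scales <= 0))
    stop_parameter("scales must be non-empty and positive")
  if (length(weights) != length(scales) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop_parameter("weights must match scales, be >= 0 and sum to 1")
  if (!(stretch_low >= 0 && stretch_low < stretch_high && stretch_high <= 1))
    stop_parameter("need 0 <= stretch_low < stretch_high <= 1")
  structure(list(scales = as.numeric(scales), weights = as.numeric(weights),
                 alpha = alpha, beta = beta,
                 stretch_low = stretch_low, stretch_high = stretch_high,
                 stretch_mode = stretch_mode),
            class = "retinex_params")
}

# sampled-and-normalized Gaussian taps at integer offsets -r..r,
# truncated at 3 sigma
gaussian_taps <- function(sigma) {
  r <- ceiling(3 * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# Kernels wider than this switch from direct separable convolution to
# the FFT route; both evaluate the identical kernel and boundary.
.direct_kernel_limit <- 129L

# Spectrum of the truncated Gaussian wrapped onto the 2H x 2W circular
# grid of the symmetric image extension. Separable, so it is the outer
# product of two 1D spectra; the wrapped kernel is even, so the spectra
# are real. Cached per (H, W, sigma): all scenes of one size share it.
.spectrum_cache <- new.env(parent = emptyenv())

kernel_spectrum <- function(H, W, sigma) {
  key <- sprintf("%d_%d_%g", H, W, sigma)
  hit <- .spectrum_cache[[key]]
  if (!is.null(hit)) return(hit)
  wrap <- function(n2, taps) {
    r <- (length(taps) - 1L) %/% 2L
    k <- numeric(n2)
    pos <- ((-r):r) %% n2 + 1L
    for (i in seq_along(pos)) k[pos[i]] <- k[pos[i]] + taps[i]
    k
  }
  taps <- gaussian_taps(sigma)
  s <- outer(Re(stats::fft(wrap(2L * H, taps))),
             Re(stats::fft(wrap(2L * W, taps))))
  .spectrum_cache[[key]] <- s
  s
}

# Convolution with the truncated Gaussian under mirror reflection via
# FFT: circular convolution of the symmetric 2x extension of the image
# equals reflection-boundary convolution exactly (the extension is
# 2n-periodic and symmetric, matching the reflection rule of the direct
# path), for kernels of any width.
surround_fft <- function(channel, sigma) {
  H <- nrow(channel); W <- ncol(channel)
  E <- channel[c(1:H, H:1), c(1:W, W:1)]
  S <- kernel_spectrum(H, W, sigma)
  z <- fftwtools::fftw2d(fftwtools::fftw2d(E) * S, inverse = 1)
  Re(z)[1:H, 1:W] / (4 * H * W)
}

# All large-scale surrounds of a 3-channel stack at once: the forward
# FFTs do not depend on sigma, and two real channels ride one complex
# transform (kernel spectra are real, so real and imaginary parts stay
# independent).
surround_fft_stack <- function(x, sigmas) {
  H <- dim(x)[1]; W <- dim(x)[2]
  ri <- c(1:H, H:1); ci <- c(1:W, W:1)
  F1 <- fftwtools::fftw2d(x[ri, ci, 1] + (0 + 1i) * x[ri, ci, 2])
  F2 <- fftwtools::fftw2d(x[ri, ci, 3])
  N <- 4 * H * W
  lapply(sigmas, function(s) {
    S <- kernel_spectrum(H, W, s)
    z1 <- fftwtools::fftw2d(F1 * S, inverse = 1) / N
    z2 <- fftwtools::fftw2d(F2 * S, inverse = 1) / N
    out <- array(0, c(H, W, 3))
    out[, , 1] <- Re(z1)[1:H, 1:W]
    out[, , 2] <- Im(z1)[1:H, 1:W]
    out[, , 3] <- Re(z2)[1:H, 1:W]
    out
  })
}

#' Gaussian surround of one channel
#'
#' Convolves a 2D intensity channel with a normalized, 3-sigma-truncated
#' Gaussian kernel, applied separably with mirror-reflection boundary
#' handling. This is the surround estimate inside single-scale retinex.
#'
#' @param channel numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; must be > 0.
#' @return matrix of the same shape.
#' @export
gaussian_surround <- function(channel, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop_parameter("sigma must be a single positive number")
  if (!is.matrix(channel) || length(channel) == 0L)
    stop_parameter("channel must be a non-empty matrix")
  taps <- gaussian_taps(sigma)
  if (length(taps) <= .direct_kernel_limit)
    conv_sep_reflect(channel, taps)
  else
    surround_fft(channel, sigma)
}

#' Multi-scale retinex with color restoration
#'
#' Per channel `i`, computes the single-scale retinex response
#' `log(I_i + 1) - log(surround_sigma(I_i) + 1)` at each scale, takes the
#' weighted sum over scales, multiplies by the color-restoration factor
#' `C_i = beta * (log(alpha * I_i + 1) - log(I_R + I_G + I_B + 1))`, and
#' linearly maps the result to 0..255 by clipping at the configured
#' percentiles. Natural logs with a +1 offset keep zero pixels finite.
#'
#' @param scene RGB scene array (`height x width x 3`, 0..255).
#' @param params a [retinex_params()] object.
#' @return enhanced scene of the same shape and 8-bit range.
#' @export
msrcr <- function(scene, params = retinex_params()) {
  if (!is.array(scene) || length(dim(scene)) != 3L || dim(scene)[3] != 3L)
    stop_parameter("msrcr needs a 3-channel RGB scene")
  id <- scene_id(scene)
  x <- unclass(scene)
  storage.mode(x) <- "double"

  klen <- vapply(params$scales, function(s) length(gaussian_taps(s)),
                 integer(1))
  big <- klen > .direct_kernel_limit
  surrounds <- vector("list", length(params$scales))
  if (any(big)) surrounds[big] <- surround_fft_stack(x, params$scales[big])
  for (n in which(!big)) {
    s <- array(0, dim(x))
    for (i in 1:3)
      s[, , i] <- conv_sep_reflect(x[, , i], gaussian_taps(params$scales[n]))
    surrounds[[n]] <- s
  }

  log_sum <- log(x[, , 1] + x[, , 2] + x[, , 3] + 1)
  out <- array(0, dim(x))
  for (i in 1:3) {
    ch <- x[, , i]
    log_ch <- log(ch + 1)
    resp <- 0
    for (n in seq_along(params$scales))
      resp <- resp + params$weights[n] *
        (log_ch - log(surrounds[[n]][, , i] + 1))
    crf <- params$beta * (log(params$alpha * ch + 1) - log_sum)
    out[, , i] <- crf * resp
  }

  if (params$stretch_mode == "per-channel") {
    for (i in 1:3) out[, , i] <- stretch_channel(out[, , i], params)
  } else {
    luma <- 0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3]
    b <- stretch_bounds(luma, params)
    for (i in 1:3) out[, , i] <- stretch_apply(out[, , i], b)
  }
  as_scene(out, id = id)
}

stretch_bounds <- function(v, params) {
  quantile(v, c(params$stretch_low, params$stretch_high),
           names = FALSE, type = 7)
}

stretch_apply <- function(v, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  if (hi - lo < .Machine$double.eps * max(1, abs(hi)))
    return(array(128, dim(v)))  # flat response: map to mid-gray
  quantize8((v - lo) / (hi - lo) * 255)
}

stretch_channel <- function(v, params) {
  stretch_apply(v, stretch_bounds(v, params))
}
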