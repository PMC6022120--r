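#' Saliency parameters
#'
#' Parameters of the three per-source saliency maps.
#'
#' * `sigma_c` — width of the colour prior on min-max normalized a*/b*
#'   (unitless, default 0.25).
#' * `sigma_d` — width of the centre-bias location prior in pixels
#'   (default 114).
#' * `bandpass` — band-pass filter for the frequency prior: `"log-gabor"`
#'   (frequency domain, default) or `"dog"` (spatial difference of
#'   Gaussians).
#' * `omega0`, `sigma_f` — log-Gabor centre frequency (cycles/pixel) and
#'   bandwidth parameter (defaults 0.002 and 6.2, the published defaults of
#'   the frequency/colour/location saliency detector this follows).
#' * `dog_sigmas` — inner/outer widths of the DoG fallback.
#' * `smooth` — [gaussian_spec()] applied to each raw map (default
#'   sigma 2, r 7): a small blur that stabilizes the per-pixel winner
#'   selection downstream.
#'
#' @param sigma_c,sigma_d,omega0,sigma_f Positive reals, see above.
#' @param bandpass `"log-gabor"` or `"dog"`.
#' @param dog_sigmas Length-2 increasing positive vector.
#' @param smooth A [gaussian_spec()].
#' @return An object of class `saliency_params`.
#' @export
saliency_params <- function(sigma_c = 0.25, sigma_d = 114,
                            bandpass = c("log-gabor", "dog"),
                            omega0 = 0.002, sigma_f = 6.2,
                            dog_sigmas = c(1, 10),
                            smooth = gaussian_spec(2, 7)) {
  bandpass <- match.arg(bandpass)
  for (nm in c("sigma_c", "sigma_d", "omega0", "sigma_f")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  if (length(dog_sigmas) != 2L || any(dog_sigmas <= 0) || diff(dog_sigmas) <= 0)
    stop("'dog_sigmas' must be two increasing positive values", call. = FALSE)
  if (!inherits(smooth, "gaussian_spec")) stop("'smooth' must be a gaussian_spec")
  structure(list(sigma_c = sigma_c, sigma_d = sigma_d, bandpass = bandpass,
                 omega0 = omega0, sigma_f = sigma_f, dog_sigmas = dog_sigmas,
                 smooth = smooth),
            class = "saliency_params")
}

#' @export
print.saliency_params <- function(x, ...) {
  cat(sprintf(
    "<saliency_params> sigma_c=%g sigma_d=%g px bandpass=%s (omega0=%g, sigma_f=%g) smooth sigma=%g r=%d\n",
    x$sigma_c, x$sigma_d, x$bandpass, x$omega0, x$sigma_f,
    x$smooth$sigma, x$smooth$r))
  invisible(x)
}

# band-pass filter a plane. log-Gabor acts in the frequency domain (zero DC);
# DoG is the spatial fallback, also zero-mean.
bandpass_filter <- function(p, params) {
  if (params$bandpass == "dog") {
    return(gaussian_smooth(p, gaussian_spec(params$dog_sigmas[1])) -
           gaussian_smooth(p, gaussian_spec(params$dog_sigmas[2])))
  }
  h <- nrow(p); w <- ncol(p)
  fy <- (seq_len(h) - 1L); fy[fy > h / 2] <- fy[fy > h / 2] - h
  fx <- (seq_len(w) - 1L); fx[fx > w / 2] <- fx[fx > w / 2] - w
  rho <- sqrt(outer((fy / h)^2, (fx / w)^2, "+"))
  lg <- matrix(0, h, w)
  nz <- rho > 0
  lg[nz] <- exp(-(log(rho[nz] / params$omega0))^2 / (2 * log(params$sigma_f)^2))
  Re(stats::fft(stats::fft(p) * lg, inverse = TRUE)) / (h * w)
}

#' Frequency prior of the visual saliency map
#'
#' Band-pass filters the three CIELAB planes and takes the per-pixel
#' Euclidean norm of the responses. The filter has no DC response, so flat
#' regions score (near) zero and band-limited structure scores high.
#'
#' @param img `H x W x 3` RGB array in `[0, 1]`.
#' @param params A [saliency_params()].
#' @return Nonnegative `H x W` matrix.
#' @export
frequency_prior <- function(img, params = saliency_params()) {
  lab <- rgb_to_cielab(img)
  sqrt(bandpass_filter(lab$L, params)^2 +
       bandpass_filter(lab$a, params)^2 +
       bandpass_filter(lab$b, params)^2)
}

#' Colour ("warmth") prior of the visual saliency map
#'
#' Min-max normalizes a* and b* to `[0, 1]` per image and scores each pixel
#' by `1 - exp(-(a'^2 + b'^2) / sigma_c^2)`: warm (reddish/yellowish) pixels
#' approach 1, cold ones approach 0. A flat (degenerate) channel normalizes
#' to all zeros.
#'
#' @inheritParams frequency_prior
#' @return `H x W` matrix with values in `[0, 1)`.
#' @export
color_prior <- function(img, params = saliency_params()) {
  lab <- rgb_to_cielab(img)
  an <- minmax01(lab$a)
  bn <- minmax01(lab$b)
  1 - exp(-(an^2 + bn^2) / params$sigma_c^2)
}

#' Location (centre-bias) prior of the visual saliency map
#'
#' `exp(-||k - c||^2 / sigma_d^2)` with `c` the image centre, reflecting
#' the centre bias of human gaze.
#'
#' @param shape Length-2 integer vector `(H, W)`.
#' @param params A [saliency_params()].
#' @return `H x W` matrix with values in `(0, 1]`.
#' @export
location_prior <- function(shape, params = saliency_params()) {
  h <- shape[1]; w <- shape[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
  exp(-d2 / params$sigma_d^2)
}

#' Visual saliency map
#'
#' Per-pixel product of the frequency, colour and location priors, then
#' Gaussian smoothed.
#'
#' @inheritParams frequency_prior
#' @return Nonnegative `H x W` matrix.
#' @export
visual_saliency_map <- function(img, params = saliency_params()) {
  vs <- frequency_prior(img, params) *
        color_prior(img, params) *
        location_prior(dim(img)[1:2], params)
  gaussian_smooth(vs, params$smooth)
}

# Scharr x-derivative kernel; the y kernel is its transpose
.scharr_x <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), nrow = 3, byrow = TRUE) / 16

#' Scharr partial derivatives of a luminance plane
#'
#' Convolution with the 3x3 Scharr kernel `(1/16)[3 0 -3; 10 0 -10; 3 0 -3]`
#' for the horizontal derivative and its transpose for the vertical one
#' (replicate borders). The luminance input is conventionally the `L`
#' channel of [rgb_to_lmn()].
#'
#' @param lum `H x W` luminance matrix.
#' @return List of matrices `gx`, `gy`.
#' @export
scharr_gradients <- function(lum) {
  stopifnot(is.matrix(lum))
  list(gx = conv2_replicate(lum, .scharr_x),
       gy = conv2_replicate(lum, t(.scharr_x)))
}

#' Gradient magnitude saliency map
#'
#' Root of the summed squared Scharr derivatives, Gaussian smoothed. High
#' where the image is sharp; defocus blur suppresses it, which is what
#' makes it the focus-discriminating term of the weight maps.
#'
#' @param lum `H x W` luminance matrix.
#' @param params A [saliency_params()].
#' @return Nonnegative `H x W` matrix.
#' @export
gradient_saliency_map <- function(lum, params = saliency_params()) {
  g <- scharr_gradients(lum)
  gaussian_smooth(sqrt(g$gx^2 + g$gy^2), params$smooth)
}

#' Chrominance (colour-distortion) saliency map
#'
#' Per-pixel product of the two opponent chrominance channels `M` and `N`
#' of [rgb_to_lmn()], rectified to its absolute value (the product is
#' signed, and the weight-map exponents require a nonnegative base), then
#' Gaussian smoothed.
#'
#' @inheritParams frequency_prior
#' @return Nonnegative `H x W` matrix.
#' @export
chrominance_saliency_map <- function(img, params = saliency_params()) {
  lmn <- rgb_to_lmn(img)
  gaussian_smooth(abs(lmn$M * lmn$N), params$smooth)
}

#' Compute the full saliency bundle for one source image
#'
#' Computes the visual saliency (VS), gradient magnitude (GM) and
#' chrominance (CD) maps and, by default, min-max normalizes each to
#' `[0, 1]` so the three incommensurate scales can be combined
#' multiplicatively into a weight map.
#'
#' @inheritParams frequency_prior
#' @param normalize Min-max normalize each map to `[0, 1]` (default TRUE).
#' @return An object of class `saliency_bundle`: list of `H x W` matrices
#'   `vs`, `gm`, `cd`.
#' @export
saliency_bundle <- function(img, params = saliency_params(), normalize = TRUE) {
  img <- as_color_image(img)
  vs <- visual_saliency_map(img, params)
  gm <- gradient_saliency_map(luminance(img), params)
  cd <- chrominance_saliency_map(img, params)
  if (normalize) {
    vs <- minmax01(vs); gm <- minmax01(gm); cd <- minmax01(cd)
  }
  structure(list(vs = vs, gm = gm, cd = cd), class = "saliency_bundle")
}
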