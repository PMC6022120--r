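#' Gaussian kernel specification
#'
#' Describes a normalized, truncated 2-D Gaussian smoothing kernel by its
#' standard deviation `sigma` (pixels) and half-width `r` (pixels). The
#' kernel has `(2r+1)^2` taps and sums to one. When `r` is omitted it
#' defaults to the usual three-sigma support `ceiling(3 * sigma)`.
#'
#' @param sigma Positive standard deviation in pixels.
#' @param r Positive integer half-width in pixels; default `ceiling(3*sigma)`.
#' @return An object of class `gaussian_spec` with fields `sigma` and `r`.
#' @examples
#' gaussian_spec(2)       # r = 6
#' gaussian_spec(5, 15)
#' @export
gaussian_spec <- function(sigma, r = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  if (is.null(r)) r <- as.integer(ceiling(3 * sigma))
  r <- as.integer(r)
  if (r < 1L) stop("'r' must be a positive integer", call. = FALSE)
  structure(list(sigma = sigma, r = r), class = "gaussian_spec")
}

#' @export
print.gaussian_spec <- function(x, ...) {
  cat(sprintf("<gaussian_spec> sigma = %g px, r = %d px\n", x$sigma, x$r))
  invisible(x)
}

# 1-D normalized Gaussian taps at offsets -r..r
gaussian_taps <- function(sigma, r) {
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# replicate-pad a matrix by (ry, rx) on each side
pad_replicate <- function(m, ry, rx = ry) {
  h <- nrow(m); w <- ncol(m)
  m[c(rep(1L, ry), seq_len(h), rep(h, ry)),
    c(rep(1L, rx), seq_len(w), rep(w, rx)), drop = FALSE]
}

# separable correlation with replicate borders; ky along rows, kx along cols.
# All kernels used through here are symmetric, so correlation == convolution.
conv_sep <- function(m, ky, kx = ky) {
  h <- nrow(m); w <- ncol(m)
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  p <- m[c(rep(1L, ry), seq_len(h), rep(h, ry)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(ky))
    out <- out + ky[t] * p[(t - 1L) + seq_len(h), , drop = FALSE]
  p <- out[, c(rep(1L, rx), seq_len(w), rep(w, rx)), drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(kx))
    out <- out + kx[t] * p[, (t - 1L) + seq_len(w), drop = FALSE]
  out
}

# full 2-D convolution (kernel flipped) with replicate borders; small kernels
conv2_replicate <- function(m, kern) {
  h <- nrow(m); w <- ncol(m)
  ry <- (nrow(kern) - 1L) %/% 2L
  rx <- (ncol(kern) - 1L) %/% 2L
  p <- pad_replicate(m, ry, rx)
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(kern))) for (j in seq_len(ncol(kern))) {
    kv <- kern[nrow(kern) - i + 1L, ncol(kern) - j + 1L]  # flip => convolution
    if (kv != 0)
      out <- out + kv * p[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w), drop = FALSE]
  }
  out
}

# windowed mean over (2r+1)^2 with replicate borders
box_mean <- function(m, r) {
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  conv_sep(m, k)
}

# windowed population variance / standard deviation, replicate borders
box_var <- function(m, r) {
  v <- box_mean(m * m, r) - box_mean(m, r)^2
  v[v < 0] <- 0
  v
}

box_sd <- function(m, r) sqrt(box_var(m, r))

#' Smooth a single-channel plane with a Gaussian kernel
#'
#' Convolves a plane with the normalized, truncated Gaussian described by
#' `spec`, using replicate padding at the borders so the output has the
#' same size as the input and constants are preserved exactly.
#'
#' @param p Numeric matrix (H x W plane).
#' @param spec A [gaussian_spec()].
#' @return Numeric matrix of the same dimensions.
#' @examples
#' p <- matrix(runif(64), 8, 8)
#' q <- gaussian_smooth(p, gaussian_spec(1))
#' @export
gaussian_smooth <- function(p, spec) {
  stopifnot(is.matrix(p))
  if (!inherits(spec, "gaussian_spec")) stop("'spec' must be a gaussian_spec")
  conv_sep(p, gaussian_taps(spec$sigma, spec$r))
}

# smooth each channel of an H x W x 3 array
gaussian_smooth_rgb <- function(img, spec) {
  k <- gaussian_taps(spec$sigma, spec$r)
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- conv_sep(img[, , ch], k)
  out
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# min-max rescale to [0,1]. A channel whose range is negligible against its
# magnitude (a constant up to floating-point slop) maps to all zeros rather
# than amplifying rounding noise to full scale.
minmax01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 1e-9 * max(abs(hi), abs(lo), 1)) {
    m[] <- 0
    return(m)
  }
  (m - lo) / (hi - lo)
}
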