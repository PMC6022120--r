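#' Validate a colour image array
#'
#' The working representation throughout the package is an `H x W x 3`
#' numeric array in RGB order with values in `[0, 1]`. This checks shape,
#' finiteness and range (with a small tolerance for floating-point slop,
#' after which values are clamped).
#'
#' @param img Numeric `H x W x 3` array.
#' @return The validated (and clamped) array.
#' @export
as_color_image <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("colour image must be an H x W x 3 array", call. = FALSE)
  if (!all(is.finite(img))) stop("colour image contains non-finite values", call. = FALSE)
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop("colour image values must lie in [0, 1]", call. = FALSE)
  clamp01(img)
}

# sRGB -> XYZ (D65) matrix, IEC 61966-2-1
.srgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                      0.2126729, 0.7151522, 0.0721750,
                      0.0193339, 0.1191920, 0.9503041),
                    nrow = 3, byrow = TRUE)
# D65 reference white: the matrix image of RGB = (1,1,1), so the neutral
# axis maps exactly to a* = b* = 0
.d65 <- rowSums(.srgb2xyz)

#' Convert an sRGB image to CIELAB planes
#'
#' Applies the sRGB transfer function (gamma expansion), the sRGB-primaries
#' RGB to XYZ matrix, and the CIE L*a*b* transform with the D65 reference
#' white. L* lies in `[0, 100]`; a* and b* are signed opponent channels
#' (green-red and blue-yellow).
#'
#' @param img `H x W x 3` RGB array in `[0, 1]`.
#' @return A list of three `H x W` matrices: `L`, `a`, `b`.
#' @examples
#' px <- array(c(1, 0, 0), dim = c(1, 1, 3))  # pure red
#' rgb_to_cielab(px)
#' @export
rgb_to_cielab <- function(img) {
  img <- as_color_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- matrix(img, ncol = 3L)              # columns R, G, B
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb2xyz)
  xyz <- sweep(xyz, 2L, .d65, "/")
  delta <- 6 / 29
  f <- ifelse(xyz > delta^3, xyz^(1 / 3), xyz / (3 * delta^2) + 4 / 29)
  Lst <- 116 * f[, 2] - 16
  ast <- 500 * (f[, 1] - f[, 2])
  bst <- 200 * (f[, 2] - f[, 3])
  list(L = matrix(Lst, h, w), a = matrix(ast, h, w), b = matrix(bst, h, w))
}

# LMN opponent colour space matrix (rows: L, M, N; columns R, G, B)
.lmn <- matrix(c(0.06, 0.63, 0.27,
                 0.30, 0.04, -0.35,
                 0.34, -0.60, 0.17),
               nrow = 3, byrow = TRUE)

#' Convert an RGB image to the LMN opponent colour space
#'
#' A fixed linear map: `L` is the luminance channel used for gradient
#' computation and as the guided-filter guidance; `M` and `N` are the two
#' chrominance (opponent) channels feeding the colour-distortion saliency.
#'
#' @param img `H x W x 3` RGB array in `[0, 1]`.
#' @return A list of three `H x W` matrices: `L`, `M`, `N`.
#' @examples
#' rgb_to_lmn(array(1, dim = c(1, 1, 3)))  # white: L=0.96, M=-0.01, N=-0.09
#' @export
rgb_to_lmn <- function(img) {
  img <- as_color_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- matrix(img, ncol = 3L) %*% t(.lmn)
  list(L = matrix(out[, 1], h, w),
       M = matrix(out[, 2], h, w),
       N = matrix(out[, 3], h, w))
}

# luminance plane (LMN L channel) of a colour image
luminance <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  matrix(matrix(img, ncol = 3L) %*% .lmn[1, ], h, w)
}
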