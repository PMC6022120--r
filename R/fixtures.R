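# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smoothed uniform-noise plane in [0,1], a cheap band-limited texture
noise_plane <- function(h, w, sigma) {
  minmax01(gaussian_smooth(matrix(stats::runif(h * w), h, w),
                           gaussian_spec(sigma)))
}

#' Generate a deterministic all-in-focus ground-truth image
#'
#' Three kinds:
#' * `"plant-like"` — random elliptical green blobs (pods/leaves) with
#'   darker rims over a brownish textured soil background, plus fine
#'   grain, so the gradient saliency has structure everywhere;
#' * `"texture"` — multi-scale smoothed colour noise with fine grain;
#' * `"checker"` — an exact black/white checkerboard (cell size 8 px),
#'   with no randomness.
#'
#' @param kind `"plant-like"`, `"texture"` or `"checker"`.
#' @param shape `(H, W)` integer vector, default `c(512, 512)`.
#' @param seed Integer seed; the output is bit-reproducible per seed.
#' @param cell Checker cell size in pixels (checker kind only).
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @examples
#' img <- make_truth("plant-like", c(64, 64), seed = 1)
#' @export
make_truth <- function(kind = c("plant-like", "texture", "checker"),
                       shape = c(512, 512), seed = 1, cell = 8L) {
  kind <- match.arg(kind)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  stopifnot(h >= 8L, w >= 8L)
  if (kind == "checker") {
    rowband <- (seq_len(h) - 1L) %/% cell
    colband <- (seq_len(w) - 1L) %/% cell
    m <- outer(rowband, colband, function(a, b) (a + b) %% 2L) * 1
    return(array(rep(m, 3L), dim = c(h, w, 3L)))
  }
  with_local_seed(seed, {
    if (kind == "texture") {
      img <- array(0, dim = c(h, w, 3L))
      for (ch in 1:3) {
        img[, , ch] <- 0.55 * noise_plane(h, w, 6) +
          0.30 * noise_plane(h, w, 2) +
          0.15 * matrix(stats::runif(h * w), h, w)
      }
      return(clamp01(0.1 + 0.8 * img))
    }
    # plant-like: textured soil background + elliptical green blobs
    soil <- 0.5 * noise_plane(h, w, 8) + 0.5 * noise_plane(h, w, 2)
    img <- array(0, dim = c(h, w, 3L))
    img[, , 1] <- 0.35 + 0.25 * soil
    img[, , 2] <- 0.28 + 0.20 * soil
    img[, , 3] <- 0.18 + 0.15 * soil
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    n_blob <- max(12L, as.integer(round(25 * (h * w) / (512 * 512))))
    leaf_tex <- noise_plane(h, w, 1.5)
    for (i in seq_len(n_blob)) {
      cy <- stats::runif(1, 0.1 * h, 0.9 * h)
      cx <- stats::runif(1, 0.1 * w, 0.9 * w)
      ry <- stats::runif(1, 0.02, 0.09) * h
      rx <- stats::runif(1, 0.015, 0.05) * w
      th <- stats::runif(1, 0, pi)
      u <- (yy - cy) * cos(th) + (xx - cx) * sin(th)
      v <- -(yy - cy) * sin(th) + (xx - cx) * cos(th)
      d <- (u / ry)^2 + (v / rx)^2
      inside <- d <= 1
      rim <- d > 0.7 & inside
      g <- stats::runif(1, 0.45, 0.75)
      shade <- 0.75 + 0.5 * leaf_tex
      img[, , 1][inside] <- (0.18 * g * shade)[inside]
      img[, , 2][inside] <- (g * shade)[inside]
      img[, , 3][inside] <- (0.22 * g * shade)[inside]
      img[, , 1][rim] <- 0.10
      img[, , 2][rim] <- 0.30
      img[, , 3][rim] <- 0.08
    }
    grain <- matrix(stats::runif(h * w, -0.04, 0.04), h, w)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + grain
    clamp01(img)
  })
}

#' Build a synthetic multi-focus pair with known ground truth
#'
#' Emulates a two-exposure focal stack: source 1 equals the ground truth
#' inside `mask` and a Gaussian-blurred copy (defocus surrogate) outside;
#' source 2 is complementary. An optional feathered transition band blends
#' the two regions smoothly, and optional seeded Gaussian sensor noise can
#' be added. Because the truth is known, recovery of the fusion pipeline
#' is directly measurable (e.g. with [psnr()]).
#'
#' @param truth `H x W x 3` ground-truth image (see [make_truth()]).
#' @param mask Logical/binary `H x W` in-focus mask for source 1; default
#'   is the left vertical half-plane.
#' @param blur_sigma Positive defocus blur width in pixels (default 3).
#' @param transition Feathering width in pixels (0 = hard mask, default).
#' @param noise_sd Gaussian sensor noise sd (default 0 = off).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return List of class `synthetic_pair`: `truth`, `sources` (list of 2),
#'   `masks` (list of 2 binary matrices summing to 1 everywhere),
#'   `blur_sigma`, `seed`.
#' @export
make_multifocus_pair <- function(truth, mask = NULL, blur_sigma = 3,
                                 transition = 0, noise_sd = 0, seed = 1) {
  truth <- as_color_image(truth)
  h <- dim(truth)[1]; w <- dim(truth)[2]
  if (!is.finite(blur_sigma) || blur_sigma <= 0)
    stop("'blur_sigma' must be > 0", call. = FALSE)
  if (is.null(mask)) {
    mask <- matrix(0, h, w)
    mask[, seq_len(w %/% 2)] <- 1
  }
  mask <- (mask > 0.5) * 1
  stopifnot(identical(dim(mask), c(h, w)))
  blurred <- gaussian_smooth_rgb(truth, gaussian_spec(blur_sigma))
  soft <- if (transition > 0)
    gaussian_smooth(mask, gaussian_spec(transition)) else mask
  mix <- function(m) {
    out <- truth
    for (ch in 1:3) out[, , ch] <- m * truth[, , ch] + (1 - m) * blurred[, , ch]
    out
  }
  s1 <- mix(soft)
  s2 <- mix(1 - soft)
  if (noise_sd > 0) {
    with_local_seed(seed, {
      s1 <- clamp01(s1 + array(stats::rnorm(length(s1), 0, noise_sd), dim = dim(s1)))
      s2 <- clamp01(s2 + array(stats::rnorm(length(s2), 0, noise_sd), dim = dim(s2)))
    })
  }
  structure(list(truth = truth, sources = list(s1, s2),
                 masks = list(mask, 1 - mask),
                 blur_sigma = blur_sigma, seed = seed),
            class = "synthetic_pair")
}

# blob-shaped in-focus mask variant: union of a few seeded ellipses
blob_mask <- function(shape, seed = 1, n_blob = 3L) {
  h <- shape[1]; w <- shape[2]
  with_local_seed(seed, {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- matrix(0, h, w)
    for (i in seq_len(n_blob)) {
      cy <- stats::runif(1, 0.2 * h, 0.8 * h)
      cx <- stats::runif(1, 0.2 * w, 0.8 * w)
      ry <- stats::runif(1, 0.12, 0.25) * h
      rx <- stats::runif(1, 0.12, 0.25) * w
      mask[((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1] <- 1
    }
    mask
  })
}
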