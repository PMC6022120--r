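#' Sigmoid constants of the edge-preservation metric
#'
#' Shape constants of the two sigmoids converting relative edge strength
#' and orientation into preservation values. Defaults are the originating
#' metric's published values.
#'
#' @param gamma_g,k_g,sigma_g Strength sigmoid: scale, slope, midpoint.
#' @param gamma_a,k_a,sigma_a Orientation sigmoid: scale, slope, midpoint.
#' @return An object of class `edge_metric_constants`.
#' @export
edge_metric_constants <- function(gamma_g = 0.9994, k_g = -15, sigma_g = 0.5,
                                  gamma_a = 0.9879, k_a = -22, sigma_a = 0.8) {
  structure(list(gamma_g = gamma_g, k_g = k_g, sigma_g = sigma_g,
                 gamma_a = gamma_a, k_a = k_a, sigma_a = sigma_a),
            class = "edge_metric_constants")
}

# coerce a metric input to a luminance plane in [0,1]
metric_plane <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) x <- luminance(as_color_image(x))
  stopifnot(is.matrix(x))
  x
}

# Shannon entropy (bits) of a probability vector
.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# quantize a [0,1] plane to 0..255 integer levels
.quant8 <- function(x) {
  q <- as.integer(round(clamp01(x) * 255))
  q
}

#' Normalized mutual-information fusion metric (QMI)
#'
#' `QMI = 2 * (I(X,F)/(H(X)+H(F)) + I(Y,F)/(H(Y)+H(F)))`: how much
#' information from each source survives in the fused image, normalized by
#' the marginal entropies. Entropies and mutual information are estimated
#' from 256-bin joint histograms of the 8-bit-quantized luminance planes.
#' A perfect copy of identical sources scores 2; a fused image independent
#' of the sources scores near 0. A constant (zero-entropy) image
#' contributes 0 to its term, with a warning.
#'
#' @param x,y Source images (planes or RGB arrays).
#' @param f Fused image.
#' @return Single number in `[0, 2]`.
#' @export
qmi <- function(x, y, f) {
  x <- metric_plane(x); y <- metric_plane(y); f <- metric_plane(f)
  stopifnot(identical(dim(x), dim(f)), identical(dim(y), dim(f)))
  qf <- .quant8(f)
  term <- function(src) {
    qs <- .quant8(src)
    joint <- tabulate(qs * 256L + qf + 1L, nbins = 65536L) / length(qf)
    hs <- .entropy(rowsum(joint, rep(0:255, each = 256))[, 1])
    hf <- .entropy(rowsum(joint, rep(0:255, times = 256))[, 1])
    if (hs + hf == 0) {
      warning("constant image: zero entropy, metric term set to 0")
      return(0)
    }
    mi <- hs + hf - .entropy(joint)
    mi / (hf + hs)
  }
  2 * (term(x) + term(y))
}

# box sums over w x w windows at all fully-interior ("valid") positions,
# via the integral image; returns an (H-w+1) x (W-w+1) matrix
box_sum_valid <- function(m, w) {
  S <- rbind(0, apply(m, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  h <- nrow(m); wd <- ncol(m)
  i <- seq_len(h - w + 1L); j <- seq_len(wd - w + 1L)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

# SSIM ingredients on valid windows; population moments over w^2 pixels
local_moments <- function(a, w) {
  n <- w * w
  mu <- box_sum_valid(a, w) / n
  list(mu = mu, var = pmax(box_sum_valid(a * a, w) / n - mu^2, 0))
}

local_cov <- function(a, b, w, ma, mb) {
  box_sum_valid(a * b, w) / (w * w) - ma * mb
}

ssim_map <- function(a, b, w, C1, C2) {
  ma <- local_moments(a, w); mb <- local_moments(b, w)
  cab <- local_cov(a, b, w, ma$mu, mb$mu)
  ((2 * ma$mu * mb$mu + C1) * (2 * cab + C2)) /
    ((ma$mu^2 + mb$mu^2 + C1) * (ma$var + mb$var + C2))
}

#' Structural-similarity fusion metric (QY)
#'
#' In each sliding window: where the two sources are structurally similar
#' (`SSIM(x,y) >= 0.75`) the fused window is compared against a
#' variance-weighted combination of both sources; where they differ (one
#' in focus, one not) the better of `SSIM(x,f)` and `SSIM(y,f)` is taken.
#' QY is the mean over all fully-interior windows. Identical images score
#' 1. Windows where both sources have zero variance use weight 0.5.
#'
#' @param x,y Source images (planes or RGB arrays).
#' @param f Fused image.
#' @param window Odd window side length (default 7).
#' @return Single number (at most 1).
#' @export
qy <- function(x, y, f, window = 7L) {
  x <- metric_plane(x); y <- metric_plane(y); f <- metric_plane(f)
  stopifnot(identical(dim(x), dim(f)), identical(dim(y), dim(f)))
  w <- as.integer(window)
  if (w %% 2L != 1L || w < 3L) stop("'window' must be an odd integer >= 3")
  if (any(dim(x) < w)) stop("image smaller than the SSIM window")
  C1 <- (0.01)^2; C2 <- (0.03)^2   # dynamic range 1
  sxy <- ssim_map(x, y, w, C1, C2)
  sxf <- ssim_map(x, f, w, C1, C2)
  syf <- ssim_map(y, f, w, C1, C2)
  vx <- local_moments(x, w)$var
  vy <- local_moments(y, w)$var
  lam <- ifelse(vx + vy > 0, vx / (vx + vy), 0.5)
  per <- ifelse(sxy >= 0.75,
                lam * sxf + (1 - lam) * syf,
                pmax(sxf, syf))
  mean(per)
}

.sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), nrow = 3, byrow = TRUE)

# Sobel gradient strength and orientation, replicate borders
sobel_strength <- function(p) {
  sx <- conv2_replicate(p, .sobel_x)
  sy <- conv2_replicate(p, t(.sobel_x))
  alpha <- atan(sy / sx)
  alpha[!is.finite(alpha)] <- 0           # 0/0 pixels: no orientation
  list(g = sqrt(sx^2 + sy^2), alpha = alpha)
}

#' Edge-information preservation fusion metric (QAB/F)
#'
#' Sobel gradient strength and orientation are extracted from both sources
#' and the fused image; per pixel, relative strength (ratio of the weaker
#' to the stronger gradient) and relative orientation agreement are pushed
#' through sigmoids giving an edge-preservation value in `[0, 1]`; the
#' final score is the average of the per-source preservation values
#' weighted by the source gradient strengths. Pixels where both gradients
#' vanish carry no edge information: their relative strength is 0, and
#' their weight is 0.
#'
#' @param a,b Source images (planes or RGB arrays).
#' @param f Fused image.
#' @param consts An [edge_metric_constants()].
#' @return Single number in `[0, 1]`.
#' @export
qabf <- function(a, b, f, consts = edge_metric_constants()) {
  a <- metric_plane(a); b <- metric_plane(b); f <- metric_plane(f)
  stopifnot(identical(dim(a), dim(f)), identical(dim(b), dim(f)))
  ef <- sobel_strength(f)
  per_source <- function(src) {
    es <- sobel_strength(src)
    gsf <- ifelse(es$g > ef$g, ef$g / es$g, es$g / ef$g)
    gsf[!is.finite(gsf)] <- 0             # both gradients zero
    asf <- 1 - abs(es$alpha - ef$alpha) / (pi / 2)
    qg <- consts$gamma_g / (1 + exp(consts$k_g * (gsf - consts$sigma_g)))
    qa <- consts$gamma_a / (1 + exp(consts$k_a * (asf - consts$sigma_a)))
    list(q = qg * qa, w = es$g)
  }
  pa <- per_source(a); pb <- per_source(b)
  denom <- sum(pa$w + pb$w)
  if (denom == 0) {
    warning("no edge information in either source; metric set to 0")
    return(0)
  }
  sum(pa$q * pa$w + pb$q * pb$w) / denom
}

#' Peak signal-to-noise ratio against a reference
#'
#' `10 * log10(1 / MSE)` for unit-range images; `Inf` for identical
#' inputs. A full-reference convenience used with the synthetic fixtures
#' (the no-reference fusion metrics are [qmi()], [qy()], [qabf()]).
#'
#' @param x Image to score.
#' @param ref Ground-truth image, same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref) {
  stopifnot(identical(dim(x), dim(ref)))
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' Score a fused image against its two sources
#'
#' Computes the three no-reference fusion quality metrics in one call.
#'
#' @param a,b Source images.
#' @param f Fused image.
#' @param window QY window (default 7).
#' @param consts QAB/F sigmoid constants.
#' @return An object of class `metric_report`: list with `qmi`, `qy`,
#'   `qabf` and the parameters used.
#' @export
metric_report <- function(a, b, f, window = 7L,
                          consts = edge_metric_constants()) {
  structure(list(qmi = qmi(a, b, f),
                 qy = qy(a, b, f, window),
                 qabf = qabf(a, b, f, consts),
                 window = as.integer(window), consts = consts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> QMI=%.4f QY=%.4f QAB/F=%.4f\n",
              x$qmi, x$qy, x$qabf))
  invisible(x)
}
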