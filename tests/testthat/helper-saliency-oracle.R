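# Single-function saliency oracles: each recomputes a whole map from the
# raw RGB input with its own colour conversion, filtering and smoothing
# code (matrix-product DFT instead of fft(), dense loop convolutions).

oracle_lab <- function(img) {
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  white <- rowSums(M)
  h <- dim(img)[1]; w <- dim(img)[2]
  L <- a <- b <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rgb <- img[i, j, ]
    lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
    xyz <- as.vector(M %*% lin) / white
    f <- ifelse(xyz > (6 / 29)^3, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
    L[i, j] <- 116 * f[2] - 16
    a[i, j] <- 500 * (f[1] - f[2])
    b[i, j] <- 200 * (f[2] - f[3])
  }
  list(L = L, a = a, b = b)
}

# circular band-pass filtering via an explicit DFT matrix product
oracle_loggabor <- function(p, omega0, sigma_f) {
  h <- nrow(p); w <- ncol(p)
  Wh <- exp(-2i * pi * outer(0:(h - 1), 0:(h - 1)) / h)
  Ww <- exp(-2i * pi * outer(0:(w - 1), 0:(w - 1)) / w)
  spec <- Wh %*% p %*% Ww
  fy <- 0:(h - 1); fy[fy > h / 2] <- fy[fy > h / 2] - h
  fx <- 0:(w - 1); fx[fx > w / 2] <- fx[fx > w / 2] - w
  rho <- sqrt(outer((fy / h)^2, (fx / w)^2, "+"))
  lg <- matrix(0, h, w)
  lg[rho > 0] <- exp(-(log(rho[rho > 0] / omega0))^2 / (2 * log(sigma_f)^2))
  Re(Conj(Wh) %*% (spec * lg) %*% Conj(Ww)) / (h * w)
}

oracle_vs_map <- function(img, params) {
  lab <- oracle_lab(img)
  sf <- sqrt(oracle_loggabor(lab$L, params$omega0, params$sigma_f)^2 +
             oracle_loggabor(lab$a, params$omega0, params$sigma_f)^2 +
             oracle_loggabor(lab$b, params$omega0, params$sigma_f)^2)
  norm01 <- function(m) if (max(m) > min(m)) (m - min(m)) / (max(m) - min(m)) else m * 0
  an <- norm01(lab$a); bn <- norm01(lab$b)
  sc <- 1 - exp(-(an^2 + bn^2) / params$sigma_c^2)
  h <- nrow(sf); w <- ncol(sf)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  sd_prior <- exp(-(outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")) /
                    params$sigma_d^2)
  oracle_gauss_smooth(sf * sc * sd_prior, params$smooth$sigma, params$smooth$r)
}

oracle_gm_map <- function(img, params) {
  lum <- matrix(0, dim(img)[1], dim(img)[2])
  for (i in seq_len(dim(img)[1])) for (j in seq_len(dim(img)[2]))
    lum[i, j] <- sum(c(0.06, 0.63, 0.27) * img[i, j, ])
  kx <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), 3, 3, byrow = TRUE) / 16
  gx <- oracle_conv2(lum, kx)
  gy <- oracle_conv2(lum, t(kx))
  oracle_gauss_smooth(sqrt(gx^2 + gy^2), params$smooth$sigma, params$smooth$r)
}

oracle_cd_map <- function(img, params) {
  h <- dim(img)[1]; w <- dim(img)[2]
  M <- N <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    M[i, j] <- sum(c(0.30, 0.04, -0.35) * img[i, j, ])
    N[i, j] <- sum(c(0.34, -0.60, 0.17) * img[i, j, ])
  }
  oracle_gauss_smooth(abs(M * N), params$smooth$sigma, params$smooth$r)
}
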