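# Independent brute-force oracles. Everything here is written as a direct,
# loop-based transliteration of the underlying formulas and shares no code
# with the package internals it checks.

# index clamped to [1, n]: replicate border
.cl <- function(i, n) pmin(pmax(i, 1L), n)

# dense 2-D convolution (kernel flipped) with replicate borders
oracle_conv2 <- function(m, kern) {
  h <- nrow(m); w <- ncol(m)
  ry <- (nrow(kern) - 1L) %/% 2L
  rx <- (ncol(kern) - 1L) %/% 2L
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -ry:ry) for (dj in -rx:rx)
      acc <- acc + kern[ry + 1L + di, rx + 1L + dj] *
        m[.cl(i - di, h), .cl(j - dj, w)]
    out[i, j] <- acc
  }
  out
}

# normalized Gaussian kernel matrix (truncated at radius r)
oracle_gauss_kernel <- function(sigma, r) {
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

oracle_gauss_smooth <- function(m, sigma, r) {
  oracle_conv2(m, oracle_gauss_kernel(sigma, r))
}

# gradient-domain guided filter by explicit per-window least squares:
# replicate-pad, loop over every window, solve for (a, b), average the
# coefficients over windows, and form Q = a_bar * G + b_bar.
oracle_gdgif <- function(P, G, zeta1, eps, lam, reg_form = "divide") {
  h <- nrow(P); w <- ncol(P)
  z <- zeta1
  pad <- function(m) {
    m[.cl((1 - z):(h + z), h), .cl((1 - z):(w + z), w), drop = FALSE]
  }
  Pp <- pad(P); Gp <- pad(G)
  win <- function(m, i, j) m[(i):(i + 2 * z), (j):(j + 2 * z)]  # padded coords
  sd_win <- function(i, j, r) {
    v <- Gp[.cl((i + z - r):(i + z + r), h + 2 * z),
            .cl((j + z - r):(j + z + r), w + 2 * z)]
    sqrt(max(mean(v^2) - mean(v)^2, 0))
  }
  chi <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    chi[i, j] <- sd_win(i, j, 1L) * sd_win(i, j, z)
  Gam <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    Gam[i, j] <- mean((chi[i, j] + eps) / (chi + eps))
  mu <- mean(chi); spread <- mu - min(chi)
  gam <- if (spread <= .Machine$double.eps * max(mu, 1))
    matrix(0.5, h, w)
  else 1 - 1 / (1 + exp((4 / spread) * (chi - mu)))
  a <- matrix(0, h, w); b <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gw <- win(Gp, i, j); pw <- win(Pp, i, j)
    reg <- if (reg_form == "divide") lam / Gam[i, j] else lam * Gam[i, j]
    varg <- mean(gw^2) - mean(gw)^2
    covgp <- mean(gw * pw) - mean(gw) * mean(pw)
    a[i, j] <- (covgp + reg * gam[i, j]) / (max(varg, 0) + reg)
    b[i, j] <- mean(pw) - a[i, j] * mean(gw)
  }
  ap <- pad(a); bp <- pad(b)
  Q <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    Q[i, j] <- mean(win(ap, i, j)) * G[i, j] + mean(win(bp, i, j))
  Q
}

# --- metric transliterations ------------------------------------------------

oracle_qmi <- function(x, y, f) {
  q <- function(m) pmin(pmax(round(m * 255), 0), 255)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  one <- function(s, f) {
    joint <- matrix(0, 256, 256)
    qs <- q(s); qf <- q(f)
    for (i in seq_along(qs))
      joint[qs[i] + 1, qf[i] + 1] <- joint[qs[i] + 1, qf[i] + 1] + 1
    joint <- joint / length(qs)
    hs <- ent(rowSums(joint)); hf <- ent(colSums(joint))
    if (hs + hf == 0) return(0)
    (hs + hf - ent(joint)) / (hs + hf)
  }
  2 * (one(x, f) + one(y, f))
}

oracle_qy <- function(x, y, f, w = 7L) {
  C1 <- 1e-4; C2 <- 9e-4
  ssim_win <- function(a, b) {
    ma <- mean(a); mb <- mean(b)
    va <- mean(a^2) - ma^2; vb <- mean(b^2) - mb^2
    cab <- mean(a * b) - ma * mb
    ((2 * ma * mb + C1) * (2 * cab + C2)) /
      ((ma^2 + mb^2 + C1) * (va + vb + C2))
  }
  h <- nrow(x); wd <- ncol(x)
  vals <- c()
  for (i in seq_len(h - w + 1L)) for (j in seq_len(wd - w + 1L)) {
    wx <- x[i:(i + w - 1L), j:(j + w - 1L)]
    wy <- y[i:(i + w - 1L), j:(j + w - 1L)]
    wf <- f[i:(i + w - 1L), j:(j + w - 1L)]
    vx <- mean(wx^2) - mean(wx)^2
    vy <- mean(wy^2) - mean(wy)^2
    lam <- if (vx + vy > 0) vx / (vx + vy) else 0.5
    v <- if (ssim_win(wx, wy) >= 0.75)
      lam * ssim_win(wx, wf) + (1 - lam) * ssim_win(wy, wf)
    else max(ssim_win(wx, wf), ssim_win(wy, wf))
    vals <- c(vals, v)
  }
  mean(vals)
}

oracle_qabf <- function(a, b, f, Gg = 0.9994, Kg = -15, sg = 0.5,
                        Ga = 0.9879, Ka = -22, sa = 0.8) {
  sob_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  grad <- function(m) {
    sx <- oracle_conv2(m, sob_x)
    sy <- oracle_conv2(m, t(sob_x))
    al <- atan(sy / sx); al[!is.finite(al)] <- 0
    list(g = sqrt(sx^2 + sy^2), al = al)
  }
  gf <- grad(f)
  pres <- function(src) {
    gs <- grad(src)
    h <- nrow(src); w <- ncol(src)
    q <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      ga <- gs$g[i, j]; gF <- gf$g[i, j]
      G <- if (ga > gF) gF / ga else if (gF > 0) ga / gF else 0
      A <- 1 - abs(gs$al[i, j] - gf$al[i, j]) / (pi / 2)
      q[i, j] <- (Gg / (1 + exp(Kg * (G - sg)))) *
        (Ga / (1 + exp(Ka * (A - sa))))
    }
    list(q = q, w = gs$g)
  }
  pa <- pres(a); pb <- pres(b)
  sum(pa$q * pa$w + pb$q * pb$w) / sum(pa$w + pb$w)
}

# --- shared small fixtures --------------------------------------------------

random_plane <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

random_image <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

# smooth random image: band-limited so subsampled filtering is accurate
smooth_plane <- function(h, w, seed, sigma = 6) {
  p <- gaussian_smooth(random_plane(h, w, seed), gaussian_spec(sigma))
  (p - min(p)) / (max(p) - min(p))
}

small_pair <- function(h = 128, w = 128, seed = 1, blur_sigma = 3) {
  make_multifocus_pair(make_truth("plant-like", c(h, w), seed = seed),
                       blur_sigma = blur_sigma)
}

# pixels within `band` px of the in-focus mask boundary
boundary_band <- function(mask, band = 8) {
  bm <- mffuse:::box_mean(mask, band)
  bm > 1e-9 & bm < 1 - 1e-9
}
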