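#' Gradient-domain guided filter parameters
#'
#' * `zeta1` — window radius in pixels; local linear models are fit in
#'   `(2*zeta1+1)^2` windows (default 4).
#' * `eps` — small positive constant stabilizing the edge-aware weighting
#'   ratio (default 1e-6).
#' * `lam` — regularization strength of the slope penalty; default
#'   `(0.001 * L)^2`, tied to the dynamic-range constant as in the guided
#'   filter family.
#' * `s` — integer subsampling factor of the fast variant (default 4;
#'   `s = 1` disables subsampling).
#' * `L` — dynamic-range constant (default 9).
#'
#' @param zeta1 Positive integer window radius.
#' @param eps Positive real.
#' @param s Integer `>= 1`.
#' @param L Positive real.
#' @param lam Positive real; default `(0.001 * L)^2`.
#' @return An object of class `gdfgf_params`.
#' @export
gdfgf_params <- function(zeta1 = 4, eps = 1e-6, s = 4, L = 9,
                         lam = (0.001 * L)^2) {
  zeta1 <- as.integer(zeta1); s <- as.integer(s)
  if (zeta1 < 1L) stop("'zeta1' must be >= 1", call. = FALSE)
  if (s < 1L) stop("'s' must be >= 1", call. = FALSE)
  if (!is.finite(eps) || eps <= 0) stop("'eps' must be > 0", call. = FALSE)
  if (!is.finite(lam) || lam <= 0) stop("'lam' must be > 0", call. = FALSE)
  if (!is.finite(L) || L <= 0) stop("'L' must be > 0", call. = FALSE)
  structure(list(zeta1 = zeta1, eps = eps, lam = lam, s = s, L = L),
            class = "gdfgf_params")
}

#' @export
print.gdfgf_params <- function(x, ...) {
  cat(sprintf("<gdfgf_params> zeta1=%d eps=%g lam=%g s=%d L=%g\n",
              x$zeta1, x$eps, x$lam, x$s, x$L))
  invisible(x)
}

# chi(k) = sd in 3x3 window * sd in (2*zeta1+1)^2 window
edge_strength_chi <- function(G, params) {
  box_sd(G, 1L) * box_sd(G, params$zeta1)
}

#' Edge-aware weighting of the gradient-domain guided filter
#'
#' `chi(k)` is the product of the local standard deviations of the guidance
#' in a 3x3 window and in the filter window; the weighting
#' `Gamma(k) = mean_i (chi(k)+eps) / (chi(i)+eps)` is greater than 1 on
#' edges and below 1 in flat regions, so dividing the regularizer by it
#' weakens smoothing across edges.
#'
#' @param G Guidance plane (`H x W` matrix).
#' @param params A [gdfgf_params()].
#' @return `H x W` matrix of positive weights with mean-reciprocal 1 scale.
#' @export
edge_aware_weight <- function(G, params = gdfgf_params()) {
  stopifnot(is.matrix(G), all(is.finite(G)))
  chi <- edge_strength_chi(G, params)
  (chi + params$eps) * mean(1 / (chi + params$eps))
}

#' Edge-indicator slope target gamma
#'
#' Maps the edge strength `chi` through a sigmoid centred at its mean:
#' `gamma(k) = 1 - 1 / (1 + exp(eta * (chi(k) - mean(chi))))` with
#' `eta = 4 / (mean(chi) - min(chi))`. Near 1 on strong edges (pulling the
#' local slope toward 1, i.e. edge preservation) and near 0 in flat areas.
#' A constant `chi` (flat guidance, `eta` undefined) yields 0.5 everywhere.
#'
#' @param chi Nonnegative `H x W` matrix of edge strengths.
#' @return `H x W` matrix in `(0, 1)`.
#' @export
gamma_k <- function(chi) {
  stopifnot(is.matrix(chi))
  mu <- mean(chi)
  spread <- mu - min(chi)
  if (spread <= .Machine$double.eps * max(mu, 1)) {
    chi[] <- 0.5
    return(chi)
  }
  eta <- 4 / spread
  1 - 1 / (1 + exp(eta * (chi - mu)))
}

#' Gradient-domain guided filter
#'
#' Filters `P` guided by `G`: in every `(2*zeta1+1)^2` window a linear
#' model `Q = a*G + b` is fit to `P` with a slope penalty
#' `(lam / Gamma) * (a - gamma)^2` whose strength adapts per pixel via the
#' edge-aware weighting, pulling slopes toward the edge indicator `gamma`
#' instead of toward zero. Per-pixel coefficients are window-averaged
#' before the output `Q = a_bar * G + b_bar` is formed. Window statistics
#' use replicate borders.
#'
#' @param P Input plane (`H x W` matrix), e.g. a weight map.
#' @param G Guidance plane, same shape (e.g. source luminance).
#' @param params A [gdfgf_params()].
#' @param reg_form `"divide"` (default; regularizer `lam / Gamma`, the
#'   edge-preserving form) or `"multiply"` (`lam * Gamma`).
#' @return Filtered `H x W` matrix.
#' @export
gdgif <- function(P, G, params = gdfgf_params(),
                  reg_form = c("divide", "multiply")) {
  reg_form <- match.arg(reg_form)
  stopifnot(is.matrix(P), is.matrix(G))
  if (!identical(dim(P), dim(G)))
    stop("'P' and 'G' must have identical dimensions", call. = FALSE)
  z <- params$zeta1
  chi <- edge_strength_chi(G, params)
  Gam <- (chi + params$eps) * mean(1 / (chi + params$eps))
  gam <- gamma_k(chi)
  reg <- if (reg_form == "divide") params$lam / Gam else params$lam * Gam
  mG <- box_mean(G, z)
  mP <- box_mean(P, z)
  covGP <- box_mean(G * P, z) - mG * mP
  varG <- box_var(G, z)
  a <- (covGP + reg * gam) / (varG + reg)
  b <- mP - a * mG
  box_mean(a, z) * G + box_mean(b, z)
}

# nearest-neighbour subsampling: every s-th row/column starting at 1
nn_downsample <- function(m, s) {
  m[seq(1L, nrow(m), by = s), seq(1L, ncol(m), by = s), drop = FALSE]
}

# bilinear upsampling to (h, w), aligned with nn_downsample's grid: the
# subsample at index k sits at full-resolution coordinate 1 + (k-1)*s
bilinear_upsample <- function(m, h, w, s) {
  interp_rows <- function(m, n) {
    xi <- (seq_len(n) - 1) / s + 1
    i0 <- pmin(floor(xi), nrow(m))
    i1 <- pmin(i0 + 1, nrow(m))
    t <- xi - i0
    m[i0, , drop = FALSE] * (1 - t) + m[i1, , drop = FALSE] * t
  }
  t(interp_rows(t(interp_rows(m, h)), w))
}

#' Fast (subsampled) gradient-domain guided filter
#'
#' Runs [gdgif()] on nearest-neighbour-subsampled `P` and `G` (factor `s`),
#' then upsamples the averaged coefficients bilinearly and applies them to
#' the full-resolution guidance: `Q = a_bar * G + b_bar`. With `s = 1` this
#' is exactly [gdgif()].
#'
#' @inheritParams gdgif
#' @return Filtered `H x W` matrix.
#' @export
fast_gdgif <- function(P, G, params = gdfgf_params(),
                       reg_form = c("divide", "multiply")) {
  reg_form <- match.arg(reg_form)
  stopifnot(is.matrix(P), is.matrix(G))
  if (!identical(dim(P), dim(G)))
    stop("'P' and 'G' must have identical dimensions", call. = FALSE)
  s <- params$s
  if (s == 1L) return(gdgif(P, G, params, reg_form))
  if (s > min(dim(P)) / 4)
    stop("subsampling factor 's' too large for the image size", call. = FALSE)
  # window radius shrinks with the image so the spatial footprint is kept
  z <- max(1L, as.integer(round(params$zeta1 / s)))
  params_lo <- params; params_lo$zeta1 <- z
  Ps <- nn_downsample(P, s)
  Gs <- nn_downsample(G, s)
  chi <- edge_strength_chi(Gs, params_lo)
  Gam <- (chi + params$eps) * mean(1 / (chi + params$eps))
  gam <- gamma_k(chi)
  reg <- if (reg_form == "divide") params$lam / Gam else params$lam * Gam
  mG <- box_mean(Gs, z)
  mP <- box_mean(Ps, z)
  covGP <- box_mean(Gs * Ps, z) - mG * mP
  varG <- box_var(Gs, z)
  a <- (covGP + reg * gam) / (varG + reg)
  b <- mP - a * mG
  a_bar <- bilinear_upsample(box_mean(a, z), nrow(P), ncol(P), s)
  b_bar <- bilinear_upsample(box_mean(b, z), nrow(P), ncol(P), s)
  a_bar * G + b_bar
}
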