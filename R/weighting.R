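#' Saliency exponents
#'
#' The three exponents controlling the relative importance of the visual
#' saliency, gradient and chrominance maps in the weight-map product
#' `W = VS^alpha * GM^beta * CD^gamma`. Defaults are the reference
#' operating point `alpha = 1`, `beta = 0.89`, `gamma = 0.31`; an exponent
#' of 0 switches the corresponding map off entirely (`0^0` is taken as 1).
#'
#' @param alpha,beta,gamma Nonnegative reals; at least one must be positive.
#' @return An object of class `exponent_params`.
#' @export
exponent_params <- function(alpha = 1, beta = 0.89, gamma = 0.31) {
  v <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(v)) || any(v < 0))
    stop("exponents must be finite and nonnegative", call. = FALSE)
  if (all(v == 0)) stop("at least one exponent must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "exponent_params")
}

#' @export
print.exponent_params <- function(x, ...) {
  cat(sprintf("<exponent_params> alpha=%g beta=%g gamma=%g\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

# x^e with the 0^0 := 1 convention (R's native behaviour)
pow0 <- function(x, e) x^e

#' Combine saliency bundles into raw weight maps
#'
#' For each source `n`, `W_n = VS_n^alpha * GM_n^beta * CD_n^gamma`
#' elementwise. All maps must be nonnegative (rectified and normalized
#' upstream; see [saliency_bundle()]).
#'
#' @param bundles List of [saliency_bundle()] objects, one per source.
#' @param exps An [exponent_params()].
#' @return `H x W x N` weight stack.
#' @export
combine_saliencies <- function(bundles, exps = exponent_params()) {
  stopifnot(length(bundles) >= 1L)
  dims <- dim(bundles[[1]]$vs)
  out <- array(0, dim = c(dims, length(bundles)))
  for (n in seq_along(bundles)) {
    b <- bundles[[n]]
    if (!identical(dim(b$vs), dims))
      stop("all saliency bundles must share the same shape", call. = FALSE)
    if (min(b$vs) < 0 || min(b$gm) < 0 || min(b$cd) < 0)
      stop("saliency maps must be nonnegative (rectify/normalize upstream)",
           call. = FALSE)
    out[, , n] <- pow0(b$vs, exps$alpha) * pow0(b$gm, exps$beta) *
      pow0(b$cd, exps$gamma)
  }
  out
}

#' Per-pixel winner-take-all binarization of a weight stack
#'
#' At each pixel the source with the maximal weight receives 1 and all
#' others 0. Ties are broken toward the lowest source index, so exactly one
#' source wins every pixel.
#'
#' @param stack `H x W x N` weight stack, `N >= 2`.
#' @return Binary `H x W x N` stack.
#' @export
argmax_binarize <- function(stack) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L, dim(stack)[3] >= 2L)
  n <- dim(stack)[3]
  best <- stack[, , 1L]
  idx <- matrix(1L, dim(stack)[1], dim(stack)[2])
  for (k in 2:n) {
    upd <- stack[, , k] > best       # strict: earlier index keeps ties
    best[upd] <- stack[, , k][upd]
    idx[upd] <- k
  }
  out <- array(0, dim = dim(stack))
  for (k in seq_len(n)) out[, , k] <- (idx == k) * 1
  out
}

#' Normalize a weight stack to a per-pixel partition of unity
#'
#' Divides each pixel's weights by their sum across sources. Pixels where
#' all sources have weight zero receive the uniform weight `1/N`.
#'
#' @param stack Nonnegative `H x W x N` weight stack.
#' @return `H x W x N` stack summing to 1 at every pixel.
#' @export
normalize_weights <- function(stack) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (min(stack) < 0) stop("weights must be nonnegative", call. = FALSE)
  n <- dim(stack)[3]
  s <- apply(stack, c(1, 2), sum)
  zero <- s == 0
  s[zero] <- 1
  for (k in seq_len(n)) {
    w <- stack[, , k] / s
    w[zero] <- 1 / n
    stack[, , k] <- w
  }
  stack
}
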