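#' Morphological cleanup parameters
#'
#' @param binarize_threshold Threshold in `(0, 1)` separating focus from
#'   defocus in a refined weight map (default 0.5).
#' @param min_area Minimum connected-component area in pixels kept by the
#'   area opening; `NULL` (default) means 1\% of the image area, computed
#'   at call time.
#' @param apply Logical; apply the cleanup inside [refine_weights()]
#'   (default TRUE).
#' @return An object of class `morph_params`.
#' @export
morph_params <- function(binarize_threshold = 0.5, min_area = NULL,
                         apply = TRUE) {
  if (!is.numeric(binarize_threshold) || binarize_threshold <= 0 ||
      binarize_threshold >= 1)
    stop("'binarize_threshold' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.null(min_area)) {
    min_area <- as.integer(min_area)
    if (min_area < 1L) stop("'min_area' must be a positive integer", call. = FALSE)
  }
  structure(list(binarize_threshold = binarize_threshold,
                 min_area = min_area, apply = isTRUE(apply)),
            class = "morph_params")
}

#' Fusion configuration
#'
#' Collects every tunable of the fusion pipeline with its default
#' operating point: saliency exponents `alpha = 1`, `beta = 0.89`,
#' `gamma = 0.31`; two guided-filter refinement passes with
#' `zeta1 = 4`, `eps = 1e-6` each; subsampling `s = 4` and dynamic-range
#' constant `L = 9`; base/detail decomposition Gaussian `sigma = 5`,
#' `r = 15`.
#'
#' @param exponents An [exponent_params()].
#' @param saliency A [saliency_params()].
#' @param pass1,pass2 [gdfgf_params()] for the base- and detail-layer
#'   refinement passes.
#' @param morph A [morph_params()].
#' @param decomposition A [gaussian_spec()] for the base layer.
#' @param reg_form Regularization form of the guided filter, `"divide"`
#'   (default) or `"multiply"`; see [gdgif()].
#' @param detail_guidance Guidance of the second refinement pass:
#'   `"source"` (default; the source luminance) or `"base"` (the refined
#'   base weight map).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(exponents = exponent_params(),
                          saliency = saliency_params(),
                          pass1 = gdfgf_params(zeta1 = 4, eps = 1e-6),
                          pass2 = gdfgf_params(zeta1 = 4, eps = 1e-6),
                          morph = morph_params(),
                          decomposition = gaussian_spec(5, 15),
                          reg_form = c("divide", "multiply"),
                          detail_guidance = c("source", "base")) {
  stopifnot(inherits(exponents, "exponent_params"),
            inherits(saliency, "saliency_params"),
            inherits(pass1, "gdfgf_params"),
            inherits(pass2, "gdfgf_params"),
            inherits(morph, "morph_params"),
            inherits(decomposition, "gaussian_spec"))
  structure(list(exponents = exponents, saliency = saliency,
                 pass1 = pass1, pass2 = pass2, morph = morph,
                 decomposition = decomposition,
                 reg_form = match.arg(reg_form),
                 detail_guidance = match.arg(detail_guidance)),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("<fusion_config>\n")
  cat(sprintf("  exponents: alpha=%g beta=%g gamma=%g\n",
              x$exponents$alpha, x$exponents$beta, x$exponents$gamma))
  cat(sprintf("  refinement: zeta1=%d/%d eps=%g/%g s=%d L=%g reg_form=%s\n",
              x$pass1$zeta1, x$pass2$zeta1, x$pass1$eps, x$pass2$eps,
              x$pass1$s, x$pass1$L, x$reg_form))
  cat(sprintf("  decomposition: sigma=%g r=%d; detail guidance: %s\n",
              x$decomposition$sigma, x$decomposition$r, x$detail_guidance))
  cat(sprintf("  morphology: %s (threshold=%g, min_area=%s)\n",
              if (x$morph$apply) "on" else "off", x$morph$binarize_threshold,
              if (is.null(x$morph$min_area)) "1% of image" else x$morph$min_area))
  invisible(x)
}

#' Two-scale base/detail decomposition
#'
#' `base` is the Gaussian-smoothed image (per channel, replicate borders);
#' `detail = img - base` is the signed residual, so `base + detail`
#' reconstructs the input exactly.
#'
#' @param img `H x W x 3` RGB array in `[0, 1]`.
#' @param spec A [gaussian_spec()]; default `sigma = 5`, `r = 15`.
#' @return List with `base` and `detail` arrays.
#' @export
two_scale_decompose <- function(img, spec = gaussian_spec(5, 15)) {
  img <- as_color_image(img)
  base <- gaussian_smooth_rgb(img, spec)
  list(base = base, detail = img - base)
}

# connected-component edge list of a logical matrix; 8-neighbourhood by
# default, 4-neighbourhood (no diagonals) for background/hole labelling
component_membership <- function(mask, connect8 = TRUE) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- matrix(seq_len(h * w), h, w)
  pair <- function(a, b, sel) cbind(a[sel], b[sel])
  edges <- list(pair(idx[-h, ], idx[-1, ], mask[-h, ] & mask[-1, ]),
                pair(idx[, -w], idx[, -1], mask[, -w] & mask[, -1]))
  if (connect8) {
    edges <- c(edges,
               list(pair(idx[-h, -w], idx[-1, -1], mask[-h, -w] & mask[-1, -1]),
                    pair(idx[-1, -w], idx[-h, -1], mask[-1, -w] & mask[-h, -1])))
  }
  g <- igraph::make_graph(t(do.call(rbind, edges)), n = h * w, directed = FALSE)
  igraph::components(g)
}

# fill enclosed background regions ("holes") smaller than max_area; larger
# enclosed regions are legitimate structures, not holes, and are kept
fill_small_holes <- function(mask, max_area) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  if (!any(bg)) return(mask)
  comp <- component_membership(bg, connect8 = FALSE)
  border_ids <- unique(comp$membership[c(seq_len(h), (w - 1) * h + seq_len(h),
                                         ((seq_len(w) - 1) * h) + 1,
                                         (seq_len(w) - 1) * h + h)])
  memb <- matrix(comp$membership, h, w)
  hole <- bg & !(memb %in% border_ids) &
    matrix(comp$csize[comp$membership] < max_area, h, w)
  mask | hole
}

# 8-connected area opening: keep components of size >= min_area
area_open <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  comp <- component_membership(mask, connect8 = TRUE)
  mask & matrix(comp$csize[comp$membership] >= min_area,
                nrow(mask), ncol(mask))
}

#' Morphological cleanup of a refined weight map
#'
#' Thresholds the map, fills small holes in the below-threshold mask,
#' complements it, fills small holes again, and removes 8-connected
#' components smaller than `min_area`. The result is the cleaned binary
#' above-threshold mask cast back to a real-valued plane, i.e. small
#' spurious focus/defocus islands and pinholes are removed on both sides
#' of the decision. "Small" means below `min_area` throughout: an enclosed
#' region larger than that is treated as a legitimate focus/defocus region,
#' not a hole, so blob-shaped in-focus subjects surrounded by defocus
#' survive the cleanup.
#'
#' @param w `H x W` weight map in `[0, 1]`.
#' @param morph A [morph_params()].
#' @return `H x W` matrix with entries in `{0, 1}`.
#' @export
morphological_cleanup <- function(w, morph = morph_params()) {
  stopifnot(is.matrix(w))
  if (min(w) < -1e-9 || max(w) > 1 + 1e-9)
    stop("'w' must lie in [0, 1]", call. = FALSE)
  min_area <- morph$min_area
  if (is.null(min_area)) min_area <- ceiling(0.01 * length(w))
  mask <- w < morph$binarize_threshold
  t1 <- fill_small_holes(mask, min_area)
  t2 <- !t1
  t3 <- fill_small_holes(t2, min_area)
  area_open(t3, min_area) * 1
}

#' Refine binarized weight maps with the fast gradient-domain guided filter
#'
#' For each source, the base-layer weight map is the guided-filter
#' refinement of its binary weight map (guidance: the source's luminance),
#' and the detail-layer weight map is a second, independent refinement of
#' the base-layer map. Optional morphological cleanup then snaps both maps
#' back to clean binary regions, and both stacks are renormalized to
#' per-pixel partitions of unity.
#'
#' @param stack Binarized, normalized `H x W x N` weight stack.
#' @param sources List of `N` colour images matching the stack.
#' @param cfg A [fusion_config()].
#' @return List of two `H x W x N` stacks, `w_base` and `w_detail`, each
#'   summing to 1 at every pixel.
#' @export
refine_weights <- function(stack, sources, cfg = fusion_config()) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  n <- dim(stack)[3]
  if (length(sources) != n)
    stop("number of sources must match the weight stack", call. = FALSE)
  w_base <- array(0, dim = dim(stack))
  w_detail <- array(0, dim = dim(stack))
  for (k in seq_len(n)) {
    lum <- luminance(as_color_image(sources[[k]]))
    wb <- fast_gdgif(stack[, , k], lum, cfg$pass1, cfg$reg_form)
    guide2 <- if (cfg$detail_guidance == "source") lum else wb
    wd <- fast_gdgif(wb, guide2, cfg$pass2, cfg$reg_form)
    if (cfg$morph$apply) {
      wb <- morphological_cleanup(clamp01(wb), cfg$morph)
      wd <- morphological_cleanup(clamp01(wd), cfg$morph)
    }
    w_base[, , k] <- clamp01(wb)
    w_detail[, , k] <- clamp01(wd)
  }
  list(w_base = normalize_weights(w_base),
       w_detail = normalize_weights(w_detail))
}

#' Blend decomposed sources under refined weight maps
#'
#' Fused base `= sum_n W_base_n * base_n` and fused detail
#' `= sum_n W_detail_n * detail_n` (one weight map per source, shared
#' across the three colour channels to avoid colour fringing); the fused
#' image is their sum, clipped to `[0, 1]` only at this final step.
#'
#' @param decomps List of [two_scale_decompose()] results, one per source.
#' @param rw Refined weights from [refine_weights()].
#' @return Fused `H x W x 3` array in `[0, 1]`.
#' @export
blend <- function(decomps, rw) {
  n <- length(decomps)
  stopifnot(dim(rw$w_base)[3] == n, dim(rw$w_detail)[3] == n)
  fused <- array(0, dim = dim(decomps[[1]]$base))
  for (k in seq_len(n)) {
    for (ch in 1:3) {
      fused[, , ch] <- fused[, , ch] +
        rw$w_base[, , k] * decomps[[k]]$base[, , ch] +
        rw$w_detail[, , k] * decomps[[k]]$detail[, , ch]
    }
  }
  clamp01(fused)
}

#' Fuse multi-focus images
#'
#' End-to-end pipeline: per-source saliency bundles (visual, gradient,
#' chrominance), multiplicative combination into weight maps, per-pixel
#' winner-take-all binarization, guided-filter refinement with
#' morphological cleanup, two-scale decomposition and weighted blending.
#' Fully deterministic for fixed inputs and configuration.
#'
#' @param sources List of `N >= 2` co-registered `H x W x 3` RGB arrays in
#'   `[0, 1]` with identical dimensions.
#' @param cfg A [fusion_config()].
#' @param keep_intermediate Logical; if TRUE the result carries an
#'   `"intermediate"` attribute with the saliency bundles, raw/binarized
#'   weight stacks and refined weight stacks.
#' @return Fused `H x W x 3` array in `[0, 1]`.
#' @examples
#' fx <- make_multifocus_pair(make_truth("texture", c(48, 48), seed = 1),
#'                            blur_sigma = 2)
#' fused <- fuse(fx$sources, fusion_config(morph = morph_params(apply = FALSE)))
#' @export
fuse <- function(sources, cfg = fusion_config(), keep_intermediate = FALSE) {
  if (!is.list(sources) || length(sources) < 2L)
    stop("'sources' must be a list of at least two images", call. = FALSE)
  sources <- lapply(sources, as_color_image)
  dims <- dim(sources[[1]])
  for (s in sources)
    if (!identical(dim(s), dims))
      stop("all source images must share identical dimensions", call. = FALSE)
  bundles <- lapply(sources, saliency_bundle, params = cfg$saliency)
  raw <- combine_saliencies(bundles, cfg$exponents)
  bin <- normalize_weights(argmax_binarize(raw))
  rw <- refine_weights(bin, sources, cfg)
  decomps <- lapply(sources, two_scale_decompose, spec = cfg$decomposition)
  fused <- blend(decomps, rw)
  if (keep_intermediate)
    attr(fused, "intermediate") <- list(bundles = bundles, raw_weights = raw,
                                        binary_weights = bin, refined = rw)
  fused
}
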