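test_that("frequency prior vanishes on flat images and peaks at structure", {
  flat <- array(0.37, dim = c(32, 32, 3))
  sf <- frequency_prior(flat)
  expect_lt(max(abs(sf)), 1e-10)
  # bright square on dark background: response concentrates near the square
  img <- array(0.05, dim = c(64, 64, 3))
  img[28:36, 28:36, ] <- 0.95
  sf <- frequency_prior(img)
  expect_true(all(sf >= 0))
  inside <- mean(sf[24:40, 24:40])
  outside <- mean(sf[c(1:12, 53:64), c(1:12, 53:64)])
  expect_gt(inside, 5 * outside)
})

test_that("colour prior matches its closed form and range", {
  # achromatic image: a* and b* are flat, normalize to zero, SC = 0
  gray <- array(rep(matrix(seq(0, 1, length.out = 64), 8, 8), 3),
                dim = c(8, 8, 3))
  expect_lt(max(color_prior(gray)), 1e-9)
  # image whose a*/b* maxima coincide at one warm pixel: there a'=b'=1 and
  # SC = 1 - exp(-2 / sigma_c^2)
  img <- array(0.5, dim = c(2, 2, 3))
  img[1, 1, ] <- c(1, 0, 0)    # red: max a*, max b* among these two colours
  sc <- color_prior(img, saliency_params(sigma_c = 0.25))
  expect_equal(sc[1, 1], 1 - exp(-2 / 0.25^2), tolerance = 1e-12)
  r <- color_prior(random_image(16, 16, seed = 5))
  expect_true(all(r >= 0 & r < 1))
})

test_that("location prior is centred, symmetric, and matches substitution", {
  sd_map <- location_prior(c(101, 101), saliency_params(sigma_d = 114))
  expect_equal(sd_map[51, 51], 1)
  expect_equal(sd_map, sd_map[101:1, ], tolerance = 1e-12)
  expect_equal(sd_map, sd_map[, 101:1], tolerance = 1e-12)
  expect_equal(sd_map[1, 1], exp(-(50^2 + 50^2) / 114^2), tolerance = 1e-12)
})

test_that("visual saliency map recomposes from its priors", {
  img <- random_image(32, 32, seed = 6)
  p <- saliency_params()
  recomposed <- gaussian_smooth(
    frequency_prior(img, p) * color_prior(img, p) *
      location_prior(c(32, 32), p), p$smooth)
  expect_equal(visual_saliency_map(img, p), recomposed, tolerance = 1e-10)
  # any zero prior kills the product: an achromatic image has SC = 0
  gray <- array(rep(random_plane(16, 16, seed = 7), 3), dim = c(16, 16, 3))
  expect_lt(max(abs(visual_saliency_map(gray))), 1e-9)
})

test_that("Scharr gradients respond correctly to ramps and rotations", {
  expect_equal(scharr_gradients(matrix(0.7, 8, 8))$gx, matrix(0, 8, 8))
  # horizontal unit ramp: |gx| = 2 in the interior (the 16/16-normalized
  # kernel weights f(x+1) - f(x-1), a two-pixel baseline), gy = 0
  ramp <- matrix(rep(1:10, each = 10), 10, 10)   # I(x, y) = x along columns
  g <- scharr_gradients(ramp)
  expect_equal(abs(g$gx[3:8, 3:8]), matrix(2, 6, 6), tolerance = 1e-12)
  expect_equal(g$gy[3:8, 3:8], matrix(0, 6, 6), tolerance = 1e-12)
  # 90-degree rotation (transpose) swaps the roles of |gx| and |gy|
  p <- random_plane(16, 16, seed = 8)
  g1 <- scharr_gradients(p)
  g2 <- scharr_gradients(t(p))
  expect_equal(abs(g2$gx), t(abs(g1$gy)), tolerance = 1e-12)
  expect_equal(abs(g2$gy), t(abs(g1$gx)), tolerance = 1e-12)
})

test_that("gradient saliency is contrast-shift invariant and edge-localized", {
  p <- random_plane(24, 24, seed = 9)
  expect_equal(gradient_saliency_map(p), gradient_saliency_map(p + 0.3),
               tolerance = 1e-12)
  expect_lt(max(gradient_saliency_map(matrix(0.5, 24, 24))), 1e-12)
  # vertical step edge: the smoothed ridge sits along the edge
  step <- cbind(matrix(0, 24, 12), matrix(1, 24, 12))
  gm <- gradient_saliency_map(step, saliency_params())
  expect_true(all(gm[, 12] > gm[, 3]))
  expect_true(all(gm[, 13] > gm[, 22]))
})

test_that("the three saliency maps match single-function brute-force oracles", {
  img <- random_image(32, 32, seed = 10)
  p <- saliency_params()
  expect_equal(visual_saliency_map(img, p), oracle_vs_map(img, p),
               tolerance = 1e-10)
  expect_equal(gradient_saliency_map(luminance(img), p), oracle_gm_map(img, p),
               tolerance = 1e-10)
  expect_equal(chrominance_saliency_map(img, p), oracle_cd_map(img, p),
               tolerance = 1e-10)
})

test_that("chrominance saliency handles achromatic and black images", {
  expect_equal(chrominance_saliency_map(array(0, dim = c(12, 12, 3))),
               matrix(0, 12, 12))
  v <- random_plane(16, 16, seed = 11)
  gray <- array(rep(v, 3), dim = c(16, 16, 3))
  lmn <- rgb_to_lmn(gray)
  expect_equal(lmn$M, -0.01 * v, tolerance = 1e-12)
  expect_equal(lmn$N, -0.09 * v, tolerance = 1e-12)
  cd <- chrominance_saliency_map(gray)
  expect_equal(cd, gaussian_smooth(abs(-0.01 * v * -0.09 * v),
                                   saliency_params()$smooth),
               tolerance = 1e-12)
  expect_true(all(cd >= 0))
  expect_true(all(chrominance_saliency_map(random_image(16, 16, 12)) >= 0))
})

test_that("saliency maps are translation-equivariant away from borders", {
  img <- random_image(64, 64, seed = 13)
  # circular shift: preserves the global pixel population, so the per-image
  # min-max normalizations are unchanged and only border effects remain
  shifted <- img[c(6:64, 1:5), , , drop = FALSE]
  # centre bias is the one deliberately non-equivariant term; widen it out,
  # and use the spatial band-pass so every stage has finite support
  p <- saliency_params(sigma_d = 1e8, bandpass = "dog", dog_sigmas = c(1, 3))
  inner <- 25:40   # support: dog r=9 + smooth r=7 < margin of 19
  lum <- function(x) mffuse:::luminance(x)
  for (fn in list(function(x) visual_saliency_map(x, p),
                  function(x) gradient_saliency_map(lum(x), p),
                  function(x) chrominance_saliency_map(x, p))) {
    a <- fn(img); b <- fn(shifted)
    expect_equal(b[inner - 5, inner], a[inner, inner], tolerance = 1e-8)
  }
})

test_that("gradient saliency separates sharp from defocused copies", {
  truth <- make_truth("plant-like", c(96, 96), seed = 3)
  blurred <- array(0, dim = dim(truth))
  for (ch in 1:3)
    blurred[, , ch] <- gaussian_smooth(truth[, , ch], gaussian_spec(3))
  gm_sharp <- gradient_saliency_map(luminance(truth))
  gm_blur <- gradient_saliency_map(luminance(blurred))
  expect_gt(mean(gm_sharp), 1.5 * mean(gm_blur))
})

test_that("saliency bundles are normalized and nonnegative", {
  b <- saliency_bundle(random_image(24, 24, seed = 14))
  for (m in b[c("vs", "gm", "cd")]) {
    expect_gte(min(m), 0)
    expect_lte(max(m), 1)
    expect_equal(max(m), 1)
  }
})
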