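test_that("two-scale decomposition reconstructs the input exactly", {
  img <- random_image(32, 32, seed = 41)
  d <- two_scale_decompose(img, gaussian_spec(5, 15))
  expect_equal(d$base + d$detail, img, tolerance = 1e-9)
  flat <- array(0.6, dim = c(16, 16, 3))
  expect_equal(two_scale_decompose(flat)$detail, array(0, dim = c(16, 16, 3)))
  # impulse: base is the (truncated, normalized) Gaussian kernel
  imp <- array(0, dim = c(17, 17, 3)); imp[9, 9, ] <- 1
  d <- two_scale_decompose(imp, gaussian_spec(1, 3))
  expect_equal(d$base[6:12, 6:12, 1], oracle_gauss_kernel(1, 3),
               tolerance = 1e-12)
})

test_that("morphological cleanup fills pinholes and removes islands", {
  m <- matrix(0, 32, 32)
  m[5:28, 5:28] <- 1
  m[14:15, 14:15] <- 0          # pinhole in the focus region
  m[1:2, 30:31] <- 1            # 2x2 spurious island
  cleaned <- morphological_cleanup(m, morph_params(min_area = 25))
  expect_equal(cleaned[14:15, 14:15], matrix(1, 2, 2))
  expect_equal(cleaned[1:2, 30:31], matrix(0, 2, 2))
  # a clean mask passes through unchanged
  clean <- matrix(0, 32, 32); clean[, 17:32] <- 1
  expect_equal(morphological_cleanup(clean, morph_params(min_area = 25)), clean)
  expect_error(morphological_cleanup(m * 2, morph_params()), "\\[0, 1\\]")
})

test_that("cleanup also fills holes in the defocus (below-threshold) side", {
  m <- matrix(1, 32, 32)
  m[10:20, 10:20] <- 0
  m[14:16, 14:16] <- 1          # island inside the defocus hole
  cleaned <- morphological_cleanup(m, morph_params(min_area = 25))
  expect_equal(cleaned[14:16, 14:16], matrix(0, 3, 3))
})

test_that("refinement preserves degenerate constant weights and normalizes", {
  flat_img <- array(0.5, dim = c(32, 32, 3))
  stack <- array(0, dim = c(32, 32, 2))
  stack[, , 1] <- 1
  cfg <- fusion_config(pass1 = gdfgf_params(s = 1), pass2 = gdfgf_params(s = 1))
  rw <- refine_weights(stack, list(flat_img, flat_img), cfg)
  expect_equal(rw$w_base[, , 1], matrix(1, 32, 32), tolerance = 1e-9)
  expect_equal(rw$w_base[, , 2], matrix(0, 32, 32), tolerance = 1e-9)
  expect_equal(apply(rw$w_base, c(1, 2), sum), matrix(1, 32, 32),
               tolerance = 1e-9)
  expect_equal(apply(rw$w_detail, c(1, 2), sum), matrix(1, 32, 32),
               tolerance = 1e-9)
  expect_error(refine_weights(stack, list(flat_img), cfg), "match")
})

test_that("refined weights align with guidance edges", {
  # binary weights whose boundary sits 3 px off the true luminance edge:
  # guided refinement pulls the 0.5 crossing back toward the edge
  h <- 64; w <- 64
  img <- array(0.1, dim = c(h, w, 3)); img[, 33:64, ] <- 0.9
  stack <- array(0, dim = c(h, w, 2))
  stack[, 1:35, 1] <- 1                 # offset boundary at column 35
  stack[, , 2] <- 1 - stack[, , 1]
  cfg <- fusion_config(pass1 = gdfgf_params(s = 1), pass2 = gdfgf_params(s = 1),
                       morph = morph_params(apply = FALSE))
  rw <- refine_weights(stack, list(img, img), cfg)
  crossing <- apply(rw$w_base[, , 1], 1, function(row) max(which(row >= 0.5)))
  expect_true(all(abs(crossing - 32) <= 2))
})

test_that("blending honours degenerate weights", {
  s1 <- random_image(24, 24, seed = 42)
  s2 <- random_image(24, 24, seed = 43)
  decomps <- lapply(list(s1, s2), two_scale_decompose)
  w1 <- array(0, dim = c(24, 24, 2)); w1[, , 1] <- 1
  rw <- list(w_base = w1, w_detail = w1)
  expect_equal(blend(decomps, rw), s1, tolerance = 1e-12)
  # identical sources under any 0.5/0.5 split reproduce the source
  decomps2 <- lapply(list(s1, s1), two_scale_decompose)
  w5 <- array(0.5, dim = c(24, 24, 2))
  expect_equal(blend(decomps2, list(w_base = w5, w_detail = w5)), s1,
               tolerance = 1e-12)
})

test_that("fusing an image with itself returns the image", {
  img <- make_truth("plant-like", c(64, 64), seed = 5)
  expect_lt(max(abs(fuse(list(img, img)) - img)), 1e-6)
})

test_that("fusion is symmetric in the source order away from ties", {
  fx <- small_pair(h = 96, w = 96, seed = 6, blur_sigma = 2)
  bundles <- lapply(fx$sources, saliency_bundle)
  raw <- combine_saliencies(bundles)
  expect_equal(sum(raw[, , 1] == raw[, , 2]), 0)  # no tie pixels here
  f12 <- fuse(fx$sources)
  f21 <- fuse(rev(fx$sources))
  expect_equal(f12, f21, tolerance = 1e-12)
})

test_that("fusion rejects malformed inputs", {
  img <- random_image(16, 16, seed = 44)
  expect_error(fuse(list(img)), "at least two")
  expect_error(fuse(list(img, random_image(16, 18, seed = 45))), "identical")
})

test_that("fused output recovers the ground truth on a synthetic pair", {
  fx <- small_pair(h = 160, w = 160, seed = 7, blur_sigma = 3)
  fused <- fuse(fx$sources, keep_intermediate = TRUE)
  p_fused <- psnr(fused, fx$truth)
  p_best <- max(psnr(fx$sources[[1]], fx$truth), psnr(fx$sources[[2]], fx$truth))
  expect_gte(p_fused, 30)
  expect_gte(p_fused, p_best + 5)
  # fused stays within the per-pixel source envelope up to small overshoot
  lo <- pmin(fx$sources[[1]], fx$sources[[2]])
  hi <- pmax(fx$sources[[1]], fx$sources[[2]])
  expect_lt(max(pmax(fused - hi, 0, lo - fused)), 0.2)
  over <- mean(fused > hi + 0.05 | fused < lo - 0.05)
  expect_lt(over, 0.02)
})
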