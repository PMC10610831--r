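test_that("gray_dilate matches the brute-force max filter and its edge cases", {
  expect_equal(gray_dilate(matrix(7, 5, 5), 3), matrix(7, 5, 5))
  m <- matrix(200, 9, 9); m[5, 5] <- 10
  expect_equal(gray_dilate(m, 3), matrix(200, 9, 9))      # dark pixel removed
  g <- matrix(sample(0:255, 80, TRUE), 8, 10)
  expect_equal(gray_dilate(g, 1), g)                      # identity element
  set.seed(42)
  for (k in c(3, 5)) {
    r <- matrix(sample(0:255, 256, TRUE), 16, 16)
    expect_equal(gray_dilate(r, k), brute_window(r, k, max))
  }
  expect_error(gray_dilate(matrix(1, 3, 3), 4), "odd")
})

test_that("median3 matches the brute-force per-window median", {
  expect_equal(median3(matrix(40, 6, 6)), matrix(40, 6, 6))
  m <- matrix(100, 7, 7); m[4, 4] <- 255                  # salt outlier
  expect_equal(median3(m)[4, 4], 100)
  cb <- matrix(rep(c(0, 255), length.out = 64), 8, 8)     # checkerboard
  expect_equal(median3(cb), brute_window(cb, 3, median))
  set.seed(7)
  for (i in 1:4) {
    r <- matrix(sample(0:255, 256, TRUE), 16, 16)
    expect_equal(median3(r), brute_window(r, 3, median))
  }
})

test_that("background_difference and normalisation behave as declared", {
  x <- matrix(sample(0:255, 100, TRUE), 10, 10)
  expect_equal(background_difference(x, x), matrix(0, 10, 10))
  expect_equal(background_difference(matrix(200, 4, 4), matrix(50, 4, 4)),
               matrix(150, 4, 4))
  expect_error(background_difference(x, matrix(0, 9, 10)), "dimensions")
  expect_equal(normalize_0_255(matrix(c(10, 20), 5, 4)),
               matrix(c(0, 255), 5, 4))
  expect_equal(normalize_0_255(matrix(99, 3, 3)), matrix(0, 3, 3))
  idn <- matrix(seq(0, 255, length.out = 64), 8, 8)
  expect_equal(normalize_0_255(idn), idn)
})

test_that("adaptive_enhance masks bright content and respects limits", {
  u <- matrix(128, 20, 20)
  expect_false(any(adaptive_enhance(u, 5, 5)$mask))       # uniform -> empty
  rib <- matrix(20, 32, 32); rib[14:18, 5:28] <- 220      # bright ribbon
  res <- adaptive_enhance(rib, 15, 10)
  inside <- res$mask[15:17, 8:25]
  expect_true(all(inside))
  # against a global-Otsu oracle on the bimodal fixture
  thr <- EBImage::otsu(EBImage::as.Image(t(rib) / 255)) * 255
  expect_equal(res$mask[15:17, 8:25], (rib > thr)[15:17, 8:25])
  expect_false(any(adaptive_enhance(rib, 15, 1e9)$mask))  # offset -> Inf
  expect_true(all(res$image >= 0 & res$image <= 255))
})

test_that("shadow elimination homogenises the background and recovers the foreground", {
  sc <- generate_scene(c(Y = 2, G = 1, P = 1), shadow_strength = 0.6, seed = 5,
                       canvas = c(448, 448), with_block = FALSE)
  pp <- eliminate_shadow(sc$image)
  g0 <- to_gray(sc$image); g1 <- to_gray(pp$image)
  bg <- !sc$fg_mask
  expect_lt(sd(g1[bg]), sd(g0[bg]))                        # background settles
  iou_fg <- sum(pp$mask & sc$fg_mask) / sum(pp$mask | sc$fg_mask)
  expect_gte(iou_fg, 0.8)
  # shadow-free scene: mask is nearly exact
  sc0 <- generate_scene(c(Y = 2, G = 1, P = 1), shadow_strength = 0, seed = 5,
                        canvas = c(448, 448), with_block = FALSE)
  pp0 <- eliminate_shadow(sc0$image)
  expect_gte(sum(pp0$mask & sc0$fg_mask) / sum(pp0$mask | sc0$fg_mask), 0.9)
  # pure background image stays near-uniform
  flat <- array(rep(to_gray(sc0$image) * 0 + 220, 3), c(448, 448, 3)) +
    array(rnorm(448 * 448 * 3, 0, 2), c(448, 448, 3))
  ppf <- eliminate_shadow(flat)
  expect_lt(sd(to_gray(ppf$image)), 3)
})

test_that("shadow elimination is near-idempotent on an already-clean scene", {
  sc <- generate_scene(c(Y = 1, Z = 1), shadow_strength = 0.5, seed = 13,
                       canvas = c(384, 384), with_block = FALSE)
  p1 <- eliminate_shadow(sc$image)
  p2 <- eliminate_shadow(p1$image)
  changed <- mean(abs(to_gray(p2$image) - to_gray(p1$image)) > 5)
  expect_lt(changed, 0.02)
})

test_that("augmentation transforms pixels and boxes consistently", {
  sc <- tiny_scene()
  idcfg <- augment_config(0, 0, 0, 0, 0, 0, 0, 0, 0)
  a0 <- augment(sc, idcfg, seed = 3)
  expect_identical(a0$image, sc$image)
  expect_identical(a0$boxes, sc$boxes)
  fl <- augment_config(0, 0, 0, 0, 0, fliplr = 1, 0, 0, 0)
  a1 <- augment(sc, fl, seed = 3)
  a2 <- augment(a1, fl, seed = 4)
  expect_identical(a2$image, sc$image)                     # involution
  expect_equal(a2$boxes$cx, sc$boxes$cx, tolerance = 1e-12)
  # translate/scale keep boxes inside the unit square
  ts <- augment_config(0.015, 0.7, 0.4, translate = 0.2, scale = 0.5,
                       fliplr = 0.5, 0, 0, 0)
  for (s in 1:5) {
    b <- augment(sc, ts, seed = s)$boxes
    expect_true(all(b$cx - b$w / 2 >= -1e-9 & b$cx + b$w / 2 <= 1 + 1e-9))
    expect_true(all(b$cy - b$h / 2 >= -1e-9 & b$cy + b$h / 2 <= 1 + 1e-9))
  }
})

test_that("mosaic preserves classes and never grows the box count", {
  sc <- tiny_scene()
  others <- lapply(2:4, function(s)
    generate_scene(c(P = 1, Z = 1), seed = s, canvas = c(256, 256), ppmm = 5,
                   length_range = c(8, 14), width_range = c(1, 2.5)))
  ms <- mosaic_scenes(c(list(sc), others))
  total_in <- nrow(sc$boxes) + sum(vapply(others, function(s) nrow(s$boxes), 1L))
  expect_lte(nrow(ms$boxes), total_in)
  expect_true(all(ms$boxes$label %in% c("Y", "G", "P", "Z")))
  expect_equal(dim(ms$image), dim(sc$image))
  mu <- mixup_scenes(sc, others[[1]])
  expect_equal(nrow(mu$boxes), nrow(sc$boxes) + nrow(others[[1]]$boxes))
  pi1 <- paste_in_instance(sc, others[[2]])
  expect_equal(nrow(pi1$boxes), nrow(sc$boxes) + 1)
})

test_that("every preprocessing step keeps values inside [0, 255] and shapes fixed", {
  sc <- tiny_scene()
  g <- to_gray(sc$image)
  for (out in list(gray_dilate(sc$image, 5), median3(g),
                   background_difference(g, median3(g)),
                   normalize_0_255(g))) {
    expect_equal(dim(out), dim(g))
    expect_true(all(out >= 0 & out <= 255))
  }
  pp <- eliminate_shadow(sc$image)
  expect_equal(dim(pp$image), dim(sc$image))
  expect_true(all(pp$image >= 0 & pp$image <= 255))
})
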