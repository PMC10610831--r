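test_that("straight ribbons render at the specified pixel geometry", {
  sp <- ribbon_spec("Y", 10, 1, 0, center = c(100, 60), rotation = 0, ppmm = 10)
  rb <- generate_ribbon(sp, canvas = c(120, 200))
  fg <- which(rb$mask, arr.ind = TRUE)
  # 100 px along the centerline, 10 px across (plus <= 1 px rasterisation)
  expect_lte(abs(diff(range(fg[, 2])) + 1 - 100), 2)
  expect_lte(abs(diff(range(fg[, 1])) + 1 - 10), 2)
  expect_equal(rb$length_mm, 10)
  expect_equal(rb$width_mm, 1)
})

test_that("arc ribbons have the analytic area and arc geometry of the generating circle", {
  # constant-width tube along an arc: area = length x width; the rendered
  # mask must match within the rasterisation allowance (one px of boundary)
  for (cur in c(0.02, 0.05, -0.08)) {
    sp <- ribbon_spec("G", 15, 1.5, cur, center = c(150, 150), rotation = 33,
                      ppmm = 10)
    rb <- generate_ribbon(sp, canvas = c(300, 300))
    area <- sum(rb$mask)
    L <- 15 * 10; w <- 1.5 * 10
    expect_lt(abs(area - (L + 1) * (w + 1)) / (L * w), 0.08)
    # chord between tube end regions <= arc length
    fg <- which(rb$mask, arr.ind = TRUE)
    expect_lte(max(dist(fg[chull(fg), ])), L + w + 2)
  }
})

test_that("ribbon rendering is deterministic and validates its canvas", {
  sp <- ribbon_spec("Z", 12, 1.2, 0.03, center = c(80, 80), rotation = 10,
                    ppmm = 10)
  a <- generate_ribbon(sp, canvas = c(160, 160), seed = 5)
  b <- generate_ribbon(sp, canvas = c(160, 160), seed = 5)
  expect_identical(a$mask, b$mask)
  sp_big <- ribbon_spec("Z", 30, 1.2, 0, center = c(80, 80), rotation = 0,
                        ppmm = 10)
  expect_error(generate_ribbon(sp_big, canvas = c(100, 100)), "canvas")
})

test_that("ribbon_spec validates its invariants", {
  expect_error(ribbon_spec("Q", 10, 1), "class_label")
  expect_error(ribbon_spec("Y", 1, 2), "exceed")
  expect_error(ribbon_spec("Y", -1, 1), "positive")
})

test_that("scenes carry one in-frame box per ribbon and exact truth rows", {
  sc <- generate_scene(c(Y = 1), seed = 3, canvas = c(320, 320))
  expect_equal(nrow(sc$boxes), 1)
  expect_equal(sc$boxes$label, "Y")
  sc2 <- generate_scene(c(Y = 2, G = 1, Z = 2), seed = 9, canvas = c(640, 640))
  expect_equal(nrow(sc2$boxes), 5)
  expect_equal(nrow(sc2$truths), 5)
  expect_setequal(sc2$truths$id, sc2$boxes$id)
  with(sc2$boxes, {
    expect_true(all(cx - w / 2 >= 0 & cx + w / 2 <= 1))
    expect_true(all(cy - h / 2 >= 0 & cy + h / 2 <= 1))
  })
})

test_that("overlap placement produces intersecting boxes when requested", {
  sc <- generate_scene(c(Y = 2, G = 2), overlap_fraction = 1, seed = 21,
                       canvas = c(640, 640))
  expect_equal(nrow(sc$boxes), 4)
  xy <- with(sc$boxes, cbind((cx - w / 2), (cy - h / 2), (cx + w / 2), (cy + h / 2))) * 640
  got_overlap <- FALSE
  for (i in 1:3) for (j in (i + 1):4) {
    if (iou(xy[i, ], xy[j, ]) > 0) got_overlap <- TRUE
  }
  expect_true(got_overlap)
})

test_that("the calibration block renders at its physical pixel size", {
  sc <- generate_scene(c(Y = 1), with_block = TRUE, seed = 4,
                       canvas = c(320, 320), ppmm = 10, block_mm = c(3, 9))
  expect_lte(abs(sc$block_px_length - 90), 1)
  expect_lte(abs(measure_block_px(sc$image) - 90), 1.5)
})

test_that("scenes are byte-identical for equal seeds and differ across seeds", {
  a <- generate_scene(c(Y = 1, P = 1), seed = 8, canvas = c(320, 320))
  b <- generate_scene(c(Y = 1, P = 1), seed = 8, canvas = c(320, 320))
  c <- generate_scene(c(Y = 1, P = 1), seed = 9, canvas = c(320, 320))
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  expect_false(identical(a$image, c$image))
})

test_that("manifest splits exactly at the configured ratio, per label", {
  m <- build_manifest(c(Y = 1000, G = 1000, P = 1000, Z = 1000), c(7, 3), seed = 1)
  expect_equal(sum(m$split == "train"), 2800)
  expect_equal(sum(m$split == "test"), 1200)
  tab <- table(m$label, m$split)
  expect_true(all(tab[, "train"] == 700))
  expect_true(all(tab[, "test"] == 300))
  # indivisible counts: floor on the test side
  m2 <- build_manifest(c(Y = 10), c(2, 1), seed = 1)
  expect_equal(sum(m2$split == "test"), 3)
  expect_equal(sum(m2$split == "train"), 7)
  # degenerate ratio
  m3 <- build_manifest(c(Y = 17, G = 5), c(1, 0), seed = 1)
  expect_true(all(m3$split == "train"))
})

test_that("a manifest split is a partition and deterministic in the seed", {
  m1 <- build_manifest(c(Y = 40, G = 25), c(7, 3), seed = 5)
  m2 <- build_manifest(c(Y = 40, G = 25), c(7, 3), seed = 5)
  m3 <- build_manifest(c(Y = 40, G = 25), c(7, 3), seed = 6)
  expect_identical(m1, m2)
  expect_false(identical(m1$split, m3$split))
  expect_equal(nrow(m1), 65)
  expect_equal(anyDuplicated(m1$record_id), 0)
  expect_setequal(unique(m1$split), c("train", "test"))
})

test_that("scene round-trips through PNG + label files", {
  sc <- generate_scene(c(Y = 1, G = 1), with_block = TRUE, seed = 2,
                       canvas = c(320, 320))
  d <- withr::local_tempdir()
  write_scene(sc, d, "s1")
  img <- read_image(file.path(d, "s1.png"))
  expect_equal(dim(img), dim(sc$image))
  expect_equal(max(abs(img - sc$image)), 0)
  lb <- read_yolo_labels(file.path(d, "s1.txt"))
  expect_equal(nrow(lb), 2)
  expect_equal(lb$class, sc$boxes$class)
  expect_equal(lb$cx, sc$boxes$cx, tolerance = 1e-6)
})

test_that("the reference acquisition composition sums to its stated total", {
  comp <- shred_image_composition()
  expect_equal(nrow(comp), 11)
  expect_equal(sum(comp$quantity), 5300)
  expect_equal(sum(comp$quantity[!comp$blended]), 4000)
})
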