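cal10 <- calibrate(90, 9)     # 10 px/mm, the reference-block configuration

test_that("calibration is the plain pixel/mm ratio with validation", {
  expect_equal(cal10$pixels_per_mm, 10)
  expect_equal(calibrate(90, 3)$pixels_per_mm, 30)
  expect_error(calibrate(-1, 3), "positive")
  expect_error(calibrate(90, 0), "positive")
  sc <- generate_scene(c(Y = 1), with_block = TRUE, seed = 4,
                       canvas = c(320, 320), ppmm = 10, block_mm = c(3, 9))
  cal <- calibrate(measure_block_px(sc$image), 9)
  expect_lt(abs(cal$pixels_per_mm - 10) / 10, 0.02)
})

test_that("crop_and_select keeps the contour nearest the box centre", {
  img <- array(230, c(80, 120, 3))
  img[30:39, 20:99, ] <- 90                       # target bar
  img[5:12, 5:20, ] <- 60                         # corner fragment of neighbour
  box <- data.frame(cx = 0.5, cy = (34.5) / 80, w = 90 / 120, h = 30 / 80)
  mask <- crop_and_select(img, box)
  off <- attr(mask, "offset")
  sel <- which(mask, arr.ind = TRUE)
  rows <- sel[, 1] + off[1] - 1
  expect_true(all(rows >= 30 & rows <= 39))       # neighbour removed
  expect_gte(sum(mask), 10 * 80 * 0.95)
  expect_error(crop_and_select(array(230, c(40, 40, 3)),
                               data.frame(cx = .5, cy = .5, w = .5, h = .5)),
               "no object")
})

test_that("rotate_to_horizontal recovers the rectangle of a rotated bar", {
  mask <- matrix(FALSE, 60, 140); mask[25:34, 20:119] <- TRUE
  rc <- rotate_to_horizontal(mask)
  expect_equal(rc$x1, 100); expect_equal(rc$y1, 10)
  expect_lt(rc$residual_deg, 0.5)
  # pre-rotated 30 degrees: rectangle recovered within 1 px
  rb <- generate_ribbon(ribbon_spec("Y", 10, 1, 0, center = c(100, 100),
                                    rotation = 30, ppmm = 10), c(200, 200))
  rc2 <- rotate_to_horizontal(rb$mask)
  expect_lte(abs(rc2$x1 - 101), 2)
  expect_lte(abs(rc2$y1 - 11), 2)
  expect_gte(rc2$x1, rc2$y1)                      # long side horizontal
  sq <- matrix(FALSE, 40, 40); sq[10:29, 10:29] <- TRUE
  rcs <- rotate_to_horizontal(sq)
  expect_equal(rcs$x1, rcs$y1)
  expect_error(rotate_to_horizontal(matrix(c(TRUE, rep(FALSE, 8)), 3, 3)),
               "degenerate")
})

test_that("strips partition the mask and reject sub-2-px widths", {
  mask <- matrix(FALSE, 30, 100); mask[10:19, 1:100] <- TRUE
  rc <- rotate_to_horizontal(mask)
  strips <- slice_strips(rc, 10)
  expect_length(strips, 10)
  expect_true(all(vapply(strips, function(s) ncol(s$mask), 1L) == 10))
  expect_equal(sum(vapply(strips, function(s) sum(s$mask), 1L)), sum(rc$mask))
  expect_error(slice_strips(rc, 99), "2 px")
  expect_error(slice_strips(rc, 1), ">= 2")
})

test_that("length recovers straight bars, semicircles and multi-bend ribbons", {
  mask <- matrix(FALSE, 60, 140); mask[25:34, 20:119] <- TRUE
  rc <- rotate_to_horizontal(mask)
  l <- length_of(rc, 10, cal10)
  expect_lt(abs(l$length_mm - 10) / 10, 0.03)
  # semicircular arc: curvature 0.1/mm, length pi*r with r = 10 mm
  rb <- generate_ribbon(ribbon_spec("Y", pi * 10, 1.5, 0.1,
                                    center = c(150, 150), rotation = 0,
                                    ppmm = 10), c(300, 300))
  l2 <- length_of(rotate_to_horizontal(rb$mask), 50, cal10)
  expect_lt(abs(l2$length_mm - pi * 10) / (pi * 10), 0.03)
  # multi-bend (S-curve) ribbon of known total length
  rb3 <- generate_ribbon(ribbon_spec("G", 22, 1.8, c(0.06, -0.06),
                                     center = c(150, 150), rotation = 10,
                                     ppmm = 10), c(300, 300))
  l3 <- length_of(rotate_to_horizontal(rb3$mask), 50, cal10)
  expect_lt(abs(l3$length_mm - 22) / 22, 0.05)
  # arc length never beats the chord between end centroids
  ce <- l2$fit$centroids
  chord <- sqrt(sum((ce[1, ] - ce[nrow(ce), ])^2))
  expect_gte(l2$fit$arc_length_px, chord)
})

test_that("strip inscribed-circle diameters equal exhaustive interior search", {
  set.seed(19)
  shapes <- c(
    lapply(1:3, function(i) {
      m <- matrix(FALSE, 24, 48)
      m[sample(6:18, 1):(18 + sample(0:5, 1)), 4:44] <- TRUE
      m
    }),
    lapply(1:3, function(i) {
      sp <- ribbon_spec("Y", runif(1, 3, 4.2), runif(1, 0.8, 1.4),
                        runif(1, -0.15, 0.15), center = c(32, 32),
                        rotation = runif(1, 0, 180), ppmm = 10)
      generate_ribbon(sp, canvas = c(64, 64))$mask
    })
  )
  for (m in shapes) {
    rc <- rotate_to_horizontal(m)
    strips <- slice_strips(rc, 5)
    di <- shredmorph:::strip_diameters(rc, strips)
    for (k in seq_along(strips)) {
      if (strips[[k]]$empty) next
      cols <- (strips[[k]]$x_lo + 1):strips[[k]]$x_hi
      expect_equal(di[k], 2 * oracle_strip_radius(rc$mask, cols) - 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("width recovers bars and constant-width arcs within tolerance", {
  mask <- matrix(FALSE, 60, 140); mask[25:34, 20:119] <- TRUE
  rc <- rotate_to_horizontal(mask)
  w <- width_of(rc, 10, cal10)
  expect_lte(abs(w$width_mm - 1), 0.1)            # within 1 px equivalent
  rb <- generate_ribbon(ribbon_spec("G", 15, 2.5, -0.05, center = c(150, 150),
                                    rotation = 130, ppmm = 10), c(300, 300))
  w2 <- width_of(rotate_to_horizontal(rb$mask), 50, cal10)
  expect_lt(abs(w2$width_mm - 2.5) / 2.5, 0.15)
  expect_true(all(w2$profile$diameters_px <= rotate_to_horizontal(rb$mask)$y1 + 1,
                  na.rm = TRUE))
})

test_that("measurements are rotation-invariant and scale-equivariant", {
  lens <- c(); wids <- c()
  for (ang in seq(0, 170, by = 10)) {
    rb <- generate_ribbon(ribbon_spec("Y", 14, 1.6, 0.03, center = c(120, 120),
                                      rotation = ang, ppmm = 10), c(240, 240))
    rc <- rotate_to_horizontal(rb$mask)
    lens <- c(lens, length_of(rc, 50, cal10)$length_mm)
    wids <- c(wids, width_of(rc, 50, cal10)$width_mm)
  }
  expect_lt(diff(range(lens)) / mean(lens), 0.03)
  expect_lt(diff(range(wids)) / mean(wids), 0.08)
  # doubling ppmm doubles pixels but leaves mm nearly unchanged
  m1 <- generate_ribbon(ribbon_spec("Z", 12, 1.5, 0.04, center = c(100, 100),
                                    rotation = 25, ppmm = 10), c(200, 200))
  m2 <- generate_ribbon(ribbon_spec("Z", 12, 1.5, 0.04, center = c(200, 200),
                                    rotation = 25, ppmm = 20), c(400, 400))
  r1 <- rotate_to_horizontal(m1$mask); r2 <- rotate_to_horizontal(m2$mask)
  l1 <- length_of(r1, 50, cal10)
  l2 <- length_of(r2, 50, calibrate(180, 9))
  expect_lt(abs(r2$x1 / r1$x1 - 2), 0.1)
  expect_lt(abs(l2$length_mm - l1$length_mm) / l1$length_mm, 0.02)
})

test_that("measure_scene reports per-object rows, errors and aggregates", {
  sc <- generate_scene(c(Y = 1), with_block = TRUE, seed = 31,
                       canvas = c(448, 448), shadow_strength = 0)
  cal <- calibrate(sc$block_px_length, sc$block_mm[2])
  rep1 <- measure_scene(sc$image, sc$boxes, cal, truths = sc$truths)
  expect_s3_class(rep1, "size_report")
  expect_equal(nrow(rep1), 1)
  expect_lt(abs(rep1$rel_err_len_pct), 5)
  expect_lt(abs(rep1$rel_err_wid_pct), 15)
  # empty box list -> empty report
  rep0 <- measure_scene(sc$image, sc$boxes[0, ], cal)
  expect_equal(nrow(rep0), 0)
})
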