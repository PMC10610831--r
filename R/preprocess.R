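#' Background-shadow elimination and training-time augmentation
#'
#' The shadow-elimination pipeline targets scenes of dark fragments on a
#' light, unevenly lit ground. It estimates the (shadowed) background by
#' grayscale dilation large enough to swallow the fragments, median-filters
#' the estimate, takes the absolute difference against the original gray
#' image (shadows, present in both, cancel; fragments stand out), normalises
#' the difference to 0-255 and finally derives a foreground mask by adaptive
#' local-mean thresholding, which drives the output enhancement.
#'
#' @name preprocess
NULL

validate_gray <- function(image, what = "image") {
  assert_that(is.matrix(image) && length(image) > 0,
              "%s must be a non-empty matrix", what)
  assert_that(all(image >= 0 & image <= 255), "%s values must lie in [0, 255]", what)
  invisible(image)
}

#' Grayscale conversion followed by square dilation
#'
#' Dilation (a running max over a \code{kernel_size} square, replicate edges)
#' expands the bright background and erodes dark fragments; with a kernel
#' wider than the fragments it yields a background estimate that retains the
#' smooth shading/shadow field.
#'
#' @param image RGB array or gray matrix, values 0-255.
#' @param kernel_size odd integer >= 1; 1 is the identity (grayscale only).
#' @return gray matrix 0-255.
#' @export
gray_dilate <- function(image, kernel_size = 3) {
  assert_that(length(image) > 0, "empty image")
  g <- to_gray(image)
  validate_gray(g)
  max_filter(g, kernel_size)
}

# vectorised median of 9: sort each row triple, then the median of nine is
# med3(max of row minima, med3 of row medians, min of row maxima)
.median9 <- function(v) {
  med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))
  sort3 <- function(a, b, c) {
    lo <- pmin(a, b, c); hi <- pmax(a, b, c)
    list(lo = lo, mid = med3(a, b, c), hi = hi)
  }
  r1 <- sort3(v[[1]], v[[2]], v[[3]])
  r2 <- sort3(v[[4]], v[[5]], v[[6]])
  r3 <- sort3(v[[7]], v[[8]], v[[9]])
  med3(pmax(r1$lo, r2$lo, r3$lo),
       med3(r1$mid, r2$mid, r3$mid),
       pmin(r1$hi, r2$hi, r3$hi))
}

#' 3 x 3 median filter with replicate-padded edges
#'
#' @param image gray matrix 0-255, at least 3 x 3.
#' @return gray matrix of the same size.
#' @export
median3 <- function(image) {
  validate_gray(image)
  assert_that(nrow(image) >= 3 && ncol(image) >= 3, "image must be at least 3 x 3")
  p <- pad_replicate(image, 1L)
  H <- nrow(image); W <- ncol(image)
  v <- vector("list", 9)
  k <- 1
  for (dj in 0:2) for (di in 0:2) {
    v[[k]] <- p[di + seq_len(H), dj + seq_len(W), drop = FALSE]
    k <- k + 1
  }
  .median9(v)
}

#' Per-pixel absolute difference between two gray images
#'
#' Regions identical in both map to 0 (black); fragments that were removed
#' from the processed background estimate show up bright.
#'
#' @param original,processed gray matrices of equal size.
#' @return gray matrix 0-255.
#' @export
background_difference <- function(original, processed) {
  validate_gray(original, "original"); validate_gray(processed, "processed")
  assert_that(all(dim(original) == dim(processed)),
              "original and processed images must have the same dimensions")
  abs(original - processed)
}

#' Min-max normalisation to the 0-255 range
#'
#' A constant image maps to all zeros (the convention for a difference image
#' in which nothing changed).
#'
#' @param image gray matrix.
#' @return gray matrix spanning 0-255 (or all zero).
#' @export
normalize_0_255 <- function(image) {
  assert_that(is.matrix(image), "image must be a matrix")
  rng <- range(image)
  if (diff(rng) == 0) return(matrix(0, nrow(image), ncol(image)))
  (image - rng[1]) / diff(rng) * 255
}

#' Adaptive local-mean threshold and enhancement
#'
#' A pixel is foreground when it exceeds its local box mean (window
#' \code{window}) by more than \code{offset}. The returned image is the input
#' with foreground multiplied by \code{gain} (clamped to 255) and background
#' suppressed by \code{bg_gain}.
#'
#' @param image gray matrix 0-255.
#' @param window odd integer >= 3; the local-mean window.
#' @param offset threshold offset above the local mean.
#' @param gain foreground multiplier (default 1.2).
#' @param bg_gain background multiplier (default 0.5).
#' @return list(image = enhanced gray matrix, mask = logical foreground mask).
#' @export
adaptive_enhance <- function(image, window = 15, offset = 5, gain = 1.2,
                             bg_gain = 0.5) {
  validate_gray(image)
  assert_that(is_count(window) && window %% 2 == 1 && window >= 3,
              "window must be an odd integer >= 3")
  mu <- box_mean(image, window)
  mask <- image > mu + offset
  out <- image * bg_gain
  out[mask] <- clamp(image[mask] * gain)
  list(image = out, mask = mask)
}

#' Background-shadow elimination (full pipeline)
#'
#' Composes grayscale dilation, 3 x 3 median filtering, background
#' differencing, 0-255 normalisation and adaptive threshold enhancement, then
#' reassembles an RGB image whose background is homogenised to its median
#' colour while foreground pixels keep (optionally boosted) original values.
#'
#' @param image RGB array H x W x 3, 0-255.
#' @param dilate_kernel odd integer; must exceed the widest fragment in px for
#'   the background estimate to swallow the fragments (default 41, suited to
#'   fragments up to ~4 mm wide at 10 px/mm).
#' @param window,offset adaptive-threshold parameters. The window is sized to
#'   the content, not the frame: it should be comparable to the widest
#'   fragment (default 33 px, about one fragment width at the 10 px/mm
#'   working scale); much larger windows let a dark fragment's local mean
#'   suppress a faint neighbour. Offset (default 12) sits about three
#'   standard deviations above the normalised background noise.
#' @param gain foreground boost applied in the output (default 1 = keep).
#' @param min_size foreground components smaller than this many pixels are
#'   discarded as speckle (default 25).
#' @return list(image = RGB array, mask = logical foreground mask,
#'   difference = normalised difference image).
#' @export
eliminate_shadow <- function(image, dilate_kernel = 41, window = NULL,
                             offset = 12, gain = 1, min_size = 25) {
  assert_that(length(dim(image)) == 3, "image must be an H x W x 3 array")
  g0 <- to_gray(image)
  if (is.null(window)) window <- min(33, max(15, min(dim(g0)) %/% 4 * 2 + 1))
  bg <- median3(gray_dilate(image, dilate_kernel))
  diffn <- normalize_0_255(background_difference(g0, bg))
  enh <- adaptive_enhance(diffn, window = window, offset = offset)
  mask <- from_ebi(EBImage::fillHull(as_ebi(enh$mask))) > 0
  if (min_size > 0 && any(mask)) {
    lab <- from_ebi(EBImage::bwlabel(as_ebi(mask)))
    sz <- tabulate(lab)
    mask <- mask & matrix(sz[pmax(lab, 1L)], nrow(mask)) >= min_size
  }
  # hysteresis growth: a coiled fragment wider than the window spacing pulls
  # its own local mean up and loses its interior; grow each confident
  # component into connected pixels above a component-referenced floor
  if (any(mask)) {
    lab <- from_ebi(EBImage::bwlabel(as_ebi(mask)))
    grown <- mask
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      n_comp <- sum(comp)
      floor_k <- 0.75 * stats::median(diffn[comp])
      cand <- diffn > floor_k | comp
      lab2 <- from_ebi(EBImage::bwlabel(as_ebi(cand)))
      seed <- which(comp & diffn == max(diffn[comp]))[1]
      reg <- lab2 == lab2[seed]
      if (sum(reg) <= 4 * n_comp) grown <- grown | reg
    }
    mask <- from_ebi(EBImage::fillHull(as_ebi(grown))) > 0
  }
  out <- image
  bg_idx <- which(!mask)
  for (ch in 1:3) {
    plane <- out[, , ch]
    med <- stats::median(plane[bg_idx])
    plane[bg_idx] <- med
    if (gain != 1) plane[mask] <- clamp(plane[mask] * gain)
    out[, , ch] <- plane
  }
  list(image = out, mask = mask, difference = diffn)
}

#' Augmentation configuration with the standard single-stage-detector defaults
#'
#' @param hsv_h,hsv_s,hsv_v fractional jitter gains for hue, saturation,
#'   value (defaults 0.015, 0.7, 0.4).
#' @param translate maximal fractional translation (default 0.2).
#' @param scale maximal fractional rescale (default 0.5).
#' @param fliplr probability of a left-right flip (default 0.5).
#' @param mosaic probability of 4-scene mosaic stitching (default 1).
#' @param mixup probability of blending with a second scene (default 0.05).
#' @param paste_in probability of copy-pasting an object instance (default 0.05).
#' @return an \code{augment_config} list.
#' @export
augment_config <- function(hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4,
                           translate = 0.2, scale = 0.5, fliplr = 0.5,
                           mosaic = 1, mixup = 0.05, paste_in = 0.05) {
  cfg <- list(hsv_h = hsv_h, hsv_s = hsv_s, hsv_v = hsv_v,
              translate = translate, scale = scale, fliplr = fliplr,
              mosaic = mosaic, mixup = mixup, paste_in = paste_in)
  probs <- unlist(cfg[c("fliplr", "mosaic", "mixup", "paste_in")])
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  assert_that(all(unlist(cfg) >= 0), "gains must be non-negative")
  structure(cfg, class = "augment_config")
}

.apply_hsv <- function(image, g) {
  if (all(unlist(g[c("hsv_h", "hsv_s", "hsv_v")]) == 0)) return(image)
  d <- dim(image)
  rgbm <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
  hsvm <- grDevices::rgb2hsv(rgbm, maxColorValue = 255)
  jit <- stats::runif(3, -1, 1) * c(g$hsv_h, g$hsv_s, g$hsv_v)
  hsvm[1, ] <- (hsvm[1, ] + jit[1]) %% 1
  hsvm[2, ] <- clamp(hsvm[2, ] * (1 + jit[2]), 0, 1)
  hsvm[3, ] <- clamp(hsvm[3, ] * (1 + jit[3]), 0, 1)
  # numeric hsv -> rgb (avoids per-pixel colour strings)
  h6 <- hsvm[1, ] * 6; s <- hsvm[2, ]; v <- hsvm[3, ]
  i <- floor(h6) %% 6; f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- image
  out[, , 1] <- matrix(round(r * 255), d[1], d[2])
  out[, , 2] <- matrix(round(g * 255), d[1], d[2])
  out[, , 3] <- matrix(round(b * 255), d[1], d[2])
  out
}

.bg_fill_color <- function(image) {
  # median of the image border, a robust background estimate
  border <- rbind(image[1, , ], image[nrow(image[, , 1]), , ])
  apply(border, 2, stats::median)
}

.shift_image <- function(image, dx, dy) {
  d <- dim(image); H <- d[1]; W <- d[2]
  fill <- .bg_fill_color(image)
  out <- array(0, d)
  for (ch in 1:3) out[, , ch] <- fill[ch]
  src_x <- seq_len(W) - dx; src_y <- seq_len(H) - dy
  ok_x <- src_x >= 1 & src_x <= W; ok_y <- src_y >= 1 & src_y <= H
  out[which(ok_y), which(ok_x), ] <- image[src_y[ok_y], src_x[ok_x], , drop = FALSE]
  out
}

.resize_rgb <- function(image, H, W) {
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    out[, , ch] <- from_ebi(EBImage::resize(as_ebi(image[, , ch]), w = W, h = H))
  }
  clamp(out)
}

.scene_like <- function(scene, image, boxes) {
  out <- scene
  out$image <- image
  out$boxes <- boxes
  out$fg_mask <- NULL          # pixel-level truth is not tracked through augmentation
  out
}

#' Augment a scene (pixels and boxes consistently)
#'
#' Applies, in order: HSV jitter, translation, scaling, left-right flip,
#' mosaic stitching, mixup blending and instance paste-in, each governed by
#' \code{cfg}. Boxes are transformed with the pixels, clipped to the frame
#' and dropped when they fall fully outside.
#'
#' @param scene a \code{shred_scene}.
#' @param cfg an \code{\link{augment_config}}.
#' @param seed integer seed.
#' @param pool optional list of additional scenes used by mosaic/mixup/
#'   paste_in; without a pool those ops fall back to self-combination.
#' @return an augmented \code{shred_scene}.
#' @export
augment <- function(scene, cfg = augment_config(), seed = 1, pool = list()) {
  assert_that(inherits(cfg, "augment_config"), "cfg must be an augment_config")
  with_seed(seed, {
    img <- scene$image; boxes <- scene$boxes
    d <- dim(img); H <- d[1]; W <- d[2]
    img <- .apply_hsv(img, cfg)
    if (cfg$translate > 0) {
      dx <- round(runif1(-cfg$translate, cfg$translate) * W)
      dy <- round(runif1(-cfg$translate, cfg$translate) * H)
      img <- .shift_image(img, dx, dy)
      boxes$cx <- boxes$cx + dx / W; boxes$cy <- boxes$cy + dy / H
      boxes <- clip_boxes(boxes)
    }
    if (cfg$scale > 0) {
      s <- 1 + runif1(-cfg$scale, cfg$scale)
      H2 <- max(8, round(H * s)); W2 <- max(8, round(W * s))
      scaled <- .resize_rgb(img, H2, W2)
      fill <- .bg_fill_color(img)
      canvas <- array(0, c(H, W, 3))
      for (ch in 1:3) canvas[, , ch] <- fill[ch]
      if (s >= 1) {            # centre crop
        oy <- (H2 - H) %/% 2; ox <- (W2 - W) %/% 2
        canvas <- scaled[oy + seq_len(H), ox + seq_len(W), , drop = FALSE]
        boxes$cx <- (boxes$cx * W2 - ox) / W; boxes$cy <- (boxes$cy * H2 - oy) / H
        boxes$w <- boxes$w * W2 / W; boxes$h <- boxes$h * H2 / H
      } else {                 # centre pad
        oy <- (H - H2) %/% 2; ox <- (W - W2) %/% 2
        canvas[oy + seq_len(H2), ox + seq_len(W2), ] <- scaled
        boxes$cx <- (boxes$cx * W2 + ox) / W; boxes$cy <- (boxes$cy * H2 + oy) / H
        boxes$w <- boxes$w * W2 / W; boxes$h <- boxes$h * H2 / H
      }
      img <- canvas
      boxes <- clip_boxes(boxes)
    }
    if (stats::runif(1) < cfg$fliplr) {
      img <- img[, rev(seq_len(W)), , drop = FALSE]
      boxes$cx <- 1 - boxes$cx
    }
    cur <- .scene_like(scene, img, boxes)
    if (stats::runif(1) < cfg$mosaic && length(pool) >= 3) {
      cur <- mosaic_scenes(c(list(cur), pool[1:3]))
    }
    if (stats::runif(1) < cfg$mixup && length(pool) >= 1) {
      cur <- mixup_scenes(cur, pool[[sample(length(pool), 1)]])
    }
    if (stats::runif(1) < cfg$paste_in) {
      cur <- paste_in_instance(cur, if (length(pool)) pool[[sample(length(pool), 1)]] else cur)
    }
    cur
  })
}

#' Stitch four scenes into a 2 x 2 mosaic
#'
#' Each scene is downscaled to a quadrant of the first scene's frame; class
#' labels are preserved and boxes remapped, so the output box count never
#' exceeds the sum of the inputs'.
#'
#' @param scenes list of exactly 4 \code{shred_scene}s.
#' @return a \code{shred_scene}.
#' @export
mosaic_scenes <- function(scenes) {
  assert_that(length(scenes) == 4, "mosaic requires exactly 4 scenes")
  d <- dim(scenes[[1]]$image); H <- d[1]; W <- d[2]
  h2 <- H %/% 2; w2 <- W %/% 2
  img <- array(0, c(H, W, 3))
  all_boxes <- list()
  quads <- list(c(0, 0), c(0, w2), c(h2, 0), c(h2, w2))
  for (i in 1:4) {
    sc <- scenes[[i]]
    small <- .resize_rgb(sc$image, h2, w2)
    oy <- quads[[i]][1]; ox <- quads[[i]][2]
    img[oy + seq_len(h2), ox + seq_len(w2), ] <- small
    b <- sc$boxes
    if (nrow(b)) {
      b$cx <- (b$cx * w2 + ox) / W; b$cy <- (b$cy * h2 + oy) / H
      b$w <- b$w * w2 / W; b$h <- b$h * h2 / H
      all_boxes[[i]] <- b
    }
  }
  boxes <- clip_boxes(do.call(rbind, all_boxes))
  boxes$id <- seq_len(nrow(boxes))
  .scene_like(scenes[[1]], clamp(img), boxes)
}

#' Blend two scenes (mixup)
#'
#' Pixel blend with a Beta(8, 8)-drawn weight; the box lists are concatenated.
#'
#' @param a,b \code{shred_scene}s of equal frame size.
#' @return a \code{shred_scene}.
#' @export
mixup_scenes <- function(a, b) {
  assert_that(all(dim(a$image) == dim(b$image)), "mixup needs equal frame sizes")
  lam <- stats::rbeta(1, 8, 8)
  img <- clamp(round(lam * a$image + (1 - lam) * b$image))
  boxes <- rbind(a$boxes, b$boxes)
  boxes$id <- seq_len(nrow(boxes))
  .scene_like(a, img, boxes)
}

#' Copy one annotated instance from a donor scene into a scene
#'
#' The donor box region is copied to a uniformly drawn location; a new box is
#' appended.
#'
#' @param scene target \code{shred_scene}.
#' @param donor donor \code{shred_scene} (may be the target itself).
#' @return a \code{shred_scene} with one extra box (when the donor has any).
#' @export
paste_in_instance <- function(scene, donor) {
  if (nrow(donor$boxes) == 0) return(scene)
  d <- dim(scene$image); H <- d[1]; W <- d[2]
  b <- donor$boxes[sample(nrow(donor$boxes), 1), , drop = FALSE]
  src <- yolo_to_xyxy(b$cx, b$cy, b$w, b$h, ncol(donor$image[, , 1]),
                      nrow(donor$image[, , 1]))
  x0 <- max(1, round(src[1])); x1 <- min(dim(donor$image)[2], round(src[3]))
  y0 <- max(1, round(src[2])); y1 <- min(dim(donor$image)[1], round(src[4]))
  ph <- y1 - y0 + 1; pw <- x1 - x0 + 1
  if (ph >= H || pw >= W) return(scene)
  ty <- sample(H - ph, 1); tx <- sample(W - pw, 1)
  img <- scene$image
  img[ty + seq_len(ph) - 1, tx + seq_len(pw) - 1, ] <-
    donor$image[y0:y1, x0:x1, , drop = FALSE]
  nb <- b
  yl <- xyxy_to_yolo(tx - 1, ty - 1, tx - 1 + pw, ty - 1 + ph, W, H)
  nb$cx <- yl[1]; nb$cy <- yl[2]; nb$w <- yl[3]; nb$h <- yl[4]
  boxes <- rbind(scene$boxes, nb)
  boxes$id <- seq_len(nrow(boxes))
  .scene_like(scene, img, boxes)
}
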