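#' Two-dimensional size calculation for curved fragments (LWC)
#'
#' Given a detection box, the target fragment is cropped and isolated
#' (binarise, keep the contour whose centroid is nearest the box centre),
#' rotated so its minimum-area bounding rectangle is horizontal, and sliced
#' into n vertical strips. Length is the arc length of a smoothing spline
#' through the per-strip foreground centroids (plus the residual horizontal
#' end segments, so flat fragment tips count); width is the mean over strips
#' of the maximum-inscribed-circle diameter, obtained from the interior
#' Euclidean distance transform. Pixel measurements are converted to mm by a
#' calibration factor derived from a reference block of known physical size.
#'
#' @name lwc
NULL

#' Pixel calibration from a reference block
#'
#' \code{pixels_per_mm = block_pixel_length / block_mm_length}.
#'
#' @param block_pixel_length measured block length in px.
#' @param block_mm_length actual block length in mm.
#' @return a \code{calibration}: list(pixels_per_mm, block_px, block_mm).
#' @export
calibrate <- function(block_pixel_length, block_mm_length) {
  assert_that(is.numeric(block_pixel_length) && block_pixel_length > 0,
              "block_pixel_length must be positive")
  assert_that(is.numeric(block_mm_length) && block_mm_length > 0,
              "block_mm_length must be positive")
  structure(list(pixels_per_mm = block_pixel_length / block_mm_length,
                 block_px = block_pixel_length, block_mm = block_mm_length),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.4g px/mm (block %g px / %g mm)\n",
              x$pixels_per_mm, x$block_px, x$block_mm))
  invisible(x)
}

#' Measure the calibration block in a scene image
#'
#' Finds the saturated-blue block by colour, takes its minimum-area rectangle
#' and returns the long side in px.
#'
#' @param image RGB array 0-255.
#' @return block pixel length (long side).
#' @export
measure_block_px <- function(image) {
  bm <- image[, , 3] > 150 & image[, , 1] < 120 & image[, , 2] < 120
  assert_that(any(bm), "no calibration block found in the image")
  rect <- min_area_rect(bm)
  rect$long
}

# --- geometry helpers ------------------------------------------------------

# Minimum-area bounding rectangle of a binary mask via rotating calipers over
# the convex hull of foreground pixel corners. Returns long/short side (px)
# and the angle (deg, in matrix coords with y down) of the long side.
min_area_rect <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  assert_that(nrow(fg) > 1, "mask is degenerate (fewer than 2 pixels)")
  # use pixel corners so a 1-px-thin mask still has area
  pts <- rbind(cbind(fg[, 2] - 0.5, fg[, 1] - 0.5), cbind(fg[, 2] + 0.5, fg[, 1] - 0.5),
               cbind(fg[, 2] - 0.5, fg[, 1] + 0.5), cbind(fg[, 2] + 0.5, fg[, 1] + 0.5))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    a <- atan2(e[2], e[1])
    rot <- cbind(c(cos(-a), sin(-a)), c(-sin(-a), cos(-a)))
    q <- hull %*% t(rot)
    dx <- diff(range(q[, 1])); dy <- diff(range(q[, 2]))
    if (is.null(best) || dx * dy < best$area) {
      ang <- if (dx >= dy) a else a + pi / 2
      best <- list(area = dx * dy, long = max(dx, dy), short = min(dx, dy),
                   angle_deg = (ang * 180 / pi) %% 180)
    }
  }
  best
}

#' Crop a detection box and isolate the target fragment
#'
#' The crop is binarised against the background level estimated from the crop
#' border (median minus a noise-scaled margin; foreground = darker by
#' default). A global Otsu threshold is used as fallback when the border
#' estimate degenerates (e.g. the object covers most of the border). A plain
#' Otsu split is deliberately not the primary rule: crops of blended scenes
#' often contain fragments of two different shades, and the bimodal split
#' then lands between the two fragments rather than between fragments and
#' ground. Connected components are extracted and the component whose
#' centroid lies nearest the box centre is kept (ties broken toward the
#' larger area), eliminating fragments of neighbouring objects caught in the
#' box.
#'
#' @param image RGB array 0-255.
#' @param box one-row data.frame (cx, cy, w, h, YOLO-normalised) or numeric
#'   c(cx, cy, w, h).
#' @param invert set TRUE when fragments are brighter than the ground.
#' @param pad_px extra crop margin around the box (default 2).
#' @param fg_mask optional precomputed full-image foreground segmentation
#'   (e.g. from \code{\link{eliminate_shadow}}); when supplied it replaces the
#'   crop-level binarisation, and only component selection is performed here.
#' @return logical mask of the target object, in full-image coordinates
#'   cropped to the padded box (attribute \code{offset} = c(row0, col0)).
#' @export
crop_and_select <- function(image, box, invert = FALSE, pad_px = 2,
                            fg_mask = NULL) {
  if (is.data.frame(box)) box <- unlist(box[1, c("cx", "cy", "w", "h")])
  H <- dim(image)[1]; W <- dim(image)[2]
  xy <- yolo_to_xyxy(box[1], box[2], box[3], box[4], W, H)
  x0 <- max(1L, floor(xy[1]) - pad_px); x1 <- min(W, ceiling(xy[3]) + pad_px)
  y0 <- max(1L, floor(xy[2]) - pad_px); y1 <- min(H, ceiling(xy[4]) + pad_px)
  assert_that(x1 > x0 && y1 > y0, "box lies outside the image")
  g <- to_gray(image[y0:y1, x0:x1, , drop = FALSE])
  if (!is.null(fg_mask)) {
    assert_that(all(dim(fg_mask) == c(H, W)),
                "fg_mask must match the image dimensions")
    fgm <- fg_mask[y0:y1, x0:x1, drop = FALSE]
  } else {
    border <- c(g[1, ], g[nrow(g), ], g[, 1], g[, ncol(g)])
    med_b <- stats::median(border)
    margin <- max(8, 4 * stats::mad(border))
    thr <- if (invert) med_b + margin else med_b - margin
    fgm <- if (invert) g > thr else g < thr
    frac <- mean(fgm)
    if (frac > 0.9 || frac < 0.005) {      # border estimate degenerate
      thr <- EBImage::otsu(as_ebi(g / 255)) * 255
      fgm <- if (invert) g > thr else g < thr
    }
  }
  assert_that(any(fgm), "no object found in the crop")
  lab <- from_ebi(EBImage::bwlabel(as_ebi(fgm)))
  ncomp <- max(lab)
  ctr <- c((box[1] * W - x0 + 1), (box[2] * H - y0 + 1))   # (x, y) in crop coords
  stats <- lapply(seq_len(ncomp), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    list(k = k, n = nrow(idx),
         d = sqrt((mean(idx[, 2]) - ctr[1])^2 + (mean(idx[, 1]) - ctr[2])^2))
  })
  stats <- stats[vapply(stats, `[[`, 0, "n") >= 5]   # ignore speckle
  assert_that(length(stats) > 0, "no object found in the crop")
  d <- vapply(stats, `[[`, 0, "d"); n <- vapply(stats, `[[`, 0, "n")
  cand <- which(abs(d - min(d)) < 1e-9)
  pick <- stats[[cand[which.max(n[cand])]]]$k
  sel <- lab == pick
  # a soft shadow skirt absorbed into the component is markedly brighter than
  # the fragment body: when the component's intensity histogram is strongly
  # bimodal, keep only the dark phase (guarded so plain texture noise, which
  # is unimodal, is never split)
  if (!invert && sum(sel) >= 50) {
    vals <- g[sel]
    t2 <- EBImage::otsu(as_ebi(matrix(vals / 255, 1)), range = c(0, 1)) * 255
    lo <- vals[vals <= t2]; hi <- vals[vals > t2]
    if (length(lo) >= 0.45 * length(vals) && length(hi) > 0 &&
        mean(hi) - mean(lo) > 25) {
      ref <- sel & g <= t2
      lab2 <- from_ebi(EBImage::bwlabel(as_ebi(ref)))
      if (max(lab2) > 0) {
        sz <- tabulate(lab2)
        sel <- lab2 == which.max(sz)
      }
    }
  }
  # fill interior holes (texture noise crossing the threshold)
  out <- from_ebi(EBImage::fillHull(as_ebi(sel))) > 0
  attr(out, "offset") <- c(y0, x0)
  out
}

#' Rotate a mask so its minimum-area rectangle is horizontal
#'
#' @param mask logical matrix (one object).
#' @return a \code{rotated_crop}: list(mask, x1 = long side px, y1 = short
#'   side px, angle_deg = rotation applied). The coordinate frame is anchored
#'   at the rectangle (the returned mask is cropped to it).
#' @export
rotate_to_horizontal <- function(mask) {
  rect <- min_area_rect(mask)
  ang <- rect$angle_deg
  if (ang > 90) ang <- ang - 180          # smallest rotation to horizontal
  rot <- if (abs(ang) < 1e-9) mask else rotate_mask(mask, -ang)
  fg <- which(rot, arr.ind = TRUE)
  assert_that(nrow(fg) > 1, "rotation produced a degenerate mask")
  rot <- rot[min(fg[, 1]):max(fg[, 1]), min(fg[, 2]):max(fg[, 2]), drop = FALSE]
  check <- min_area_rect(rot)
  resid <- min(check$angle_deg %% 90, 90 - check$angle_deg %% 90)
  structure(list(mask = rot, x1 = ncol(rot), y1 = nrow(rot),
                 rect_long = check$long, rect_short = check$short,
                 angle_deg = -ang, residual_deg = resid),
            class = "rotated_crop")
}

#' Slice a rotated crop into n vertical strips
#'
#' Strips have width \code{delta_x = x1 / n}; strips narrower than 2 px are
#' rejected. Empty strips (no foreground) are flagged.
#'
#' @param rc a \code{rotated_crop}.
#' @param n number of strips (>= 2).
#' @return list of lists (mask, x_lo, x_hi, empty); the strip masks partition
#'   the foreground.
#' @export
slice_strips <- function(rc, n = 50) {
  assert_that(is_count(n) && n >= 2, "n must be an integer >= 2")
  dx <- rc$x1 / n
  assert_that(dx >= 2, "strips narrower than 2 px (n too large for this object)")
  edges <- round(seq(0, rc$x1, length.out = n + 1))
  lapply(seq_len(n), function(i) {
    cols <- (edges[i] + 1):edges[i + 1]
    sub <- rc$mask[, cols, drop = FALSE]
    list(mask = sub, x_lo = edges[i], x_hi = edges[i + 1], empty = !any(sub))
  })
}

# per-strip foreground centroids (x, y) in rotated-crop coordinates
strip_centroids <- function(rc, strips) {
  cent <- lapply(strips, function(s) {
    if (s$empty) return(NULL)
    fg <- which(s$mask, arr.ind = TRUE)
    c(x = s$x_lo + mean(fg[, 2]) - 0.5, y = mean(fg[, 1]) - 0.5)
  })
  do.call(rbind, cent)
}

# walk from (x0, y0) along unit direction (tx, ty) while inside the mask;
# returns the traversed distance, capped
walk_inside <- function(mask, x0, y0, tx, ty, cap) {
  step <- 0.25
  d <- 0
  H <- nrow(mask); W <- ncol(mask)
  while (d < cap) {
    d2 <- d + step
    xi <- round(x0 + tx * d2 + 0.5); yi <- round(y0 + ty * d2 + 0.5)
    if (xi < 1 || xi > W || yi < 1 || yi > H || !mask[yi, xi]) break
    d <- d2
  }
  d
}

#' Centerline length of a rotated fragment
#'
#' Fits a cubic smoothing spline y(x) through the ordered strip centroids and
#' integrates its arc length by dense chordal sampling. Centroids within half
#' a tube width of the horizontal extremes are excluded from the fit (there
#' the cross-section is cut by the fragment tip and the centroid no longer
#' tracks the medial axis); the fitted curve is then extended from each end
#' centroid along its tangent, walking inside the mask up to the tip face, so
#' the full tip-to-tip centerline counts. Below 4 usable centroids a polyline
#' with horizontal end residuals is used instead.
#'
#' @param rc a \code{rotated_crop}.
#' @param n strip count (default 50).
#' @param cal a \code{\link{calibrate}} result.
#' @return list(length_mm, fit = list(centroids, arc_length_px, m, n_used)).
#' @export
length_of <- function(rc, n = 50, cal) {
  assert_that(inherits(cal, "calibration"), "cal must be a calibration")
  strips <- slice_strips(rc, n)
  ce <- strip_centroids(rc, strips)
  assert_that(!is.null(ce) && nrow(ce) >= 2, "fewer than 2 non-empty strips")
  ord <- order(ce[, "x"])
  x <- ce[ord, "x"]; y <- ce[ord, "y"]
  di <- strip_diameters(rc, strips)
  trim <- 0.5 * stats::median(di, na.rm = TRUE)
  fg_cols <- range(which(colSums(rc$mask) > 0))
  keep <- x >= (fg_cols[1] - 1) + trim & x <= fg_cols[2] - trim
  if (sum(keep) >= 4) {
    xi <- x[keep]; yi <- y[keep]
    fit <- stats::smooth.spline(xi, yi, df = max(4, min(length(xi) - 1,
                                                        round(length(xi) * 0.6))))
    xs <- seq(min(xi), max(xi), length.out = 1000)
    ys <- stats::predict(fit, xs)$y
    arc <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
    cap <- 3 * trim + 3
    for (end in c(1, length(xs))) {
      sl <- stats::predict(fit, xs[end], deriv = 1)$y
      sgn <- if (end == 1) -1 else 1
      nrm <- sqrt(1 + sl^2)
      arc <- arc + walk_inside(rc$mask, xs[end], ys[end],
                               sgn / nrm, sgn * sl / nrm, cap)
    }
  } else {
    arc <- sum(sqrt(diff(x)^2 + diff(y)^2))
    arc <- arc + max(0, min(x) - (fg_cols[1] - 1)) + max(0, fg_cols[2] - max(x))
  }
  list(length_mm = arc / cal$pixels_per_mm,
       fit = list(centroids = ce[ord, , drop = FALSE], arc_length_px = arc,
                  m = length(strips), n_used = nrow(ce)))
}

# largest inscribed-circle diameter per strip from the interior distance
# transform of the full mask (centre restricted to the strip)
strip_diameters <- function(rc, strips) {
  # pad with a background border so the crop edge bounds the object
  padded <- matrix(FALSE, rc$y1 + 2L, rc$x1 + 2L)
  padded[1L + seq_len(rc$y1), 1L + seq_len(rc$x1)] <- rc$mask
  dist <- from_ebi(EBImage::distmap(as_ebi(padded * 1)))[1L + seq_len(rc$y1),
                                                         1L + seq_len(rc$x1)]
  vapply(strips, function(s) {
    if (s$empty) return(NA_real_)
    cols <- (s$x_lo + 1):s$x_hi
    dmax <- max(dist[, cols])
    if (dmax <= 0) NA_real_ else 2 * dmax - 1
  }, 0)
}

#' Mean maximum-inscribed-circle width of a rotated fragment
#'
#' Per strip, the largest circle centred in the strip and contained in the
#' object has radius equal to the maximum of the interior distance transform
#' there; the width is the mean diameter over non-empty strips, converted
#' to mm.
#'
#' @inheritParams length_of
#' @return list(width_mm, profile = list(diameters_px, mean_diameter_px)).
#' @export
width_of <- function(rc, n = 50, cal) {
  assert_that(inherits(cal, "calibration"), "cal must be a calibration")
  strips <- slice_strips(rc, n)
  di <- strip_diameters(rc, strips)
  ok <- !is.na(di)
  assert_that(sum(ok) >= 2, "fewer than 2 non-empty strips")
  list(width_mm = mean(di[ok]) / cal$pixels_per_mm,
       profile = list(diameters_px = di, mean_diameter_px = mean(di[ok])))
}

#' Measure every detected object in a scene
#'
#' Runs crop -> contour selection -> rotation -> length/width for each box.
#' Per-object failures are recorded (NA measurements) and the pipeline
#' continues. When truths are supplied, signed relative errors
#' \code{100 * (measured - actual) / actual} are reported per object.
#'
#' @param image RGB array 0-255.
#' @param boxes data.frame (id, class or label, cx, cy, w, h).
#' @param cal a \code{\link{calibrate}} result.
#' @param n strip count.
#' @param truths optional data.frame (id, length_mm, width_mm).
#' @param invert,fg_mask passed to \code{\link{crop_and_select}}.
#' @return a \code{size_report} data.frame: id, label, length_mm, width_mm
#'   and, with truths, rel_err_len_pct, rel_err_wid_pct.
#' @export
measure_scene <- function(image, boxes, cal, n = 50, truths = NULL,
                          invert = FALSE, fg_mask = NULL) {
  assert_that(inherits(cal, "calibration"), "cal must be a calibration")
  if (is.null(boxes) || nrow(boxes) == 0) {
    out <- data.frame(id = integer(), label = character(),
                      length_mm = numeric(), width_mm = numeric())
    return(structure(out, class = c("size_report", "data.frame")))
  }
  rows <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, , drop = FALSE]
    lab <- if ("label" %in% names(b)) b$label else shred_classes[b$class + 1]
    id <- if ("id" %in% names(b)) b$id else i
    res <- tryCatch({
      mask <- crop_and_select(image, b, invert = invert, fg_mask = fg_mask)
      rc <- rotate_to_horizontal(mask)
      n_i <- n
      while (rc$x1 / n_i < 2 && n_i > 2) n_i <- max(2, floor(rc$x1 / 2))
      len <- length_of(rc, n_i, cal)
      wid <- width_of(rc, n_i, cal)
      data.frame(id = id, label = lab, length_mm = len$length_mm,
                 width_mm = wid$width_mm, error = NA_character_)
    }, error = function(e) {
      warning(sprintf("object %s: %s", id, conditionMessage(e)), call. = FALSE)
      data.frame(id = id, label = lab, length_mm = NA_real_,
                 width_mm = NA_real_, error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(truths)) {
    out$error <- NULL
  } else {
    k <- match(out$id, truths$id)
    out$actual_length_mm <- truths$length_mm[k]
    out$actual_width_mm <- truths$width_mm[k]
    out$rel_err_len_pct <- 100 * (out$length_mm - out$actual_length_mm) / out$actual_length_mm
    out$rel_err_wid_pct <- 100 * (out$width_mm - out$actual_width_mm) / out$actual_width_mm
    out$error <- NULL
  }
  structure(out, class = c("size_report", "data.frame"))
}

#' Aggregate a size report per class and in total
#'
#' Mirrors the usual reporting layout: one Total-<class> row per class and a
#' final Total row. Aggregate relative errors compare summed measured lengths
#' against summed actual lengths (and length-weighted means for width), the
#' convention for multi-part manual truths.
#'
#' @param report a \code{size_report} with truth columns.
#' @return data.frame(group, n, rel_err_len_pct, rel_err_wid_pct).
#' @export
aggregate_report <- function(report) {
  assert_that("rel_err_len_pct" %in% names(report),
              "report must carry ground truth to aggregate errors")
  ok <- !is.na(report$length_mm)
  r <- report[ok, , drop = FALSE]
  agg_of <- function(d) {
    len_err <- 100 * (sum(d$length_mm) - sum(d$actual_length_mm)) / sum(d$actual_length_mm)
    wt <- d$actual_length_mm
    wid_meas <- sum(d$width_mm * wt) / sum(wt)
    wid_act <- sum(d$actual_width_mm * wt) / sum(wt)
    c(len = len_err, wid = 100 * (wid_meas - wid_act) / wid_act)
  }
  labs <- intersect(shred_classes, unique(r$label))
  rows <- lapply(labs, function(lb) {
    d <- r[r$label == lb, , drop = FALSE]
    e <- agg_of(d)
    data.frame(group = paste0("Total-", lb), n = nrow(d),
               rel_err_len_pct = e["len"], rel_err_wid_pct = e["wid"])
  })
  e <- agg_of(r)
  rows[[length(rows) + 1]] <- data.frame(group = "Total", n = nrow(r),
                                         rel_err_len_pct = e["len"],
                                         rel_err_wid_pct = e["wid"])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.size_report <- function(x, ...) {
  cat(sprintf("size report: %d object(s), %d measured\n",
              nrow(x), sum(!is.na(x$length_mm))))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.size_report <- function(object, ...) {
  if ("rel_err_len_pct" %in% names(object)) aggregate_report(object)
  else print.data.frame(object)
}
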