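#' Synthetic blended-shred scenes with exact ground truth
#'
#' The generator renders curved "ribbon" fragments (constant-width tubes swept
#' along a straight segment or circular arc) of the four shred classes
#' Y (tobacco silk), G (cut stem), P (expanded tobacco silk) and
#' Z (reconstituted sheet) on a light background, optionally with pairwise
#' overlap, soft shadows and a rectangular calibration block of known physical
#' size. Every scene carries exact per-object ground truth (centerline length
#' and tube width in mm) and YOLO-style bounding-box annotations, so the
#' measurement and evaluation code can be validated end to end without any
#' photographic data.
#'
#' @name synthgen
NULL

# Run expr with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  assert_that(is_count(seed + 1), "seed must be a non-negative integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Specify one synthetic ribbon fragment
#'
#' @param class_label one of "Y", "G", "P", "Z".
#' @param length_mm centerline (medial-axis) length in mm; must exceed the width.
#' @param width_mm constant tube width in mm.
#' @param curvature signed curvature in 1/mm (0 = straight); may be a vector,
#'   in which case the centerline is a chain of equal-length circular arcs
#'   (an S-shaped, multi-bend fragment).
#' @param center pixel coordinates c(x, y) of the centerline midpoint.
#' @param rotation initial heading in degrees.
#' @param ppmm image scale in pixels per mm.
#' @return a \code{ribbon_spec} list.
#' @export
ribbon_spec <- function(class_label, length_mm, width_mm, curvature = 0,
                        center = c(0, 0), rotation = 0, ppmm = 10) {
  assert_that(class_label %in% shred_classes, "class_label must be Y, G, P or Z")
  assert_that(is.numeric(length_mm) && length_mm > 0, "length_mm must be positive")
  assert_that(is.numeric(width_mm) && width_mm > 0, "width_mm must be positive")
  assert_that(length_mm > width_mm, "length_mm must exceed width_mm")
  assert_that(is.numeric(ppmm) && ppmm > 0, "ppmm must be positive")
  structure(list(class_label = class_label, length_mm = length_mm,
                 width_mm = width_mm, curvature = curvature,
                 center = center, rotation = rotation, ppmm = ppmm),
            class = "ribbon_spec")
}

# Sample the centerline at arc-length steps ds (px). Piecewise-constant
# curvature integrated with the midpoint rule; returns an (n x 2) matrix of
# (x, y) pixel coordinates, recentred so the mid-arc point sits at `center`.
ribbon_centerline <- function(spec, ds = 0.25) {
  L <- spec$length_mm * spec$ppmm
  kappa <- spec$curvature / spec$ppmm          # 1/px
  n <- max(2L, ceiling(L / ds) + 1L)
  s <- seq(0, L, length.out = n)
  seg <- pmin(floor(s / L * length(kappa)) + 1L, length(kappa))
  k_at <- kappa[seg]
  dsv <- diff(s)
  th0 <- spec$rotation * pi / 180
  # heading at midpoints of each step
  th <- th0 + cumsum(c(0, k_at[-n] * dsv))
  thm <- th[-n] + k_at[-n] * dsv / 2
  x <- cumsum(c(0, cos(thm) * dsv))
  y <- cumsum(c(0, sin(thm) * dsv))
  mid <- c(x[ceiling(n / 2)], y[ceiling(n / 2)])
  cbind(x = x - mid[1] + spec$center[1], y = y - mid[2] + spec$center[2])
}

#' Render one ribbon as a binary mask
#'
#' The tube has flat (butt) ends, so its tip-to-tip extent along the
#' centerline equals \code{length_mm} exactly and its local thickness equals
#' \code{width_mm} everywhere; the recorded ground truth is therefore the
#' actual medial-axis length of the rendered mask.
#'
#' @param spec a \code{\link{ribbon_spec}}.
#' @param canvas c(height, width) of the target canvas in px.
#' @param seed integer seed (the mask is fully determined by the geometry;
#'   the seed is accepted for interface symmetry and reserved for future
#'   stochastic texture).
#' @return list with \code{mask} (logical matrix), \code{length_mm},
#'   \code{width_mm}, \code{class_label}.
#' @export
generate_ribbon <- function(spec, canvas = c(1280, 1280), seed = 0) {
  assert_that(inherits(spec, "ribbon_spec"), "spec must be a ribbon_spec")
  cl <- ribbon_centerline(spec)
  r <- spec$width_mm * spec$ppmm / 2
  # stamp points on a dense grid across the tube: centerline sample x normal offset
  th <- atan2(c(diff(cl[, 2]), NA), c(diff(cl[, 1]), NA))
  th[length(th)] <- th[length(th) - 1]
  offs <- seq(-r, r, by = 0.35)
  if (length(offs) < 2) offs <- c(-r, 0, r)
  xs <- rep(cl[, 1], times = length(offs)) +
        rep(-sin(th), times = length(offs)) * rep(offs, each = nrow(cl))
  ys <- rep(cl[, 2], times = length(offs)) +
        rep(cos(th), times = length(offs)) * rep(offs, each = nrow(cl))
  xi <- round(xs); yi <- round(ys)
  if (any(xi < 1 | xi > canvas[2] | yi < 1 | yi > canvas[1])) {
    stopf("ribbon exceeds the %d x %d canvas", canvas[1], canvas[2])
  }
  mask <- matrix(FALSE, canvas[1], canvas[2])
  mask[cbind(yi, xi)] <- TRUE
  # close pinholes left by stamping quantisation
  mask <- EBImage::fillHull(mask) > 0
  list(mask = mask, length_mm = spec$length_mm, width_mm = spec$width_mm,
       class_label = spec$class_label)
}

# Per-class base colour (RGB, 0-255) and texture noise sd. Chosen to be
# class-separable and darker than the light background, not photorealistic:
# Y yellow-brown silk, G pale woody stem, P light expanded silk, Z dark
# uniform reconstituted sheet.
.class_appearance <- list(
  Y = list(col = c(158, 112, 44),  noise = 10),
  G = list(col = c(190, 175, 120), noise = 9),
  P = list(col = c(205, 170, 130), noise = 8),
  Z = list(col = c(120, 92, 60),   noise = 2)
)

.block_color <- c(40, 60, 200)   # saturated blue calibration block
.bg_level <- 228                 # light ground

#' Generate a complete synthetic scene
#'
#' @param n_per_class named list/vector, e.g. \code{c(Y = 2, G = 1)}: ribbons
#'   per class.
#' @param overlap_fraction probability, per ribbon after the first, of being
#'   placed so that it overlaps an already-placed ribbon (the overlapped
#'   objects keep separate boxes, mirroring multi-label annotation).
#' @param with_block render a rectangular calibration block of
#'   \code{block_mm} (short, long) mm size and record its pixel length.
#' @param shadow_strength 0 disables shadows; 1 = strong soft shadows
#'   (low-frequency multiplicative gradient plus a penumbra under each ribbon).
#' @param seed integer seed; scenes are byte-identical for equal seeds.
#' @param canvas c(height, width) px.
#' @param ppmm pixels per mm.
#' @param block_mm calibration block physical size (short, long) in mm.
#' @param length_range,width_range,curvature_range sampling ranges for ribbon
#'   geometry (mm, mm, 1/mm).
#' @return a \code{shred_scene}: list with \code{image} (H x W x 3, 0-255),
#'   \code{boxes} (data.frame id, class, label, cx, cy, w, h), \code{truths}
#'   (data.frame id, label, length_mm, width_mm), \code{fg_mask} (logical
#'   ground-truth foreground), \code{block_px_length}, \code{ppmm}.
#' @export
generate_scene <- function(n_per_class, overlap_fraction = 0,
                           with_block = FALSE, shadow_strength = 0, seed = 1,
                           canvas = c(1280, 1280), ppmm = 10,
                           block_mm = c(3, 9),
                           length_range = c(8, 25), width_range = c(1, 2.8),
                           curvature_range = c(-0.06, 0.06)) {
  assert_that(overlap_fraction >= 0 && overlap_fraction <= 1,
              "overlap_fraction must lie in [0, 1]")
  labels <- rep(names(n_per_class), times = unlist(n_per_class))
  assert_that(length(labels) > 0 && all(labels %in% shred_classes),
              "n_per_class must be a named count vector over Y, G, P, Z")
  with_seed(seed, {
    H <- canvas[1]; W <- canvas[2]
    occupied <- matrix(FALSE, H, W)
    masks <- list(); specs <- list()
    margin <- 0.18 * min(H, W)
    for (i in seq_along(labels)) {
      placed <- FALSE
      want_overlap <- i > 1 && stats::runif(1) < overlap_fraction
      for (try in seq_len(60)) {
        len <- runif1(length_range[1], length_range[2])
        wid <- runif1(width_range[1], min(width_range[2], len / 3))
        cur <- runif1(curvature_range[1], curvature_range[2])
        # keep total turning below ~150 deg so the fragment stays measurable
        if (abs(cur) * len > 2.6) cur <- sign(cur) * 2.6 / len
        if (want_overlap && length(masks) > 0) {
          anchor <- specs[[sample(length(masks), 1)]]$center
          ctr <- anchor + stats::runif(2, -0.25, 0.25) * len * ppmm
        } else {
          ctr <- c(runif1(margin, W - margin), runif1(margin, H - margin))
        }
        sp <- ribbon_spec(labels[i], len, wid, cur, center = ctr,
                          rotation = runif1(0, 360), ppmm = ppmm)
        rb <- tryCatch(generate_ribbon(sp, canvas = canvas),
                       error = function(e) NULL)
        if (is.null(rb)) next
        hit <- any(rb$mask & occupied)
        if (hit != want_overlap && try < 50) next
        occupied <- occupied | rb$mask
        masks[[i]] <- rb; specs[[i]] <- sp
        placed <- TRUE
        break
      }
      if (!placed) stopf("could not place ribbon %d after bounded retries", i)
    }

    # calibration block
    block_px_length <- NULL; block_mask <- NULL
    if (with_block) {
      bw <- round(block_mm[1] * ppmm); bl <- round(block_mm[2] * ppmm)
      for (try in seq_len(60)) {
        x0 <- round(runif1(10, W - bl - 10)); y0 <- round(runif1(10, H - bw - 10))
        sel <- matrix(FALSE, H, W); sel[y0:(y0 + bw - 1), x0:(x0 + bl - 1)] <- TRUE
        if (!any(sel & occupied)) { block_mask <- sel; break }
      }
      assert_that(!is.null(block_mask), "could not place the calibration block")
      block_px_length <- bl
      occupied <- occupied | block_mask
    }

    # compose image
    img <- array(0, dim = c(H, W, 3))
    bg <- matrix(.bg_level, H, W) + matrix(stats::rnorm(H * W, 0, 2), H, W)
    for (ch in 1:3) img[, , ch] <- bg
    # object-cast penumbrae darken the background only; the global
    # illumination gradient (applied after painting, below) shades everything
    illum <- matrix(1, H, W)
    if (shadow_strength > 0) {
      gx <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
      gy <- matrix(seq(0, 1, length.out = H), H, W)
      a <- stats::runif(2, -1, 1)
      illum <- 1 - shadow_strength * 0.18 * (0.5 + 0.5 * sin(2 * pi * (a[1] * gx + a[2] * gy)))
      off <- round(0.6 * ppmm)
      pen_total <- matrix(1, H, W)
      for (rb in masks) {
        sh <- matrix(FALSE, H, W)
        src <- rb$mask
        sh[(1 + off):H, (1 + off):W] <- src[1:(H - off), 1:(W - off)]
        pen <- box_mean(sh * 1, 2 * round(0.45 * ppmm) + 1)
        pen_total <- pen_total * (1 - 0.5 * shadow_strength * pen)
      }
      for (ch in 1:3) img[, , ch] <- img[, , ch] * pen_total
    }
    # paint ribbons (later ones on top, matching the overlap convention)
    for (i in seq_along(masks)) {
      ap <- .class_appearance[[labels[i]]]
      idx <- which(masks[[i]]$mask)
      tex <- stats::rnorm(length(idx), 0, ap$noise)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- ap$col[ch] + tex
        img[, , ch] <- plane
      }
    }
    if (!is.null(block_mask)) {
      idx <- which(block_mask)
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[idx] <- .block_color[ch]; img[, , ch] <- plane
      }
    }
    for (ch in 1:3) img[, , ch] <- img[, , ch] * illum
    img <- clamp(round(img))

    # annotations: tight bbox of each ribbon mask, YOLO-normalised
    boxes <- do.call(rbind, lapply(seq_along(masks), function(i) {
      fg <- which(masks[[i]]$mask, arr.ind = TRUE)
      x0 <- min(fg[, 2]) - 1; x1 <- max(fg[, 2])
      y0 <- min(fg[, 1]) - 1; y1 <- max(fg[, 1])
      yl <- xyxy_to_yolo(x0, y0, x1, y1, W, H)
      data.frame(id = i, class = class_index(labels[i]), label = labels[i],
                 cx = yl[1], cy = yl[2], w = yl[3], h = yl[4])
    }))
    truths <- data.frame(id = seq_along(masks), label = labels,
                         length_mm = vapply(masks, `[[`, 0, "length_mm"),
                         width_mm = vapply(masks, `[[`, 0, "width_mm"))
    fg <- Reduce(`|`, lapply(masks, `[[`, "mask"))
    structure(list(image = img, boxes = boxes, truths = truths,
                   fg_mask = fg, block_px_length = block_px_length,
                   block_mm = if (with_block) block_mm else NULL,
                   ppmm = ppmm, seed = seed),
              class = "shred_scene")
  })
}

#' @export
print.shred_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("synthetic shred scene: %d x %d px, %d object(s) [%s]%s\n",
              d[1], d[2], nrow(x$boxes), paste(x$boxes$label, collapse = ","),
              if (!is.null(x$block_px_length))
                sprintf(", calibration block %g px", x$block_px_length) else ""))
  invisible(x)
}

#' Build a dataset manifest and its train/test split
#'
#' Records are split per label at \code{ratio} (train:test); the test count is
#' \code{floor(n * test / (train + test))} and the remainder goes to train, so
#' divisible inputs split exactly (e.g. 4 x 1000 at 7:3 gives 2800/1200 and
#' 4 x 1700 gives 4760/2040). The shuffle is deterministic for a fixed seed.
#'
#' @param counts_by_label named vector of record counts per label.
#' @param ratio length-2 numeric (train, test), both non-negative, sum > 0.
#' @param seed integer seed for the per-label shuffle.
#' @return data.frame with columns record_id, label, split ("train"/"test").
#' @export
build_manifest <- function(counts_by_label, ratio = c(7, 3), seed = 1) {
  assert_that(length(ratio) == 2 && all(ratio >= 0) && sum(ratio) > 0,
              "ratio must be two non-negative numbers with a positive sum")
  counts <- unlist(counts_by_label)
  assert_that(length(counts) > 0 && all(counts >= 1) &&
                all(counts == round(counts)), "counts must be positive integers")
  assert_that(!is.null(names(counts)) && all(nzchar(names(counts))),
              "counts_by_label must be named")
  with_seed(seed, {
    out <- lapply(names(counts), function(lb) {
      n <- counts[[lb]]
      ids <- sprintf("%s_%05d", lb, seq_len(n))
      n_test <- floor(n * ratio[2] / sum(ratio))
      split <- rep("train", n)
      split[sample.int(n, n_test)] <- "test"
      data.frame(record_id = ids, label = lb, split = split)
    })
    do.call(rbind, out)
  })
}

#' Reference acquisition design for blended-shred image sets
#'
#' The image-set composition the generator emulates: the four pure classes,
#' the six pairwise blends and the four-way blend, with the usual acquisition
#' quantities (1000 per pure class, 200 per pairwise blend, 100 four-way;
#' 5300 images in total). \code{blended} marks records that contain more than
#' one class.
#'
#' @return data.frame(source, classes, quantity, blended).
#' @export
shred_image_composition <- function() {
  pure <- data.frame(source = paste("pure", shred_classes),
                     classes = shred_classes, quantity = 1000, blended = FALSE)
  pairs <- utils::combn(shred_classes, 2)
  two <- data.frame(source = paste0("blend ", pairs[1, ], "-", pairs[2, ]),
                    classes = paste(pairs[1, ], pairs[2, ], sep = "+"),
                    quantity = 200, blended = TRUE)
  four <- data.frame(source = "blend Y-G-P-Z",
                     classes = paste(shred_classes, collapse = "+"),
                     quantity = 100, blended = TRUE)
  rbind(pure, two, four)
}

#' Write a scene to disk as PNG + YOLO labels + ground-truth CSV
#'
#' @param scene a \code{shred_scene}.
#' @param dir output directory (created if missing).
#' @param stem file stem; writes \code{stem.png}, \code{stem.txt},
#'   \code{stem_truth.csv} and, when a block is present,
#'   \code{stem_block.csv} with its pixel and mm length.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  png::writePNG(scene$image / 255, img_path)
  lab_path <- file.path(dir, paste0(stem, ".txt"))
  write_yolo_labels(scene$boxes, lab_path)
  tr_path <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(scene$truths, tr_path, row.names = FALSE)
  paths <- c(img_path, lab_path, tr_path)
  if (!is.null(scene$block_px_length)) {
    bp <- file.path(dir, paste0(stem, "_block.csv"))
    utils::write.csv(data.frame(block_px_length = scene$block_px_length,
                                block_mm_length = scene$block_mm[2]),
                     bp, row.names = FALSE)
    paths <- c(paths, bp)
  }
  invisible(paths)
}

#' Read an RGB image (PNG/JPEG written by this package) as 0-255 array
#' @param path PNG file path.
#' @return H x W x 3 array in [0, 255].
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  round(px[, , 1:3] * 255)
}
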