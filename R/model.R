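#' Single-stage detection-network components
#'
#' Pure-R reference implementations of the network pieces used for blended
#' fragment detection: CBS convolution units (conv + SiLU), a residual
#' multi-branch backbone block ("Re-I" block: ELAN-style parallel taps fused
#' with a residual skip), a four-stage backbone compressed to 1:2:2:1 blocks
#' with pyramid taps at strides 8/16/32, a serial spatial-pyramid pooling
#' block (SPPFCSPC: three chained 5 x 5 max-pools replacing parallel
#' 5/9/13 pools with an identical receptive field), a decoupled detection
#' head (shared 1 x 1 reduction, then disjoint classification and
#' localisation/objectness branches), and the complete-IoU training
#' objective. Components are constructible and forward-passable on the CPU;
#' \code{\link{smoke_train}} exercises the CIoU + objectness + classification
#' loss end to end at desk scale. Feature maps are arrays [C, H, W].
#'
#' @name model
NULL

silu <- function(x) x / (1 + exp(-x))
sigmoid <- function(x) 1 / (1 + exp(-x))

# --- conv primitive --------------------------------------------------------

new_conv <- function(cin, cout, k = 1, stride = 1, act = TRUE,
                     init = c("he", "zero")) {
  init <- match.arg(init)
  nw <- cout * cin * k * k
  W <- if (init == "zero") matrix(0, cout, cin * k * k)
       else matrix(stats::rnorm(nw, 0, sqrt(2 / (cin * k * k))), cout, cin * k * k)
  list(type = "conv", W = W, b = numeric(cout), cin = cin, cout = cout,
       k = k, stride = stride, pad = (k - 1L) %/% 2L, act = act)
}

# im2col: [C, H, W] -> [C*k*k, Ho*Wo], offset-major rows to match new_conv's W
im2col <- function(x, k, stride, pad) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  if (pad > 0) {
    xp <- array(0, c(C, H + 2 * pad, W + 2 * pad))
    xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  } else xp <- x
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  ri <- seq(1L, by = stride, length.out = Ho)
  ci <- seq(1L, by = stride, length.out = Wo)
  out <- matrix(0, C * k * k, Ho * Wo)
  o <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    sl <- xp[, ri + di, ci + dj, drop = FALSE]
    out[o + seq_len(C), ] <- matrix(sl, C, Ho * Wo)
    o <- o + C
  }
  attr(out, "hw") <- c(Ho, Wo)
  out
}

conv_fwd <- function(l, x) {
  cols <- im2col(x, l$k, l$stride, l$pad)
  hw <- attr(cols, "hw")
  y <- l$W %*% cols + l$b
  if (l$act) y <- silu(y)
  array(y, c(l$cout, hw[1], hw[2]))
}

# same-size max pooling, window k, windows clamped at the borders
maxpool_same <- function(x, k) {
  d <- dim(x)
  out <- x
  for (c in seq_len(d[1])) out[c, , ] <- max_filter(matrix(x[c, , ], d[2], d[3]), k)
  out
}

# 2 x 2 / stride 2 downsampling max pool
maxpool2 <- function(x) {
  d <- dim(x)
  H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
  ri <- seq(1L, by = 2L, length.out = H2); ci <- seq(1L, by = 2L, length.out = W2)
  pmax(x[, ri, ci, drop = FALSE], x[, ri + 1L, ci, drop = FALSE],
       x[, ri, ci + 1L, drop = FALSE], x[, ri + 1L, ci + 1L, drop = FALSE])
}

concat_c <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  stopifnot(all(vapply(xs, function(z) all(dim(z)[2:3] == d[2:3]), TRUE)))
  array(do.call(rbind, lapply(xs, function(z) matrix(z, dim(z)[1], d[2] * d[3]))),
        c(sum(vapply(xs, function(z) dim(z)[1], 1L)), d[2], d[3]))
}

#' Count the parameters of a network component
#'
#' Sums, over every convolution the component declares, the weight and bias
#' element counts.
#'
#' @param component any component built by the \code{build_*} constructors.
#' @return integer parameter count.
#' @export
n_params <- function(component) {
  if (is.list(component)) {
    if (identical(component$type, "conv")) {
      return(length(component$W) + length(component$b))
    }
    return(sum(vapply(component, n_params, 0)))
  }
  0
}

# recursively zero every conv weight (for tests of raw-output structure)
zero_params <- function(component) {
  if (is.list(component)) {
    if (identical(component$type, "conv")) {
      component$W[] <- 0; component$b[] <- 0
      return(component)
    }
    for (i in seq_along(component)) {
      if (is.list(component[[i]])) component[[i]] <- zero_params(component[[i]])
    }
  }
  component
}

#' Forward-pass a built component
#'
#' @param component a component built by one of the \code{build_*} functions.
#' @param x input feature array [C, H, W] (for the backbone: [3, H, W]).
#' @return the component's output (array, or named list for the backbone).
#' @export
forward <- function(component, x) {
  assert_that(is.list(component) && !is.null(component$fwd),
              "not a forward-passable component")
  component$fwd(component, x)
}

# --- Re-I block ------------------------------------------------------------

#' Build a residual multi-branch backbone block
#'
#' Internals: a 1 x 1 reduction to \code{channels_out / 2}, two stacked
#' 3 x 3 convolutions tapped individually, a 1 x 1 input projection, ELAN-style
#' concatenation of all four, a 1 x 1 fusion to \code{channels_out}, plus an
#' identity skip (1 x 1-projected when the channel counts differ): the minimal
#' structure combining multi-scale parallel convolution with residual feature
#' reuse.
#'
#' @param channels_in,channels_out positive channel counts.
#' @return a forward-passable component.
#' @export
build_re_i_block <- function(channels_in, channels_out) {
  assert_that(is_count(channels_in) && is_count(channels_out),
              "channel counts must be positive integers")
  ch <- max(1L, channels_out %/% 2L)
  comp <- list(
    type = "re_i_block",
    red  = new_conv(channels_in, ch, 1),
    t1   = new_conv(ch, ch, 3),
    t2   = new_conv(ch, ch, 3),
    proj = new_conv(channels_in, ch, 1),
    fuse = new_conv(4L * ch, channels_out, 1),
    skip = if (channels_in == channels_out) NULL
           else new_conv(channels_in, channels_out, 1, act = FALSE),
    use_skip = TRUE,
    fwd = function(self, x) {
      r <- conv_fwd(self$red, x)
      a <- conv_fwd(self$t1, r)
      b <- conv_fwd(self$t2, a)
      p <- conv_fwd(self$proj, x)
      y <- conv_fwd(self$fuse, concat_c(p, r, a, b))
      if (self$use_skip) {
        s <- if (is.null(self$skip)) x else conv_fwd(self$skip, x)
        y <- y + s
      }
      y
    })
  comp
}

#' Backbone configuration
#'
#' @param block_counts blocks per stage (default 1, 2, 2, 1 — the compressed
#'   variant of the usual 3, 4, 6, 3 residual layout).
#' @param stage_channels channels per stage (default 64, 128, 256, 512).
#' @param in_channels input channels (3 for RGB).
#' @return a \code{backbone_config} list.
#' @export
backbone_config <- function(block_counts = c(1, 2, 2, 1),
                            stage_channels = c(64, 128, 256, 512),
                            in_channels = 3) {
  assert_that(length(block_counts) == 4 && all(block_counts >= 1) &&
                all(block_counts == round(block_counts)),
              "block_counts must be 4 positive integers")
  assert_that(length(stage_channels) == 4 && all(stage_channels >= 2),
              "stage_channels must be 4 channel counts")
  structure(list(block_counts = as.integer(block_counts),
                 stage_channels = as.integer(stage_channels),
                 in_channels = as.integer(in_channels)),
            class = "backbone_config")
}

#' Build the four-stage backbone with pyramid taps
#'
#' Stages enter with a stride-2 CBS and stack \code{block_counts[i]} Re-I
#' blocks. Taps: stage 1 reaches the stride-8 P3 level via CBS plus a
#' downsampling max-pool, stage 2 via CBS; stage 3 supplies P4 (stride 16)
#' via CBS; stage 4 feeds the neck's SPPFCSPC, whose output is P5
#' (stride 32). Input spatial size must be divisible by 32.
#'
#' @param cfg a \code{\link{backbone_config}}.
#' @param seed integer seed for weight initialisation (builds are
#'   reproducible: same cfg and seed give identical parameters).
#' @return a forward-passable component; \code{forward()} returns
#'   list(P3, P4, P5).
#' @export
build_backbone <- function(cfg = backbone_config(), seed = 1) {
  assert_that(inherits(cfg, "backbone_config"), "cfg must be a backbone_config")
  with_seed(seed, {
    ch <- cfg$stage_channels
    stem <- new_conv(cfg$in_channels, 32, 3, stride = 2)
    stage <- list(); cin <- 32L
    for (i in 1:4) {
      entry <- new_conv(cin, ch[i], 3, stride = 2)
      blocks <- lapply(seq_len(cfg$block_counts[i]), function(j)
        build_re_i_block(ch[i], ch[i]))
      stage[[i]] <- list(entry = entry, blocks = blocks)
      cin <- ch[i]
    }
    p3c <- ch[2]
    tap1 <- new_conv(ch[1], p3c %/% 2L, 1)       # + MP to stride 8
    tap2 <- new_conv(ch[2], p3c %/% 2L, 1)
    p3_fuse <- new_conv(p3c, p3c, 1)
    p4_tap <- new_conv(ch[3], ch[3], 1)
    sppf <- build_sppfcspc(ch[4], seed = seed + 1)
    comp <- list(type = "backbone", cfg = cfg, stem = stem, stage = stage,
                 tap1 = tap1, tap2 = tap2, p3_fuse = p3_fuse, p4_tap = p4_tap,
                 sppf = sppf,
                 out_channels = c(P3 = p3c, P4 = ch[3], P5 = ch[4]),
                 fwd = function(self, x) {
                   d <- dim(x)
                   assert_that(d[2] %% 32 == 0 && d[3] %% 32 == 0,
                               "input spatial size must be divisible by 32")
                   h <- conv_fwd(self$stem, x)
                   feats <- vector("list", 4)
                   for (i in 1:4) {
                     h <- conv_fwd(self$stage[[i]]$entry, h)
                     for (bl in self$stage[[i]]$blocks) h <- bl$fwd(bl, h)
                     feats[[i]] <- h
                   }
                   t1 <- maxpool2(conv_fwd(self$tap1, feats[[1]]))
                   t2 <- conv_fwd(self$tap2, feats[[2]])
                   P3 <- conv_fwd(self$p3_fuse, concat_c(t1, t2))
                   P4 <- conv_fwd(self$p4_tap, feats[[3]])
                   P5 <- forward(self$sppf, feats[[4]])
                   list(P3 = P3, P4 = P4, P5 = P5)
                 })
    comp
  })
}

#' Build the serial spatial-pyramid pooling block (SPPFCSPC)
#'
#' Cross-stage-partial layout: two 1 x 1 entries split the channels; the pool
#' branch applies three chained same-size 5 x 5 max-pools (equivalent to
#' parallel 5/9/13 pools — two serial 5s equal one 9, three equal one 13 —
#' so the receptive field is unchanged while each pool stays small),
#' concatenates the intermediate results, fuses, and rejoins the bypass half.
#' Shape-preserving.
#'
#' @param channels input (= output) channel count.
#' @param mode "serial" (default) or "parallel" (the 5/9/13 variant; identical
#'   outputs and parameter count, slower pooling).
#' @param seed integer seed.
#' @return a forward-passable component.
#' @export
build_sppfcspc <- function(channels, mode = c("serial", "parallel"), seed = 1) {
  assert_that(is_count(channels) && channels >= 2, "channels must be >= 2")
  mode <- match.arg(mode)
  with_seed(seed, {
    h <- channels %/% 2L
    comp <- list(
      type = "sppfcspc", mode = mode,
      a = new_conv(channels, h, 1), b = new_conv(channels, h, 1),
      a2 = new_conv(h, h, 3),
      fuse = new_conv(4L * h, h, 1),
      out = new_conv(2L * h, channels, 1),
      fwd = function(self, x) {
        a <- conv_fwd(self$a2, conv_fwd(self$a, x))
        if (self$mode == "serial") {
          p1 <- maxpool_same(a, 5)
          p2 <- maxpool_same(p1, 5)
          p3 <- maxpool_same(p2, 5)
        } else {
          p1 <- maxpool_same(a, 5)
          p2 <- maxpool_same(a, 9)
          p3 <- maxpool_same(a, 13)
        }
        y <- conv_fwd(self$fuse, concat_c(a, p1, p2, p3))
        conv_fwd(self$out, concat_c(y, conv_fwd(self$b, x)))
      })
    comp
  })
}

#' Build the decoupled detection head
#'
#' A shared 1 x 1 channel reduction feeds two parallel branches with disjoint
#' parameters: a convolutional classification branch, and a localisation
#' branch (1 x 1 convolutions, the per-location equivalent of a dense layer)
#' emitting 4 box coordinates plus an objectness/IoU output. Raw outputs per
#' location: \code{n_anchors * (4 + 1 + n_classes)} channels, returned as an
#' array [n_anchors, 4 + 1 + n_classes, H, W].
#'
#' @param channels_in input channels.
#' @param n_classes number of classes (>= 1).
#' @param n_anchors anchors per location (default 3).
#' @param width internal branch width (default 128).
#' @param seed integer seed.
#' @param init "he" (default) or "zero" weight initialisation.
#' @return a forward-passable component.
#' @export
build_decoupled_head <- function(channels_in, n_classes = 4, n_anchors = 3,
                                 width = 128, seed = 1, init = "he") {
  assert_that(is_count(n_classes), "n_classes must be >= 1")
  with_seed(seed, {
    comp <- list(
      type = "decoupled_head", n_classes = n_classes, n_anchors = n_anchors,
      stem = new_conv(channels_in, width, 1, init = init),
      cls_conv = new_conv(width, width, 3, init = init),
      cls_out = new_conv(width, n_anchors * n_classes, 1, act = FALSE, init = init),
      reg_conv = new_conv(width, width, 3, init = init),
      reg_out = new_conv(width, n_anchors * 4, 1, act = FALSE, init = init),
      obj_out = new_conv(width, n_anchors * 1, 1, act = FALSE, init = init),
      fwd = function(self, x) {
        s <- conv_fwd(self$stem, x)
        fc <- conv_fwd(self$cls_conv, s)
        fr <- conv_fwd(self$reg_conv, s)
        cls <- conv_fwd(self$cls_out, fc)
        reg <- conv_fwd(self$reg_out, fr)
        obj <- conv_fwd(self$obj_out, fr)
        assemble_head_output(reg, obj, cls, self$n_anchors, self$n_classes)
      })
    comp
  })
}

# [na*4,H,W] + [na,H,W] + [na*ncls,H,W] -> [na, 4+1+ncls, H, W]
assemble_head_output <- function(reg, obj, cls, na, ncls) {
  d <- dim(reg); H <- d[2]; W <- d[3]
  out <- array(0, c(na, 5 + ncls, H, W))
  for (a in seq_len(na)) {
    out[a, 1:4, , ] <- reg[(a - 1) * 4 + 1:4, , ]
    out[a, 5, , ] <- obj[a, , ]
    out[a, 5 + seq_len(ncls), , ] <- cls[(a - 1) * ncls + seq_len(ncls), , ]
  }
  out
}

#' Assemble the full detector (backbone + per-level decoupled heads)
#'
#' Standard single-stage conventions: 3 anchors per level, strides 8/16/32.
#'
#' @param cfg a \code{\link{backbone_config}}.
#' @param n_classes number of classes.
#' @param img_size input image side (multiple of 32).
#' @param head_width decoupled-head branch width.
#' @param seed integer seed.
#' @return a \code{detector} list (backbone, heads, anchors, strides).
#' @export
build_detector <- function(cfg = backbone_config(), n_classes = 4,
                           img_size = 256, head_width = 64, seed = 1) {
  backbone <- build_backbone(cfg, seed = seed)
  oc <- backbone$out_channels
  strides <- c(P3 = 8, P4 = 16, P5 = 32)
  anchors <- list(P3 = cbind(w = c(10, 16, 24), h = c(13, 8, 20)),
                  P4 = cbind(w = c(30, 45, 38), h = c(20, 32, 48)),
                  P5 = cbind(w = c(60, 90, 120), h = c(80, 60, 110)))
  heads <- list()
  for (i in seq_along(oc)) {
    lv <- names(oc)[i]
    heads[[lv]] <- build_decoupled_head(oc[[i]], n_classes, 3,
                                        width = head_width, seed = seed + i)
  }
  structure(list(backbone = backbone, heads = heads, anchors = anchors,
                 strides = strides, n_classes = n_classes, img_size = img_size),
            class = "detector")
}

#' @export
print.detector <- function(x, ...) {
  cat(sprintf("single-stage detector: %d classes, strides %s, %d parameters\n",
              x$n_classes, paste(x$strides, collapse = "/"),
              n_params(x$backbone) + sum(vapply(x$heads, n_params, 0))))
  invisible(x)
}

scene_to_tensor <- function(scene) {
  img <- scene$image / 255
  aperm(img, c(3, 1, 2))
}

# decode raw head outputs at given cells/anchors into pixel boxes
decode_box <- function(raw4, anchor, cx_cell, cy_cell, stride) {
  bx <- (2 * sigmoid(raw4[1]) - 0.5 + cx_cell) * stride
  by <- (2 * sigmoid(raw4[2]) - 0.5 + cy_cell) * stride
  bw <- anchor[1] * (2 * sigmoid(raw4[3]))^2
  bh <- anchor[2] * (2 * sigmoid(raw4[4]))^2
  c(bx - bw / 2, by - bh / 2, bx + bw / 2, by + bh / 2)
}

# target assignment: each truth box -> (level, anchor, cell) with best
# anchor shape match per level; one positive per level per truth
assign_targets <- function(boxes, img_hw, anchors, strides) {
  out <- list()
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    bw <- b$w * img_hw[2]; bh <- b$h * img_hw[1]
    bx <- b$cx * img_hw[2]; by <- b$cy * img_hw[1]
    for (lv in names(strides)) {
      s <- strides[[lv]]
      an <- anchors[[lv]]
      fit <- abs(log(pmax(bw, 2) / an[, "w"])) + abs(log(pmax(bh, 2) / an[, "h"]))
      a <- which.min(fit)
      ci <- min(max(floor(bx / s), 0), img_hw[2] %/% s - 1)
      cj <- min(max(floor(by / s), 0), img_hw[1] %/% s - 1)
      out[[length(out) + 1]] <- list(level = lv, anchor = a, cell = c(ci, cj),
                                     gt = c(bx - bw / 2, by - bh / 2,
                                            bx + bw / 2, by + bh / 2),
                                     class = b$class)
    }
  }
  out
}

#' Desk-scale smoke training of the detection objective
#'
#' Freezes the randomly initialised backbone and head branch features and
#' optimises the head's final 1 x 1 output convolutions by stochastic
#' gradient descent on the full detection objective: mean CIoU loss over
#' assigned anchors, binary cross-entropy objectness over all locations and
#' binary cross-entropy classification at assigned anchors. Box-coordinate
#' gradients are obtained by central finite differences on the four raw
#' outputs of each positive; objectness/classification gradients are
#' analytic. This is a correctness exercise of the objective, not model
#' training.
#'
#' @param scenes list of >= 4 small \code{shred_scene}s with square frames of
#'   side divisible by 32 (e.g. 64 x 64).
#' @param epochs number of epochs (default 20).
#' @param seed integer seed; traces are identical for equal seeds.
#' @param lr learning rate.
#' @param cfg backbone configuration (default: narrow 16/32/64/128 channels).
#' @return a \code{smoke_trace}: list(loss = per-epoch numeric,
#'   components = data.frame(ciou, obj, cls)).
#' @export
smoke_train <- function(scenes, epochs = 20, seed = 1, lr = 0.2,
                        cfg = backbone_config(stage_channels = c(16, 32, 64, 128))) {
  assert_that(length(scenes) >= 4, "smoke training needs at least 4 scenes")
  d1 <- dim(scenes[[1]]$image)
  assert_that(d1[1] %% 32 == 0 && d1[2] %% 32 == 0,
              "scene frames must be divisible by 32")
  with_seed(seed, {
    det <- build_detector(cfg, n_classes = 4, img_size = d1[1],
                          head_width = 32, seed = seed)
    lvls <- names(det$strides)
    # frozen features: backbone taps and head branch features per scene
    feats <- lapply(scenes, function(sc) {
      taps <- forward(det$backbone, scene_to_tensor(sc))
      per_lvl <- list()
      for (lv in lvls) {
        hd <- det$heads[[lv]]
        s <- conv_fwd(hd$stem, taps[[lv]])
        per_lvl[[lv]] <- list(fc = conv_fwd(hd$cls_conv, s),
                              fr = conv_fwd(hd$reg_conv, s))
      }
      per_lvl
    })
    targets <- lapply(scenes, function(sc)
      assign_targets(sc$boxes, dim(sc$image)[1:2], det$anchors, det$strides))

    epoch_pass <- function(update) {
      tot <- c(ciou = 0, obj = 0, cls = 0); n_pos <- 0
      for (si in seq_along(scenes)) {
        for (lv in lvls) {
          hd <- det$heads[[lv]]
          fc <- feats[[si]][[lv]]$fc; fr <- feats[[si]][[lv]]$fr
          H <- dim(fr)[2]; W <- dim(fr)[3]
          fc_m <- matrix(fc, dim(fc)[1], H * W); fr_m <- matrix(fr, dim(fr)[1], H * W)
          reg <- hd$reg_out$W %*% fr_m + hd$reg_out$b
          obj <- hd$obj_out$W %*% fr_m + hd$obj_out$b
          cls <- hd$cls_out$W %*% fc_m + hd$cls_out$b
          na <- hd$n_anchors; nc <- hd$n_classes
          obj_t <- matrix(0, na, H * W)
          g_reg <- matrix(0, nrow(reg), H * W)
          g_cls <- matrix(0, nrow(cls), H * W)
          pos <- Filter(function(t) t$level == lv, targets[[si]])
          s <- det$strides[[lv]]
          for (t in pos) {
            loc <- t$cell[1] * H + t$cell[2] + 1   # column-major [row=cy, col=cx]
            a <- t$anchor
            ridx <- (a - 1) * 4 + 1:4
            raw4 <- reg[ridx, loc]
            anchor <- det$anchors[[lv]][a, ]
            f_ciou <- function(r) ciou_loss(decode_box(r, anchor, t$cell[1],
                                                       t$cell[2], s), t$gt)
            l0 <- f_ciou(raw4)
            tot["ciou"] <- tot["ciou"] + l0
            n_pos <- n_pos + 1
            obj_t[a, loc] <- 1
            cidx <- (a - 1) * nc + seq_len(nc)
            y <- as.numeric(seq_len(nc) - 1 == t$class)
            pcl <- sigmoid(cls[cidx, loc])
            tot["cls"] <- tot["cls"] - sum(y * log(pcl + 1e-12) +
                                           (1 - y) * log(1 - pcl + 1e-12))
            if (update) {
              eps <- 1e-4
              g4 <- vapply(1:4, function(k) {
                rp <- raw4; rm <- raw4
                rp[k] <- rp[k] + eps; rm[k] <- rm[k] - eps
                (f_ciou(rp) - f_ciou(rm)) / (2 * eps)
              }, 0)
              g_reg[ridx, loc] <- g_reg[ridx, loc] + g4
              g_cls[cidx, loc] <- g_cls[cidx, loc] + (pcl - y)
            }
          }
          pobj <- sigmoid(obj)
          tot["obj"] <- tot["obj"] - mean(obj_t * log(pobj + 1e-12) +
                                          (1 - obj_t) * log(1 - pobj + 1e-12))
          if (update) {
            g_obj <- (pobj - obj_t) / length(obj)
            scale <- 1 / max(1, length(pos))
            hd$reg_out$W <- hd$reg_out$W - lr * scale * (g_reg %*% t(fr_m))
            hd$reg_out$b <- hd$reg_out$b - lr * scale * rowSums(g_reg)
            hd$obj_out$W <- hd$obj_out$W - lr * (g_obj %*% t(fr_m))
            hd$obj_out$b <- hd$obj_out$b - lr * rowSums(g_obj)
            hd$cls_out$W <- hd$cls_out$W - lr * scale * (g_cls %*% t(fc_m))
            hd$cls_out$b <- hd$cls_out$b - lr * scale * rowSums(g_cls)
            det$heads[[lv]] <<- hd
          }
        }
      }
      c(ciou = tot[["ciou"]] / max(1, n_pos),
        obj = tot[["obj"]] / (length(scenes) * length(lvls)),
        cls = tot[["cls"]] / max(1, n_pos))
    }

    comp <- matrix(0, epochs, 3, dimnames = list(NULL, c("ciou", "obj", "cls")))
    for (e in seq_len(epochs)) {
      comp[e, ] <- epoch_pass(update = TRUE)
      assert_that(all(is.finite(comp[e, ])), "training diverged (non-finite loss)")
    }
    structure(list(loss = rowSums(comp), components = as.data.frame(comp),
                   detector = det),
              class = "smoke_trace")
  })
}

#' @export
print.smoke_trace <- function(x, ...) {
  n <- length(x$loss)
  cat(sprintf("smoke training: %d epochs, total loss %.4f -> %.4f\n",
              n, x$loss[1], x$loss[n]))
  invisible(x)
}
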