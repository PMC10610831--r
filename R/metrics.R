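#' Detection evaluation: matching, precision/recall, AP and mAP
#'
#' Predictions and truths are data.frames in YOLO-normalised form (columns
#' class, cx, cy, w, h; predictions additionally conf). Matching is greedy in
#' descending confidence: a prediction is a true positive when its best-IoU,
#' same-class, still-unmatched truth reaches the IoU threshold; every truth
#' can absorb at most one prediction. AP uses all-point interpolation (the
#' exact discrete analogue of the area under the precision-recall curve) and
#' mAP averages per-class APs; mAP@.5:.95 averages over IoU thresholds
#' 0.50, 0.55, ..., 0.95.
#'
#' @name metrics
NULL

.df_to_xyxy <- function(df, width_px = 1000, height_px = 1000) {
  if (nrow(df) == 0) return(matrix(numeric(), 0, 4))
  yolo_to_xyxy(df$cx, df$cy, df$w, df$h, width_px, height_px)
}

#' Match predictions to ground-truth boxes
#'
#' @param predictions data.frame(class, cx, cy, w, h, conf).
#' @param truths data.frame(class, cx, cy, w, h).
#' @param iou_threshold IoU cutoff in (0, 1].
#' @return a \code{match_result}: list with TP, FP, FN counts, and
#'   \code{flags} (logical TP flag per prediction, ordered by descending
#'   confidence, input order breaking ties) plus the matching \code{order}.
#' @export
match_detections <- function(predictions, truths, iou_threshold = 0.5) {
  assert_that(iou_threshold > 0 && iou_threshold <= 1,
              "iou_threshold must lie in (0, 1]")
  np <- nrow(predictions); nt <- nrow(truths)
  if (np == 0) {
    return(structure(list(TP = 0L, FP = 0L, FN = nt, flags = logical(),
                          order = integer()), class = "match_result"))
  }
  conf <- if ("conf" %in% names(predictions)) predictions$conf else rep(1, np)
  ord <- order(-conf, seq_len(np))      # ties broken by input order
  pb <- .df_to_xyxy(predictions)
  tb <- .df_to_xyxy(truths)
  used <- rep(FALSE, nt)
  flags <- logical(np)
  for (k in seq_len(np)) {
    i <- ord[k]
    best <- 0; best_j <- 0L
    for (j in seq_len(nt)) {
      if (used[j] || truths$class[j] != predictions$class[i]) next
      u <- iou(pb[i, ], tb[j, ])
      if (u > best) { best <- u; best_j <- j }
    }
    if (best_j > 0L && best >= iou_threshold) {
      flags[k] <- TRUE
      used[best_j] <- TRUE
    }
  }
  tp <- sum(flags)
  structure(list(TP = tp, FP = np - tp, FN = nt - tp, flags = flags,
                 order = ord), class = "match_result")
}

#' Precision and recall of a match result
#'
#' \code{precision = TP / (TP + FP)}, \code{recall = TP / (TP + FN)}; a zero
#' denominator yields 0 with a warning.
#'
#' @param m a \code{match_result}.
#' @return a number in [0, 1].
#' @export
precision <- function(m) {
  if (m$TP + m$FP == 0) { warning("no predictions; precision defined as 0"); return(0) }
  m$TP / (m$TP + m$FP)
}

#' @rdname precision
#' @export
recall <- function(m) {
  if (m$TP + m$FN == 0) { warning("no ground truth; recall defined as 0"); return(0) }
  m$TP / (m$TP + m$FN)
}

#' Average precision from ranked true-positive flags
#'
#' All-point interpolation: the precision curve is made monotone
#' non-increasing from the right and summed over recall increments.
#'
#' @param flags logical vector of per-prediction TP flags, ordered by
#'   descending confidence.
#' @param n_truths number of ground-truth boxes of the class.
#' @return AP in [0, 1]; \code{NA} when \code{n_truths} is 0 (undefined).
#' @export
average_precision <- function(flags, n_truths) {
  if (n_truths == 0) return(NA_real_)
  if (length(flags) == 0 || !any(flags)) return(0)
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  prec <- tp / (tp + fp)
  rec <- tp / n_truths
  # monotone envelope from the right
  penv <- rev(cummax(rev(prec)))
  drec <- diff(c(0, rec))
  sum(penv * drec)
}

#' Per-class AP and mAP over one or many IoU thresholds
#'
#' @param predictions data.frame(class, cx, cy, w, h, conf); pooled over the
#'   evaluation set (add an \code{image} column to keep scenes separate —
#'   matching is then done per image).
#' @param truths data.frame(class, cx, cy, w, h) with an optional matching
#'   \code{image} column.
#' @param classes integer class ids evaluated (default 0:3).
#' @return an \code{ap_result}: list with \code{ap50} (per-class vector),
#'   \code{map50}, \code{map50_95}, \code{thresholds}, and the full per-class
#'   by-threshold AP matrix \code{ap_matrix}.
#' @export
map_range <- function(predictions, truths, classes = 0:3) {
  thresholds <- seq(0.5, 0.95, by = 0.05)
  imgs <- if ("image" %in% names(predictions) || "image" %in% names(truths)) {
    union(unique(predictions$image), unique(truths$image))
  } else {
    predictions$image <- 1L; truths$image <- 1L
    1L
  }
  apm <- matrix(NA_real_, length(classes), length(thresholds),
                dimnames = list(paste0("class", classes), sprintf("%.2f", thresholds)))
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    nt_total <- sum(truths$class == cls)
    if (nt_total == 0) next                      # undefined: excluded from mean
    for (ti in seq_along(thresholds)) {
      flag_list <- list(); conf_list <- list()
      for (im in imgs) {
        p <- predictions[predictions$class == cls & predictions$image == im, , drop = FALSE]
        t <- truths[truths$class == cls & truths$image == im, , drop = FALSE]
        if (nrow(p) == 0) next
        m <- match_detections(p, t, thresholds[ti])
        conf <- if ("conf" %in% names(p)) p$conf else rep(1, nrow(p))
        flag_list[[length(flag_list) + 1]] <- m$flags
        conf_list[[length(conf_list) + 1]] <- sort(conf, decreasing = TRUE)
      }
      flags <- unlist(flag_list); confs <- unlist(conf_list)
      if (is.null(flags)) { apm[ci, ti] <- 0; next }
      ord <- order(-confs, seq_along(confs))
      apm[ci, ti] <- average_precision(flags[ord], nt_total)
    }
  }
  ap50 <- apm[, 1]
  structure(list(ap50 = ap50,
                 map50 = mean(ap50, na.rm = TRUE),
                 map50_95 = mean(rowMeans(apm), na.rm = TRUE),
                 thresholds = thresholds, ap_matrix = apm),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat("detection evaluation\n")
  cat("  per-class AP@.5: ",
      paste(sprintf("%s=%.3f", rownames(x$ap_matrix), x$ap50), collapse = "  "), "\n")
  cat(sprintf("  mAP@.5     = %.4f\n", x$map50))
  cat(sprintf("  mAP@.5:.95 = %.4f  (over %d IoU thresholds)\n",
              x$map50_95, length(x$thresholds)))
  invisible(x)
}

#' Evaluate directories of YOLO prediction and truth label files
#'
#' Files are paired by basename; predictions may carry a sixth confidence
#' column (assumed 1 when absent). Predictions below \code{conf_min} are
#' discarded before evaluation.
#'
#' @param pred_dir,truth_dir directories of .txt label files.
#' @param conf_min confidence cutoff applied to predictions.
#' @param classes integer class ids (default 0:3).
#' @return list(result = \code{ap_result}, table = per-class data.frame with
#'   AP@.5, precision and recall at IoU 0.5).
#' @export
evaluate_labels <- function(pred_dir, truth_dir, conf_min = 0, classes = 0:3) {
  tfiles <- list.files(truth_dir, pattern = "\\.txt$", full.names = TRUE)
  assert_that(length(tfiles) > 0, "no truth label files in %s", truth_dir)
  preds <- list(); trs <- list()
  for (tf in tfiles) {
    stem <- sub("\\.txt$", "", basename(tf))
    t <- read_yolo_labels(tf); if (nrow(t)) t$image <- stem
    pf <- file.path(pred_dir, basename(tf))
    p <- read_yolo_labels(pf)
    if (!"conf" %in% names(p)) p$conf <- rep(1, nrow(p))
    p <- p[p$conf >= conf_min, , drop = FALSE]
    if (nrow(p)) p$image <- stem
    trs[[stem]] <- t; preds[[stem]] <- p
  }
  predictions <- do.call(rbind, preds); truths <- do.call(rbind, trs)
  res <- map_range(predictions, truths, classes)
  per_class <- do.call(rbind, lapply(classes, function(cls) {
    p <- predictions[predictions$class == cls, , drop = FALSE]
    t <- truths[truths$class == cls, , drop = FALSE]
    # pooled counts over images at IoU .5
    tp <- fp <- 0L
    for (im in unique(c(p$image, t$image))) {
      m <- match_detections(p[p$image == im, , drop = FALSE],
                            t[t$image == im, , drop = FALSE], 0.5)
      tp <- tp + m$TP; fp <- fp + m$FP
    }
    fn <- nrow(t) - tp
    data.frame(class = cls, label = shred_classes[cls + 1],
               n_truth = nrow(t), n_pred = nrow(p),
               ap50 = unname(res$ap50[paste0("class", cls)]),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }))
  list(result = res, table = per_class)
}
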