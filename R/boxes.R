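#' Boxes are length-4 numeric vectors c(x0, y0, x1, y1) in pixels with
#' x1 > x0 and y1 > y0. YOLO label rows are (class, cx, cy, w, h) normalised
#' to [0, 1] relative to the image size.
#' @name boxes
NULL

validate_box <- function(b, what = "box") {
  assert_that(is.numeric(b) && length(b) == 4 && all(is.finite(b)),
              "%s must be a finite numeric length-4 vector (x0, y0, x1, y1)", what)
  assert_that(b[3] > b[1] && b[4] > b[2],
              "%s is degenerate: need x1 > x0 and y1 > y0", what)
  invisible(b)
}

#' Intersection over union of two axis-aligned boxes
#'
#' @param b,bgt boxes \code{c(x0, y0, x1, y1)} in pixels.
#' @return IoU in [0, 1].
#' @export
iou <- function(b, bgt) {
  validate_box(b, "b"); validate_box(bgt, "bgt")
  ix <- max(0, min(b[3], bgt[3]) - max(b[1], bgt[1]))
  iy <- max(0, min(b[4], bgt[4]) - max(b[2], bgt[2]))
  inter <- ix * iy
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  inter / (area(b) + area(bgt) - inter)
}

#' Complete-IoU loss between a predicted and a ground-truth box
#'
#' Returns \code{1 - IoU + rho^2 / c^2 + a * v} where \code{rho} is the
#' distance between box centers, \code{c} the diagonal of the smallest
#' enclosing box, \code{v = (4 / pi^2) (atan(wg/hg) - atan(w/h))^2} the
#' aspect-ratio consistency term and \code{a = v / (1 - IoU + v)} its weight
#' (zero when the boxes coincide).
#'
#' @inheritParams iou
#' @return non-negative loss; 0 iff the boxes are identical.
#' @export
ciou_loss <- function(b, bgt) {
  u <- iou(b, bgt)
  cx <- (b[1] + b[3]) / 2;  cy <- (b[2] + b[4]) / 2
  gx <- (bgt[1] + bgt[3]) / 2; gy <- (bgt[2] + bgt[4]) / 2
  rho2 <- (cx - gx)^2 + (cy - gy)^2
  ex <- max(b[3], bgt[3]) - min(b[1], bgt[1])
  ey <- max(b[4], bgt[4]) - min(b[2], bgt[2])
  c2 <- ex^2 + ey^2
  w <- b[3] - b[1]; h <- b[4] - b[2]
  wg <- bgt[3] - bgt[1]; hg <- bgt[4] - bgt[2]
  v <- (4 / pi^2) * (atan(wg / hg) - atan(w / h))^2
  a <- if (v == 0) 0 else v / ((1 - u) + v)
  1 - u + rho2 / c2 + a * v
}

# YOLO normalised (cx, cy, w, h) -> pixel (x0, y0, x1, y1)
yolo_to_xyxy <- function(cx, cy, w, h, width_px, height_px) {
  cbind(x0 = (cx - w / 2) * width_px,
        y0 = (cy - h / 2) * height_px,
        x1 = (cx + w / 2) * width_px,
        y1 = (cy + h / 2) * height_px)
}

# pixel (x0, y0, x1, y1) -> YOLO normalised (cx, cy, w, h)
xyxy_to_yolo <- function(x0, y0, x1, y1, width_px, height_px) {
  cbind(cx = (x0 + x1) / 2 / width_px,
        cy = (y0 + y1) / 2 / height_px,
        w  = (x1 - x0) / width_px,
        h  = (y1 - y0) / height_px)
}

# Clip a YOLO box data.frame to [0,1]^4; drop boxes with no remaining area.
clip_boxes <- function(boxes) {
  if (nrow(boxes) == 0) return(boxes)
  x0 <- pmax(boxes$cx - boxes$w / 2, 0); x1 <- pmin(boxes$cx + boxes$w / 2, 1)
  y0 <- pmax(boxes$cy - boxes$h / 2, 0); y1 <- pmin(boxes$cy + boxes$h / 2, 1)
  keep <- x1 - x0 > 1e-6 & y1 - y0 > 1e-6
  out <- boxes[keep, , drop = FALSE]
  x0 <- x0[keep]; x1 <- x1[keep]; y0 <- y0[keep]; y1 <- y1[keep]
  out$cx <- (x0 + x1) / 2; out$cy <- (y0 + y1) / 2
  out$w <- x1 - x0; out$h <- y1 - y0
  out
}

#' Read and write YOLO-format label files
#'
#' One line per object: \code{class cx cy w h}, whitespace separated,
#' normalised coordinates; an optional sixth column holds a confidence.
#' Class indices 0-3 map to the shred classes Y, G, P, Z.
#'
#' @param path label file path.
#' @return data.frame with columns class (integer), cx, cy, w, h and, when
#'   present in the file, conf.
#' @export
read_yolo_labels <- function(path) {
  empty <- data.frame(class = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
  if (!file.exists(path) || file.size(path) == 0) return(empty)
  m <- utils::read.table(path, header = FALSE)
  names(m)[1:5] <- c("class", "cx", "cy", "w", "h")
  if (ncol(m) >= 6) names(m)[6] <- "conf"
  m$class <- as.integer(m$class)
  m
}

#' @rdname read_yolo_labels
#' @param boxes data.frame with columns class, cx, cy, w, h (and optionally
#'   conf, written as a sixth column).
#' @export
write_yolo_labels <- function(boxes, path) {
  cols <- c("class", "cx", "cy", "w", "h")
  if ("conf" %in% names(boxes)) cols <- c(cols, "conf")
  lines <- apply(boxes[, cols, drop = FALSE], 1, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(as.character(lines), path)
  invisible(path)
}

shred_classes <- c("Y", "G", "P", "Z")

class_index <- function(label) {
  i <- match(label, shred_classes)
  assert_that(all(!is.na(i)), "unknown class label; expected one of Y, G, P, Z")
  i - 1L
}
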