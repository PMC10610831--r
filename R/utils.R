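#' @import stats utils
#' @importFrom grDevices rgb2hsv hsv col2rgb
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x >= 1

clamp <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

#' Convert an RGB array to an 8-bit grayscale matrix
#'
#' Uses the Rec.601 luma weights (0.299, 0.587, 0.114). Accepts either an
#' \code{H x W x 3} array with values in [0, 255] or an already-gray matrix,
#' which is returned rounded and clamped.
#'
#' @param image numeric array \code{H x W x 3} (or matrix) in [0, 255].
#' @return integer-valued matrix in [0, 255].
#' @export
to_gray <- function(image) {
  if (is.matrix(image)) return(round(clamp(image)))
  assert_that(length(dim(image)) == 3 && dim(image)[3] >= 3,
              "expected an H x W x 3 RGB array or a matrix")
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  round(clamp(g))
}

# Replicate-pad a matrix by r rows/cols on every side.
pad_replicate <- function(m, r) {
  if (r == 0) return(m)
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# Running max filter of odd width k along matrix rows (i.e. across columns),
# replicate edges. Vectorised via shifted pmax.
.rowwise_max <- function(m, k) {
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(m)
  p <- pad_replicate(m, 0L)
  p <- p[, c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r)), drop = FALSE]
  out <- p[, seq_len(ncol(m)), drop = FALSE]
  for (s in seq_len(2L * r)) {
    out <- pmax(out, p[, s + seq_len(ncol(m)), drop = FALSE])
  }
  out
}

# Square (k x k) grayscale dilation = separable running max, replicate edges.
max_filter <- function(m, k) {
  assert_that(is_count(k) && k %% 2 == 1, "kernel size must be a positive odd integer")
  t(.rowwise_max(t(.rowwise_max(m, k)), k))
}

# Box local mean of odd width k, replicate edges, via cumulative sums.
box_mean <- function(m, k) {
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(m)
  p <- pad_replicate(m, r)
  cs <- apply(p, 2, cumsum)
  cs <- rbind(0, cs)
  rs <- cs[seq_len(nrow(m)) + 2L * r + 1L, , drop = FALSE] -
        cs[seq_len(nrow(m)), , drop = FALSE]          # row sums over k rows
  cs2 <- t(apply(rs, 1, cumsum))
  cs2 <- cbind(0, cs2)
  out <- cs2[, seq_len(ncol(m)) + 2L * r + 1L, drop = FALSE] -
         cs2[, seq_len(ncol(m)), drop = FALSE]
  out / (k * k)
}

# EBImage stores images as [x, y]; the package convention is matrix [row=y, col=x].
as_ebi <- function(m) EBImage::as.Image(t(m))
from_ebi <- function(img) t(as.matrix(img))

# Rotate a binary mask by `angle` degrees (positive = the direction that maps a
# segment drawn at +angle in matrix coordinates onto the horizontal when
# rotated by -angle); canvas expands, background 0, output re-binarised.
rotate_mask <- function(mask, angle) {
  r <- EBImage::rotate(as_ebi(mask), angle, bg.col = 0)
  from_ebi(r) > 0.5
}

# Uniform draws used throughout the generator; kept here so every module
# shares one RNG discipline (R's own stream, seeded once per entry point).
runif1 <- function(lo, hi) stats::runif(1, lo, hi)
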