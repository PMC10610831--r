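# Independent brute-force oracles used across the suite. These are written
# directly from first principles and never call the implementation paths they
# check.

# per-window brute-force median / max filters with replicate padding
brute_window <- function(m, k, fun) {
  r <- (k - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ri <- pmin(pmax(i + (-r:r), 1), H)
    ci <- pmin(pmax(j + (-r:r), 1), W)
    out[i, j] <- fun(m[ri, ci])
  }
  out
}

# scalar complete-IoU loss recomputed term by term from its definition
oracle_ciou <- function(b, g) {
  inter_w <- max(0, min(b[3], g[3]) - max(b[1], g[1]))
  inter_h <- max(0, min(b[4], g[4]) - max(b[2], g[2]))
  inter <- inter_w * inter_h
  u <- inter / ((b[3] - b[1]) * (b[4] - b[2]) +
                (g[3] - g[1]) * (g[4] - g[2]) - inter)
  rho2 <- ((b[1] + b[3]) / 2 - (g[1] + g[3]) / 2)^2 +
          ((b[2] + b[4]) / 2 - (g[2] + g[4]) / 2)^2
  c2 <- (max(b[3], g[3]) - min(b[1], g[1]))^2 +
        (max(b[4], g[4]) - min(b[2], g[2]))^2
  v <- 4 / pi^2 * (atan((g[3] - g[1]) / (g[4] - g[2])) -
                   atan((b[3] - b[1]) / (b[4] - b[2])))^2
  a <- if (v == 0) 0 else v / (1 - u + v)
  1 - u + rho2 / c2 + a * v
}

# explicit precision-recall staircase area from ranked TP flags
oracle_ap <- function(flags, n_truths) {
  if (!any(flags)) return(0)
  tp <- 0; fp <- 0
  pr <- matrix(0, length(flags), 2)
  for (i in seq_along(flags)) {
    if (flags[i]) tp <- tp + 1 else fp <- fp + 1
    pr[i, ] <- c(tp / n_truths, tp / (tp + fp))
  }
  # area under the staircase with the interpolated (running-max-from-right)
  # precision at each distinct recall step
  area <- 0
  prev_r <- 0
  for (i in seq_len(nrow(pr))) {
    if (pr[i, 1] > prev_r) {
      p_best <- max(pr[i:nrow(pr), 2])
      area <- area + (pr[i, 1] - prev_r) * p_best
      prev_r <- pr[i, 1]
    }
  }
  area
}

# exhaustive largest-inscribed-circle radius with centre restricted to given
# columns: for every interior pixel, the distance to the nearest background
# pixel (mask border padded as background)
oracle_strip_radius <- function(mask, cols) {
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(FALSE, H + 2, W + 2)
  padded[1 + seq_len(H), 1 + seq_len(W)] <- mask
  bg <- which(!padded, arr.ind = TRUE)
  best <- 0
  for (j in cols) for (i in seq_len(H)) {
    if (!mask[i, j]) next
    d <- sqrt(min((bg[, 1] - (i + 1))^2 + (bg[, 2] - (j + 1))^2))
    if (d > best) best <- d
  }
  best
}

# random valid pixel box (x0, y0, x1, y1)
random_box <- function(lim = 100) {
  x <- sort(runif(2, 0, lim)); y <- sort(runif(2, 0, lim))
  while (diff(x) < 1) x <- sort(runif(2, 0, lim))
  while (diff(y) < 1) y <- sort(runif(2, 0, lim))
  c(x[1], y[1], x[2], y[2])
}

# small shared scene, cached per session
tiny_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_scene(c(Y = 1, G = 1), seed = 11, canvas = c(256, 256),
                               ppmm = 5, length_range = c(8, 14),
                               width_range = c(1, 2.5))
    }
    cache
  }
})
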