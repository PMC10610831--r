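test_that("iou covers the identical, disjoint and hand-computed cases", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)  # areas 4+4-1
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("greedy matching applies the single-match rule per truth", {
  tr <- data.frame(class = 0, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  pr1 <- data.frame(class = 0, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2, conf = 0.9)
  m <- match_detections(pr1, tr, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))
  pr2 <- rbind(pr1, transform(pr1, conf = 0.8))
  m2 <- match_detections(pr2, tr, 0.5)
  expect_equal(c(m2$TP, m2$FP), c(1, 1))
  # class mismatch is never a match
  pr3 <- transform(pr1, class = 1)
  m3 <- match_detections(pr3, tr, 0.5)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(0, 1, 1))
})

test_that("matching agrees with a plain re-enactment on random 5x3 fixtures", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- data.frame(class = 0, cx = runif(3, .2, .8), cy = runif(3, .2, .8),
                     w = runif(3, .1, .3), h = runif(3, .1, .3))
    pr <- tr[sample(3, 5, TRUE), ]
    pr$cx <- pmin(pmax(pr$cx + rnorm(5, 0, 0.03), .05), .95)
    pr$conf <- runif(5)
    m <- match_detections(pr, tr, 0.5)
    # independent re-enactment of greedy descending-confidence matching
    ord <- order(-pr$conf, seq_len(5))
    used <- rep(FALSE, 3); flags <- logical(5)
    to_xy <- function(d, i) c((d$cx[i] - d$w[i] / 2) * 1000, (d$cy[i] - d$h[i] / 2) * 1000,
                              (d$cx[i] + d$w[i] / 2) * 1000, (d$cy[i] + d$h[i] / 2) * 1000)
    for (k in seq_len(5)) {
      i <- ord[k]; best <- 0; bj <- 0
      for (j in 1:3) {
        if (used[j]) next
        u <- iou(to_xy(pr, i), to_xy(tr, j))
        if (u > best) { best <- u; bj <- j }
      }
      if (bj > 0 && best >= 0.5) { flags[k] <- TRUE; used[bj] <- TRUE }
    }
    expect_equal(m$flags, flags)
    expect_equal(m$TP, sum(flags))
    expect_equal(m$TP + m$FN, 3)
    expect_equal(m$TP + m$FP, 5)
  }
})

test_that("precision and recall handle the printed examples and empty inputs", {
  m <- structure(list(TP = 9, FP = 1, FN = 0), class = "match_result")
  expect_equal(precision(m), 0.9)
  m0 <- structure(list(TP = 0, FP = 0, FN = 5), class = "match_result")
  expect_equal(recall(m0), 0)
  expect_warning(precision(m0), "precision")
})

test_that("average precision equals the staircase oracle on enumerated fixtures", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE), 3), 1)
  expect_equal(average_precision(c(FALSE), 1), 0)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE, FALSE), 2),
               oracle_ap(c(TRUE, FALSE, TRUE, FALSE), 2))
  # every flag pattern with <= 6 predictions and feasible truth counts
  for (np in 1:6) {
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), np))
    for (r in seq_len(nrow(grid))) {
      flags <- as.logical(grid[r, ])
      for (nt in max(1, sum(flags)):(sum(flags) + 2)) {
        expect_equal(average_precision(flags, nt), oracle_ap(flags, nt),
                     info = sprintf("np=%d nt=%d flags=%s", np, nt,
                                    paste(as.integer(flags), collapse = "")))
      }
    }
  }
})

test_that("mAP uses exactly 10 thresholds and is monotone in the IoU cutoff", {
  sc <- generate_scene(c(Y = 2, G = 2, P = 1, Z = 1), seed = 17,
                       canvas = c(640, 640))
  tr <- sc$boxes
  # jittered predictions
  set.seed(99)
  pr <- transform(tr, cx = cx + rnorm(6, 0, 0.004), w = w * runif(6, 0.9, 1.1),
                  conf = runif(6, 0.5, 1))
  res <- map_range(pr, tr)
  expect_equal(res$thresholds, seq(0.5, 0.95, by = 0.05))
  expect_length(res$thresholds, 10)
  expect_gte(res$map50 + 1e-12, res$map50_95)
  expect_true(all(res$ap_matrix >= 0 & res$ap_matrix <= 1, na.rm = TRUE))
  # perfect detector: both metrics are exactly 1
  perfect <- transform(tr, conf = 1)
  resp <- map_range(perfect, tr)
  expect_equal(resp$map50, 1)
  expect_equal(resp$map50_95, 1)
})

test_that("duplicate true-positive predictions never increase AP", {
  flags <- c(TRUE, TRUE, FALSE)
  base <- average_precision(flags, 2)
  # a duplicate detection of an already-matched truth ranks as FP
  dup <- average_precision(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_lte(dup, base)
})

test_that("directory evaluation pairs files and applies the confidence cutoff", {
  d <- withr::local_tempdir()
  td <- file.path(d, "truth"); pd <- file.path(d, "pred")
  dir.create(td); dir.create(pd)
  sc <- generate_scene(c(Y = 1, G = 1, P = 1, Z = 1), seed = 23,
                       canvas = c(640, 640))
  write_yolo_labels(sc$boxes, file.path(td, "a.txt"))
  pr <- sc$boxes
  pr$conf <- c(0.9, 0.8, 0.7, 0.1)
  write_yolo_labels(pr, file.path(pd, "a.txt"))
  ev <- evaluate_labels(pd, td, conf_min = 0.5)
  expect_equal(nrow(ev$table), 4)
  # the 0.1-confidence prediction was dropped: its class has no predictions
  expect_equal(sum(ev$table$n_pred), 3)
  expect_true(all(ev$table$ap50[ev$table$n_pred == 1] == 1))
})
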