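# Detection scoring: IoU, greedy matching, P/R/F1, 11-point AP, mAP and
# the normalised confusion matrix.

box <- function(x1, y1, x2, y2) c(x1, y1, x2, y2)

test_that("IoU covers identity, disjointness and the hand-derived overlap", {
  expect_equal(box_iou(box(0, 0, 2, 2), box(0, 0, 2, 2)), 1.0)
  expect_equal(box_iou(box(0, 0, 1, 1), box(5, 5, 6, 6)), 0.0)
  expect_equal(box_iou(box(0, 0, 2, 2), box(1, 1, 3, 3)), 1 / 7)
  expect_equal(box_iou(box(1, 1, 3, 3), box(0, 0, 2, 2)), 1 / 7)  # symmetry
  expect_error(box_iou(box(0, 0, 0, 2), box(0, 0, 1, 1)), "degenerate")
})

test_that("matching is confidence-ranked, class-aware and single-use per ground truth", {
  gt <- data.frame(class = 0L, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  d1 <- data.frame(class = 0L, conf = 0.9, x1 = 0, y1 = 0, x2 = 10, y2 = 6)  # IoU 0.6
  expect_true(match_detections(d1, gt, 0.5)$tp)

  d2 <- rbind(d1, data.frame(class = 0L, conf = 0.95, x1 = 0, y1 = 0, x2 = 10, y2 = 7))
  mt <- match_detections(d2, gt, 0.5)
  expect_equal(mt$tp, c(FALSE, TRUE))   # higher confidence row wins the GT

  # class-aware: a perfect overlap of the wrong class is an FP
  d3 <- data.frame(class = 1L, conf = 0.99, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  expect_false(match_detections(d3, gt, 0.5)$tp)
})

test_that("matching agrees with the independent IoU-matrix oracle on random instances", {
  set.seed(77)
  for (rep in 1:25) {
    gts <- random_boxes(sample(0:5, 1))[, -2]
    dets <- random_boxes(sample(0:7, 1))
    expect_equal(match_detections(dets, gts, 0.3)$tp, oracle_match(dets, gts, 0.3))
    expect_equal(match_detections(dets, gts, 0.6)$tp, oracle_match(dets, gts, 0.6))
  }
})

test_that("precision/recall/F1 handle the printed values and degenerate counts", {
  expect_equal(precision_recall_f1(0, 0, 0), c(precision = 0, recall = 0, f1 = 0))
  r <- precision_recall_f1(6, 2, 2)
  expect_equal(unname(r["precision"]), unname(r["recall"]))
  expect_equal(unname(r["f1"]), unname(r["precision"]))  # harmonic-mean fixed point
  # the published precision/recall pair combines to the published F1
  p <- 0.798; rr <- 0.864
  f1 <- 2 * p * rr / (p + rr)
  expect_equal(round(f1, 4), 0.8297)
  expect_equal(round(f1 * 100, 1), 83.0)  # printed 82.9 stems from unrounded inputs
})

test_that("11-point AP matches hand-traced staircases", {
  gt2 <- data.frame(class = 0L, x1 = c(0, 20), y1 = c(0, 20),
                    x2 = c(10, 30), y2 = c(10, 30))
  # perfect single detection on a single GT
  d <- data.frame(class = 0L, conf = 0.9, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  expect_equal(ap50_11point(d, gt2[1, ]), 1.0)
  # ranked TP, FP, TP over two ground truths: (6*1 + 5*(2/3)) / 11
  d3 <- data.frame(class = 0L, conf = c(0.9, 0.8, 0.7),
                   x1 = c(0, 50, 20), y1 = c(0, 50, 20),
                   x2 = c(10, 60, 30), y2 = c(10, 60, 30))
  expect_equal(ap50_11point(d3, gt2), 28 / 33)
  expect_equal(ap50_11point(d3[0, ], gt2), 0)
  expect_true(is.na(ap50_11point(d3, gt2[0, ])))
})

test_that("AP is order-invariant under confidence rescaling and never helped by duplicate FPs", {
  set.seed(78)
  for (rep in 1:10) {
    gts <- random_boxes(sample(1:4, 1))[, -2]
    dets <- random_boxes(sample(1:6, 1))
    ap <- ap50_11point(dets, gts)
    resc <- dets
    resc$conf <- (rank(dets$conf, ties.method = "first") / (nrow(dets) + 1))^3
    expect_equal(ap50_11point(resc, gts), ap)
    dup <- rbind(dets, data.frame(class = dets$class[1], conf = min(dets$conf) / 2,
                                  x1 = 90, y1 = 90, x2 = 99, y2 = 99))
    expect_lte(ap50_11point(dup, gts), ap + 1e-12)
  }
})

test_that("11-point AP stays inside the exact-interpolation sanity envelope", {
  set.seed(79)
  for (rep in 1:20) {
    gts <- random_boxes(sample(1:5, 1))[, -2]
    dets <- random_boxes(sample(1:8, 1))
    a11 <- ap50_11point(dets, gts)
    aex <- oracle_ap_exact(dets, gts)
    expect_gte(a11, aex - 1 / 11 - 1e-9)
    expect_lte(a11, aex + 1 / 11 + 1e-9)
    expect_equal(a11, oracle_ap11(dets, gts))
  }
})

test_that("mAP is the unweighted class mean and mAP50-95 never exceeds mAP50", {
  gt <- data.frame(class = c(0L, 1L), x1 = c(0, 20), y1 = c(0, 20),
                   x2 = c(10, 30), y2 = c(10, 30))
  d <- data.frame(class = c(0L, 1L), conf = c(0.9, 0.9),
                  x1 = c(0, 70), y1 = c(0, 70), x2 = c(10, 80), y2 = c(10, 80))
  r <- map_over_classes_and_thresholds(d, gt)
  expect_equal(r$map50, 0.5)        # one perfect class, one missed class
  expect_equal(r$map50_95, 0.5)     # the perfect box stays perfect at all IoUs

  set.seed(80)
  for (rep in 1:10) {
    gts <- random_boxes(sample(2:6, 1), classes = 0:2)[, -2]
    dets <- random_boxes(sample(2:9, 1), classes = 0:2)
    r <- map_over_classes_and_thresholds(dets, gts)
    expect_lte(r$map50_95, r$map50 + 1e-12)
    # independent per-class, per-threshold oracle loop
    cls <- sort(unique(gts$class))
    ap50 <- sapply(cls, function(cc)
      oracle_ap11(dets[dets$class == cc, ], gts[gts$class == cc, ], 0.5))
    expect_equal(unname(r$ap50), unname(ap50))
    all_thr <- sapply(cls, function(cc) mean(sapply(seq(0.5, 0.95, 0.05), function(t)
      oracle_ap11(dets[dets$class == cc, ], gts[gts$class == cc, ], t))))
    expect_equal(r$map50_95, mean(all_thr))
  }
  expect_error(map_over_classes_and_thresholds(d, gt[0, ]), "ground truth")
})

test_that("the normalised confusion matrix has unit rows and a working background margin", {
  gt <- data.frame(class = c(0L, 1L), x1 = c(0, 20), y1 = c(0, 20),
                   x2 = c(10, 30), y2 = c(10, 30))
  perfect <- data.frame(class = c(0L, 1L), conf = c(0.9, 0.9),
                        x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30), y2 = c(10, 30))
  cm <- normalized_confusion(perfect, gt, num_classes = 2L)
  expect_equal(cm[1, 1], 1); expect_equal(cm[2, 2], 1)

  none <- perfect[0, ]
  cm0 <- normalized_confusion(none, gt, num_classes = 2L)
  expect_equal(cm0[1, 3], 1); expect_equal(cm0[2, 3], 1)

  # hand-counted mixed case: GT classes (0,0,1); detections: one correct 0,
  # one 0 predicted as 1, one background FP of class 0
  gt3 <- data.frame(class = c(0L, 0L, 1L), x1 = c(0, 40, 20), y1 = c(0, 40, 20),
                    x2 = c(10, 50, 30), y2 = c(10, 50, 30))
  d3 <- data.frame(class = c(0L, 1L, 0L), conf = c(0.9, 0.8, 0.7),
                   x1 = c(0, 40, 70), y1 = c(0, 40, 70),
                   x2 = c(10, 50, 80), y2 = c(10, 50, 80))
  cm3 <- normalized_confusion(d3, gt3, num_classes = 2L)
  expect_equal(cm3[1, ], c(class0 = 0.5, class1 = 0.5, background = 0))
  expect_equal(unname(cm3[2, 3]), 1)        # the class-1 GT went undetected
  expect_equal(unname(cm3[3, 1]), 1)        # background row holds the stray FP
  rs <- rowSums(cm3)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
})
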