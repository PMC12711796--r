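# Detection evaluation: IoU matching, precision/recall/F1, 11-point
# interpolated AP at IoU 0.5, mAP50 and mAP50-95, and a row-normalised
# confusion matrix with a background row/column.
#
# Detections are data frames with columns class (0-based id), conf and
# x1, y1, x2, y2 (continuous pixels); ground truths have class and the box
# columns. Matching is class-aware and greedy in confidence order, each
# ground truth usable at most once.

#' Intersection over union of two boxes
#'
#' @param a,b numeric length-4 vectors `(x1, y1, x2, y2)` with `x2 > x1`
#'   and `y2 > y1`.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box: x2 > x1 and y2 > y1 are required")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / ua
}

empty_dets <- function() data.frame(class = integer(), conf = numeric(),
                                    x1 = numeric(), y1 = numeric(),
                                    x2 = numeric(), y2 = numeric())

#' Match detections against ground truth
#'
#' Detections are processed in descending confidence; each is a true
#' positive iff its best-IoU unmatched same-class ground truth reaches the
#' IoU threshold. Every ground truth can be matched at most once.
#'
#' @param dets detection data frame (`class`, `conf`, box columns).
#' @param gts ground-truth data frame (`class`, box columns).
#' @param iou_thr IoU threshold in `(0, 1)`.
#' @return list with `tp` (logical per detection, in the original row
#'   order), `order` (confidence ranking), `gt_matched` (logical per GT).
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  if (iou_thr <= 0 || iou_thr >= 1) stop("iou_thr must lie in (0, 1)")
  nd <- nrow(dets); ng <- nrow(gts)
  tp <- logical(nd)
  gt_used <- logical(ng)
  gt_of <- rep(NA_integer_, nd)
  ord <- order(-dets$conf)
  for (r in ord) {
    best <- 0; best_g <- 0L
    if (ng > 0) for (gi in seq_len(ng)) {
      if (gt_used[gi] || gts$class[gi] != dets$class[r]) next
      v <- box_iou(as.numeric(dets[r, c("x1", "y1", "x2", "y2")]),
                   as.numeric(gts[gi, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; best_g <- gi }
    }
    if (best >= iou_thr && best_g > 0L) {
      tp[r] <- TRUE
      gt_used[best_g] <- TRUE
      gt_of[r] <- best_g
    }
  }
  list(tp = tp, order = ord, gt_matched = gt_used, gt_of = gt_of)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; any
#' zero-denominator case returns 0 by convention.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' 11-point interpolated average precision for one class
#'
#' Traces precision/recall in confidence order at the given IoU threshold
#' and averages, over the recall nodes 0.0, 0.1, ..., 1.0, the maximum
#' precision attained at recall >= node.
#'
#' @param dets single-class detections.
#' @param gts single-class ground truths.
#' @param iou_thr matching IoU threshold (default 0.5).
#' @return AP in `[0, 1]`; `NA` if there are no ground truths (such a
#'   class is excluded from the class mean).
#' @export
ap50_11point <- function(dets, gts, iou_thr = 0.5) {
  ng <- nrow(gts)
  if (ng == 0L) return(NA_real_)
  if (nrow(dets) == 0L) return(0)
  mt <- match_detections(dets, gts, iou_thr)
  tp_ranked <- mt$tp[mt$order]
  cum_tp <- cumsum(tp_ranked)
  cum_fp <- cumsum(!tp_ranked)
  prec <- cum_tp / (cum_tp + cum_fp)
  rec <- cum_tp / ng
  nodes <- seq(0, 1, by = 0.1)
  ap <- 0
  for (r0 in nodes) {
    ok <- rec >= r0 - 1e-12
    ap <- ap + if (any(ok)) max(prec[ok]) else 0
  }
  ap / 11
}

#' Class-mean AP at IoU 0.5 and averaged over IoU 0.5-0.95
#'
#' @param dets detections over all classes.
#' @param gts ground truths over all classes.
#' @param classes class ids to evaluate; defaults to all ids present in
#'   the ground truth. Classes without ground truth are excluded.
#' @return list with `map50`, `map50_95` and the per-class `ap50` vector.
#' @export
map_over_classes_and_thresholds <- function(dets, gts, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(gts$class))
  classes <- classes[classes %in% gts$class]
  if (!length(classes)) stop("no class with ground truth to evaluate")
  thrs <- seq(0.5, 0.95, by = 0.05)
  ap50 <- setNames(numeric(length(classes)), classes)
  ap_all <- matrix(0, nrow = length(classes), ncol = length(thrs))
  for (ci in seq_along(classes)) {
    dc <- dets[dets$class == classes[ci], , drop = FALSE]
    gc <- gts[gts$class == classes[ci], , drop = FALSE]
    for (ti in seq_along(thrs))
      ap_all[ci, ti] <- ap50_11point(dc, gc, thrs[ti])
    ap50[ci] <- ap_all[ci, 1]
  }
  list(map50 = mean(ap50), map50_95 = mean(rowMeans(ap_all)), ap50 = ap50)
}

#' Full detection evaluation
#'
#' Counts TP/FP/FN at a fixed confidence threshold and IoU 0.5, and
#' computes the ranked AP summaries.
#'
#' @param dets,gts detection / ground-truth data frames.
#' @param conf_thr confidence threshold for the P/R/F1 counts.
#' @param iou_thr matching IoU threshold.
#' @return list of class `lbs_eval` with counts, precision/recall/F1,
#'   per-class AP50, mAP50 and mAP50-95.
#' @export
evaluate_detections <- function(dets, gts, conf_thr = 0.25, iou_thr = 0.5) {
  dk <- dets[dets$conf >= conf_thr, , drop = FALSE]
  mt <- match_detections(dk, gts, iou_thr)
  tp <- sum(mt$tp); fp <- nrow(dk) - tp; fn <- nrow(gts) - tp
  prf <- precision_recall_f1(tp, fp, fn)
  maps <- map_over_classes_and_thresholds(dets, gts)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = prf[["precision"]], recall = prf[["recall"]],
                 f1 = prf[["f1"]], ap50 = maps$ap50,
                 map50 = maps$map50, map50_95 = maps$map50_95),
            class = "lbs_eval")
}

#' Row-normalised confusion matrix with background
#'
#' Rows are true classes plus a background row (false positives); columns
#' are predicted classes plus a background column (missed ground truths).
#' Matching is class-agnostic here so that cross-class confusions are
#' visible; each non-empty true-class row sums to 1.
#'
#' @param dets,gts detection / ground-truth data frames.
#' @param iou_thr IoU threshold for associating boxes.
#' @param conf_thr detections below this confidence are ignored.
#' @param num_classes number of classes.
#' @return `(num_classes + 1) x (num_classes + 1)` matrix.
#' @export
normalized_confusion <- function(dets, gts, iou_thr = 0.45, conf_thr = 0.25,
                                 num_classes = 5L) {
  if (iou_thr <= 0 || iou_thr >= 1 || conf_thr < 0 || conf_thr > 1)
    stop("invalid thresholds")
  k <- num_classes + 1L
  cm <- matrix(0, k, k,
               dimnames = list(true = c(paste0("class", 0:(num_classes - 1)), "background"),
                               pred = c(paste0("class", 0:(num_classes - 1)), "background")))
  dk <- dets[dets$conf >= conf_thr, , drop = FALSE]
  dk <- dk[order(-dk$conf), , drop = FALSE]
  ng <- nrow(gts)
  gt_used <- logical(ng)
  for (r in seq_len(nrow(dk))) {
    best <- 0; best_g <- 0L
    if (ng > 0) for (gi in seq_len(ng)) {
      if (gt_used[gi]) next
      v <- box_iou(as.numeric(dk[r, c("x1", "y1", "x2", "y2")]),
                   as.numeric(gts[gi, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; best_g <- gi }
    }
    if (best >= iou_thr && best_g > 0L) {
      gt_used[best_g] <- TRUE
      cm[gts$class[best_g] + 1L, dk$class[r] + 1L] <-
        cm[gts$class[best_g] + 1L, dk$class[r] + 1L] + 1
    } else {
      cm[k, dk$class[r] + 1L] <- cm[k, dk$class[r] + 1L] + 1  # background row
    }
  }
  if (ng > 0) for (gi in which(!gt_used))
    cm[gts$class[gi] + 1L, k] <- cm[gts$class[gi] + 1L, k] + 1
  for (i in seq_len(k)) {
    s <- sum(cm[i, ])
    if (s > 0) cm[i, ] <- cm[i, ] / s
  }
  cm
}

#' Evaluate prediction and ground-truth label directories
#'
#' Reads YOLO-format label files (`class cx cy w h [conf]`, normalised)
#' from two directories with matching file names, evaluates them jointly
#' and optionally writes a JSON metrics report.
#'
#' @param pred_dir directory of prediction label files (with confidence).
#' @param gt_dir directory of ground-truth label files.
#' @param image_size `c(width, height)` used to de-normalise coordinates.
#' @param out optional path of the JSON report.
#' @param conf_thr,iou_thr thresholds for the counting metrics.
#' @return the `lbs_eval` result, invisibly when `out` is given.
#' @export
evaluate_label_dirs <- function(pred_dir, gt_dir, image_size = c(640L, 640L),
                                out = NULL, conf_thr = 0.25, iou_thr = 0.5) {
  gfiles <- sort(list.files(gt_dir, pattern = "\\.txt$"))
  dets <- list(); gts <- list()
  for (f in gfiles) {
    g <- read_yolo_labels(file.path(gt_dir, f), image_size)
    pfile <- file.path(pred_dir, f)
    p <- if (file.exists(pfile)) read_yolo_labels(pfile, image_size) else empty_dets()
    # offset each image into its own coordinate slab so boxes never
    # interact across images
    off <- (match(f, gfiles) - 1) * (max(image_size) * 4)
    for (cc in c("x1", "x2")) { g[[cc]] <- g[[cc]] + off; p[[cc]] <- p[[cc]] + off }
    gts[[f]] <- g; dets[[f]] <- p
  }
  gts <- do.call(rbind, gts); dets <- do.call(rbind, dets)
  if (is.null(dets$conf) || all(is.na(dets$conf))) dets$conf <- 1
  res <- evaluate_detections(dets, gts, conf_thr, iou_thr)
  if (!is.null(out)) {
    jsonlite::write_json(list(tp = res$tp, fp = res$fp, fn = res$fn,
                              precision = res$precision, recall = res$recall,
                              f1 = res$f1, ap50 = as.list(res$ap50),
                              map50 = res$map50, map50_95 = res$map50_95),
                         out, auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}

#' @export
print.lbs_eval <- function(x, ...) {
  cat(sprintf("detection eval: TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  cat(sprintf("  mAP50 %.4f  mAP50-95 %.4f\n", x$map50, x$map50_95))
  invisible(x)
}
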