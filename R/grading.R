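# Ripeness annotation pipeline: box-initialised graph-cut segmentation of
# the fruit, HSV red-pixel proportion inside the segmented mask, and
# five-grade maturity assignment.
#
# Segmentation follows the GrabCut scheme: pixels outside the user box are
# definite background; the box interior starts as probable foreground;
# Gaussian-mixture colour models of both regions are refitted and an s-t
# minimum cut of the pixel lattice (data terms from the mixture
# log-likelihoods, contrast-sensitive smoothness terms) reassigns the
# interior, iterating a fixed number of times. The minimum cut is computed
# with igraph; mixture fitting uses a deterministic quantile-seeded k-means
# so the whole pipeline is RNG-free.

#' Grading thresholds
#'
#' Grade boundaries on the red-pixel fraction and the HSV red gamut.
#' The upper-grade onsets 0.5 / 0.8 / 0.9 follow the five-grade maturity
#' standard ("half or more", "80% or more", "90% or more"); the
#' breaker onset and the red gamut are configurable repository defaults.
#'
#' @param t_breaker onset of the breaker grade.
#' @param t_half,t_commercial,t_full onsets of the upper grades.
#' @param hue_max,hue_min red hue bounds in degrees: a hue is red when
#'   `<= hue_max` or `>= hue_min`.
#' @param sat_min,val_min minimum saturation and value of a red pixel.
#' @return an object of class `lbs_grade_thresholds`.
#' @export
grade_thresholds <- function(t_breaker = 0.05, t_half = 0.5,
                             t_commercial = 0.8, t_full = 0.9,
                             hue_max = 20, hue_min = 340,
                             sat_min = 0.25, val_min = 0.20) {
  if (!(0 < t_breaker && t_breaker < t_half && t_half < t_commercial &&
        t_commercial < t_full && t_full < 1))
    stop("thresholds must satisfy 0 < breaker < half < commercial < full < 1")
  structure(list(t_breaker = t_breaker, t_half = t_half,
                 t_commercial = t_commercial, t_full = t_full,
                 hue_max = hue_max, hue_min = hue_min,
                 sat_min = sat_min, val_min = val_min),
            class = "lbs_grade_thresholds")
}

#' Grade a red fraction
#'
#' Grade boundaries are inclusive on the upper side ("or more"): 0.5, 0.8
#' and 0.9 map to half-ripe, commercially-ripe and fully-ripe.
#'
#' @param fraction red-pixel fraction in `[0, 1]`.
#' @param thresholds a [grade_thresholds()].
#' @return list with `grade` (name) and `id` (0-based class id).
#' @export
grade_maturity <- function(fraction, thresholds = grade_thresholds()) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  id <- if (fraction < thresholds$t_breaker) 0L
        else if (fraction < thresholds$t_half) 1L
        else if (fraction < thresholds$t_commercial) 2L
        else if (fraction < thresholds$t_full) 3L
        else 4L
  list(grade = ripeness_grades()[id + 1L], id = id)
}

#' Red-pixel fraction of a masked region
#'
#' Converts the masked pixels to HSV and reports the share whose hue falls
#' in the red gamut with sufficient saturation and value.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param mask `H x W` logical mask; must select at least one pixel.
#' @param thresholds a [grade_thresholds()] carrying the red gamut.
#' @return fraction in `[0, 1]`.
#' @export
red_fraction <- function(image, mask, thresholds = grade_thresholds()) {
  if (!any(mask)) stop("red_fraction: empty mask")
  idx <- which(mask)
  n <- length(idx)
  hsv <- grDevices::rgb2hsv(r = image[idx], g = image[idx + length(mask)],
                            b = image[idx + 2 * length(mask)], maxColorValue = 1)
  hue <- hsv[1, ] * 360
  red <- (hue <= thresholds$hue_max | hue >= thresholds$hue_min) &
    hsv[2, ] >= thresholds$sat_min & hsv[3, ] >= thresholds$val_min
  sum(red) / n
}

# deterministic diagonal-covariance Gaussian mixture fit: quantile-seeded
# Lloyd iterations (empty clusters dropped) followed by per-cluster moments
fit_gmm <- function(X, K = 5L, iters = 6L) {
  n <- nrow(X)
  K <- max(1L, min(K, n))
  lum <- as.numeric(X %*% c(0.299, 0.587, 0.114))
  seeds <- X[order(lum)[unique(round(seq(1, n, length.out = K)))], , drop = FALSE]
  seeds <- unique(seeds)
  for (it in seq_len(iters)) {
    d2 <- vapply(seq_len(nrow(seeds)), function(k)
      rowSums(sweep(X, 2, seeds[k, ])^2), numeric(n))
    cl <- max.col(-matrix(d2, nrow = n), ties.method = "first")
    keep <- sort(unique(cl))
    seeds <- t(vapply(keep, function(k) colMeans(X[cl == k, , drop = FALSE]),
                      numeric(ncol(X))))
  }
  lapply(seq_len(nrow(seeds)), function(k) {
    Xi <- X[cl == keep[k], , drop = FALSE]
    v <- if (nrow(Xi) > 1L) apply(Xi, 2, stats::var) else rep(0, ncol(X))
    list(w = nrow(Xi) / n, mu = colMeans(Xi), var = pmax(v, 1e-4))
  })
}

gmm_nll <- function(comps, X) {
  n <- nrow(X)
  dens <- matrix(-Inf, n, length(comps))
  for (k in seq_along(comps)) {
    cm <- comps[[k]]
    d2 <- sweep(X, 2, cm$mu)^2
    dens[, k] <- log(cm$w) - 0.5 * sum(log(2 * pi * cm$var)) -
      0.5 * (d2 %*% (1 / cm$var))
  }
  mx <- apply(dens, 1, max)
  -(mx + log(rowSums(exp(dens - mx))))
}

#' Box-initialised graph-cut foreground segmentation
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param box numeric `(x1, y1, x2, y2)` in pixels, inside the image, with
#'   positive area.
#' @param iterations refit/cut iterations (default 5).
#' @param gamma smoothness strength of the contrast-sensitive pairwise
#'   term.
#' @return `H x W` logical mask, refined to its largest connected
#'   component (a fruit is a single blob, so slivers of neighbouring
#'   objects caught inside the box are dropped). If the cut leaves no
#'   foreground or the colour models are uninformative (for example on a
#'   constant-colour image), a warning is raised and the box interior is
#'   returned as fallback.
#' @export
segment_foreground <- function(image, box, iterations = 5L, gamma = 50) {
  H <- dim(image)[1]; W <- dim(image)[2]
  x1 <- floor(box[1]) + 1L; y1 <- floor(box[2]) + 1L
  x2 <- ceiling(box[3]); y2 <- ceiling(box[4])
  if (box[3] <= box[1] || box[4] <= box[2]) stop("box has non-positive area")
  if (x1 < 1L || y1 < 1L || x2 > W || y2 > H) stop("box outside the image")
  bw <- x2 - x1 + 1L; bh <- y2 - y1 + 1L
  npix <- bw * bh

  # pixel colours
  flat <- function(yy, xx) cbind(image[cbind(yy, xx, 1)],
                                 image[cbind(yy, xx, 2)],
                                 image[cbind(yy, xx, 3)])
  in_y <- rep(y1:y2, times = bw); in_x <- rep(x1:x2, each = bh)
  Xin <- flat(in_y, in_x)
  out_mask <- matrix(TRUE, H, W); out_mask[y1:y2, x1:x2] <- FALSE
  oidx <- which(out_mask)
  if (length(oidx) > 4000L)
    oidx <- oidx[round(seq(1, length(oidx), length.out = 4000L))]
  oy <- ((oidx - 1L) %% H) + 1L; ox <- ((oidx - 1L) %/% H) + 1L
  Xbg_out <- flat(oy, ox)

  # lattice edges inside the box (4-neighbourhood); node id = row-major
  # within the box: id = (x - x1) * bh + (y - y1) + 1
  nid <- function(y, x) (x - x1) * bh + (y - y1) + 1L
  er_a <- nid(rep(y1:(y2 - 1L), times = bw), rep(x1:x2, each = bh - 1L))
  er_b <- er_a + 1L
  ec_a <- nid(rep(y1:y2, times = bw - 1L), rep(x1:(x2 - 1L), each = bh))
  ec_b <- ec_a + bh
  pair_a <- c(er_a, ec_a); pair_b <- c(er_b, ec_b)
  dif2 <- rowSums((Xin[pair_a, , drop = FALSE] - Xin[pair_b, , drop = FALSE])^2)
  beta <- 1 / max(2 * mean(dif2), 1e-8)
  wpair <- gamma * exp(-beta * dif2)

  fg <- rep(TRUE, npix)  # initial foreground = box interior
  src <- npix + 1L; snk <- npix + 2L
  big <- 1e9
  for (it in seq_len(iterations)) {
    Xfg <- Xin[fg, , drop = FALSE]
    if (nrow(Xfg) < 8L) break
    Xbg <- rbind(Xbg_out, Xin[!fg, , drop = FALSE])
    gm_fg <- fit_gmm(Xfg); gm_bg <- fit_gmm(Xbg)
    d_fg <- pmin(gmm_nll(gm_fg, Xin), big)   # cost of labelling fg
    d_bg <- pmin(gmm_nll(gm_bg, Xin), big)   # cost of labelling bg
    if (it == 1L && max(abs(d_fg - d_bg)) < 1e-6) {
      # colour models carry no information (e.g. a constant image)
      warning("graph cut produced an empty mask; falling back to the box interior")
      mask <- matrix(FALSE, H, W)
      mask[y1:y2, x1:x2] <- TRUE
      return(mask)
    }
    off <- min(d_fg, d_bg)
    gr <- igraph::graph_from_edgelist(
      cbind(c(pair_a, rep(src, npix), seq_len(npix)),
            c(pair_b, seq_len(npix), rep(snk, npix))), directed = FALSE)
    cap <- c(wpair, d_bg - off + 1e-6, d_fg - off + 1e-6)
    ct <- igraph::min_cut(gr, source = src, target = snk, capacity = cap,
                          value.only = FALSE)
    side_src <- if (src %in% ct$partition1) ct$partition1 else ct$partition2
    new_fg <- seq_len(npix) %in% as.integer(side_src)
    if (identical(new_fg, fg)) { fg <- new_fg; break }
    fg <- new_fg
  }

  mask <- matrix(FALSE, H, W)
  if (!any(fg)) {
    warning("graph cut produced an empty mask; falling back to the box interior")
    mask[y1:y2, x1:x2] <- TRUE
    return(mask)
  }
  sel <- cbind(in_y[fg], in_x[fg])
  mask[sel] <- TRUE
  largest_component(mask)
}

# keep only the largest 4-connected component of a binary mask (the fruit
# is a single blob; slivers of neighbouring objects inside the box are
# dropped)
largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  best <- integer(0); best_n <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    comp <- integer(0)
    lab[start] <- nxt
    H <- nrow(mask)
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      comp <- c(comp, p)
      y <- ((p - 1L) %% H) + 1L; x <- ((p - 1L) %/% H) + 1L
      for (q in c(if (y > 1L) p - 1L, if (y < H) p + 1L,
                  if (x > 1L) p - H, if (x < ncol(mask)) p + H)) {
        if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
      }
    }
    if (length(comp) > best_n) { best <- comp; best_n <- length(comp) }
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[best] <- TRUE
  out
}

#' Annotate fruits in an image
#'
#' For every box: graph-cut segmentation, red-pixel fraction, maturity
#' grade, and a YOLO label row. A record is flagged for manual review when
#' the mask-based red fraction and a segmentation-free estimate over the
#' box's inscribed ellipse disagree by more than `review_gap` (occlusion
#' or segmentation trouble tends to underestimate the visible red share).
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param boxes data frame (or matrix) with `x1, y1, x2, y2` pixel columns.
#' @param thresholds a [grade_thresholds()].
#' @param iterations graph-cut iterations.
#' @param review_gap disagreement threshold that raises the review flag.
#' @return list with `records` (one row per fruit: box, `red_fraction`,
#'   `grade`, `class`, `needs_review`) and `labels` (data frame ready for
#'   [write_yolo_labels()]).
#' @export
annotate_image <- function(image, boxes, thresholds = grade_thresholds(),
                           iterations = 5L, review_gap = 0.2) {
  boxes <- as.data.frame(boxes)
  n <- nrow(boxes)
  if (n == 0L)
    return(list(records = data.frame(),
                labels = data.frame(class = integer(), x1 = numeric(),
                                    y1 = numeric(), x2 = numeric(),
                                    y2 = numeric())))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    bx <- as.numeric(boxes[i, c("x1", "y1", "x2", "y2")])
    mask <- segment_foreground(image, bx, iterations)
    rf <- red_fraction(image, mask, thresholds)
    # segmentation-free comparison estimate over the box's inscribed
    # ellipse (the expected fruit footprint)
    cy <- (bx[2] + bx[4]) / 2; cx <- (bx[1] + bx[3]) / 2
    ry <- (bx[4] - bx[2]) / 2; rx <- (bx[3] - bx[1]) / 2
    yy <- row(matrix(0, dim(image)[1], dim(image)[2]))
    xx <- col(matrix(0, dim(image)[1], dim(image)[2]))
    boxmask <- ((xx - 0.5 - cx) / rx)^2 + ((yy - 0.5 - cy) / ry)^2 <= 1
    rf_box <- red_fraction(image, boxmask, thresholds)
    gr <- grade_maturity(rf, thresholds)
    recs[[i]] <- data.frame(x1 = bx[1], y1 = bx[2], x2 = bx[3], y2 = bx[4],
                            red_fraction = rf, grade = gr$grade,
                            class = gr$id,
                            needs_review = abs(rf - rf_box) > review_gap)
  }
  records <- do.call(rbind, recs)
  list(records = records,
       labels = data.frame(class = records$class, x1 = records$x1,
                           y1 = records$y1, x2 = records$x2, y2 = records$y2))
}

#' Read an RGB image
#'
#' PNG images are read natively; JPEG files are supported when the EBImage
#' package is installed.
#'
#' @param path image file path.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    e <- EBImage::readImage(path)
    img <- aperm(as.array(e), c(2, 1, 3))
  } else {
    stop("only PNG images are supported without EBImage: ", path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}
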