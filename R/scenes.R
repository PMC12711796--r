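# Synthetic strawberry-like scenes with exact ground truth.
#
# Fruits are rendered as axis-aligned ellipses whose red-coloured region is
# an angular sector growing from the fruit tip (the bottom of the ellipse),
# mimicking the tip-first ripening gradient of real strawberries; the
# sector is sized by pixel count, so the rendered red share matches the
# requested coverage up to rasterisation. Leaf-shaped green occluders and a
# textured soil background provide clutter. A scene is a pure function of
# its specification, including the seed.

#' Scene specification
#'
#' @param image_size square image side in pixels.
#' @param n_fruits integer range `c(min, max)` of fruits per scene.
#' @param axis_range range of the fruit semi-minor axis in pixels.
#' @param coverages either `NULL` (sampled according to `class_mix`) or an
#'   explicit vector of red-coverage fractions in `[0, 1]`, one per fruit.
#' @param class_mix probabilities over the five ripeness classes used when
#'   sampling coverages; default balanced.
#' @param n_occluders integer range of leaf occluders.
#' @param occluder_opacity alpha of the occluders in `[0, 1]`.
#' @param noise_scale amplitude of the background texture noise.
#' @param seed integer seed; the scene is a deterministic function of the
#'   full specification.
#' @return an object of class `lbs_scene_spec`.
#' @export
scene_spec <- function(image_size = 192L, n_fruits = c(3L, 5L),
                       axis_range = c(14L, 26L), coverages = NULL,
                       class_mix = rep(0.2, 5), n_occluders = c(0L, 2L),
                       occluder_opacity = 0.9, noise_scale = 0.04,
                       seed = 0L) {
  if (!is.null(coverages) && (any(coverages < 0) || any(coverages > 1)))
    stop("coverages must lie in [0, 1]")
  if (length(class_mix) != 5L || any(class_mix < 0))
    stop("class_mix must be five non-negative weights")
  structure(list(image_size = as.integer(image_size),
                 n_fruits = as.integer(n_fruits),
                 axis_range = as.numeric(axis_range),
                 coverages = coverages,
                 class_mix = class_mix / sum(class_mix),
                 n_occluders = as.integer(n_occluders),
                 occluder_opacity = occluder_opacity,
                 noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "lbs_scene_spec")
}

# coverage intervals per class, kept off the grade boundaries so that
# rasterisation cannot flip the true class
class_coverage_range <- function(class_id) {
  switch(class_id + 1L,
         c(0.000, 0.035),   # unripe
         c(0.070, 0.470),   # breaker
         c(0.520, 0.780),   # half-ripe
         c(0.810, 0.885),   # commercially-ripe
         c(0.915, 1.000))   # fully-ripe
}

#' Generate one synthetic scene
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`H x W x 3` array in `[0, 1]`) and `truth`,
#'   a data frame with one row per fruit: `class`, `coverage` (requested),
#'   `red_share` (rasterised red share actually rendered), `x1, y1, x2, y2`
#'   (tight pixel box) plus the scene `seed`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  if (!inherits(spec, "lbs_scene_spec")) stop("spec must be a scene_spec()")
  set.seed(spec$seed)
  S <- spec$image_size
  if (max(spec$axis_range) * 2.4 >= S)
    stop("fruit axis range too large for the image size")

  # textured soil background
  img <- array(0, c(S, S, 3))
  base <- c(0.36, 0.26, 0.17)
  tex <- matrix(stats::runif(S * S, -1, 1), S, S)
  tex <- avg_pool3(array(tex, c(1, 1, S, S)))[1, 1, , ] * 3  # smoothed
  for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + spec$noise_scale * tex, 0), 1)

  nf <- if (spec$n_fruits[1] == spec$n_fruits[2]) spec$n_fruits[1]
        else sample(spec$n_fruits[1]:spec$n_fruits[2], 1L)
  cov <- spec$coverages
  cls <- integer(nf)
  if (is.null(cov)) {
    cls <- sample(0:4, nf, replace = TRUE, prob = spec$class_mix)
    cov <- vapply(cls, function(k) {
      rg <- class_coverage_range(k); stats::runif(1, rg[1], rg[2])
    }, numeric(1))
  } else {
    if (length(cov) < nf) nf <- length(cov)
    cov <- cov[seq_len(nf)]
    cls <- vapply(cov, function(p) grade_maturity(p)$id, integer(1))
  }

  yy <- matrix(seq_len(S), S, S)          # row index = y
  xx <- matrix(seq_len(S), S, S, byrow = TRUE)
  truth <- NULL
  centers <- matrix(0, 0, 3)  # cx, cy, enclosing radius
  for (i in seq_len(nf)) {
    b <- stats::runif(1, spec$axis_range[1], spec$axis_range[2])  # semi-x
    a <- b * stats::runif(1, 1.05, 1.3)                           # semi-y
    ok <- FALSE
    for (try in 1:40) {
      cx <- stats::runif(1, b + 2, S - b - 1)
      cy <- stats::runif(1, a + 2, S - a - 1)
      # fruits must not interpenetrate: a later fruit would repaint an
      # earlier one and corrupt its ground-truth red share
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) -
                centers[, 3]) > 1.02 * max(a, b)) {
        ok <- TRUE; break
      }
    }
    if (!ok) next
    centers <- rbind(centers, c(cx, cy, max(a, b)))
    inside <- ((xx - cx) / b)^2 + ((yy - cy) / a)^2 <= 1
    n_in <- sum(inside)
    if (n_in < 8L) next
    # angular deviation from the tip axis (tip points down, +y)
    theta <- abs(atan2(xx[inside] - cx, yy[inside] - cy))   # 0 at the tip
    k_red <- round(cov[i] * n_in)
    red_sel <- logical(n_in)
    if (k_red > 0) red_sel[order(theta)[seq_len(k_red)]] <- TRUE
    idx <- which(inside)
    speck <- stats::runif(n_in, -0.03, 0.03)
    colr <- cbind(0.80 + speck, 0.10 + speck / 2, 0.12 + speck / 2) # ripe red
    colg <- cbind(0.55 + speck, 0.74 + speck, 0.38 + speck)         # unripe green-white
    px <- ifelse(red_sel, colr[, 1], colg[, 1])
    pg <- ifelse(red_sel, colr[, 2], colg[, 2])
    pb <- ifelse(red_sel, colr[, 3], colg[, 3])
    img[idx] <- pmin(pmax(px, 0), 1)
    img[idx + S * S] <- pmin(pmax(pg, 0), 1)
    img[idx + 2 * S * S] <- pmin(pmax(pb, 0), 1)
    xs <- range(xx[inside]); ys <- range(yy[inside])
    truth <- rbind(truth, data.frame(
      class = cls[i], coverage = cov[i], red_share = k_red / n_in,
      x1 = xs[1] - 1, y1 = ys[1] - 1, x2 = xs[2], y2 = ys[2]))
  }
  if (is.null(truth))
    truth <- data.frame(class = integer(), coverage = numeric(),
                        red_share = numeric(), x1 = numeric(), y1 = numeric(),
                        x2 = numeric(), y2 = numeric())

  no <- if (spec$n_occluders[2] > 0)
    sample(spec$n_occluders[1]:spec$n_occluders[2], 1L) else 0L
  for (j in seq_len(no)) {
    b <- stats::runif(1, 8, 18); a <- stats::runif(1, 4, 9)
    cx <- stats::runif(1, 1, S); cy <- stats::runif(1, 1, S)
    ang <- stats::runif(1, 0, pi)
    xr <- (xx - cx) * cos(ang) + (yy - cy) * sin(ang)
    yr <- -(xx - cx) * sin(ang) + (yy - cy) * cos(ang)
    leaf <- (xr / b)^2 + (yr / a)^2 <= 1
    al <- spec$occluder_opacity
    lc <- c(0.20, 0.47, 0.18)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[leaf] <- (1 - al) * plane[leaf] + al * lc[ch]
      img[, , ch] <- plane
    }
  }
  truth$seed <- spec$seed
  list(image = img, truth = truth)
}

#' Write a synthetic dataset in YOLO layout
#'
#' Produces `images/*.png`, `labels/*.txt` and a `data.yaml` naming the
#' five ripeness classes. Optionally emulates class imbalance through the
#' sampling mix and then augments scenes containing rare classes with a
#' horizontal flip and a +/-15 degree rotation.
#'
#' @param n number of base scenes.
#' @param out_dir output directory (created if missing).
#' @param class_mix sampling probabilities of the five classes.
#' @param seed integer seed.
#' @param image_size square image side.
#' @param augment_classes class ids whose scenes are additionally
#'   flip/rotate augmented (`NULL` for none).
#' @param augment_factor extra augmented copies per matching scene (1 or 2).
#' @return data frame listing the written images, their label files and
#'   the classes they contain.
#' @export
generate_dataset <- function(n, out_dir, class_mix = rep(0.2, 5), seed = 0L,
                             image_size = 192L, augment_classes = NULL,
                             augment_factor = 1L) {
  stopifnot(n >= 1L)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  emit <- function(stem, img, truth) {
    ipath <- file.path(out_dir, "images", paste0(stem, ".png"))
    lpath <- file.path(out_dir, "labels", paste0(stem, ".txt"))
    png::writePNG(img, ipath)
    write_yolo_labels(truth, lpath, c(dim(img)[2], dim(img)[1]))
    rows[[length(rows) + 1L]] <<- data.frame(
      image = ipath, label = lpath,
      classes = paste(sort(unique(truth$class)), collapse = ","))
  }
  for (i in seq_len(n)) {
    sp <- scene_spec(image_size = image_size, class_mix = class_mix,
                     seed = seed * 100003L + i)
    sc <- generate_scene(sp)
    if (nrow(sc$truth) == 0L) next
    emit(sprintf("scene_%04d", i), sc$image, sc$truth)
    if (!is.null(augment_classes) &&
        any(sc$truth$class %in% augment_classes) && augment_factor >= 1L) {
      fl <- flip_h(sc$image, sc$truth)
      emit(sprintf("scene_%04d_flip", i), fl$image, fl$truth)
      if (augment_factor >= 2L) {
        rt <- rotate_scene(sc$image, sc$truth, 15 * pi / 180)
        emit(sprintf("scene_%04d_rot", i), rt$image, rt$truth)
      }
    }
  }
  df <- do.call(rbind, rows)
  yaml::write_yaml(list(path = normalizePath(out_dir),
                        train = "images", val = "images",
                        names = as.list(setNames(ripeness_grades(),
                                                 as.character(0:4)))),
                   file.path(out_dir, "data.yaml"))
  df
}

flip_h <- function(img, truth) {
  W <- dim(img)[2]
  out <- img[, W:1, , drop = FALSE]
  t2 <- truth
  t2$x1 <- W - truth$x2
  t2$x2 <- W - truth$x1
  list(image = out, truth = t2)
}

rotate_scene <- function(img, truth, angle) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  # inverse map (nearest neighbour)
  xs <- cos(angle) * (xx - cx) + sin(angle) * (yy - cy) + cx
  ys <- -sin(angle) * (xx - cx) + cos(angle) * (yy - cy) + cy
  xi <- pmin(pmax(round(xs), 1), W); yi <- pmin(pmax(round(ys), 1), H)
  out <- array(0, dim(img))
  for (ch in 1:3) {
    plane <- img[, , ch]
    out[, , ch] <- matrix(plane[cbind(as.vector(yi), as.vector(xi))], H, W)
  }
  t2 <- truth
  for (i in seq_len(nrow(truth))) {
    xsq <- c(truth$x1[i], truth$x2[i], truth$x1[i], truth$x2[i])
    ysq <- c(truth$y1[i], truth$y1[i], truth$y2[i], truth$y2[i])
    xr <- cos(angle) * (xsq - cx) - sin(angle) * (ysq - cy) + cx
    yr <- sin(angle) * (xsq - cx) + cos(angle) * (ysq - cy) + cy
    t2$x1[i] <- max(min(xr), 0); t2$x2[i] <- min(max(xr), W)
    t2$y1[i] <- max(min(yr), 0); t2$y2[i] <- min(max(yr), H)
  }
  list(image = out, truth = t2)
}

#' The five ripeness grade names in class-id order
#' @return character vector of length 5.
#' @export
ripeness_grades <- function()
  c("unripe", "breaker", "half-ripe", "commercially-ripe", "fully-ripe")

#' Deterministic train/validation/test split
#'
#' Shuffles the items with the given seed and apportions the split sizes
#' by the largest-remainder method, so the sizes are as close as possible
#' to the exact ratios while always summing to `length(items)`.
#'
#' @param items vector or list of items to split.
#' @param ratios three positive ratio weights, default `c(7, 2, 1)`.
#' @param seed shuffle seed.
#' @return named list `train`, `val`, `test`; disjoint, union = items.
#' @export
split_dataset <- function(items, ratios = c(7, 2, 1), seed = 0L) {
  if (length(ratios) != 3L || any(ratios <= 0)) stop("ratios must be 3 positive numbers")
  n <- length(items)
  q <- n * ratios / sum(ratios)
  sizes <- floor(q)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(q - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  i1 <- perm[seq_len(sizes[1])]
  i2 <- perm[sizes[1] + seq_len(sizes[2])]
  i3 <- perm[sizes[1] + sizes[2] + seq_len(sizes[3])]
  list(train = items[sort(i1)], val = items[sort(i2)], test = items[sort(i3)])
}
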