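# Independent brute-force oracles used to cross-check the package's
# vectorised implementations. Everything here is deliberately written as
# plain nested loops over array indices and shares no code with R/.

oracle_conv <- function(x, w, b = NULL, stride = 1L, pad = NULL, groups = 1L) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cing <- dim(w)[3]; cout <- dim(w)[4]
  if (is.null(pad)) pad <- kh %/% 2L
  coutg <- cout %/% groups
  H2 <- (H + 2 * pad - kh) %/% stride + 1L
  W2 <- (W + 2 * pad - kw) %/% stride + 1L
  out <- array(0, c(B, cout, H2, W2))
  for (bb in 1:B) for (oc in 1:cout) {
    grp <- (oc - 1L) %/% coutg
    for (i in 1:H2) for (j in 1:W2) {
      acc <- 0
      for (ci in 1:cing) for (ki in 1:kh) for (kj in 1:kw) {
        yy <- (i - 1L) * stride + ki - pad
        xx <- (j - 1L) * stride + kj - pad
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W)
          acc <- acc + x[bb, grp * cing + ci, yy, xx] * w[ki, kj, ci, oc]
      }
      out[bb, oc, i, j] <- acc + if (is.null(b)) 0 else b[oc]
    }
  }
  out
}

oracle_avgpool3 <- function(x) {
  d <- dim(x)
  out <- array(0, d)
  for (bb in 1:d[1]) for (cc in 1:d[2]) for (i in 1:d[3]) for (j in 1:d[4]) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      yy <- i + di; xx <- j + dj
      if (yy >= 1 && yy <= d[3] && xx >= 1 && xx <= d[4])
        acc <- acc + x[bb, cc, yy, xx]
    }
    out[bb, cc, i, j] <- acc / 9
  }
  out
}

oracle_unfold <- function(x) {
  d <- dim(x)
  H <- d[3] %/% 2L; W <- d[4] %/% 2L
  out <- array(0, c(d[1], d[2], H, W, 4L))
  for (bb in 1:d[1]) for (cc in 1:d[2]) for (i in 1:H) for (j in 1:W)
    for (k in 1:4)
      out[bb, cc, i, j, k] <-
        x[bb, cc, 2L * i - 1L + (k - 1L) %/% 2L, 2L * j - 1L + (k - 1L) %% 2L]
  out
}

# step-by-step LAWDS composition using the primitives above
oracle_lawds <- function(x, p) {
  a_raw <- oracle_conv(oracle_avgpool3(x), p$att$w, p$att$b)
  aw <- oracle_unfold(a_raw)
  d <- dim(aw)
  A <- aw
  for (bb in 1:d[1]) for (cc in 1:d[2]) for (i in 1:d[3]) for (j in 1:d[4]) {
    e <- exp(aw[bb, cc, i, j, ] - max(aw[bb, cc, i, j, ]))
    A[bb, cc, i, j, ] <- e / sum(e)
  }
  xd <- oracle_conv(x, p$ds$w, p$ds$b, stride = 2L, groups = p$g)
  C <- dim(x)[2]
  out <- array(0, c(d[1], C, d[3], d[4]))
  for (bb in 1:d[1]) for (cc in 1:C) for (i in 1:d[3]) for (j in 1:d[4])
    out[bb, cc, i, j] <- sum(A[bb, cc, i, j, ] * xd[bb, 4L * (cc - 1L) + 1:4, i, j])
  out
}

oracle_star <- function(x, p) {
  C <- dim(x)[2]
  xs <- oracle_conv(x, p$dw1$w, p$dw1$b, groups = C)
  x1 <- oracle_conv(xs, p$f1$w, p$f1$b)
  x2 <- oracle_conv(xs, p$f2$w, p$f2$b)
  gated <- pmin(pmax(x1, 0), 6) * x2
  red <- oracle_conv(gated, p$g$w, p$g$b)
  x + oracle_conv(red, p$dw2$w, p$dw2$b, groups = C)
}

oracle_c3k2_star <- function(x, p) {
  silu <- function(z) z / (1 + exp(-z))
  y <- silu(oracle_conv(x, p$cv1$w, p$cv1$b))
  ch <- p$ch
  a <- y[, 1:ch, , , drop = FALSE]
  b <- y[, (ch + 1):(2 * ch), , , drop = FALSE]
  ys <- list(a, b)
  cur <- b
  for (chain in p$ms) {
    for (st in chain$modules) cur <- oracle_star(cur, st)
    ys[[length(ys) + 1]] <- cur
  }
  cc <- do.call(function(...) {
    xs <- list(...)
    d <- dim(xs[[1]])
    out <- array(0, c(d[1], sum(sapply(xs, function(z) dim(z)[2])), d[3], d[4]))
    at <- 0
    for (z in xs) { out[, at + seq_len(dim(z)[2]), , ] <- z; at <- at + dim(z)[2] }
    out
  }, ys)
  silu(oracle_conv(cc, p$cv2$w, p$cv2$b))
}

# independent detection matcher: explicit IoU matrix + rank loop
oracle_match <- function(dets, gts, thr) {
  iou1 <- function(a, b) {
    iw <- min(a[3], b[3]) - max(a[1], b[1])
    ih <- min(a[4], b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  nd <- nrow(dets); ng <- nrow(gts)
  M <- matrix(0, max(nd, 1), max(ng, 1))
  if (nd > 0 && ng > 0)
    for (i in 1:nd) for (j in 1:ng)
      M[i, j] <- if (dets$class[i] == gts$class[j])
        iou1(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
             as.numeric(gts[j, c("x1", "y1", "x2", "y2")])) else 0
  used <- logical(ng)
  tp <- logical(nd)
  for (i in order(-dets$conf)) {
    if (ng == 0) break
    cand <- which(!used & M[i, ] >= thr)
    if (length(cand)) {
      j <- cand[which.max(M[i, cand])]
      used[j] <- TRUE
      tp[i] <- TRUE
    }
  }
  tp
}

# independent 11-point AP: rank trace + node maxima
oracle_ap11 <- function(dets, gts, thr = 0.5) {
  ng <- nrow(gts)
  if (ng == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  ord <- order(-dets$conf)
  tp <- oracle_match(dets, gts, thr)[ord]
  ps <- cumsum(tp) / seq_along(tp)
  rs <- cumsum(tp) / ng
  mean(sapply(seq(0, 1, 0.1), function(r0) {
    sel <- rs >= r0 - 1e-12
    if (any(sel)) max(ps[sel]) else 0
  }))
}

# exact (all-point) interpolated AP, for the sanity envelope
oracle_ap_exact <- function(dets, gts, thr = 0.5) {
  ng <- nrow(gts)
  if (ng == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  ord <- order(-dets$conf)
  tp <- oracle_match(dets, gts, thr)[ord]
  ps <- cumsum(tp) / seq_along(tp)
  rs <- cumsum(tp) / ng
  # precision envelope, integrated over recall steps
  penv <- rev(cummax(rev(ps)))
  ap <- 0
  prev_r <- 0
  for (k in seq_along(rs)) {
    ap <- ap + (rs[k] - prev_r) * penv[k]
    prev_r <- rs[k]
  }
  ap
}

random_boxes <- function(n, classes = 0:1, img = 100) {
  if (n == 0)
    return(data.frame(class = integer(), conf = numeric(), x1 = numeric(),
                      y1 = numeric(), x2 = numeric(), y2 = numeric()))
  x1 <- runif(n, 0, img - 12); y1 <- runif(n, 0, img - 12)
  data.frame(class = sample(classes, n, replace = TRUE),
             conf = round(runif(n), 3),
             x1 = x1, y1 = y1,
             x2 = x1 + runif(n, 4, 12), y2 = y1 + runif(n, 4, 12))
}

# raw-map encoder matching decode_predictions(): one box, one scale
encode_box <- function(box, class_id, grids, strides, nc = 5, reg_max = 16,
                       scale = 1, conf_logit = 6) {
  raw <- lapply(seq_along(grids), function(s)
    array(-30, c(1, 4 * reg_max + nc, grids[s], grids[s])))
  stride <- strides[scale]
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  j <- max(1, min(grids[scale], ceiling(cx / stride)))
  i <- max(1, min(grids[scale], ceiling(cy / stride)))
  ax <- (j - 0.5) * stride; ay <- (i - 0.5) * stride
  dist <- c(ax - box[1], ay - box[2], box[3] - ax, box[4] - ay) / stride
  for (side in 1:4) {
    d <- max(0, min(reg_max - 1, dist[side]))
    lo <- floor(d); hi <- ceiling(d)
    p_hi <- d - lo
    base <- (side - 1) * reg_max
    if (lo == hi) {
      raw[[scale]][1, base + lo + 1, i, j] <- 0
    } else {
      raw[[scale]][1, base + lo + 1, i, j] <- log(max(1 - p_hi, 1e-9))
      raw[[scale]][1, base + hi + 1, i, j] <- log(max(p_hi, 1e-9))
    }
  }
  raw[[scale]][1, 4 * reg_max + class_id + 1, i, j] <- conf_logit
  raw
}
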