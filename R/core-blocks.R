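# The three bespoke building blocks of the detector:
#
#  * LAWDS - light adaptive-weight downsampling: an attention branch
#    (3x3 average pool, 1x1 conv) scores every pixel, the scores are
#    regrouped into 2x2 windows and softmax-normalised, and a grouped
#    strided 3x3 convolution supplies four candidate features per output
#    pixel which are fused by the normalised weights.
#  * Star_Block - dual-path gated bottleneck: a 7x7 depthwise conv, two
#    parallel 1x1 expansions combined by ReLU6-gated element-wise
#    multiplication, a 1x1 reduction, a second 7x7 depthwise conv, and a
#    residual connection with optional stochastic depth.
#  * Weighted fusion node - ReLU-rectified learnable scalar weights,
#    normalised by their sum plus a small epsilon.

#' Rearrange a feature map into 2x2 windows
#'
#' Regroups an even-sized feature map of shape `(B, C, 2H, 2W)` into a 5-D
#' array of shape `(B, C, H, W, 4)` where the trailing dimension holds the
#' four pixels of each non-overlapping 2x2 window in row-major order:
#' top-left, top-right, bottom-left, bottom-right.
#'
#' @param x 4-D feature-map array `(batch, channels, height, width)` with
#'   even spatial dimensions.
#' @return 5-D array `(batch, channels, height/2, width/2, 4)`.
#' @examples
#' x <- array(1:4, c(1, 1, 2, 2))
#' window_unfold(x)[1, 1, 1, 1, ]   # the four window entries
#' @export
window_unfold <- function(x) {
  fm_assert(x)
  d <- dim(x)
  if (d[3] %% 2L != 0L || d[4] %% 2L != 0L)
    stop("window_unfold requires even spatial dimensions, got ",
         d[3], "x", d[4])
  H <- d[3] %/% 2L; W <- d[4] %/% 2L
  out <- array(0, c(d[1], d[2], H, W, 4L))
  oi <- seq.int(1L, by = 2L, length.out = H)
  oj <- seq.int(1L, by = 2L, length.out = W)
  out[, , , , 1] <- x[, , oi,      oj,      drop = FALSE]
  out[, , , , 2] <- x[, , oi,      oj + 1L, drop = FALSE]
  out[, , , , 3] <- x[, , oi + 1L, oj,      drop = FALSE]
  out[, , , , 4] <- x[, , oi + 1L, oj + 1L, drop = FALSE]
  out
}

#' Inverse of [window_unfold()]
#'
#' @param a 5-D windowed array `(B, C, H, W, 4)`.
#' @return 4-D array `(B, C, 2H, 2W)`.
#' @export
window_fold <- function(a) {
  d <- dim(a)
  if (length(d) != 5L || d[5] != 4L)
    stop("window_fold expects a (B, C, H, W, 4) array")
  out <- array(0, c(d[1], d[2], 2L * d[3], 2L * d[4]))
  oi <- seq.int(1L, by = 2L, length.out = d[3])
  oj <- seq.int(1L, by = 2L, length.out = d[4])
  out[, , oi,      oj     ] <- a[, , , , 1]
  out[, , oi,      oj + 1L] <- a[, , , , 2]
  out[, , oi + 1L, oj     ] <- a[, , , , 3]
  out[, , oi + 1L, oj + 1L] <- a[, , , , 4]
  out
}

lawds_groups <- function(channels) {
  g <- max(1L, channels %/% 16L)
  while (channels %% g != 0L) g <- g - 1L
  g
}

#' Construct LAWDS downsampling parameters
#'
#' The module keeps the channel count and halves both spatial dimensions.
#' Its attention branch is a 1x1 convolution `C -> C` applied after a 3x3
#' average pool (stride 1, padding 1); its feature branch is a grouped
#' strided 3x3 convolution `C -> 4C` with `g = max(1, C/16)` groups
#' (reduced to the largest divisor of `C` for widths not divisible by 16).
#'
#' @param channels input (= output) channel count.
#' @return a LAWDS block usable with [lawds_forward()].
#' @export
lawds_params <- function(channels) {
  g <- lawds_groups(channels)
  new_block("lawds",
            att = new_conv(channels, channels, 1L, act = "none"),
            ds = new_conv(channels, 4L * channels, 3L, s = 2L, g = g, act = "none"),
            channels = channels, g = g)
}

#' LAWDS forward pass
#'
#' Adaptive weighted 2x2 downsampling: per output pixel, the four softmax
#' weights of its source window fuse the four aligned channels produced by
#' the grouped strided convolution. Output channel `c` is fused from the
#' grouped-conv output channels `4(c-1)+1 .. 4(c-1)+4`, which align with the
#' row-major window slots.
#'
#' @param x feature map `(B, C, 2H, 2W)` with even spatial dimensions.
#' @param p LAWDS block from [lawds_params()].
#' @return feature map `(B, C, H, W)`.
#' @export
lawds_forward <- function(x, p) {
  fm_assert(x)
  d <- dim(x)
  if (d[2] != p$channels)
    stop("LAWDS configured for ", p$channels, " channels, input has ", d[2])
  a_raw <- blk_forward(p$att, avg_pool3(x))
  A <- softmax_win4(window_unfold(a_raw))
  xd4 <- blk_forward(p$ds, x)                       # (B, 4C, H, W)
  C <- d[2]; H <- d[3] %/% 2L; W <- d[4] %/% 2L
  out <- array(0, c(d[1], C, H, W))
  for (k in 1:4) {
    idx <- seq.int(k, by = 4L, length.out = C)      # slot k of channel c at 4(c-1)+k
    Ak <- A[, , , , k, drop = FALSE]
    dim(Ak) <- dim(Ak)[1:4]
    out <- out + Ak * xd4[, idx, , , drop = FALSE]
  }
  out
}

blk_forward.lbs_lawds <- function(m, x, training = FALSE) lawds_forward(x, m)

blk_params.lbs_lawds <- function(m)
  flatten_params(list(att = blk_params(m$att), ds = blk_params(m$ds)))

blk_profile.lbs_lawds <- function(m, shape) {
  pa <- blk_profile(m$att, shape)
  pd <- blk_profile(m$ds, shape)
  in_elems <- prod(as.numeric(shape))
  out_elems <- in_elems / 4
  # 3x3 average pool, softmax over the window dimension, weighted fusion
  extra <- 9 * in_elems + 4 * in_elems + 8 * out_elems
  list(shape = c(m$channels, shape[2] %/% 2L, shape[3] %/% 2L),
       macs = pa$macs + pd$macs + extra)
}

#' Learnable-weight feature fusion
#'
#' Fuses same-shaped feature maps as
#' `O = sum_i relu(w_i) I_i / (sum_j relu(w_j) + eps)`. Negative raw weights
#' are rectified to zero; if every rectified weight is zero the output is
#' the zero map (the denominator stays at `eps`).
#'
#' @param inputs list of >= 2 feature maps with identical dimensions.
#' @param w raw (unrectified) fusion weights, one per input.
#' @param eps small positive stabiliser, default `1e-4`.
#' @return fused feature map.
#' @export
bifpn_fuse <- function(inputs, w, eps = 1e-4) {
  if (!is.list(inputs) || length(inputs) < 2L)
    stop("bifpn_fuse needs at least two input maps")
  if (length(w) != length(inputs))
    stop("one fusion weight per input is required")
  d0 <- dim(inputs[[1]])
  for (x in inputs)
    if (!identical(dim(x), d0)) stop("bifpn_fuse inputs must share a shape")
  wr <- pmax(as.numeric(w), 0)
  denom <- sum(wr) + eps
  out <- array(0, d0)
  for (i in seq_along(inputs)) out <- out + (wr[i] / denom) * inputs[[i]]
  out
}

new_fuse <- function(n_in, eps = 1e-4) new_block("fuse", w = rep(1, n_in), eps = eps)

blk_params.lbs_fuse <- function(m) list(w = m$w)

#' Star block construction
#'
#' @param channels channel count (preserved by the block).
#' @param mlp_ratio expansion ratio of the two parallel 1x1 convolutions;
#'   `mlp_ratio * channels` must be an integer.
#' @param drop_path stochastic-depth rate in `[0, 1)`; the residual branch
#'   is randomly dropped at this rate during training and identity-scaled
#'   in evaluation mode.
#' @return a star block usable with [star_block_forward()].
#' @export
star_block_params <- function(channels, mlp_ratio = 3, drop_path = 0) {
  ce <- channels * mlp_ratio
  if (abs(ce - round(ce)) > 1e-9)
    stop("mlp_ratio * channels must be an integer")
  ce <- as.integer(round(ce))
  if (drop_path < 0 || drop_path >= 1) stop("drop_path must lie in [0, 1)")
  new_block("star",
            dw1 = new_conv(channels, channels, 7L, g = channels, act = "none"),
            f1 = new_conv(channels, ce, 1L, act = "none"),
            f2 = new_conv(channels, ce, 1L, act = "none"),
            g = new_conv(ce, channels, 1L, act = "none"),
            dw2 = new_conv(channels, channels, 7L, g = channels, act = "none"),
            channels = channels, mlp_ratio = mlp_ratio, drop_path = drop_path)
}

#' Star block forward pass
#'
#' `Y = X + DropPath(DW2(G(relu6(F1(DW(X))) * F2(DW(X)))))` - the element
#' -wise product of a ReLU6-gated expansion with a parallel linear
#' expansion, reduced back to the input width.
#'
#' @param x feature map `(B, C, H, W)`.
#' @param p star block from [star_block_params()].
#' @param training logical; only in training mode is the residual branch
#'   stochastically dropped (and rescaled by `1/(1-rate)` when kept).
#' @return feature map with the input shape.
#' @export
star_block_forward <- function(x, p, training = FALSE) {
  fm_assert(x)
  xs <- blk_forward(p$dw1, x)
  gated <- act_relu6(blk_forward(p$f1, xs)) * blk_forward(p$f2, xs)
  branch <- blk_forward(p$dw2, blk_forward(p$g, gated))
  if (training && p$drop_path > 0) {
    keep <- stats::runif(dim(x)[1]) >= p$drop_path
    scale <- ifelse(keep, 1 / (1 - p$drop_path), 0)
    branch <- sweep(branch, 1L, scale, "*")
  }
  x + branch
}

blk_forward.lbs_star <- function(m, x, training = FALSE)
  star_block_forward(x, m, training)

blk_params.lbs_star <- function(m)
  flatten_params(list(dw1 = blk_params(m$dw1), f1 = blk_params(m$f1),
                      f2 = blk_params(m$f2), g = blk_params(m$g),
                      dw2 = blk_params(m$dw2)))

blk_profile.lbs_star <- function(m, shape) {
  ce <- as.integer(round(m$channels * m$mlp_ratio))
  macs <- blk_profile(m$dw1, shape)$macs +
    blk_profile(m$f1, shape)$macs + blk_profile(m$f2, shape)$macs +
    blk_profile(m$g, c(ce, shape[2], shape[3]))$macs +
    blk_profile(m$dw2, shape)$macs +
    # ReLU6 gate, element-wise product, residual addition
    2 * ce * as.numeric(shape[2]) * shape[3] + prod(as.numeric(shape))
  list(shape = shape, macs = macs)
}

# a cascade of star blocks used as the C3k2_Star transform
new_star_chain <- function(channels, depth = 1L, mlp_ratio = 3, drop_path = 0) {
  do.call(new_seq, lapply(seq_len(depth), function(i)
    star_block_params(channels, mlp_ratio, drop_path)))
}

#' Gated star CSP stage (C3k2_Star)
#'
#' Keeps the split-transform-merge layout of the standard C3k2 stage: a 1x1
#' convolution splits the input into two parallel branches, one branch is
#' transformed by `n` cascaded star blocks, and all intermediate features
#' are concatenated and merged by a final 1x1 convolution back to the
#' configured output width.
#'
#' @param c1,c2 input and output channel counts.
#' @param n number of star-chain transform modules.
#' @param e hidden-width ratio (hidden width is `round(c2 * e)`).
#' @param star_depth star blocks per transform module.
#' @param mlp_ratio star-block expansion ratio.
#' @return a block; apply it with [c3k2_star_forward()].
#' @export
c3k2_star_params <- function(c1, c2, n = 1L, e = 0.5, star_depth = 1L,
                             mlp_ratio = 3) {
  if (n < 1L) stop("n must be >= 1")
  new_c3k2(c1, c2, n = n, transform = "star", e = e,
           star_depth = star_depth, mlp_ratio = mlp_ratio)
}

#' C3k2_Star forward pass
#'
#' @param x feature map `(B, c1, H, W)`.
#' @param p block from [c3k2_star_params()].
#' @param training logical, forwarded to the star blocks' stochastic depth.
#' @return feature map `(B, c2, H, W)`.
#' @export
c3k2_star_forward <- function(x, p, training = FALSE) blk_forward(p, x, training)
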