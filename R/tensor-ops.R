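# Low-level NCHW array operations.
#
# Feature maps are dense 4-D double arrays with dim = c(batch, channels,
# height, width). Convolutions are evaluated with an im2col + BLAS matrix
# product; depthwise convolutions use a shift-and-accumulate path instead,
# which is much faster for groups == channels.

fm_assert <- function(x, what = "feature map") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop(what, " must be a 4-D array (batch, channels, height, width)")
  if (!all(is.finite(x)))
    stop(what, " contains non-finite entries")
  d <- dim(x)
  if (d[3] < 1L || d[4] < 1L)
    stop(what, " has non-positive spatial dimensions")
  invisible(x)
}

pad_nchw <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(value, c(d[1], d[2], d[3] + 2L * p, d[4] + 2L * p))
  out[, , (p + 1L):(p + d[3]), (p + 1L):(p + d[4])] <- x
  out
}

#' @noRd
conv2d_nchw <- function(x, w, b = NULL, stride = 1L, pad = NULL, groups = 1L) {
  d <- dim(x)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cing <- dim(w)[3]; cout <- dim(w)[4]
  if (is.null(pad)) pad <- kh %/% 2L
  if (C != cing * groups)
    stop("conv2d: input channels (", C, ") do not match weight layout (",
         cing, " x ", groups, " groups)")
  if (cout %% groups != 0L) stop("conv2d: output channels not divisible by groups")
  H2 <- (H + 2L * pad - kh) %/% stride + 1L
  W2 <- (W + 2L * pad - kw) %/% stride + 1L
  xp <- pad_nchw(x, pad)
  out <- array(0, c(B, cout, H2, W2))

  if (cing == 1L && groups == C) {
    # depthwise: accumulate k*k shifted, per-channel weighted slices
    mult <- cout %/% C
    for (m in seq_len(mult)) {
      oc <- seq.int(m, by = mult, length.out = C)  # channel c -> out m + (c-1)*mult
      acc <- array(0, c(B, C, H2, W2))
      for (kj in seq_len(kw)) {
        jj <- seq.int(kj, by = stride, length.out = W2)
        for (ki in seq_len(kh)) {
          ii <- seq.int(ki, by = stride, length.out = H2)
          wk <- w[ki, kj, 1L, oc]
          acc <- acc + sweep(xp[, , ii, jj, drop = FALSE], 2L, wk, "*")
        }
      }
      out[, oc, , ] <- acc
    }
  } else {
    coutg <- cout %/% groups
    npatch <- H2 * W2
    M <- matrix(0, nrow = kh * kw * cing, ncol = npatch)
    for (b_i in seq_len(B)) {
      for (g in seq_len(groups)) {
        cidx <- ((g - 1L) * cing + 1L):(g * cing)
        ocidx <- ((g - 1L) * coutg + 1L):(g * coutg)
        r <- 0L
        for (cc in cidx) {
          for (kj in seq_len(kw)) {
            jj <- seq.int(kj, by = stride, length.out = W2)
            for (ki in seq_len(kh)) {
              ii <- seq.int(ki, by = stride, length.out = H2)
              r <- r + 1L
              M[r, ] <- xp[b_i, cc, ii, jj]
            }
          }
        }
        # rows of M are ordered (ki, kj, c) fastest-first; reorder weights to match
        wg <- aperm(w[, , , ocidx, drop = FALSE], c(1L, 2L, 3L, 4L))
        Wm <- matrix(wg, nrow = kh * kw * cing, ncol = coutg)
        Y <- crossprod(Wm, M)                      # coutg x npatch
        out[b_i, ocidx, , ] <- array(Y, c(coutg, H2, W2))
      }
    }
  }
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  out
}

# im2col row order above is (ki fastest, kj, c); matrix(w_slice) flattens the
# (kh, kw, cing, coutg) weight array in exactly that order, so Wm lines up.

avg_pool3 <- function(x) {
  d <- dim(x)
  xp <- pad_nchw(x, 1L)
  out <- array(0, d)
  for (kj in 0:2) for (ki in 0:2)
    out <- out + xp[, , (1L + ki):(d[3] + ki), (1L + kj):(d[4] + kj), drop = FALSE]
  out / 9
}

max_pool <- function(x, k = 5L, pad = k %/% 2L) {
  d <- dim(x)
  xp <- pad_nchw(x, pad, value = -Inf)
  out <- array(-Inf, d)
  for (kj in seq_len(k) - 1L) for (ki in seq_len(k) - 1L)
    out <- pmax(out, xp[, , (1L + ki):(d[3] + ki), (1L + kj):(d[4] + kj), drop = FALSE])
  out
}

upsample2x <- function(x) {
  d <- dim(x)
  x[, , rep(seq_len(d[3]), each = 2L), rep(seq_len(d[4]), each = 2L), drop = FALSE]
}

concat_ch <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[2], integer(1))
  out <- array(0, c(d[1], sum(cs), d[3], d[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[2]
    out[, (at + 1L):(at + cc), , ] <- x
    at <- at + cc
  }
  out
}

act_silu  <- function(x) x / (1 + exp(-x))
act_relu  <- function(x) pmax(x, 0)
act_relu6 <- function(x) pmin(pmax(x, 0), 6)
act_sigmoid <- function(x) 1 / (1 + exp(-x))

apply_act <- function(x, act) {
  switch(act,
         silu = act_silu(x),
         relu = act_relu(x),
         relu6 = act_relu6(x),
         none = x,
         stop("unknown activation: ", act))
}

# softmax over the trailing window dimension of a (B, C, H, W, 4) array
softmax_win4 <- function(a) {
  mx <- pmax(a[, , , , 1], a[, , , , 2], a[, , , , 3], a[, , , , 4])
  e <- array(0, dim(a))
  for (k in 1:4) e[, , , , k] <- exp(a[, , , , k] - mx)
  s <- e[, , , , 1] + e[, , , , 2] + e[, , , , 3] + e[, , , , 4]
  for (k in 1:4) e[, , , , k] <- e[, , , , k] / s
  e
}
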