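# Block system: every network module is a list with class c("lbs_<type>",
# "lbs_block") carrying its parameter arrays. Three generics cover the needs
# of the package: blk_forward() evaluates the module, blk_params() returns a
# flat named list of trainable parameter arrays, and blk_profile() propagates
# a (channels, height, width) shape and accumulates multiply-accumulate
# counts for the FLOP estimator.
#
# Convolutions are stored in inference form: batch normalization is folded
# into the convolution weights and bias, so the trainable parameters of a
# conv layer are its kernel and bias.

blk_forward <- function(m, x, training = FALSE) UseMethod("blk_forward")
blk_params  <- function(m) UseMethod("blk_params")
blk_profile <- function(m, shape) UseMethod("blk_profile")

new_block <- function(type, ...) structure(list(...), class = c(paste0("lbs_", type), "lbs_block"))

# parameter initialisation: He-style fan-in scaling, drawn from the current
# RNG stream so that a model build is reproducible given a seed
init_w <- function(kh, kw, cing, cout) {
  fan_in <- kh * kw * cing
  array(stats::rnorm(kh * kw * cing * cout, sd = sqrt(2 / fan_in)),
        c(kh, kw, cing, cout))
}

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else out[[key]] <- v
  }
  out
}

## ---- conv (+ folded BN + activation) ----------------------------------

new_conv <- function(c1, c2, k = 1L, s = 1L, g = 1L, act = "silu",
                     bias = TRUE, pad = NULL) {
  stopifnot(c1 %% g == 0L, c2 %% g == 0L)
  new_block("conv",
            w = init_w(k, k, c1 %/% g, c2),
            b = if (bias) stats::rnorm(c2, sd = 0.01) else NULL,
            c1 = c1, c2 = c2, k = as.integer(k), s = as.integer(s),
            g = as.integer(g), act = act,
            pad = if (is.null(pad)) as.integer(k) %/% 2L else as.integer(pad))
}

blk_forward.lbs_conv <- function(m, x, training = FALSE) {
  apply_act(conv2d_nchw(x, m$w, m$b, stride = m$s, pad = m$pad, groups = m$g), m$act)
}

blk_params.lbs_conv <- function(m) {
  p <- list(w = m$w)
  if (!is.null(m$b)) p$b <- m$b
  p
}

blk_profile.lbs_conv <- function(m, shape) {
  stopifnot(shape[1] == m$c1)
  h2 <- (shape[2] + 2L * m$pad - m$k) %/% m$s + 1L
  w2 <- (shape[3] + 2L * m$pad - m$k) %/% m$s + 1L
  elems <- as.numeric(h2) * w2 * m$c2
  # kernel MACs plus one op per output element for the bias/normalization
  # and one for a non-trivial activation
  list(shape = c(m$c2, h2, w2),
       macs = elems * (m$c1 / m$g) * m$k * m$k +
         elems * ((!is.null(m$b)) + (m$act != "none")))
}

## ---- sequential -------------------------------------------------------

new_seq <- function(...) new_block("seq", modules = list(...))

blk_forward.lbs_seq <- function(m, x, training = FALSE) {
  for (mm in m$modules) x <- blk_forward(mm, x, training)
  x
}

blk_params.lbs_seq <- function(m) {
  ps <- lapply(m$modules, blk_params)
  names(ps) <- sprintf("m%d", seq_along(ps))
  flatten_params(ps)
}

blk_profile.lbs_seq <- function(m, shape) {
  macs <- 0
  for (mm in m$modules) {
    pr <- blk_profile(mm, shape)
    shape <- pr$shape; macs <- macs + pr$macs
  }
  list(shape = shape, macs = macs)
}

## ---- residual bottleneck (3x3 conv pair) ------------------------------

new_bottleneck <- function(c1, c2, shortcut = TRUE, e = 0.5) {
  ch <- as.integer(round(c2 * e))
  new_block("bottleneck",
            cv1 = new_conv(c1, ch, 3L),
            cv2 = new_conv(ch, c2, 3L),
            add = shortcut && c1 == c2)
}

blk_forward.lbs_bottleneck <- function(m, x, training = FALSE) {
  y <- blk_forward(m$cv2, blk_forward(m$cv1, x, training), training)
  if (m$add) x + y else y
}

blk_params.lbs_bottleneck <- function(m)
  flatten_params(list(cv1 = blk_params(m$cv1), cv2 = blk_params(m$cv2)))

blk_profile.lbs_bottleneck <- function(m, shape) {
  p1 <- blk_profile(m$cv1, shape)
  p2 <- blk_profile(m$cv2, p1$shape)
  list(shape = p2$shape,
       macs = p1$macs + p2$macs +
         if (m$add) prod(as.numeric(p2$shape)) else 0)
}

## ---- C3k (CSP stage with 2 bottlenecks) -------------------------------

new_c3k <- function(c1, c2, n = 2L, e = 0.5) {
  ch <- as.integer(round(c2 * e))
  new_block("c3k",
            cv1 = new_conv(c1, ch, 1L),
            cv2 = new_conv(c1, ch, 1L),
            cv3 = new_conv(2L * ch, c2, 1L),
            ms = lapply(seq_len(n), function(i) new_bottleneck(ch, ch, TRUE, e = 1.0)))
}

blk_forward.lbs_c3k <- function(m, x, training = FALSE) {
  a <- blk_forward(m$cv1, x, training)
  for (mm in m$ms) a <- blk_forward(mm, a, training)
  b <- blk_forward(m$cv2, x, training)
  blk_forward(m$cv3, concat_ch(list(a, b)), training)
}

blk_params.lbs_c3k <- function(m) {
  ms <- lapply(m$ms, blk_params); names(ms) <- sprintf("m%d", seq_along(ms))
  flatten_params(list(cv1 = blk_params(m$cv1), cv2 = blk_params(m$cv2),
                      cv3 = blk_params(m$cv3), ms = ms))
}

blk_profile.lbs_c3k <- function(m, shape) {
  pa <- blk_profile(m$cv1, shape); macs <- pa$macs; sh <- pa$shape
  for (mm in m$ms) { pr <- blk_profile(mm, sh); sh <- pr$shape; macs <- macs + pr$macs }
  pb <- blk_profile(m$cv2, shape); macs <- macs + pb$macs
  pc <- blk_profile(m$cv3, c(sh[1] + pb$shape[1], sh[2], sh[3]))
  list(shape = pc$shape, macs = macs + pc$macs)
}

## ---- C3k2 (split-transform-merge stage) -------------------------------
# transform = "bottleneck" (plain), "c3k" (nested CSP), or "star" (gated
# star blocks; see core-blocks.R). `n` is the number of transform modules;
# each contributes its output to the final concatenation.

new_c3k2 <- function(c1, c2, n = 1L, transform = "bottleneck", e = 0.5,
                     star_depth = 1L, mlp_ratio = 3) {
  ch <- as.integer(round(c2 * e))
  ms <- lapply(seq_len(n), function(i) {
    switch(transform,
           bottleneck = new_bottleneck(ch, ch, TRUE, e = 0.5),
           c3k = new_c3k(ch, ch, 2L),
           star = new_star_chain(ch, depth = star_depth, mlp_ratio = mlp_ratio),
           stop("unknown C3k2 transform: ", transform))
  })
  new_block("c3k2",
            cv1 = new_conv(c1, 2L * ch, 1L),
            cv2 = new_conv((2L + n) * ch, c2, 1L),
            ms = ms, ch = ch)
}

blk_forward.lbs_c3k2 <- function(m, x, training = FALSE) {
  y <- blk_forward(m$cv1, x, training)
  a <- y[, seq_len(m$ch), , , drop = FALSE]
  b <- y[, (m$ch + 1L):(2L * m$ch), , , drop = FALSE]
  ys <- list(a, b)
  cur <- b
  for (mm in m$ms) {
    cur <- blk_forward(mm, cur, training)
    ys[[length(ys) + 1L]] <- cur
  }
  blk_forward(m$cv2, concat_ch(ys), training)
}

blk_params.lbs_c3k2 <- function(m) {
  ms <- lapply(m$ms, blk_params); names(ms) <- sprintf("m%d", seq_along(ms))
  flatten_params(list(cv1 = blk_params(m$cv1), cv2 = blk_params(m$cv2), ms = ms))
}

blk_profile.lbs_c3k2 <- function(m, shape) {
  p1 <- blk_profile(m$cv1, shape)
  macs <- p1$macs
  sh <- c(m$ch, p1$shape[2], p1$shape[3])
  for (mm in m$ms) { pr <- blk_profile(mm, sh); sh <- pr$shape; macs <- macs + pr$macs }
  p2 <- blk_profile(m$cv2, c((2L + length(m$ms)) * m$ch, sh[2], sh[3]))
  list(shape = p2$shape, macs = macs + p2$macs)
}

## ---- SPPF -------------------------------------------------------------

new_sppf <- function(c1, c2, k = 5L) {
  ch <- c1 %/% 2L
  new_block("sppf",
            cv1 = new_conv(c1, ch, 1L),
            cv2 = new_conv(4L * ch, c2, 1L),
            k = as.integer(k))
}

blk_forward.lbs_sppf <- function(m, x, training = FALSE) {
  y0 <- blk_forward(m$cv1, x, training)
  y1 <- max_pool(y0, m$k)
  y2 <- max_pool(y1, m$k)
  y3 <- max_pool(y2, m$k)
  blk_forward(m$cv2, concat_ch(list(y0, y1, y2, y3)), training)
}

blk_params.lbs_sppf <- function(m)
  flatten_params(list(cv1 = blk_params(m$cv1), cv2 = blk_params(m$cv2)))

blk_profile.lbs_sppf <- function(m, shape) {
  p1 <- blk_profile(m$cv1, shape)
  p2 <- blk_profile(m$cv2, c(4L * p1$shape[1], p1$shape[2], p1$shape[3]))
  pool <- 3 * prod(as.numeric(p1$shape)) * m$k * m$k
  list(shape = p2$shape, macs = p1$macs + p2$macs + pool)
}

## ---- position-sensitive attention stage (C2PSA) -----------------------

new_attention <- function(dim, num_heads, attn_ratio = 0.5) {
  head_dim <- dim %/% num_heads
  key_dim <- as.integer(head_dim * attn_ratio)
  nh_kd <- key_dim * num_heads
  h <- dim + nh_kd * 2L
  new_block("attention",
            qkv = new_conv(dim, h, 1L, act = "none"),
            proj = new_conv(dim, dim, 1L, act = "none"),
            pe = new_conv(dim, dim, 3L, g = dim, act = "none"),
            dim = dim, num_heads = num_heads,
            key_dim = key_dim, head_dim = head_dim)
}

blk_forward.lbs_attention <- function(m, x, training = FALSE) {
  d <- dim(x); B <- d[1]; H <- d[3]; W <- d[4]; N <- H * W
  qkv <- blk_forward(m$qkv, x, training)
  scale <- m$key_dim^-0.5
  out <- array(0, c(B, m$dim, H, W))
  per_head <- 2L * m$key_dim + m$head_dim
  for (b in seq_len(B)) {
    for (hd in seq_len(m$num_heads)) {
      base <- (hd - 1L) * per_head
      getm <- function(ix) matrix(qkv[b, base + ix, , ], nrow = length(ix))  # ch x N
      q <- getm(seq_len(m$key_dim))
      k <- getm(m$key_dim + seq_len(m$key_dim))
      v <- getm(2L * m$key_dim + seq_len(m$head_dim))
      att <- crossprod(q, k) * scale                  # N x N
      att <- exp(att - apply(att, 1L, max))
      att <- att / rowSums(att)
      o <- v %*% t(att)                               # head_dim x N
      oc <- (hd - 1L) * m$head_dim + seq_len(m$head_dim)
      out[b, oc, , ] <- array(o, c(m$head_dim, H, W))
    }
  }
  # positional term on the value projection, taken per head in channel order
  vfull <- array(0, c(B, m$dim, H, W))
  for (hd in seq_len(m$num_heads)) {
    base <- (hd - 1L) * (2L * m$key_dim + m$head_dim) + 2L * m$key_dim
    oc <- (hd - 1L) * m$head_dim + seq_len(m$head_dim)
    vfull[, oc, , ] <- qkv[, base + seq_len(m$head_dim), , , drop = FALSE]
  }
  blk_forward(m$proj, out + blk_forward(m$pe, vfull, training), training)
}

blk_params.lbs_attention <- function(m)
  flatten_params(list(qkv = blk_params(m$qkv), proj = blk_params(m$proj),
                      pe = blk_params(m$pe)))

blk_profile.lbs_attention <- function(m, shape) {
  # convolutional cost only; the batched matrix products are excluded from
  # the FLOP accounting convention (see estimate_flops)
  pq <- blk_profile(m$qkv, shape)
  pp <- blk_profile(m$proj, shape)
  pe <- blk_profile(m$pe, shape)
  n <- as.numeric(shape[2]) * shape[3]
  att <- m$num_heads * n * n * (m$key_dim + m$head_dim) +  # qk and av products
    3 * m$num_heads * n * n                                # softmax
  list(shape = shape, macs = pq$macs + pp$macs + pe$macs + att)
}

new_psablock <- function(dim, num_heads) {
  new_block("psa",
            attn = new_attention(dim, num_heads),
            ffn1 = new_conv(dim, 2L * dim, 1L),
            ffn2 = new_conv(2L * dim, dim, 1L, act = "none"))
}

blk_forward.lbs_psa <- function(m, x, training = FALSE) {
  x <- x + blk_forward(m$attn, x, training)
  x + blk_forward(m$ffn2, blk_forward(m$ffn1, x, training), training)
}

blk_params.lbs_psa <- function(m)
  flatten_params(list(attn = blk_params(m$attn), ffn1 = blk_params(m$ffn1),
                      ffn2 = blk_params(m$ffn2)))

blk_profile.lbs_psa <- function(m, shape) {
  pa <- blk_profile(m$attn, shape)
  p1 <- blk_profile(m$ffn1, shape)
  p2 <- blk_profile(m$ffn2, p1$shape)
  list(shape = shape,
       macs = pa$macs + p1$macs + p2$macs + 2 * prod(as.numeric(shape)))
}

new_c2psa <- function(c1, c2, n = 1L) {
  stopifnot(c1 == c2)
  ch <- c1 %/% 2L
  new_block("c2psa",
            cv1 = new_conv(c1, 2L * ch, 1L),
            cv2 = new_conv(2L * ch, c1, 1L),
            ms = lapply(seq_len(n), function(i) new_psablock(ch, max(1L, ch %/% 64L))),
            ch = ch)
}

blk_forward.lbs_c2psa <- function(m, x, training = FALSE) {
  y <- blk_forward(m$cv1, x, training)
  a <- y[, seq_len(m$ch), , , drop = FALSE]
  b <- y[, (m$ch + 1L):(2L * m$ch), , , drop = FALSE]
  for (mm in m$ms) b <- blk_forward(mm, b, training)
  blk_forward(m$cv2, concat_ch(list(a, b)), training)
}

blk_params.lbs_c2psa <- function(m) {
  ms <- lapply(m$ms, blk_params); names(ms) <- sprintf("m%d", seq_along(ms))
  flatten_params(list(cv1 = blk_params(m$cv1), cv2 = blk_params(m$cv2), ms = ms))
}

blk_profile.lbs_c2psa <- function(m, shape) {
  p1 <- blk_profile(m$cv1, shape)
  macs <- p1$macs
  sh <- c(m$ch, shape[2], shape[3])
  for (mm in m$ms) { pr <- blk_profile(mm, sh); macs <- macs + pr$macs }
  p2 <- blk_profile(m$cv2, c(2L * m$ch, shape[2], shape[3]))
  list(shape = p2$shape, macs = macs + p2$macs)
}

## ---- parameter-free graph nodes ---------------------------------------

new_upsample <- function() new_block("upsample")
blk_forward.lbs_upsample <- function(m, x, training = FALSE) upsample2x(x)
blk_params.lbs_upsample <- function(m) list()
blk_profile.lbs_upsample <- function(m, shape)
  list(shape = c(shape[1], 2L * shape[2], 2L * shape[3]),
       macs = 4 * prod(as.numeric(shape)))

new_concat <- function() new_block("concat")
blk_params.lbs_concat <- function(m) list()
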