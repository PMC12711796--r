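# Equation-level building blocks: window rearrangement, adaptive-weight
# downsampling, weighted fusion, and the gated star bottleneck.

test_that("window_unfold follows the row-major 2x2 convention and conserves elements", {
  x <- array(c(1, 3, 2, 4), c(1, 1, 2, 2))  # [[1,2],[3,4]] row-wise
  w <- window_unfold(x)
  expect_equal(dim(w), c(1, 1, 1, 1, 4))
  expect_equal(as.numeric(w[1, 1, 1, 1, ]), c(1, 2, 3, 4))

  set.seed(11)
  x <- array(seq_len(16), c(1, 1, 4, 4))
  expect_equal(window_unfold(x), oracle_unfold(x))
  expect_equal(length(window_unfold(x)), length(x))

  xc <- array(7.5, c(2, 3, 4, 6))
  wc <- window_unfold(xc)
  expect_true(all(wc == 7.5))

  # random maps: unfold is a bijection on entries
  for (rep in 1:5) {
    x <- array(rnorm(2 * 3 * 6 * 8), c(2, 3, 6, 8))
    expect_identical(window_fold(window_unfold(x)), x)
  }

  expect_error(window_unfold(array(0, c(1, 1, 3, 4))), "even")
})

test_that("LAWDS halves the resolution, keeps channels, and normalises window weights", {
  set.seed(21)
  p <- lawds_params(16L)
  x <- array(rnorm(16 * 16), c(1, 16, 4, 4))
  y <- lawds_forward(x, p)
  expect_equal(dim(y), c(1, 16, 2, 2))

  # softmax normalisation of the attention windows
  a_raw <- lbsdet:::blk_forward(p$att, lbsdet:::avg_pool3(x))
  A <- lbsdet:::softmax_win4(window_unfold(a_raw))
  sums <- apply(A, c(1, 2, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  expect_error(lawds_forward(array(0.5, c(1, 8, 4, 4)), p), "channels")
})

test_that("LAWDS with constant attention logits reduces to the plain window mean", {
  set.seed(22)
  p <- lawds_params(16L)
  p$att$w[] <- 0
  p$att$b[] <- 3.7   # any constant logit
  x <- array(rnorm(16 * 64), c(1, 16, 8, 8))
  y <- lawds_forward(x, p)
  xd <- lbsdet:::blk_forward(p$ds, x)
  manual <- array(0, c(1, 16, 4, 4))
  for (cc in 1:16)
    manual[1, cc, , ] <- (xd[1, 4 * (cc - 1) + 1, , ] + xd[1, 4 * (cc - 1) + 2, , ] +
                          xd[1, 4 * (cc - 1) + 3, , ] + xd[1, 4 * (cc - 1) + 4, , ]) / 4
  expect_equal(y, manual, tolerance = 1e-10)
})

test_that("LAWDS matches the step-by-step primitive composition oracle", {
  set.seed(23)
  p <- lawds_params(16L)
  x <- array(rnorm(16 * 64), c(1, 16, 8, 8))
  expect_equal(lawds_forward(x, p), oracle_lawds(x, p), tolerance = 1e-5)
  expect_equal(p$g, 1L)  # 16 channels -> single group
  p32 <- lawds_params(32L)
  expect_equal(p32$g, 2L)
})

test_that("bifpn_fuse evaluates the rectified normalised weighting", {
  ones <- array(1, c(1, 2, 3, 3))
  out <- bifpn_fuse(list(ones, ones), c(1, 1))
  expect_equal(as.numeric(out[1, 1, 1, 1]), 2 / 2.0001, tolerance = 1e-12)

  i1 <- array(rnorm(18), c(1, 2, 3, 3))
  out <- bifpn_fuse(list(i1, ones), c(1, 0))
  expect_equal(out, i1 / 1.0001, tolerance = 1e-12)

  # negative weights are rectified away
  out <- bifpn_fuse(list(ones * 5, i1), c(-5, 1))
  expect_equal(out, i1 / 1.0001, tolerance = 1e-12)

  # all-zero rectified weights: zero map, not an error
  out <- bifpn_fuse(list(i1, ones), c(-1, -2))
  expect_true(all(out == 0))

  expect_error(bifpn_fuse(list(ones, array(1, c(1, 2, 3, 4))), c(1, 1)), "shape")
  expect_error(bifpn_fuse(list(ones), 1), "two")
})

test_that("bifpn_fuse output is bounded by the input range scaled by the weight sum", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    inputs <- lapply(seq_len(k), function(i) array(runif(24), c(1, 2, 3, 4)))
    w <- runif(k, 0, 3)
    out <- bifpn_fuse(inputs, w)
    scale <- sum(w) / (sum(w) + 1e-4)
    hi <- do.call(pmax, inputs); lo <- do.call(pmin, inputs)
    expect_true(all(out <= hi * scale + 1e-12))
    expect_true(all(out >= lo * scale - 1e-12))
  }
})

test_that("star block is a residual identity when the transform path is zeroed", {
  set.seed(41)
  p <- star_block_params(8L, mlp_ratio = 2)
  p$g$w[] <- 0; p$g$b[] <- 0
  p$dw2$b[] <- 0   # the trailing depthwise conv must not re-inject a bias
  x <- array(rnorm(8 * 36), c(1, 8, 6, 6))
  expect_equal(star_block_forward(x, p), x, tolerance = 1e-14)
})

test_that("star block preserves shape and matches the loop oracle", {
  set.seed(42)
  p <- star_block_params(32L, mlp_ratio = 3)
  x <- array(rnorm(2 * 32 * 64), c(2, 32, 8, 8))
  y <- star_block_forward(x, p)
  expect_equal(dim(y), dim(x))

  p4 <- star_block_params(8L, mlp_ratio = 2)
  x4 <- array(rnorm(8 * 16), c(1, 8, 4, 4))
  expect_equal(star_block_forward(x4, p4), oracle_star(x4, p4), tolerance = 1e-5)

  expect_error(star_block_params(8L, mlp_ratio = 2, drop_path = 1), "drop_path")
  expect_error(star_block_params(7L, mlp_ratio = 1.5), "integer")
})

test_that("star drop-path only acts in training mode", {
  set.seed(43)
  p <- star_block_params(8L, mlp_ratio = 2, drop_path = 0.5)
  x <- array(rnorm(8 * 16), c(1, 8, 4, 4))
  expect_identical(star_block_forward(x, p), star_block_forward(x, p))
  set.seed(1)
  tr <- replicate(20, sum(star_block_forward(x, p, training = TRUE)))
  expect_gt(length(unique(round(tr, 10))), 1)
})

test_that("C3k2_Star collapses to the split-merge skeleton when stars are zeroed", {
  set.seed(51)
  p <- c3k2_star_params(16L, 16L, n = 1L, star_depth = 1L, mlp_ratio = 2)
  for (i in seq_along(p$ms))
    for (j in seq_along(p$ms[[i]]$modules)) {
      p$ms[[i]]$modules[[j]]$g$w[] <- 0
      p$ms[[i]]$modules[[j]]$g$b[] <- 0
      p$ms[[i]]$modules[[j]]$dw2$w[] <- 0
      p$ms[[i]]$modules[[j]]$dw2$b[] <- 0
    }
  x <- array(rnorm(16 * 16), c(1, 16, 4, 4))
  y <- c3k2_star_forward(x, p)
  # with the transform branch silenced each star chain passes its input
  # through, so the merge sees (a, b, b)
  silu <- function(z) z / (1 + exp(-z))
  y1 <- silu(oracle_conv(x, p$cv1$w, p$cv1$b))
  a <- y1[, 1:8, , , drop = FALSE]; b <- y1[, 9:16, , , drop = FALSE]
  cc <- array(0, c(1, 24, 4, 4))
  cc[, 1:8, , ] <- a; cc[, 9:16, , ] <- b; cc[, 17:24, , ] <- b
  expect_equal(y, silu(oracle_conv(cc, p$cv2$w, p$cv2$b)), tolerance = 1e-6)
})

test_that("a depth-2 star chain equals two successive star applications", {
  set.seed(52)
  p <- c3k2_star_params(16L, 16L, n = 1L, star_depth = 2L, mlp_ratio = 2)
  x <- array(rnorm(16 * 16), c(1, 16, 4, 4))
  chain <- p$ms[[1]]$modules
  b <- array(rnorm(8 * 16), c(1, 8, 4, 4))
  once <- star_block_forward(star_block_forward(b, chain[[1]]), chain[[2]])
  expect_equal(lbsdet:::blk_forward(p$ms[[1]], b), once, tolerance = 1e-12)
  expect_equal(c3k2_star_forward(x, p), oracle_c3k2_star(x, p), tolerance = 1e-5)
})

test_that("every parameter of the bespoke blocks gets a finite nonzero-capable gradient", {
  set.seed(61)
  x <- array(rnorm(8 * 16), c(1, 8, 4, 4))
  check_block <- function(p, fwd) {
    f0 <- sum(fwd(x, p))
    flat <- lbsdet:::flatten_params(lbsdet:::blk_params(p))
    for (nm in names(flat)) {
      v <- flat[[nm]]
      ii <- sample(length(v), 1)
      h <- 1e-4 * max(1, abs(v[ii]))
      bump <- function(s) {
        q <- p
        # walk down the same path used by blk_assign
        q <- lbsdet:::blk_assign(q, {
          w <- flat; w[[nm]][ii] <- w[[nm]][ii] + s * h; w
        })
        q
      }
      g <- (sum(fwd(x, bump(1))) - sum(fwd(x, bump(-1)))) / (2 * h)
      expect_true(is.finite(g), info = nm)
    }
    invisible(f0)
  }
  check_block(star_block_params(8L, mlp_ratio = 2),
              function(x, p) star_block_forward(x, p))
  check_block(lawds_params(8L), function(x, p) lawds_forward(x, p))
})
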