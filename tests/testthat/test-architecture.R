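# Model assembly, parameter/FLOP accounting, forward pass and decoding.

test_that("variant presets toggle exactly the intended modules", {
  count_kind <- function(model, cls) {
    n <- 0
    for (ly in model$layers) {
      if (!is.null(ly$block) && inherits(ly$block, cls)) n <- n + 1
      if (ly$kind == "fuse") n <- n + (cls == "fuse_node")
    }
    n
  }
  has_star <- function(model) {
    found <- FALSE
    walk <- function(b) {
      if (is.null(b) || !is.list(b)) return()
      if (inherits(b, "lbs_star")) found <<- TRUE
      for (el in b) if (is.list(el)) walk(el)
    }
    for (ly in model$layers) walk(ly$block)
    found
  }
  base <- build_model(variant_spec("baseline"), seed = 0)
  expect_equal(count_kind(base, "lbs_lawds"), 0)
  expect_equal(count_kind(base, "fuse_node"), 0)
  expect_false(has_star(base))

  full <- build_model(variant_spec("full"), seed = 0)
  expect_equal(count_kind(full, "lbs_lawds"), 3)    # backbone stages 3/5/7
  expect_true(has_star(full))

  t2 <- build_model(variant_spec("test2"), seed = 0)
  expect_gt(count_kind(t2, "fuse_node"), 0)
  expect_false(has_star(t2))
  expect_equal(count_kind(t2, "lbs_lawds"), 0)

  expect_error(variant_spec("baseline", scale = "s"), "scale")
  expect_error(variant_spec("test9"), "unknown variant")
})

test_that("parameter counting matches closed forms and is build-invariant", {
  set.seed(1)
  cv <- lbsdet:::new_conv(16L, 32L, 3L)
  expect_equal(sum(lengths(lbsdet:::blk_params(cv))), 32 * (16 * 9 + 1))  # 4640

  m1 <- build_model(variant_spec("baseline"), seed = 7)
  m2 <- build_model(variant_spec("baseline"), seed = 7)
  expect_identical(count_parameters(m1), count_parameters(m2))
  expect_identical(lbsdet:::model_weights(m1), lbsdet:::model_weights(m2))
})

test_that("parameter counts decrease monotonically across the ablation grid", {
  n <- sapply(c("baseline", "test1", "test2", "test3", "test4", "full"),
              function(v) count_parameters(build_model(variant_spec(v), seed = 0))$count)
  expect_lt(n[["full"]], n[["test4"]])
  expect_lt(n[["test4"]], n[["test2"]])
  expect_lt(n[["test2"]], n[["test1"]])
  expect_lt(n[["test1"]], n[["baseline"]])
  expect_lt(n[["test3"]], n[["baseline"]])
})

test_that("the FLOP estimator agrees with the closed-form sum on a toy conv stack", {
  # three plain convolutions, no bias, no activation: pure kernel MACs
  s <- lbsdet:::new_seq(
    lbsdet:::new_conv(4L, 8L, 1L, act = "none", bias = FALSE),
    lbsdet:::new_conv(8L, 8L, 3L, act = "none", bias = FALSE),
    lbsdet:::new_conv(8L, 2L, 1L, act = "none", bias = FALSE))
  pr <- lbsdet:::blk_profile(s, c(4L, 10L, 10L))
  closed <- 100 * (8 * 4) + 100 * (8 * 8 * 9) + 100 * (2 * 8)
  expect_equal(pr$macs, closed)
  # a 1x1 conv C->C on HxW contributes 2*C^2*H*W FLOPs
  c11 <- lbsdet:::new_conv(8L, 8L, 1L, act = "none", bias = FALSE)
  expect_equal(2 * lbsdet:::blk_profile(c11, c(8L, 5L, 7L))$macs, 2 * 8 * 8 * 5 * 7)
  expect_error(estimate_flops(build_model(variant_spec(), seed = 0), 600), "32")
})

test_that("forward pass produces stride-8/16/32 grids and is deterministic", {
  m <- build_model(variant_spec("baseline"), seed = 2)
  set.seed(3)
  x <- array(rnorm(3 * 96 * 96), c(1, 3, 96, 96))
  raw <- forward_detect(m, x)
  expect_equal(lapply(raw, function(r) dim(r)[3:4]),
               list(c(12L, 12L), c(6L, 6L), c(3L, 3L)))
  expect_equal(dim(raw[[1]])[2], 4 * 16 + 5)
  expect_identical(raw, forward_detect(m, x))
  expect_error(forward_detect(m, array(0, c(1, 3, 50, 50))), "divisible")
})

test_that("a 416x416 input yields the 52/26/13 prediction grids", {
  m <- build_model(variant_spec("baseline"), seed = 2)
  sh <- estimate_flops(m, 416)  # shape propagation runs the whole graph
  expect_true(is.finite(sh$gflops))
  set.seed(4)
  raw <- forward_detect(m, array(rnorm(3 * 416 * 416), c(1, 3, 416, 416)))
  expect_equal(sapply(raw, function(r) dim(r)[3]), c(52L, 26L, 13L))
})

test_that("decoding recovers encoded boxes and suppresses duplicates", {
  grids <- c(12L, 6L, 3L); strides <- c(8L, 16L, 32L)
  raw <- encode_box(c(20.5, 18, 52.5, 49), class_id = 2, grids, strides, scale = 1)
  det <- decode_predictions(raw, conf_threshold = 0.25, strides = strides)
  expect_equal(nrow(det), 1)
  expect_equal(det$class, 2L)
  expect_lt(max(abs(as.numeric(det[1, c("x1", "y1", "x2", "y2")]) -
                    c(20.5, 18, 52.5, 49))), 1)

  # nothing can clear a confidence threshold of 1
  expect_equal(nrow(decode_predictions(raw, conf_threshold = 1)), 0)

  # two identical candidates in adjacent cells: one survivor after NMS
  raw2 <- encode_box(c(20.5, 18, 52.5, 49), class_id = 2, grids, strides, scale = 1)
  raw2[[1]][1, , , ] <- pmax(raw2[[1]][1, , , ], raw[[1]][1, , c(2:12, 12), ])
  det2 <- decode_predictions(raw2, conf_threshold = 0.25, iou_nms = 0.45,
                             strides = strides)
  expect_equal(sum(det2$class == 2L), 1)
  expect_error(decode_predictions(raw, conf_threshold = 1.5), "0, 1")
})

test_that("checkpoints round-trip the weights and the forward pass", {
  m <- build_model(variant_spec("test4"), seed = 5)
  # perturb a weight so the checkpoint differs from a fresh rebuild
  m$layers[[1]]$block$w[1] <- 0.5
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_checkpoint(path)
  expect_identical(lbsdet:::model_weights(m), lbsdet:::model_weights(m2))
  x <- array(rnorm(3 * 32 * 32), c(1, 3, 32, 32))
  expect_identical(forward_detect(m, x), forward_detect(m2, x))
  hd <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(hd$variant, "test4")
})

test_that("the YAML model config lists every layer with its wiring", {
  m <- build_model(variant_spec("full"), seed = 0)
  txt <- model_config_yaml(m)
  y <- yaml::yaml.load(txt)
  expect_equal(length(y$layers), length(m$layers))
  expect_equal(y$num_classes, 5)
  expect_true(any(vapply(y$layers, function(l) identical(l$kind, "lawds"), logical(1))))
})

test_that("sampled finite-difference gradients are finite through a small variant", {
  m <- build_model(variant_spec("test3"), seed = 6)
  g <- gradient_flow(m, imgsz = 32, tensors = 6, per_tensor = 1, seed = 1)
  expect_equal(nrow(g), 6)
  expect_true(all(is.finite(g$grad)))
})
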