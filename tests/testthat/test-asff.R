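test_that("rescaling reproduces each level's geometry", {
  x <- rarr(12, 12, 8, 1, seed = 51)
  expect_identical(rescale_to_level(x, 1, 1), x)
  # stride-8 map, two levels finer than stride 32: spatial /4
  f <- rarr(40, 40, 8, 1, seed = 52)
  y <- rescale_to_level(f, from_level = 2, to_level = 0, channels_out = 4L)
  expect_identical(dim(y), c(10L, 10L, 4L, 1L))
  # one step finer -> coarser: /2
  y2 <- rescale_to_level(rarr(20, 20, 8, 1), 1, 0, channels_out = 4L)
  expect_identical(dim(y2), c(10L, 10L, 4L, 1L))
  # coarse stride-32 map to stride 8: x4 with constant 4x4 blocks
  c <- rarr(10, 10, 6, 1, seed = 53)
  u <- rescale_to_level(c, from_level = 0, to_level = 2, channels_out = 3L)
  expect_identical(dim(u), c(40L, 40L, 3L, 1L))
  blocks <- u[seq(1, 40, 4), seq(1, 40, 4), , , drop = FALSE]
  for (a in 0:3) for (b in 0:3) {
    expect_equal(u[seq(1, 40, 4) + a, seq(1, 40, 4) + b, , , drop = FALSE],
                 blocks, tolerance = 1e-12)
  }
  expect_error(rescale_to_level(x, 0, 3), "levels")
})

test_that("fusion weights are an exact three-way softmax", {
  # equal control maps -> 1/3 everywhere
  lam <- array(0.7, c(4, 4, 3, 1))
  w <- fusion_weights_from_lambda(lam)
  expect_equal(max(abs(w$alpha - 1 / 3)), 0, tolerance = 1e-12)
  # saturation
  lam2 <- array(0, c(2, 2, 3, 1)); lam2[, , 1, ] <- 20
  expect_gt(min(fusion_weights_from_lambda(lam2)$alpha), 0.999)
  # random maps match an element-wise softmax oracle
  lam3 <- rarr(6, 6, 3, 2, seed = 54)
  w3 <- fusion_weights_from_lambda(lam3)
  for (i in 1:6) for (j in 1:6) for (n in 1:2) {
    p <- exp(lam3[i, j, , n]); p <- p / sum(p)
    expect_equal(c(w3$alpha[i, j, 1, n], w3$beta[i, j, 1, n],
                   w3$gamma[i, j, 1, n]), p, tolerance = 1e-6)
  }
})

test_that("fusion weights from rescaled features normalise per position", {
  set.seed(55)
  resc <- lapply(1:3, function(i) rarr(5, 5, 8, 2))
  w <- compute_fusion_weights(resc)
  s <- w$alpha + w$beta + w$gamma
  expect_lt(max(abs(s - 1)), 1e-6)
  expect_true(all(w$alpha >= 0 & w$alpha <= 1))
  expect_error(compute_fusion_weights(list(rarr(5, 5, 8, 1),
                                           rarr(4, 5, 8, 1),
                                           rarr(5, 5, 8, 1))), "spatial")
})

test_that("adaptive fusion is the per-position convex blend", {
  set.seed(56)
  resc <- lapply(1:3, function(i) rarr(4, 4, 5, 1))
  one <- array(1, c(4, 4, 1, 1)); zero <- array(0, c(4, 4, 1, 1))
  expect_equal(asff_fuse(resc, list(alpha = one, beta = zero, gamma = zero)),
               resc[[1]], tolerance = 1e-12)
  # identical inputs are a fixed point for any valid weights
  lam <- rarr(4, 4, 3, 1)
  w <- fusion_weights_from_lambda(lam)
  same <- list(resc[[1]], resc[[1]], resc[[1]])
  expect_equal(asff_fuse(same, w), resc[[1]], tolerance = 1e-10)
  # brute-force position loop
  f <- asff_fuse(resc, w)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(f[i, j, , 1],
                 w$alpha[i, j, 1, 1] * resc[[1]][i, j, , 1] +
                   w$beta[i, j, 1, 1] * resc[[2]][i, j, , 1] +
                   w$gamma[i, j, 1, 1] * resc[[3]][i, j, , 1],
                 tolerance = 1e-10)
  }
  # convexity envelope
  lo <- pmin(resc[[1]], resc[[2]], resc[[3]])
  hi <- pmax(resc[[1]], resc[[2]], resc[[3]])
  expect_true(all(f >= lo - 1e-10 & f <= hi + 1e-10))
})

test_that("asff head emits per-level grids with the contracted channels", {
  set.seed(57)
  levels <- list(p3 = rarr(40, 40, 16, 1), p4 = rarr(20, 20, 24, 1),
                 p5 = rarr(10, 10, 32, 1))
  out <- asff_head_forward(levels, num_classes = 4L, reg_max = 16L)
  expect_identical(vapply(out, function(l) dim(l$cls)[1], numeric(1)),
                   c(40, 20, 10))
  expect_identical(vapply(out, function(l) dim(l$cls)[3], numeric(1)),
                   rep(4, 3))
  expect_identical(vapply(out, function(l) dim(l$box)[3], numeric(1)),
                   rep(64, 3))
})

test_that("freezing alpha at 1 reproduces a head run on the level-0 map", {
  set.seed(58)
  levels <- list(p3 = rarr(16, 16, 8, 1), p4 = rarr(8, 8, 8, 1),
                 p5 = rarr(4, 4, 8, 1))
  head <- reefdet:::new_asff_head(c(8L, 8L, 8L), 4L, 8L)
  # saturate the joint conv so alpha ~ 1 at every position of level 0
  lv <- head$levels[[1]]
  lv$joint$w$value[] <- 0
  lv$joint$b$value <- c(60, 0, 0)
  out <- asff_head_forward(levels, head = head)
  # manual: rescale level-0 source to level 0 (identity), expand, branches
  tp <- reefdet:::new_tape()
  x0 <- reefdet:::op_input(tp, levels$p5)
  fused <- reefdet:::fwd_conv(tp, x0, lv$expand, FALSE)
  o <- reefdet:::fwd_branches(tp, fused, head$branches$box[[3]],
                              head$branches$cls[[3]], FALSE)
  expect_equal(out[[3]]$cls, reefdet:::tp_value(tp, o$cls),
               tolerance = 1e-8)
  expect_equal(out[[3]]$box, reefdet:::tp_value(tp, o$box),
               tolerance = 1e-8)
})

test_that("loss gradients reach all three control convolutions", {
  set.seed(59)
  head <- reefdet:::new_asff_head(c(8L, 8L, 8L), 2L, 4L)
  tp <- reefdet:::new_tape()
  pyr <- list(p3 = reefdet:::op_input(tp, rarr(8, 8, 8, 1)),
              p4 = reefdet:::op_input(tp, rarr(4, 4, 8, 1)),
              p5 = reefdet:::op_input(tp, rarr(2, 2, 8, 1)))
  out <- reefdet:::fwd_asff_head(tp, pyr, head, TRUE)
  s <- reefdet:::op_sum(tp, out[[1]]$cls)
  for (i in 2:3) s <- reefdet:::op_add(tp, s,
                                       reefdet:::op_sum(tp, out[[i]]$cls))
  params <- reefdet:::layer_params(head)
  reefdet:::zero_grads(params)
  reefdet:::tp_backward(tp, s)
  for (l in 1:3) {
    g <- head$levels[[l]]$joint$w$grad
    expect_false(is.null(g))
    expect_gt(max(abs(g)), 0)
  }
})
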