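test_that("adaptive threshold is the arithmetic mean IoU", {
  expect_equal(mean_iou_threshold(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(mean_iou_threshold(0.73), 0.73)
  set.seed(61)
  x <- runif(1000)
  s <- 0
  for (v in x) s <- s + v # independent summation oracle
  expect_equal(mean_iou_threshold(x), s / 1000, tolerance = 1e-12)
  expect_error(mean_iou_threshold(numeric(0)), "degenerate")
  expect_error(mean_iou_threshold(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("slide weight follows the piecewise exponential definition", {
  expect_equal(slide_weight(0.3, 0.5), 1.0)
  expect_equal(slide_weight(1.0, 0.5), 1.0)
  expect_equal(slide_weight(1.0, 0.2), 1.0)
  expect_equal(slide_weight(0.45, 0.5), exp(0.5), tolerance = 1e-12)
  # continuity at x = mu: third branch at mu equals the mid-branch value
  expect_equal(slide_weight(0.5, 0.5), exp(0.5), tolerance = 1e-12)
  expect_equal(slide_weight(0.5 - 1e-9, 0.5), exp(0.5), tolerance = 1e-9)
  expect_warning(w <- slide_weight(1.3, 0.5), "clamped")
  expect_equal(w, 1.0)
  expect_error(slide_weight(0.5, 1.2), "mu")
})

test_that("slide weight jump, floor and monotone decay", {
  for (mu in c(0.2, 0.5, 0.8)) {
    x <- seq(0, 1, by = 0.001)
    w <- slide_weight(x, mu)
    expect_true(all(w >= 1 - 1e-12))
    # single discontinuity at mu - 0.1 with jump exp(1 - mu) - 1
    below <- slide_weight(mu - 0.1, mu)
    above <- slide_weight(mu - 0.1 + 1e-9, mu)
    expect_equal(below, 1.0)
    expect_equal(above - below, exp(1 - mu) - 1, tolerance = 1e-6)
    # monotone non-increasing on [mu, 1]
    xs <- seq(mu, 1, length.out = 200)
    expect_true(all(diff(slide_weight(xs, mu)) <= 1e-12))
  }
})

test_that("binary cross-entropy is stable and exact", {
  expect_equal(bce(0, 1), log(2), tolerance = 1e-12)
  expect_equal(bce(0, 0), log(2), tolerance = 1e-12)
  expect_lt(bce(40, 1), 1e-12)
  expect_lt(bce(-40, 0), 1e-12)
  expect_true(is.finite(bce(800, 0))) # naive formula overflows here
  set.seed(62)
  p <- rnorm(200, 0, 3); y <- rbinom(200, 1, 0.5)
  naive <- -y * log(plogis(p)) - (1 - y) * log(1 - plogis(p))
  expect_lt(max(abs(bce(p, y) - naive)), 1e-10)
  expect_error(bce(Inf, 1), "finite")
})

test_that("slide loss reduces to mean BCE for unit weights", {
  set.seed(63)
  b <- assigned_batch(iou = runif(20), label = rbinom(20, 1, 0.4),
                      logit = rnorm(20))
  expect_equal(slide_loss(b, weights = rep(1, 20)),
               mean(bce(b$logit, b$label)), tolerance = 1e-12)
  # all x_i = 1: f(1) = 1, so the weighted loss is the plain mean
  b1 <- assigned_batch(iou = rep(1, 10), label = rbinom(10, 1, 0.5),
                       logit = rnorm(10))
  expect_equal(slide_loss(b1), mean(bce(b1$logit, b1$label)),
               tolerance = 1e-12)
})

test_that("slide loss matches the hand-computed three-sample value", {
  # (x, y, sigma(p)) = (0.2, 0, 0.1), (0.55, 0, 0.4), (0.8, 1, 0.7)
  b <- assigned_batch(iou = c(0.2, 0.55, 0.8), label = c(0, 0, 1),
                      logit = qlogis(c(0.1, 0.4, 0.7)))
  mu <- (0.2 + 0.55 + 0.8) / 3 # 0.5166667
  # branch by branch: f(0.2)=1; 0.55 >= mu so f=e^(1-0.55); f(0.8)=e^0.2
  expected <- (1 * -log(0.9) +
                 exp(0.45) * -log(0.6) +
                 exp(0.2) * -log(0.7)) / 3
  expect_equal(slide_loss(b), expected, tolerance = 1e-9)
  expect_equal(expected, 0.4473797, tolerance = 1e-6)
  # linearity in the loss factor
  expect_equal(slide_loss(b, weights = 3 * slide_weight(b$iou, mu)),
               3 * slide_loss(b), tolerance = 1e-12)
  expect_error(slide_loss(b[0, ]), "degenerate")
})

test_that("complete-IoU loss matches the term-by-term reference", {
  expect_equal(ciou_loss(c(1, 2, 5, 7), c(1, 2, 5, 7)), 0,
               tolerance = 1e-8)
  set.seed(64)
  for (i in 1:25) {
    p <- c(sort(runif(2, 0, 50)), 0, 0); p <- c(p[1], p[3], p[2], p[4])
    p <- { x1 <- runif(1, 0, 40); y1 <- runif(1, 0, 40)
           c(x1, y1, x1 + runif(1, 1, 30), y1 + runif(1, 1, 30)) }
    t <- { x1 <- runif(1, 0, 40); y1 <- runif(1, 0, 40)
           c(x1, y1, x1 + runif(1, 1, 30), y1 + runif(1, 1, 30)) }
    expect_equal(ciou_loss(p, t), ciou_ref(p, t), tolerance = 1e-8)
  }
  expect_error(ciou_loss(c(0, 0, 1, 1), c(2, 2, 2, 5)), "invalid target")
})

test_that("distribution focal loss brackets continuous offsets", {
  set.seed(65)
  logits <- rnorm(16)
  # integer target k: reduces to -log softmax_k
  for (k in c(0, 3, 14)) {
    expect_equal(dfl_loss(logits, k),
                 -(logits[k + 1] - max(logits) -
                     log(sum(exp(logits - max(logits))))),
                 tolerance = 1e-10)
  }
  # fractional target: proximity-weighted two-bin cross-entropy
  L <- matrix(rnorm(32), 16, 2)
  t <- c(2.3, 7.9)
  logp <- apply(L, 2, function(col) col - max(col) -
                  log(sum(exp(col - max(col)))))
  ref <- mean(c(-(0.7 * logp[3, 1] + 0.3 * logp[4, 1]),
                -(0.1 * logp[8, 2] + 0.9 * logp[9, 2])))
  expect_equal(dfl_loss(L, t), ref, tolerance = 1e-10)
  expect_error(dfl_loss(logits, 15.5), "outside")
})

# build a one-level prediction whose decoded box at cell (i, j) is exact
exact_pred <- function(H, W, stride, reg_max = 16L, nc = 4L) {
  box <- array(0, c(H, W, 4L * reg_max, 1L))
  # put all mass on bins 0 and 1 equally -> expectation 0.5 per side
  for (s in 0:3) {
    box[, , s * reg_max + 1L, ] <- 25
    box[, , s * reg_max + 2L, ] <- 25
  }
  list(list(cls = array(0, c(H, W, nc, 1L)), box = box, stride = stride))
}

test_that("assignment marks exact-cell targets positive with x = 1", {
  preds <- exact_pred(2L, 2L, 8)
  # target exactly covers cell (1,1): decoded box (0,0,8,8)
  a <- assign_targets(preds, targets = matrix(c(0, 0, 8, 8), 1),
                      target_classes = 2L)
  pos <- a[a$y == 1, ]
  expect_identical(nrow(pos), 1L)
  expect_identical(pos$cell, 1L)
  expect_equal(pos$x, 1, tolerance = 1e-6)
  expect_identical(pos$class, 2L)
})

test_that("assignment with no targets yields an all-negative batch", {
  preds <- exact_pred(3L, 3L, 8)
  a <- assign_targets(preds, targets = NULL)
  expect_true(all(a$y == 0))
  expect_true(all(a$x == 0))
})

test_that("contended candidates keep the higher-IoU target", {
  preds <- exact_pred(2L, 2L, 8)
  # both targets contain the (1,1) anchor centre (4,4); the first matches
  # the decoded box (0,0,8,8) perfectly
  tg <- rbind(c(0, 0, 8, 8), c(0, 0, 6, 6))
  a <- assign_targets(preds, tg, target_classes = c(1L, 2L))
  p11 <- a[a$cell == 1 & a$y == 1, ]
  expect_identical(p11$target, 1L)
  # enumeration oracle: IoU with target 1 is 1, with target 2 is 36/64
  expect_gt(1, 36 / 64)
})
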