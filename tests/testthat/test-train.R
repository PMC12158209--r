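# Training-driver contracts on a deliberately tiny dataset, so each
# test stays within seconds while still exercising the full loop.

tiny_dataset <- function(n = 10, seed = 71L) {
  dir <- tempfile("tinyds")
  sp <- scene_spec(image_size = c(64L, 64L), seed = seed,
                   n_objects = c(1L, 3L), size_range = c(0.15, 0.4))
  generate_dataset(sp, n, dir)
  dir
}

tiny_cfg <- function(...) {
  load_config(overrides = utils::modifyList(
    list(image_size = 64L, epochs = 1L, batch_size = 4L, seed = 3L,
         model = list(width_multiple = 0.125)),
    list(...)))
}

test_that("one epoch on a tiny dataset produces loss, checkpoint and log", {
  dir <- tiny_dataset()
  ck <- tempfile(fileext = ".rds")
  lg <- tempfile(fileext = ".jsonl")
  r <- train_detector(tiny_cfg(), dir, checkpoint_path = ck,
                      log_file = lg, quiet = TRUE)
  expect_identical(nrow(r$history), 1L)
  expect_true(is.finite(r$history$loss))
  expect_true(file.exists(ck))
  lines <- readLines(lg)
  expect_identical(length(lines), 1L)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_identical(parsed$epoch, 1L)
  expect_true(is.numeric(parsed$mAP50))
  unlink(c(ck, lg)); unlink(dir, recursive = TRUE)
})

test_that("early stopping halts after `patience` stagnant epochs", {
  dir <- tiny_dataset()
  # freeze the weights so validation mAP cannot improve after epoch 1
  cfg <- tiny_cfg(epochs = 10L, patience = 2L, lr0 = 0)
  r <- train_detector(cfg, dir, quiet = TRUE)
  expect_identical(nrow(r$history), 3L)
  unlink(dir, recursive = TRUE)
})

test_that("the first-batch loss replays from the assignment contract", {
  dir <- tiny_dataset(n = 6)
  cfg <- tiny_cfg(batch_size = 2L)
  items <- reefdet:::load_split(dir, "train")[1:2]
  set.seed(9)
  model <- build_model(reefdet:::run_model_config(cfg))
  x <- array(0, c(64, 64, 3, 2))
  tgts <- list()
  for (k in 1:2) {
    x[, , , k] <- items[[k]]$image
    tgts[[k]] <- reefdet:::targets_from_boxes(items[[k]]$boxes, 64, 64)
  }
  state <- new.env(); state$mu <- 0.5
  tp <- reefdet:::new_tape()
  outs <- reefdet:::fwd_model(tp, reefdet:::op_input(tp, x), model, TRUE)
  loss <- reefdet:::detection_loss(tp, outs, tgts, cfg, state)
  got <- reefdet:::tp_value(tp, loss$node)

  # independent recomputation from the head outputs and the exported
  # loss pieces: slide-weighted BCE + CIoU + DFL with the same
  # normalisation (sum / n_pos, lambda weights 0.5 / 7.5 / 1.5)
  outs_v <- lapply(outs, function(l)
    list(cls = reefdet:::tp_value(tp, l$cls),
         box = reefdet:::tp_value(tp, l$box), stride = l$stride))
  n_pos <- 0; mu_x <- c()
  per_img <- list()
  for (k in 1:2) {
    preds <- lapply(outs_v, function(l)
      list(cls = l$cls[, , , k, drop = FALSE],
           box = l$box[, , , k, drop = FALSE], stride = l$stride))
    a <- assign_targets(preds, tgts[[k]]$boxes, tgts[[k]]$classes,
                        reg_max = 16L)
    per_img[[k]] <- a
    mu_x <- c(mu_x, a$x[a$y == 1])
    n_pos <- n_pos + sum(a$y)
  }
  mu <- mean(pmin(pmax(mu_x, 0), 1))
  cls_sum <- 0; box_sum <- 0; dfl_sum <- 0
  for (k in 1:2) {
    a <- per_img[[k]]
    for (li in 1:3) {
      l <- outs_v[[li]]
      al <- a[a$level == li, ]
      d <- dim(l$cls)
      wcell <- slide_weight(pmin(pmax(al$x, 0), 1), mu)
      yv <- matrix(0, d[1] * d[2], d[3])
      posl <- al[al$y == 1, ]
      if (nrow(posl)) yv[cbind(posl$cell, posl$class)] <- 1
      logits <- matrix(l$cls[, , , k], d[1] * d[2], d[3])
      cls_sum <- cls_sum + sum(wcell * bce(logits, yv))
      if (nrow(posl)) {
        bx <- reefdet:::decode_boxes(l$box[, , , k, drop = FALSE],
                                     l$stride, 16L)
        tb <- tgts[[k]]$boxes[posl$target, , drop = FALSE]
        box_sum <- box_sum + sum(ciou_loss(bx[posl$cell, , drop = FALSE],
                                           tb))
        ac <- reefdet:::anchor_centers(d[1], d[2], l$stride)
        for (r in seq_len(nrow(posl))) {
          cell <- posl$cell[r]
          tt <- c((ac[cell, "x"] - tb[r, 1]), (ac[cell, "y"] - tb[r, 2]),
                  (tb[r, 3] - ac[cell, "x"]), (tb[r, 4] - ac[cell, "y"])) /
            l$stride
          tt <- pmin(pmax(tt, 0), 15 - 0.01)
          for (s in 1:4) {
            lg <- l$box[(cell - 1) %% d[1] + 1,
                        (cell - 1) %/% d[1] + 1,
                        (s - 1) * 16 + 1:16, k]
            dfl_sum <- dfl_sum + dfl_loss(lg, tt[s])
          }
        }
      }
    }
  }
  expected <- 0.5 * cls_sum / n_pos + 7.5 * box_sum / n_pos +
    1.5 * dfl_sum / (4 * n_pos)
  expect_equal(got, expected, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("decoded detections respect score threshold and NMS contract", {
  set.seed(73)
  m <- build_model(model_config("mas", width_multiple = 0.125))
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  outs <- model_forward(m, x)
  d <- decode_detections(outs, score_thr = 0.0009, iou_thr = 0.7)
  if (nrow(d)) {
    expect_true(all(d$score >= 0.0009))
    expect_true(all(d$class %in% 1:4))
  }
  expect_identical(
    nrow(decode_detections(outs, score_thr = 0.999999)), 0L)
})
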