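# Training driver: composite detection loss on the autodiff tape,
# SGD with momentum, per-epoch validation mAP, early stopping, and the
# noise-robustness sweep.

# composite loss for one batch; returns list(node, components, n_pos)
detection_loss <- function(tp, outs, targets, cfg, state) {
  nc <- cfg$model$num_classes
  reg_max <- cfg$model$reg_max
  N <- length(targets)
  assigns <- vector("list", N)
  # assignment on detached values
  for (n in seq_len(N)) {
    preds <- lapply(outs, function(l) {
      list(cls = tp$vals[[l$cls]][, , , n, drop = FALSE],
           box = tp$vals[[l$box]][, , , n, drop = FALSE],
           stride = l$stride)
    })
    tg <- targets[[n]]
    assigns[[n]] <- assign_targets(preds, tg$boxes, tg$classes,
                                   reg_max = reg_max)
  }
  pos_x <- unlist(lapply(assigns, function(a) a$x[a$y == 1]))
  n_pos <- length(pos_x)
  mu <- if (n_pos > 0) {
    m <- mean_iou_threshold(pmin(pmax(pos_x, 0), 1))
    min(max(m, 1e-3), 1 - 1e-3)
  } else state$mu
  state$mu <- mu
  slide_on <- isTRUE(cfg$loss$slide$enabled)
  # ---- classification term ----
  cls_terms <- vector("list", length(outs))
  for (li in seq_along(outs)) {
    l <- outs[[li]]
    d <- dim(tp$vals[[l$cls]])
    y <- array(0, dim = d)
    w <- array(1, dim = d)
    for (n in seq_len(N)) {
      a <- assigns[[n]]
      al <- a[a$level == li, ]
      if (slide_on) {
        wcell <- slide_weight(pmin(pmax(al$x, 0), 1), mu)
        w[, , , n] <- array(rep(wcell, d[3]), dim = d[1:3])
      }
      posl <- al[al$y == 1 & !is.na(al$class), ]
      if (nrow(posl)) {
        hw <- d[1] * d[2]
        yv <- as.numeric(y[, , , n])
        yv[posl$cell + (posl$class - 1L) * hw] <- 1
        y[, , , n] <- array(yv, dim = d[1:3])
      }
    }
    cls_terms[[li]] <- op_sum(tp, op_wbce(tp, l$cls, y, w))
  }
  cls_node <- cls_terms[[1]]
  for (li in 2:length(cls_terms)) cls_node <- op_add(tp, cls_node,
                                                     cls_terms[[li]])
  cls_node <- op_const_mul(tp, cls_node, 1 / max(n_pos, 1))
  total <- op_const_mul(tp, cls_node, cfg$loss$cls)
  comps <- list(cls = tpf(tp, cls_node))
  # ---- localisation terms ----
  if (n_pos > 0) {
    dfl_nodes <- list(); iou_nodes <- list()
    for (li in seq_along(outs)) {
      l <- outs[[li]]
      d <- dim(tp$vals[[l$box]])
      H <- d[1]; W <- d[2]; C <- d[3]
      for (n in seq_len(N)) {
        a <- assigns[[n]]
        posl <- a[a$level == li & a$y == 1, ]
        M <- nrow(posl)
        if (M == 0) next
        tg <- targets[[n]]
        tb <- tg$boxes[posl$target, , drop = FALSE]
        stride <- l$stride
        ac <- anchor_centers(H, W, stride)[posl$cell, , drop = FALSE]
        # ltrb distances in stride units
        tl <- (ac[, "x"] - tb[, 1]) / stride
        tt <- (ac[, "y"] - tb[, 2]) / stride
        tr <- (tb[, 3] - ac[, "x"]) / stride
        tbm <- (tb[, 4] - ac[, "y"]) / stride
        tmat <- pmin(pmax(cbind(tl, tt, tr, tbm), 0), reg_max - 1 - 0.01)
        # gather logits: columns ordered side-fastest within each positive
        idx <- integer(0)
        for (m in seq_len(M)) {
          base <- posl$cell[m] + (n - 1L) * H * W * C
          for (s in 0:3)
            idx <- c(idx, base + H * W * (s * reg_max + 0:(reg_max - 1)))
        }
        gl <- op_gather(tp, l$box, idx)
        glm <- op_reshape(tp, gl, c(reg_max, 4L * M))
        toff <- as.numeric(t(tmat)) # side-fastest to match columns
        dfl_nodes[[length(dfl_nodes) + 1]] <-
          op_sum(tp, op_dfl(tp, glm, toff))
        # decode predicted boxes and CIoU
        ev <- op_dfl_expect(tp, glm) # length 4M, side-fastest
        sel <- function(s) op_gather(tp, ev, seq(s, 4L * M, by = 4L))
        pl <- sel(1); pt <- sel(2); pr <- sel(3); pb <- sel(4)
        axn <- op_input(tp, ac[, "x"]); ayn <- op_input(tp, ac[, "y"])
        px1 <- op_sub(tp, axn, op_const_mul(tp, pl, stride))
        py1 <- op_sub(tp, ayn, op_const_mul(tp, pt, stride))
        px2 <- op_add(tp, axn, op_const_mul(tp, pr, stride))
        py2 <- op_add(tp, ayn, op_const_mul(tp, pb, stride))
        iou_nodes[[length(iou_nodes) + 1]] <-
          tape_ciou_sum(tp, px1, py1, px2, py2, tb)
      }
    }
    if (length(dfl_nodes)) {
      dfl_node <- dfl_nodes[[1]]
      if (length(dfl_nodes) > 1)
        for (i in 2:length(dfl_nodes))
          dfl_node <- op_add(tp, dfl_node, dfl_nodes[[i]])
      dfl_node <- op_const_mul(tp, dfl_node, 1 / (4 * n_pos))
      box_node <- iou_nodes[[1]]
      if (length(iou_nodes) > 1)
        for (i in 2:length(iou_nodes))
          box_node <- op_add(tp, box_node, iou_nodes[[i]])
      box_node <- op_const_mul(tp, box_node, 1 / n_pos)
      comps$dfl <- tpf(tp, dfl_node)
      comps$box <- tpf(tp, box_node)
      total <- op_add(tp, total, op_const_mul(tp, dfl_node, cfg$loss$dfl))
      total <- op_add(tp, total, op_const_mul(tp, box_node, cfg$loss$box))
    }
  }
  list(node = total, components = comps, n_pos = n_pos, mu = mu)
}

# sum of CIoU losses of predicted (node) boxes vs constant target boxes
tape_ciou_sum <- function(tp, px1, py1, px2, py2, tb) {
  eps <- 1e-9
  tx1 <- op_input(tp, tb[, 1]); ty1 <- op_input(tp, tb[, 2])
  tx2 <- op_input(tp, tb[, 3]); ty2 <- op_input(tp, tb[, 4])
  zero <- op_input(tp, numeric(nrow(tb)))
  w1 <- op_sub(tp, px2, px1); h1 <- op_sub(tp, py2, py1)
  w2 <- op_sub(tp, tx2, tx1); h2 <- op_sub(tp, ty2, ty1)
  iw <- op_pmax(tp, op_sub(tp, op_pmin(tp, px2, tx2),
                           op_pmax(tp, px1, tx1)), zero)
  ih <- op_pmax(tp, op_sub(tp, op_pmin(tp, py2, ty2),
                           op_pmax(tp, py1, ty1)), zero)
  inter <- op_mul(tp, iw, ih)
  area1 <- op_mul(tp, op_pmax(tp, w1, zero), op_pmax(tp, h1, zero))
  area2 <- op_mul(tp, w2, h2)
  un <- op_const_add(tp, op_sub(tp, op_add(tp, area1, area2), inter), eps)
  iou <- op_div(tp, inter, un)
  cw <- op_sub(tp, op_pmax(tp, px2, tx2), op_pmin(tp, px1, tx1))
  chh <- op_sub(tp, op_pmax(tp, py2, ty2), op_pmin(tp, py1, ty1))
  c2 <- op_const_add(tp, op_add(tp, op_square(tp, cw), op_square(tp, chh)),
                     eps)
  dx <- op_sub(tp, op_add(tp, px1, px2), op_add(tp, tx1, tx2))
  dy <- op_sub(tp, op_add(tp, py1, py2), op_add(tp, ty1, ty2))
  rho2 <- op_const_mul(tp, op_add(tp, op_square(tp, dx), op_square(tp, dy)),
                       0.25)
  at1 <- op_atan(tp, op_div(tp, w1, op_const_add(tp, op_pmax(tp, h1, zero),
                                                 eps)))
  at2 <- atan((tb[, 3] - tb[, 1]) / (tb[, 4] - tb[, 2] + eps))
  v <- op_const_mul(tp, op_square(tp, op_sub(tp, op_input(tp, at2), at1)),
                    4 / pi^2)
  # alpha treated as a constant (computed from current values)
  alpha <- tpf(tp, v) / (1 - tpf(tp, iou) + tpf(tp, v) + eps)
  term <- op_add(tp, op_sub(tp, op_const_add(tp, op_const_mul(tp, iou, -1),
                                             1),
                            op_const_mul(tp, op_div(tp, rho2, c2), -1)),
                 op_mul(tp, op_input(tp, alpha), v))
  op_sum(tp, term)
}

.split_cache <- new.env(parent = emptyenv())

load_split <- function(data_dir, split) {
  img_dir <- file.path(data_dir, "images", split)
  lab_dir <- file.path(data_dir, "labels", split)
  if (!dir.exists(img_dir)) stop("missing dataset split: ", img_dir,
                                 call. = FALSE)
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  key <- paste0(normalizePath(img_dir), "|", length(files))
  hit <- .split_cache[[key]]
  if (!is.null(hit)) return(hit)
  items <- lapply(files, function(f) {
    img <- png::readPNG(file.path(img_dir, f))
    boxes <- read_yolo_labels(file.path(lab_dir, sub("\\.png$", ".txt", f)))
    list(name = f, image = img, boxes = boxes)
  })
  .split_cache[[key]] <- items
  items
}

# normalised cxcywh -> pixel xyxy + 1-based classes
targets_from_boxes <- function(boxes, H, W) {
  if (nrow(boxes) == 0) return(list(boxes = NULL, classes = integer(0)))
  x1 <- (boxes$cx - boxes$w / 2) * W
  y1 <- (boxes$cy - boxes$h / 2) * H
  x2 <- (boxes$cx + boxes$w / 2) * W
  y2 <- (boxes$cy + boxes$h / 2) * H
  list(boxes = cbind(x1, y1, x2, y2), classes = boxes$class + 1L)
}

hflip_item <- function(item) {
  item$image <- item$image[, rev(seq_len(dim(item$image)[2])), ,
                           drop = FALSE]
  if (nrow(item$boxes)) item$boxes$cx <- 1 - item$boxes$cx
  item
}

vflip_item <- function(item) {
  item$image <- item$image[rev(seq_len(dim(item$image)[1])), , ,
                           drop = FALSE]
  if (nrow(item$boxes)) item$boxes$cy <- 1 - item$boxes$cy
  item
}

#' Decode raw head outputs of one image into detections
#'
#' @param outs `model_forward()` output (levels with `cls`, `box`,
#'   `stride`)
#' @param n image index within the batch
#' @param reg_max distribution bins
#' @param score_thr minimum class score
#' @param iou_thr NMS IoU threshold
#' @param max_det detection cap
#' @return data.frame `class` (1-based), `score`, `x1`, `y1`, `x2`, `y2`
#' @export
decode_detections <- function(outs, n = 1L, reg_max = 16L,
                              score_thr = 0.25, iou_thr = 0.7,
                              max_det = 300L) {
  rows <- lapply(outs, function(l) {
    cls <- l$cls[, , , n, drop = FALSE]
    d <- dim(cls)
    scores <- matrix(stats::plogis(cls), d[1] * d[2], d[3])
    bx <- decode_boxes(l$box[, , , n, drop = FALSE], l$stride, reg_max)
    keep <- which(scores >= score_thr, arr.ind = TRUE)
    if (nrow(keep) == 0) return(NULL)
    data.frame(class = keep[, 2], score = scores[keep],
               x1 = bx[keep[, 1], 1], y1 = bx[keep[, 1], 2],
               x2 = bx[keep[, 1], 3], y2 = bx[keep[, 1], 4])
  })
  dets <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(dets) || nrow(dets) == 0)
    return(data.frame(class = integer(0), score = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0)))
  nms(dets, iou_thr = iou_thr, score_thr = score_thr, max_det = max_det)
}

#' Run a model over a list of scenes and evaluate
#'
#' @param model an `rd_model`
#' @param items list of scene items (`image` in `[0,1]`, `boxes`)
#' @param score_thr decoding score threshold (low for mAP evaluation)
#' @param batch images per forward pass
#' @return list with `result` (an `eval_result`) and `detections`
#' @export
evaluate_model <- function(model, items, score_thr = 0.05, batch = 8L) {
  reg_max <- model$cfg$reg_max
  dets <- NULL; gts <- NULL
  i <- 1L
  while (i <= length(items)) {
    take <- i:min(i + batch - 1L, length(items))
    x <- array(0, dim = c(dim(items[[take[1]]]$image)[1:2], 3,
                          length(take)))
    for (k in seq_along(take)) x[, , , k] <- items[[take[k]]]$image
    outs <- model_forward(model, x, training = FALSE)
    for (k in seq_along(take)) {
      dd <- decode_detections(outs, k, reg_max, score_thr = score_thr,
                              iou_thr = 0.7, max_det = 100L)
      if (nrow(dd)) {
        dd$image <- take[k]
        dets <- rbind(dets, dd)
      }
      H <- dim(items[[take[k]]]$image)[1]
      W <- dim(items[[take[k]]]$image)[2]
      tg <- targets_from_boxes(items[[take[k]]]$boxes, H, W)
      if (!is.null(tg$boxes)) {
        gts <- rbind(gts, data.frame(image = take[k], class = tg$classes,
                                     x1 = tg$boxes[, 1], y1 = tg$boxes[, 2],
                                     x2 = tg$boxes[, 3], y2 = tg$boxes[, 4]))
      }
    }
    i <- i + batch
  }
  res <- evaluate_detections(dets, gts,
                             classes = seq_len(model$cfg$num_classes))
  list(result = res, detections = dets, ground_truth = gts)
}

#' Train a detector
#'
#' SGD with momentum and weight decay per the run configuration, linear
#' learning-rate decay to `0.01 * lr0`, horizontal-flip augmentation, an
#' exponential moving average of the weights for validation (the
#' lineage's standard evaluation weights), per-epoch validation mAP@50
#' and early stopping on `patience` epochs without improvement.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [load_config()] result
#' @param data_dir dataset directory in the generator layout
#' @param checkpoint_path optional path for the best checkpoint
#' @param log_file optional path receiving one JSON object per epoch
#' @param quiet suppress per-epoch console lines
#' @return list: `model`, `history` (data.frame), `best_mAP50`
#' @export
train_detector <- function(cfg, data_dir, checkpoint_path = NULL,
                           log_file = NULL, quiet = FALSE) {
  set.seed(cfg$seed)
  train_items <- load_split(data_dir, "train")
  val_items <- load_split(data_dir, "val")
  model <- build_model(run_model_config(cfg))
  params <- layer_params(list(model$layers, head = model$head))
  state <- new.env(parent = emptyenv())
  state$mu <- cfg$loss$slide$init_mu
  nb <- ceiling(length(train_items) / cfg$batch_size)
  total_steps <- cfg$epochs * nb
  step <- 0L
  best <- -Inf; best_epoch <- 0L
  history <- NULL
  ema <- lapply(params, function(p) p$value)
  swap_in_ema <- function() {
    for (nm in names(params)) {
      tmp <- params[[nm]]$value
      params[[nm]]$value <- ema[[nm]]
      ema[[nm]] <<- tmp
    }
  }
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(train_items))
    ep_loss <- 0; ep_n <- 0L
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):
                   min(b * cfg$batch_size, length(train_items))]
      items <- lapply(train_items[idx], function(it)
        if (stats::runif(1) < 0.5) hflip_item(it) else it)
      H <- dim(items[[1]]$image)[1]; W <- dim(items[[1]]$image)[2]
      x <- array(0, dim = c(H, W, 3, length(items)))
      tgts <- vector("list", length(items))
      for (k in seq_along(items)) {
        x[, , , k] <- items[[k]]$image
        tgts[[k]] <- targets_from_boxes(items[[k]]$boxes, H, W)
      }
      tp <- new_tape()
      outs <- fwd_model(tp, op_input(tp, x), model, training = TRUE)
      lr_frac <- 1 - (step / max(total_steps, 1)) * 0.99
      lr <- cfg$lr0 * lr_frac
      warm <- min(1, (step + 1) / max(3 * nb, 1))
      loss <- detection_loss(tp, outs, tgts, cfg, state)
      zero_grads(params)
      tp_backward(tp, loss$node)
      sgd_step(params, lr * warm, cfg$momentum, cfg$weight_decay)
      ep_loss <- ep_loss + tp$vals[[loss$node]] * length(items)
      ep_n <- ep_n + length(items)
      step <- step + 1L
      # EMA of the weights, ramping toward its asymptotic decay
      d <- 0.99 * (1 - exp(-step / 50))
      for (nm in names(params))
        ema[[nm]] <- d * ema[[nm]] + (1 - d) * params[[nm]]$value
    }
    eval_now <- epoch %% max(1L, cfg$eval_every) == 0L ||
      epoch == cfg$epochs
    if (eval_now) {
      swap_in_ema() # validate (and possibly checkpoint) the EMA weights
      ev <- evaluate_model(model, val_items)
      m50 <- ev$result$mAP50
      row <- data.frame(epoch = epoch, loss = ep_loss / ep_n,
                        mAP50 = m50, mAP50_95 = ev$result$mAP50_95,
                        P = ev$result$P, R = ev$result$R, mu = state$mu)
      history <- rbind(history, row)
      line <- jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = 6)
      if (!is.null(log_file)) cat(line, "\n", file = log_file,
                                  append = TRUE)
      if (!quiet) message(line)
      if (m50 > best) {
        best <- m50; best_epoch <- epoch
        if (!is.null(checkpoint_path)) save_checkpoint(model,
                                                       checkpoint_path)
      }
      if (epoch - best_epoch >= cfg$patience || epoch == cfg$epochs) break
      swap_in_ema() # restore the raw weights for the next training epoch
    }
  }
  if (!is.null(checkpoint_path) && !file.exists(checkpoint_path))
    save_checkpoint(model, checkpoint_path)
  list(model = model, history = history, best_mAP50 = best)
}

#' Save / load a model checkpoint
#'
#' Single-file serialised weights with the embedded model configuration.
#'
#' @param model an `rd_model`
#' @param path checkpoint file
#' @export
save_checkpoint <- function(model, path) {
  params <- layer_params(list(model$layers, head = model$head))
  bns <- layer_bn_envs(list(model$layers, head = model$head))
  saveRDS(list(cfg = unclass(model$cfg),
               values = lapply(params, function(p) p$value),
               bn = lapply(bns, function(e) list(rmean = e$rmean,
                                                 rvar = e$rvar))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return (load) the restored `rd_model`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$cfg
  class(cfg) <- "model_config"
  class(cfg$attention) <- "attention_config"
  model <- build_model(cfg)
  params <- layer_params(list(model$layers, head = model$head))
  stopifnot(identical(names(params), names(ck$values)))
  for (nm in names(params)) params[[nm]]$value <- ck$values[[nm]]
  bns <- layer_bn_envs(list(model$layers, head = model$head))
  for (nm in names(ck$bn)) {
    bns[[nm]]$rmean <- ck$bn[[nm]]$rmean
    bns[[nm]]$rvar <- ck$bn[[nm]]$rvar
  }
  model
}

#' Noise-robustness sweep
#'
#' Evaluates a trained model on a test split corrupted by Poisson noise
#' (per scale) and Gaussian noise (per sigma); `sigma = 0` and
#' `scale = Inf` leave images untouched.
#'
#' @param model an `rd_model` (or checkpoint path)
#' @param data_dir dataset directory
#' @param poisson_scales Poisson noise scales (smaller = stronger)
#' @param gaussian_sigmas Gaussian sigmas in 8-bit units
#' @param seed RNG seed for the noise draws
#' @param split dataset split to corrupt
#' @param items optional list of scene items (each with `image` in
#'   `[0, 1]` and `boxes`) evaluated instead of loading `split` from
#'   `data_dir`
#' @param csv optional output CSV path
#' @return data.frame: `kind`, `level`, `P`, `R`, `mAP50`, `mAP50_95`
#' @export
noise_sweep <- function(model, data_dir = NULL,
                        poisson_scales = c(Inf, 2.0, 1.5, 1.0, 0.5, 0.1),
                        gaussian_sigmas = c(0, 5, 10, 15, 20),
                        seed = 0L, split = "test", items = NULL,
                        csv = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.null(items)) items <- load_split(data_dir, split)
  corrupt_eval <- function(fn) {
    its <- lapply(items, function(it) {
      img8 <- array(as.integer(round(it$image * 255)), dim = dim(it$image))
      it$image <- fn(img8) / 255
      it
    })
    evaluate_model(model, its)$result
  }
  rows <- NULL
  for (s in gaussian_sigmas) {
    set.seed(seed + 1000L)
    r <- corrupt_eval(function(im) add_gaussian_noise(im, s))
    rows <- rbind(rows, data.frame(kind = "gaussian", level = s, P = r$P,
                                   R = r$R, mAP50 = r$mAP50,
                                   mAP50_95 = r$mAP50_95))
  }
  for (s in poisson_scales) {
    set.seed(seed + 2000L)
    r <- if (is.finite(s)) corrupt_eval(function(im) add_poisson_noise(im, s))
         else corrupt_eval(identity)
    rows <- rbind(rows, data.frame(kind = "poisson", level = s, P = r$P,
                                   R = r$R, mAP50 = r$mAP50,
                                   mAP50_95 = r$mAP50_95))
  }
  if (!is.null(csv)) utils::write.csv(rows, csv, row.names = FALSE)
  rows
}
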