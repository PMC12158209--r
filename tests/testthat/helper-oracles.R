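# Independent reference implementations used as oracles.  These are
# written as direct transcriptions of the definitions (double loops,
# explicit formulas) and stay independent of the package's vectorised
# code paths.

# brute-force sliding-window dilated attention
swda_brute <- function(q, k, v, rate, kern, scale) {
  d <- dim(q); H <- d[1]; W <- d[2]; N <- d[4]
  half <- (kern - 1) / 2
  y <- array(0, d)
  for (n in seq_len(N)) for (i in seq_len(H)) for (j in seq_len(W)) {
    lg <- c(); vs <- NULL
    for (a in -half:half) for (b in -half:half) {
      ii <- i + a * rate; jj <- j + b * rate
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      lg <- c(lg, sum(q[i, j, , n] * k[ii, jj, , n]) * scale)
      vs <- rbind(vs, v[ii, jj, , n])
    }
    p <- exp(lg - max(lg)); p <- p / sum(p)
    y[i, j, , n] <- as.numeric(t(vs) %*% p)
  }
  y
}

# 1x1 convolution as an explicit channel-mixing matrix product
conv1x1_ref <- function(x, w, b) {
  d <- dim(x)
  W <- matrix(w, dim(w)[3], dim(w)[4]) # cin x cout
  out <- array(0, c(d[1], d[2], dim(w)[4], d[4]))
  for (n in seq_len(d[4])) {
    xm <- matrix(x[, , , n], d[1] * d[2], d[3])
    out[, , , n] <- array(xm %*% W, c(d[1], d[2], dim(w)[4]))
  }
  for (c in seq_len(dim(w)[4])) out[, , c, ] <- out[, , c, ] + b[c]
  out
}

# literal complete-IoU reference, term by term
ciou_ref <- function(p, t) {
  eps <- 1e-9
  iw <- max(0, min(p[3], t[3]) - max(p[1], t[1]))
  ih <- max(0, min(p[4], t[4]) - max(p[2], t[2]))
  inter <- iw * ih
  a1 <- (p[3] - p[1]) * (p[4] - p[2])
  a2 <- (t[3] - t[1]) * (t[4] - t[2])
  iou <- inter / (a1 + a2 - inter + eps)
  cw <- max(p[3], t[3]) - min(p[1], t[1])
  ch <- max(p[4], t[4]) - min(p[2], t[2])
  rho2 <- ((p[1] + p[3]) / 2 - (t[1] + t[3]) / 2)^2 +
    ((p[2] + p[4]) / 2 - (t[2] + t[4]) / 2)^2
  v <- 4 / pi^2 * (atan((t[3] - t[1]) / (t[4] - t[2] + eps)) -
                     atan((p[3] - p[1]) / (p[4] - p[2] + eps)))^2
  alpha <- v / (1 - iou + v + eps)
  1 - iou + rho2 / (cw^2 + ch^2 + eps) + alpha * v
}

# COCO-style evaluator transcription: per-image greedy matching at each
# IoU threshold (detections sorted by score, ground truths matched once,
# ties to the highest IoU), then 101-point interpolated AP.
coco_eval_ref <- function(dets, gts, classes,
                          thresholds = seq(0.5, 0.95, by = 0.05)) {
  iou1 <- function(a, b) {
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
      inter
    if (un <= 0) 0 else inter / un
  }
  ap_mat <- matrix(NA_real_, length(classes), length(thresholds))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    gc <- gts[gts$class == cl, , drop = FALSE]
    dc <- dets[dets$class == cl, , drop = FALSE]
    ngt <- nrow(gc)
    for (ti in seq_along(thresholds)) {
      thr <- thresholds[ti]
      scores <- c(); matched <- c()
      for (img in unique(c(dc$image, gc$image))) {
        di <- dc[dc$image == img, , drop = FALSE]
        gi <- gc[gc$image == img, , drop = FALSE]
        if (nrow(di)) di <- di[order(-di$score), , drop = FALSE]
        used <- rep(FALSE, nrow(gi))
        for (r in seq_len(nrow(di))) {
          best <- thr - 1e-12; bj <- 0
          for (jg in seq_len(nrow(gi))) {
            if (used[jg]) next
            v <- iou1(as.numeric(di[r, c("x1", "y1", "x2", "y2")]),
                      as.numeric(gi[jg, c("x1", "y1", "x2", "y2")]))
            if (v >= thr && v > best) { best <- v; bj <- jg }
          }
          ok <- bj > 0
          if (ok) used[bj] <- TRUE
          scores <- c(scores, di$score[r])
          matched <- c(matched, ok)
        }
      }
      if (ngt == 0) { ap_mat[ci, ti] <- NA_real_; next }
      if (!length(scores) || !any(matched)) { ap_mat[ci, ti] <- 0; next }
      ord <- order(-scores)
      tp <- cumsum(matched[ord]); fp <- cumsum(!matched[ord])
      rc <- tp / ngt; pr <- tp / (tp + fp)
      # 101-point: precision at recall >= r, envelope from the right
      q <- numeric(101)
      penv <- rev(cummax(rev(pr)))
      rg <- seq(0, 1, 0.01)
      for (ri in seq_along(rg)) {
        ok <- which(rc >= rg[ri] - 1e-12)
        q[ri] <- if (length(ok)) penv[ok[1]] else 0
      }
      ap_mat[ci, ti] <- mean(q)
    }
  }
  defined <- !is.na(ap_mat[, 1])
  list(mAP50 = mean(ap_mat[defined, 1]),
       mAP50_95 = mean(rowMeans(ap_mat[defined, , drop = FALSE])),
       ap = ap_mat)
}

# random scene of boxes + jittered detections for evaluator comparisons
random_eval_case <- function(n_images = 3, n_classes = 2, seed = 1) {
  set.seed(seed)
  gts <- NULL; dets <- NULL
  for (img in seq_len(n_images)) {
    for (b in seq_len(sample(1:4, 1))) {
      x1 <- runif(1, 0, 60); y1 <- runif(1, 0, 60)
      w <- runif(1, 8, 30); h <- runif(1, 8, 30)
      cl <- sample(n_classes, 1)
      gts <- rbind(gts, data.frame(image = img, class = cl, x1 = x1,
                                   y1 = y1, x2 = x1 + w, y2 = y1 + h))
      # jittered detection, sometimes missing, sometimes duplicated
      for (r in seq_len(sample(0:2, 1))) {
        j <- rnorm(4, 0, 3)
        dets <- rbind(dets, data.frame(
          image = img, class = if (runif(1) < 0.9) cl
                               else sample(n_classes, 1),
          score = runif(1), x1 = x1 + j[1], y1 = y1 + j[2],
          x2 = x1 + w + j[3], y2 = y1 + h + j[4]))
      }
    }
    # occasional spurious detection
    if (runif(1) < 0.5) {
      x1 <- runif(1, 60, 90); y1 <- runif(1, 60, 90)
      dets <- rbind(dets, data.frame(image = img,
                                     class = sample(n_classes, 1),
                                     score = runif(1), x1 = x1, y1 = y1,
                                     x2 = x1 + 10, y2 = y1 + 10))
    }
  }
  if (!is.null(dets)) {
    dets$x2 <- pmax(dets$x2, dets$x1 + 1)
    dets$y2 <- pmax(dets$y2, dets$y1 + 1)
  }
  list(dets = dets, gts = gts)
}

# zero every parameter of a nested layer structure
zero_module <- function(m) {
  for (p in reefdet:::layer_params(m)) p$value[] <- 0
  invisible(m)
}

# small deterministic random array helper
rarr <- function(..., seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  d <- c(...)
  array(stats::rnorm(prod(d), 0, sd), dim = d)
}
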