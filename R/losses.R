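# Loss functions: Slide Loss with an adaptive IoU threshold, the
# supporting CIoU + distribution focal localisation losses, and a
# simplified target assigner.
#
# The Slide weight is a piecewise exponential function of a sample's IoU
# `x` relative to the adaptive threshold `mu` (the batch-mean IoU):
# easy negatives (x <= mu - 0.1) keep weight 1, boundary samples get the
# constant e^(1 - mu) > 1, and positives decay as e^(1 - x) toward 1.

#' Adaptive IoU threshold: the batch-mean IoU
#'
#' @param ious numeric vector of IoU values in `[0, 1]`
#' @return arithmetic mean
#' @export
mean_iou_threshold <- function(ious) {
  if (length(ious) == 0)
    stop("degenerate batch: no IoUs to average", call. = FALSE)
  if (any(ious < 0 | ious > 1 | !is.finite(ious)))
    stop("IoU values must lie in [0, 1]", call. = FALSE)
  sum(ious) / length(ious)
}

#' Slide Loss sample weight
#'
#' Piecewise exponential weight of IoU `x` around the adaptive threshold
#' `mu`: 1 for `x <= mu - 0.1`; `exp(1 - mu)` for `mu - 0.1 < x < mu`;
#' `exp(1 - x)` for `x >= mu`.  Continuous at `x = mu`, with a single
#' upward jump of `exp(1 - mu) - 1` at `x = mu - 0.1`.
#'
#' @param x IoU value(s); values outside `[0, 1]` are clamped with a
#'   warning
#' @param mu adaptive threshold in (0, 1)
#' @return numeric weight(s) `>= 1`
#' @export
slide_weight <- function(x, mu) {
  if (mu <= 0 || mu >= 1) stop("mu must lie in (0, 1)", call. = FALSE)
  if (any(x < 0 | x > 1)) {
    warning("IoU values clamped into [0, 1]")
    x <- pmin(pmax(x, 0), 1)
  }
  out <- numeric(length(x))
  lo <- x <= mu - 0.1
  hi <- x >= mu
  mid <- !lo & !hi
  out[lo] <- 1
  out[mid] <- exp(1 - mu)
  out[hi] <- exp(1 - x[hi])
  out
}

#' Binary cross-entropy from a logit
#'
#' Numerically stable `-y log(sigma(p)) - (1 - y) log(1 - sigma(p))`.
#'
#' @param logit real-valued logit(s)
#' @param label 0/1 label(s)
#' @return elementwise BCE
#' @export
bce <- function(logit, label) {
  if (any(!is.finite(logit))) stop("logit must be finite", call. = FALSE)
  pmax(logit, 0) - logit * label + log1p(exp(-abs(logit)))
}

#' Assemble an assigned batch
#'
#' @param iou per-record IoU `x_i` in `[0, 1]`
#' @param label per-record 0/1 label `y_i`
#' @param logit per-record predicted logit `p_i`
#' @return data.frame of class `assigned_batch`
#' @export
assigned_batch <- function(iou, label, logit) {
  if (length(iou) == 0) stop("degenerate batch: empty", call. = FALSE)
  stopifnot(length(iou) == length(label), length(iou) == length(logit))
  if (any(iou < 0 | iou > 1)) stop("IoU must lie in [0, 1]", call. = FALSE)
  if (!all(label %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  structure(data.frame(iou = iou, label = label, logit = logit),
            class = c("assigned_batch", "data.frame"))
}

#' Slide Loss of an assigned batch
#'
#' `(1/N) * sum_i f(x_i) * BCE(p_i, y_i)` with `f` the [slide_weight()]
#' at the adaptive threshold `mu`, which defaults to the batch-mean IoU
#' and is treated as a constant (no gradient flows through it).
#'
#' @param batch an [assigned_batch()] (or data.frame with columns `iou`,
#'   `label`, `logit`)
#' @param mu adaptive threshold; computed from `batch$iou` via
#'   [mean_iou_threshold()] when `NULL`
#' @param weights optional explicit per-record weights overriding the
#'   slide weighting (e.g. `rep(1, N)` recovers plain mean BCE)
#' @return scalar loss
#' @export
slide_loss <- function(batch, mu = NULL, weights = NULL) {
  if (nrow(batch) == 0) stop("degenerate batch: empty", call. = FALSE)
  if (is.null(mu)) {
    # keep mu inside the open interval the weight function requires,
    # even for the degenerate all-0 / all-1 IoU batches
    mu <- min(max(mean_iou_threshold(batch$iou), 1e-6), 1 - 1e-6)
  }
  if (is.null(weights)) weights <- slide_weight(batch$iou, mu)
  mean(weights * bce(batch$logit, batch$label))
}

#' Complete-IoU loss between boxes
#'
#' `1 - IoU + rho^2/c^2 + alpha v`, where `rho` is the centre distance,
#' `c` the diagonal of the smallest enclosing box, and `v` the
#' aspect-ratio consistency term.
#'
#' @param box_pred,box_target numeric length-4 vectors or n x 4 matrices,
#'   `xyxy` pixel coordinates
#' @return numeric loss value(s), 0 for identical boxes
#' @export
ciou_loss <- function(box_pred, box_target) {
  p <- matrix(box_pred, ncol = 4)
  t <- matrix(box_target, ncol = 4)
  if (any(t[, 3] <= t[, 1] | t[, 4] <= t[, 2]))
    stop("invalid target: zero-area box", call. = FALSE)
  eps <- 1e-9
  w1 <- p[, 3] - p[, 1]; h1 <- p[, 4] - p[, 2]
  w2 <- t[, 3] - t[, 1]; h2 <- t[, 4] - t[, 2]
  iw <- pmax(0, pmin(p[, 3], t[, 3]) - pmax(p[, 1], t[, 1]))
  ih <- pmax(0, pmin(p[, 4], t[, 4]) - pmax(p[, 2], t[, 2]))
  inter <- iw * ih
  union <- w1 * h1 + w2 * h2 - inter + eps
  iou <- inter / union
  cw <- pmax(p[, 3], t[, 3]) - pmin(p[, 1], t[, 1])
  chh <- pmax(p[, 4], t[, 4]) - pmin(p[, 2], t[, 2])
  c2 <- cw^2 + chh^2 + eps
  rho2 <- ((p[, 1] + p[, 3] - t[, 1] - t[, 3])^2 +
             (p[, 2] + p[, 4] - t[, 2] - t[, 4])^2) / 4
  v <- (4 / pi^2) * (atan(w2 / (h2 + eps)) - atan(w1 / (h1 + eps)))^2
  alpha <- v / (1 - iou + v + eps)
  1 - iou + rho2 / c2 + alpha * v
}

#' Distribution focal loss
#'
#' Cross-entropy of a discrete offset distribution against the two integer
#' bins bracketing each continuous target, weighted by proximity.
#'
#' @param distribution `reg_max x M` matrix of bin logits (or a length
#'   `reg_max` vector for one offset)
#' @param target_offsets continuous offsets in `[0, reg_max - 1]`
#' @return mean loss over offsets
#' @export
dfl_loss <- function(distribution, target_offsets) {
  L <- if (is.matrix(distribution)) distribution else
    matrix(distribution, ncol = 1)
  reg_max <- nrow(L)
  if (any(target_offsets < 0 | target_offsets > reg_max - 1))
    stop("target offsets outside [0, reg_max - 1]", call. = FALSE)
  tl <- pmin(floor(target_offsets), reg_max - 2)
  wr <- target_offsets - tl
  wl <- 1 - wr
  mx <- apply(L, 2, max)
  logp <- sweep(L, 2, mx + log(colSums(exp(sweep(L, 2, mx)))))
  M <- ncol(L)
  mean(-(wl * logp[cbind(tl + 1, seq_len(M))] +
           wr * logp[cbind(tl + 2, seq_len(M))]))
}

# ---- assignment -------------------------------------------------------

# anchor centre coordinates (pixels) for a level grid, matching the
# (H, W) array layout: row index i -> y, column j -> x
anchor_centers <- function(H, W, stride) {
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  cbind(x = (j - 0.5) * stride, y = (i - 0.5) * stride)
}

# decode (H, W, 4*reg_max, 1) distribution logits to xyxy boxes (pixels)
decode_boxes <- function(box_arr, stride, reg_max) {
  d <- dim(box_arr)
  H <- d[1]; W <- d[2]
  M <- H * W
  lt <- matrix(0, M, 4)
  bins <- 0:(reg_max - 1)
  bm <- matrix(box_arr, M, d[3])
  for (s in 1:4) {
    logits <- bm[, (s - 1) * reg_max + seq_len(reg_max), drop = FALSE]
    mx <- logits[, 1]
    for (b in 2:reg_max) mx <- pmax(mx, logits[, b])
    e <- exp(logits - mx)
    lt[, s] <- as.numeric(e %*% bins) / rowSums(e)
  }
  ac <- anchor_centers(H, W, stride)
  cbind(ac[, "x"] - lt[, 1] * stride, ac[, "y"] - lt[, 2] * stride,
        ac[, "x"] + lt[, 3] * stride, ac[, "y"] + lt[, 4] * stride)
}

box_iou_matrix <- function(a, b) {
  # a: n x 4, b: m x 4 (xyxy); returns n x m IoU matrix
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  area_a <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  area_b <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  for (k in seq_len(m)) {
    iw <- pmin(a[, 3], b[k, 3]) - pmax(a[, 1], b[k, 1])
    ih <- pmin(a[, 4], b[k, 4]) - pmax(a[, 2], b[k, 2])
    inter <- pmax(0, iw) * pmax(0, ih)
    un <- area_a + area_b[k] - inter
    out[, k] <- ifelse(un > 0, inter / un, 0)
  }
  out
}

#' Assign predictions to targets (simplified alignment)
#'
#' Candidates are grid cells (all levels pooled); a cell whose centre lies
#' inside a target box is scored by the IoU of its decoded predicted box
#' with that target, and the top-`k` candidates per target become
#' positives (`y = 1`, `x =` that IoU).  A candidate contended by two
#' targets keeps the higher-IoU match.  All other cells are negatives
#' with `x =` the maximum IoU of their predicted box over all targets
#' (0 when the image has no targets).
#'
#' @param predictions head outputs for one image: list of levels, each
#'   with `cls` (H, W, nc, 1), `box` (H, W, 4*reg_max, 1) and `stride`
#' @param targets matrix `n x 4` of xyxy pixel boxes (possibly 0 rows)
#' @param target_classes integer class ids (1-based), length `n`
#' @param k positives kept per target
#' @param reg_max distribution bin count used to decode
#' @return data.frame: `level`, `cell` (linear index), `x` (IoU),
#'   `y` (0/1), `class` (matched class for positives, NA otherwise),
#'   `target` (matched target index or NA)
#' @export
assign_targets <- function(predictions, targets, target_classes = NULL,
                           k = 10L, reg_max = 16L) {
  cand <- do.call(rbind, lapply(seq_along(predictions), function(li) {
    l <- predictions[[li]]
    d <- dim(l$box)
    ac <- anchor_centers(d[1], d[2], l$stride)
    bx <- decode_boxes(l$box, l$stride, reg_max)
    data.frame(level = li, cell = seq_len(d[1] * d[2]),
               ax = ac[, "x"], ay = ac[, "y"],
               x1 = bx[, 1], y1 = bx[, 2], x2 = bx[, 3], y2 = bx[, 4])
  }))
  n_cand <- nrow(cand)
  res <- data.frame(level = cand$level, cell = cand$cell,
                    x = 0, y = 0, class = NA_integer_,
                    target = NA_integer_)
  nt <- if (is.null(targets)) 0L else nrow(targets)
  if (nt == 0L) return(res)
  pred_boxes <- as.matrix(cand[, c("x1", "y1", "x2", "y2")])
  iou <- box_iou_matrix(pred_boxes, targets)
  # negatives carry max IoU over targets
  res$x <- apply(iou, 1, max)
  best_t <- rep(NA_integer_, n_cand)
  best_iou <- rep(-1, n_cand)
  for (t in seq_len(nt)) {
    inside <- cand$ax > targets[t, 1] & cand$ax < targets[t, 3] &
      cand$ay > targets[t, 2] & cand$ay < targets[t, 4]
    idx <- which(inside)
    if (length(idx) == 0) next
    ord <- idx[order(iou[idx, t], decreasing = TRUE)]
    keep <- ord[seq_len(min(k, length(ord)))]
    for (ci in keep) {
      if (iou[ci, t] > best_iou[ci]) {
        best_iou[ci] <- iou[ci, t]
        best_t[ci] <- t
      }
    }
  }
  pos <- which(!is.na(best_t))
  res$y[pos] <- 1
  res$x[pos] <- pmax(0, best_iou[pos])
  res$target[pos] <- best_t[pos]
  if (!is.null(target_classes)) res$class[pos] <- target_classes[best_t[pos]]
  res
}
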