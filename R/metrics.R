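# Detection evaluation: IoU, score-ordered greedy matching,
# precision / recall / F1, average precision by 101-point interpolation
# of the monotone precision envelope, and mAP@50 / mAP@50-95.

#' Intersection-over-union of two boxes
#'
#' @param a,b length-4 `xyxy` boxes (half-open pixel coordinates)
#' @return IoU in `[0, 1]`; 0 when the union has zero area
#' @export
box_iou <- function(a, b) {
  if (a[3] < a[1] || a[4] < a[2] || b[3] < b[1] || b[4] < b[2])
    stop("invalid box: x2 < x1 or y2 < y1", call. = FALSE)
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Greedy score-ordered matching of detections to ground truths
#'
#' Detections (single class) are sorted by descending score; each matches
#' the yet-unmatched ground truth with the highest IoU at or above
#' `iou_thr` (one-to-one).  Unmatched detections are false positives,
#' unmatched ground truths false negatives.
#'
#' @param dets data.frame with `score`, `x1`, `y1`, `x2`, `y2`
#' @param gts matrix/data.frame of ground-truth `xyxy` boxes
#' @param iou_thr IoU threshold
#' @return list: `tp` logical per detection (in score order), `order` the
#'   score ordering used, `fn` count of unmatched ground truths
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  ng <- if (is.null(gts)) 0L else nrow(gts)
  nd <- if (is.null(dets)) 0L else nrow(dets)
  if (nd == 0L) return(list(tp = logical(0), order = integer(0), fn = ng))
  ord <- order(dets$score, decreasing = TRUE)
  tp <- logical(nd)
  used <- logical(ng)
  if (ng > 0L) {
    gm <- as.matrix(gts)
    for (i in seq_len(nd)) {
      di <- ord[i]
      db <- c(dets$x1[di], dets$y1[di], dets$x2[di], dets$y2[di])
      best <- 0; bj <- 0L
      for (j in seq_len(ng)) {
        if (used[j]) next
        v <- box_iou(db, gm[j, 1:4])
        if (v >= iou_thr && v > best) { best <- v; bj <- j }
      }
      if (bj > 0L) { tp[i] <- TRUE; used[bj] <- TRUE }
    }
  }
  list(tp = tp, order = ord, fn = ng - sum(tp))
}

#' Average precision from score-ordered TP flags
#'
#' Cumulative precision/recall over the score ordering; the precision
#' envelope is made monotone non-increasing and averaged at 101 equally
#' spaced recall points `0, 0.01, ..., 1`.
#'
#' @param flags logical TP flags ordered by decreasing score
#' @param n_gt number of ground truths for the class
#' @return AP in `[0, 1]`; `NA` when `n_gt == 0` and there are no
#'   detections (undefined class)
#' @export
average_precision <- function(flags, n_gt) {
  if (n_gt == 0) {
    if (length(flags) == 0) return(NA_real_)
    return(0)
  }
  if (length(flags) == 0 || !any(flags)) return(0)
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # monotone non-increasing envelope from the right
  penv <- rev(cummax(rev(precision)))
  rq <- seq(0, 1, by = 0.01)
  # interpolated precision at recall r: max precision with recall >= r
  idx <- findInterval(rq, recall, left.open = TRUE) + 1L
  p_at <- ifelse(idx <= length(penv), penv[idx], 0)
  mean(p_at)
}

#' Evaluate detections against ground truth
#'
#' @param dets data.frame with columns `image`, `class`, `score`, `x1`,
#'   `y1`, `x2`, `y2`
#' @param gts data.frame with columns `image`, `class`, `x1`, `y1`,
#'   `x2`, `y2`
#' @param classes class vocabulary (integer ids); defaults to the ids in
#'   `gts`
#' @param iou_thresholds thresholds for the AP average (default
#'   0.50:0.05:0.95)
#' @return an `eval_result`: per-class AP at 0.5, `mAP50`, `mAP50_95`,
#'   and `P`, `R`, `F1` at the score threshold maximising F1 (IoU 0.5)
#' @export
evaluate_detections <- function(dets, gts, classes = NULL,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (is.null(gts) || nrow(gts) == 0)
    stop("evaluation requires a non-empty ground-truth set", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(gts$class))
  if (is.null(dets)) dets <- data.frame(image = integer(0),
                                        class = integer(0),
                                        score = numeric(0), x1 = numeric(0),
                                        y1 = numeric(0), x2 = numeric(0),
                                        y2 = numeric(0))
  ap <- matrix(NA_real_, length(classes), length(iou_thresholds),
               dimnames = list(classes, iou_thresholds))
  # global score-ordered flags at IoU 0.5 for P/R/F1
  all_scores <- numeric(0); all_tp <- logical(0)
  n_gt_total <- nrow(gts)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    dc <- dets[dets$class == cl, , drop = FALSE]
    gc <- gts[gts$class == cl, , drop = FALSE]
    n_gt <- nrow(gc)
    for (ti in seq_along(iou_thresholds)) {
      thr <- iou_thresholds[ti]
      flags <- logical(0)
      scores <- numeric(0)
      for (img in unique(c(dc$image, gc$image))) {
        di <- dc[dc$image == img, , drop = FALSE]
        gi <- gc[gc$image == img, c("x1", "y1", "x2", "y2"), drop = FALSE]
        m <- match_detections(di, gi, thr)
        flags <- c(flags, m$tp)
        scores <- c(scores, di$score[m$order])
      }
      ord <- order(scores, decreasing = TRUE)
      ap[ci, ti] <- average_precision(flags[ord], n_gt)
      if (abs(thr - 0.5) < 1e-9) {
        all_scores <- c(all_scores, scores)
        all_tp <- c(all_tp, flags)
      }
    }
  }
  ord <- order(all_scores, decreasing = TRUE)
  tp <- cumsum(all_tp[ord])
  fp <- cumsum(!all_tp[ord])
  P <- if (length(tp)) tp / (tp + fp) else numeric(0)
  R <- if (length(tp)) tp / n_gt_total else numeric(0)
  F1 <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
  if (length(F1)) {
    bi <- which.max(F1)
    prf <- c(P = P[bi], R = R[bi], F1 = F1[bi],
             score_thr = all_scores[ord][bi])
  } else {
    prf <- c(P = 0, R = 0, F1 = 0, score_thr = NA_real_)
  }
  ap50 <- ap[, 1]
  defined <- !is.na(ap50)
  structure(list(
    classes = classes,
    ap50 = ap50,
    ap_by_threshold = ap,
    mAP50 = mean(ap50[defined]),
    mAP50_95 = mean(rowMeans(ap)[defined]),
    P = unname(prf["P"]), R = unname(prf["R"]), F1 = unname(prf["F1"]),
    score_threshold = unname(prf["score_thr"])
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("mAP@50 %.4f  mAP@50-95 %.4f  P %.4f  R %.4f  F1 %.4f\n",
              x$mAP50, x$mAP50_95, x$P, x$R, x$F1))
  invisible(x)
}

#' Class-wise non-maximum suppression
#'
#' @param dets data.frame with `class`, `score`, `x1`, `y1`, `x2`, `y2`
#' @param iou_thr suppression IoU threshold
#' @param score_thr minimum score retained
#' @param max_det maximum detections kept
#' @return filtered data.frame
#' @export
nms <- function(dets, iou_thr = 0.7, score_thr = 0.25, max_det = 300L) {
  dets <- dets[dets$score >= score_thr, , drop = FALSE]
  if (nrow(dets) == 0) return(dets)
  keep <- logical(nrow(dets))
  bm <- cbind(dets$x1, dets$y1, dets$x2, dets$y2)
  for (cl in unique(dets$class)) {
    idx <- which(dets$class == cl)
    idx <- idx[order(dets$score[idx], decreasing = TRUE)]
    live <- rep(TRUE, length(idx))
    for (i in seq_along(idx)) {
      if (!live[i]) next
      keep[idx[i]] <- TRUE
      if (i < length(idx)) {
        rest <- (i + 1):length(idx)
        rest <- rest[live[rest]]
        if (length(rest)) {
          ious <- box_iou_matrix(bm[idx[rest], , drop = FALSE],
                                 bm[idx[i], , drop = FALSE])[, 1]
          live[rest[ious > iou_thr]] <- FALSE
        }
      }
    }
  }
  out <- dets[keep, , drop = FALSE]
  out[order(out$score, decreasing = TRUE), , drop = FALSE][
    seq_len(min(max_det, sum(keep))), , drop = FALSE]
}
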