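test_that("box IoU handles the standard cases", {
  expect_equal(box_iou(c(0, 0, 4, 4), c(0, 0, 4, 4)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  # two unit squares overlapping by half
  expect_equal(box_iou(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(box_iou(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0) # zero union
  expect_error(box_iou(c(2, 0, 1, 1), c(0, 0, 1, 1)), "invalid box")
})

test_that("greedy matching is score-ordered and one-to-one", {
  gts <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30))
  dets <- data.frame(score = c(0.9, 0.8),
                     x1 = c(0, 20), y1 = c(0, 20),
                     x2 = c(10, 30), y2 = c(10, 30))
  m <- match_detections(dets, gts, 0.5)
  expect_true(all(m$tp))
  expect_identical(m$fn, 0L)
  # zero detections
  m0 <- match_detections(NULL, gts, 0.5)
  expect_identical(m0$fn, 2L)
  # two detections on one ground truth: higher-scored one wins
  dets2 <- data.frame(score = c(0.3, 0.7),
                      x1 = c(0, 1), y1 = c(0, 1), x2 = c(10, 10),
                      y2 = c(10, 10))
  m2 <- match_detections(dets2, gts[1, , drop = FALSE], 0.5)
  expect_identical(m2$tp, c(TRUE, FALSE)) # in score order
  expect_identical(m2$order, c(2L, 1L))
})

test_that("average precision uses 101-point interpolation", {
  expect_equal(average_precision(c(TRUE, FALSE), 2), 51 / 101,
               tolerance = 1e-12)
  expect_equal(average_precision(c(TRUE, TRUE, TRUE), 3), 1)
  expect_equal(average_precision(c(FALSE, FALSE), 5), 0)
  expect_true(is.na(average_precision(logical(0), 0)))
})

test_that("evaluation of a perfect and an empty detector", {
  gts <- data.frame(image = c(1, 1, 2), class = c(1, 2, 1),
                    x1 = c(0, 20, 5), y1 = c(0, 20, 5),
                    x2 = c(10, 30, 15), y2 = c(10, 30, 15))
  perfect <- cbind(gts, score = 0.9)
  r <- evaluate_detections(perfect, gts)
  expect_equal(r$mAP50, 1)
  expect_equal(r$mAP50_95, 1)
  expect_equal(r$P, 1); expect_equal(r$R, 1); expect_equal(r$F1, 1)
  r0 <- evaluate_detections(NULL, gts)
  expect_equal(r0$R, 0)
  expect_equal(r0$mAP50, 0)
  expect_error(evaluate_detections(perfect, gts[0, ]), "non-empty")
})

test_that("a misclassified box is traded between classes as hand-traced", {
  gts <- data.frame(image = 1, class = c(1, 2),
                    x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30),
                    y2 = c(10, 30))
  dets <- data.frame(image = 1, class = c(1, 1), score = c(0.9, 0.8),
                     x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30),
                     y2 = c(10, 30))
  r <- evaluate_detections(dets, gts)
  # class 1: first det TP (recall 1), second det FP after it -> AP = 1
  # class 2: no detections -> AP = 0; mAP50 = 0.5
  expect_equal(unname(r$ap50["1"]), 1, tolerance = 1e-12)
  expect_equal(unname(r$ap50["2"]), 0)
  expect_equal(r$mAP50, 0.5)
  # max-F1 point: 1 TP + 1 FP over 2 gts -> P = 1 at 1 det: F1 = 2/3
  expect_equal(r$F1, 2 / 3, tolerance = 1e-9)
})

test_that("counting identities and threshold nesting hold", {
  set.seed(71)
  for (case in 1:5) {
    rc <- random_eval_case(n_images = 3, n_classes = 2, seed = 100 + case)
    for (cl in 1:2) {
      gcl <- rc$gts[rc$gts$class == cl, , drop = FALSE]
      dcl <- rc$dets[rc$dets$class == cl, , drop = FALSE]
      for (img in unique(gcl$image)) {
        m <- match_detections(dcl[dcl$image == img, , drop = FALSE],
                              gcl[gcl$image == img,
                                  c("x1", "y1", "x2", "y2"),
                                  drop = FALSE], 0.5)
        expect_identical(sum(m$tp) + m$fn,
                         nrow(gcl[gcl$image == img, , drop = FALSE]))
      }
    }
    r <- evaluate_detections(rc$dets, rc$gts, classes = 1:2)
    expect_gte(r$mAP50, r$mAP50_95 - 1e-12)
    # adding a zero-IoU detection never increases any AP
    far <- data.frame(image = 1, class = 1, score = 0.99, x1 = 500,
                      y1 = 500, x2 = 510, y2 = 510)
    r2 <- evaluate_detections(rbind(rc$dets, far), rc$gts, classes = 1:2)
    expect_lte(r2$mAP50, r$mAP50 + 1e-12)
    expect_lte(r2$mAP50_95, r$mAP50_95 + 1e-12)
  }
})

test_that("evaluator agrees with the COCO-style reference on random scenes", {
  for (case in 1:20) {
    rc <- random_eval_case(n_images = 3, n_classes = 2, seed = 200 + case)
    r <- evaluate_detections(rc$dets, rc$gts, classes = 1:2)
    ref <- coco_eval_ref(rc$dets, rc$gts, classes = 1:2)
    expect_equal(r$mAP50, ref$mAP50, tolerance = 1e-3)
    expect_equal(r$mAP50_95, ref$mAP50_95, tolerance = 1e-3)
  }
})

test_that("class-wise NMS suppresses overlapping duplicates only", {
  dets <- data.frame(class = c(1, 1, 2), score = c(0.9, 0.6, 0.5),
                     x1 = c(0, 1, 0), y1 = c(0, 1, 0),
                     x2 = c(10, 11, 10), y2 = c(10, 11, 10))
  out <- nms(dets, iou_thr = 0.5, score_thr = 0.25)
  # duplicate of class 1 suppressed; class 2 kept despite overlap
  expect_identical(nrow(out), 2L)
  expect_setequal(out$class, c(1, 2))
})
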