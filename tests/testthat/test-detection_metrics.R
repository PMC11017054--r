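test_that("IoU basics: identity, disjoint, overlap fraction", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(50, 50, 10, 10)), 0)
  got <- box_iou(c(0, 0, 10, 10), c(5, 5, 10, 10))
  expect_equal(got, 25 / 175)
  expect_equal(got, oracle_raster_iou(c(0, 0, 10, 10), c(5, 5, 10, 10)))
})

test_that("IoU is symmetric, bounded and translation invariant", {
  withr::with_seed(13, {
    for (i in 1:50) {
      a <- c(runif(2, 0, 100), runif(2, 1, 40))
      b <- c(runif(2, 0, 100), runif(2, 1, 40))
      ab <- box_iou(a, b)
      expect_equal(ab, box_iou(b, a))
      expect_gte(ab, 0)
      expect_lte(ab, 1)
      shift <- runif(2, -30, 30)
      expect_equal(
        box_iou(a + c(shift, 0, 0), b + c(shift, 0, 0)), ab,
        tolerance = 1e-12
      )
    }
  })
})

test_that("perfect and below-threshold predictions produce the expected confusion", {
  truth <- random_boxes(6)
  truth$confidence <- 100
  perfect <- truth
  perfect$confidence <- 90
  m <- match_detections(perfect, truth)
  expect_equal(unlist(m[c("tp", "fp", "fn")]),
               c(tp = 6L, fp = 0L, fn = 0L))

  low <- perfect
  low$confidence <- 40
  m2 <- match_detections(low, truth)
  expect_equal(unlist(m2[c("tp", "fp", "fn")]),
               c(tp = 0L, fp = 0L, fn = 6L))
})

test_that("greedy matching never beats optimal matching and ties it on small fixtures", {
  withr::with_seed(77, {
    for (i in 1:40) {
      pred <- random_boxes(sample(0:6, 1), w = 100, h = 100, max_side = 50)
      truth <- random_boxes(sample(0:6, 1), w = 100, h = 100, max_side = 50)
      truth$confidence <- 100
      got <- match_detections(pred, truth, iou_threshold = 0.3,
                              confidence_threshold = 0)$tp
      opt <- oracle_optimal_tp(pred, truth, 0.3)
      expect_lte(got, opt)
    }
  })
  # on the well-separated fixture set greedy attains the optimum
  truth <- make_detections(0, "chicken", c(0, 30, 60, 90), c(0, 0, 0, 0),
                           10, 10, confidence = 100)
  pred <- make_detections(0, "chicken", c(1, 31, 61, 200), c(0, 0, 0, 0),
                          10, 10, confidence = c(90, 80, 70, 60))
  expect_equal(match_detections(pred, truth)$tp,
               oracle_optimal_tp(pred, truth, 0.3))
})

test_that("raising thresholds never increases matches", {
  withr::with_seed(101, {
    pred <- random_boxes(40)
    truth <- random_boxes(30)
    truth$confidence <- 100
  })
  confs <- c(0, 30, 50, 70, 90)
  tps <- sapply(confs, function(ct) {
    match_detections(pred, truth, confidence_threshold = ct)$tp
  })
  fps <- sapply(confs, function(ct) {
    match_detections(pred, truth, confidence_threshold = ct)$fp
  })
  expect_true(all(diff(tps) <= 0))
  expect_true(all(diff(fps) <= 0))
  ious <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  tps_iou <- sapply(ious, function(it) {
    match_detections(pred, truth, iou_threshold = it,
                     confidence_threshold = 0)$tp
  })
  expect_true(all(diff(tps_iou) <= 0))
})

test_that("precision, recall and F1 follow their formulas", {
  # the published operating point of the chicken detector
  expect_equal(round(f1_score(90.4, 84.9), 1), 87.6)
  m <- precision_recall_f1(list(tp = 8L, fp = 2L, fn = 4L))
  expect_equal(m$precision, 80)
  expect_equal(m$recall, 100 * 8 / 12)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_true(m$f1 >= min(m$precision, m$recall) &&
                m$f1 <= max(m$precision, m$recall))
  expect_equal(f1_score(63, 63), 63)  # harmonic-mean identity at P = R
  deg <- suppressWarnings(precision_recall_f1(list(tp = 0L, fp = 0L,
                                                   fn = 5L)))
  expect_equal(unlist(deg), c(precision = 0, recall = 0, f1 = 0))
})

test_that("AP matches a hand-integrated precision-recall step curve", {
  # 5 ground-truth boxes, 10 ranked predictions hitting at ranks 1, 3, 4, 7
  truth <- make_detections(0, "chicken", seq(0, 80, 20), 0, 10, 10,
                           confidence = 100)
  far <- seq(0, 100, 20)
  pred <- dplyr::bind_rows(
    make_detections(0, "chicken", 0, 0, 10, 10, confidence = 100),   # TP
    make_detections(0, "chicken", far[1], 100, 10, 10, confidence = 95),
    make_detections(0, "chicken", 20, 0, 10, 10, confidence = 90),   # TP
    make_detections(0, "chicken", 40, 0, 10, 10, confidence = 85),   # TP
    make_detections(0, "chicken", far[2], 100, 10, 10, confidence = 80),
    make_detections(0, "chicken", far[3], 100, 10, 10, confidence = 75),
    make_detections(0, "chicken", 60, 0, 10, 10, confidence = 70),   # TP
    make_detections(0, "chicken", far[4], 100, 10, 10, confidence = 65),
    make_detections(0, "chicken", far[5], 100, 10, 10, confidence = 60),
    make_detections(0, "chicken", far[6], 100, 10, 10, confidence = 55)
  )
  metrics <- evaluate_detections(pred, truth, confidence_threshold = 0)
  # hand integration: envelope precisions 1, 3/4, 3/4, 4/7 at recall steps
  # of 0.2 each -> AP = 0.2 * (1 + 3/4 + 3/4 + 4/7) * 100
  expect_equal(unname(metrics$per_class_ap["chicken"]),
               100 * 0.2 * (1 + 3 / 4 + 3 / 4 + 4 / 7),
               tolerance = 1e-12)
})

test_that("mAP averages per-class AP and excludes truthless classes", {
  truth <- dplyr::bind_rows(
    make_detections(0, "chicken", c(0, 40), 0, 10, 10, confidence = 100),
    make_detections(0, "robot", 100, 100, 30, 20, confidence = 100)
  )
  pred_perfect <- truth
  pred_perfect$confidence <- 90
  m <- evaluate_detections(pred_perfect, truth)
  expect_equal(m$mean_ap, 100)
  expect_equal(unname(m$per_class_ap), c(100, 100))

  # one class perfect, one all wrong -> mAP 50
  pred_half <- dplyr::bind_rows(
    make_detections(0, "chicken", c(0, 40), 0, 10, 10, confidence = 90),
    make_detections(0, "robot", 300, 300, 30, 20, confidence = 90)
  )
  expect_equal(evaluate_detections(pred_half, truth)$mean_ap, 50)

  expect_warning(
    m3 <- evaluate_detections(pred_perfect, truth,
                              classes = c("chicken", "robot", "feeder")),
    "feeder"
  )
  expect_equal(m3$mean_ap, 100)
})
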