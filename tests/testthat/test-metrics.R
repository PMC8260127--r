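test_that("greedy matching classifies TP, FP and FN as defined", {
  gts <- rbind(c(0, 0, 10, 10), c(20, 0, 30, 10))
  perfect <- make_detections(gts, rep("S", 2), c(0.9, 0.8))
  m <- match_predictions(perfect, gts, 0.5)
  expect_true(all(m$tp))
  expect_true(all(m$gt_matched))

  # two predictions on one gt: the more confident wins, the other is FP
  dup <- make_detections(rbind(c(0, 0, 10, 10), c(1, 0, 11, 10)),
                         rep("S", 2), c(0.6, 0.9))
  m2 <- match_predictions(dup, gts[1, , drop = FALSE], 0.5)
  expect_equal(m2$confidence, c(0.9, 0.6))
  expect_equal(m2$tp, c(TRUE, FALSE))

  # gt with no overlapping prediction stays a false negative
  m3 <- match_predictions(perfect[1, ], gts, 0.5)
  expect_equal(m3$gt_matched, c(TRUE, FALSE))
  expect_equal(sum(!m3$gt_matched), 1L)
})

test_that("matching agrees with a loop-based oracle across orderings", {
  set.seed(41)
  for (rep in 1:12) {
    np <- sample(1:8, 1); ng <- sample(1:8, 1)
    preds <- random_boxes(np, lim = 40)
    gts <- random_boxes(ng, lim = 40)
    conf <- runif(np)
    got <- match_predictions(make_detections(preds, rep("S", np), conf),
                             gts, 0.3)
    want <- match_oracle(preds, conf, gts, 0.3)
    expect_identical(got$tp, want$tp)
    expect_identical(got$gt_matched, want$gt_matched)
  }
})

test_that("precision and recall follow their defining ratios", {
  tp <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  curve <- precision_recall(tp, n_gt = 10)
  expect_equal(curve$precision[10], 0.8)  # TP=8, FP=2
  expect_equal(curve$recall[10], 0.8)     # TP=8 of 10 gts
  expect_true(all(diff(curve$recall) >= 0))
  expect_true(all(curve$precision >= 0 & curve$precision <= 1))
  expect_true(all(curve$recall >= 0 & curve$recall <= 1))

  expect_equal(nrow(precision_recall(logical(0), n_gt = 3)), 0L)
  und <- precision_recall(c(TRUE, FALSE), n_gt = 0)
  expect_true(all(is.na(und$recall)))
})

test_that("average precision integrates the all-points envelope", {
  # perfect single detection
  expect_equal(average_precision(precision_recall(TRUE, n_gt = 1)), 1.0)
  # the worked example: ranked (TP, FP, TP) over 2 gts
  expect_equal(average_precision(precision_recall(c(TRUE, FALSE, TRUE),
                                                  n_gt = 2)),
               5 / 6, tolerance = 1e-9)
  # all false positives
  expect_equal(average_precision(precision_recall(c(FALSE, FALSE), n_gt = 2)), 0)
  # empty curve
  expect_equal(average_precision(precision_recall(logical(0), n_gt = 0)), 0)

  set.seed(43)
  for (rep in 1:20) {
    n <- sample(1:10, 1)
    tp <- runif(n) < 0.5
    n_gt <- sum(tp) + sample(0:3, 1)
    if (n_gt == 0) next
    expect_equal(average_precision(precision_recall(tp, n_gt = n_gt)),
                 ap_oracle(tp, n_gt), tolerance = 1e-12)
  }
})

test_that("mAP averages per-class AP", {
  expect_equal(mean_average_precision(c(S = 1.0, R = 0.5)), 0.75)
  expect_equal(mean_average_precision(c(S = 0.62)), 0.62)
  expect_error(mean_average_precision(numeric(0)), "at least one")
})

test_that("relative count error follows the per-class formula", {
  z <- count_error(c(a = 5, b = 7), c(a = 5, b = 7))
  expect_equal(z$mae, 0)
  ex <- count_error(c(s = 50, r = 30), c(s = 45, r = 33))
  expect_equal(unname(ex$ae), c(0.10, 0.10), tolerance = 1e-9)
  expect_equal(ex$mae, 0.10, tolerance = 1e-9)
  expect_equal(count_error(c(x = 10), c(x = 12))$mae, 0.2)

  # scale-free: multiplying all counts by k leaves mAE unchanged
  set.seed(47)
  y <- c(a = 12, b = 31, c = 7)
  t <- c(a = 10, b = 35, c = 7)
  for (k in c(2, 5, 10))
    expect_equal(count_error(y * k, t * k)$mae, count_error(y, t)$mae)

  # zero ground truth: flagged absolute fallback
  zg <- count_error(c(a = 0, b = 10), c(a = 3, b = 10))
  expect_equal(unname(zg$ae["a"]), 3)
  expect_equal(zg$zero_gt, "a")
  expect_equal(count_error(c(a = 0), c(a = 0))$mae, 0)
})

test_that("feeding ground truth back as predictions scores perfectly", {
  set.seed(51)
  gts <- lapply(1:3, function(i) {
    b <- random_boxes(5, lim = 80)
    data.frame(label = sample(c("S", "R"), 5, replace = TRUE),
               xmin = b[, 1], ymin = b[, 2], xmax = b[, 3], ymax = b[, 4])
  })
  preds <- lapply(gts, function(g) { g$confidence <- 1.0; g })
  rep <- evaluate_detections(preds, gts, classes = c("S", "R"),
                             iou_threshold = 0.5, score_threshold = 0.5)
  expect_equal(rep$mAP, 1.0)
  expect_equal(rep$mAE, 0.0)

  # removing a detection strictly increases that class's counting error
  preds2 <- preds
  drop_row <- which(preds2[[1]]$label == "S")[1]
  preds2[[1]] <- preds2[[1]][-drop_row, ]
  rep2 <- evaluate_detections(preds2, gts, classes = c("S", "R"),
                              iou_threshold = 0.5, score_threshold = 0.5)
  expect_gt(rep2$per_class$AE[rep2$per_class$class == "S"], 0)

  # a class absent everywhere scores AP 1 and is skipped in mAE
  only_s <- lapply(gts, function(g) g[g$label == "S", , drop = FALSE])
  preds_s <- lapply(preds, function(p) p[p$label == "S", , drop = FALSE])
  rep3 <- evaluate_detections(preds_s, only_s, classes = c("S", "R"),
                              iou_threshold = 0.5, score_threshold = 0.5)
  expect_equal(rep3$per_class$AP[rep3$per_class$class == "R"], 1.0)
  expect_equal(rep3$mAE, 0)
})

test_that("mAP and mAE can rank two detector outputs oppositely", {
  # one image, one class, four seeds
  gt <- data.frame(label = rep("S", 4),
                   xmin = c(0, 20, 40, 60), ymin = rep(0, 4),
                   xmax = c(10, 30, 50, 70), ymax = rep(10, 4))
  # output A: perfect localization but each seed double-counted
  boxes_a <- rbind(box_matrix(gt), box_matrix(gt) + 0.5)
  out_a <- make_detections(boxes_a, rep("S", 8),
                           c(rep(0.95, 4), rep(0.9, 4)))
  # output B: every box too loose to pass IoU 0.5, but the count is right
  boxes_b <- box_matrix(gt)
  boxes_b[, 1] <- boxes_b[, 1] + 6  # 4x10 overlap of 10x10: IoU 4/16
  boxes_b[, 3] <- boxes_b[, 3] + 6
  out_b <- make_detections(boxes_b, rep("S", 4), rep(0.9, 4))

  rep_a <- evaluate_detections(list(out_a), list(gt), "S", 0.5, 0.5)
  rep_b <- evaluate_detections(list(out_b), list(gt), "S", 0.5, 0.5)
  expect_gt(rep_a$mAP, rep_b$mAP)  # A localizes, B does not
  expect_gt(rep_a$mAE, rep_b$mAE)  # but A miscounts and B counts exactly
  expect_equal(rep_b$mAE, 0)
})

test_that("eval report CSV round-trips the per-class table", {
  rep <- evaluate_detections(
    list(make_detections(rbind(c(0, 0, 10, 10)), "S", 0.9)),
    list(data.frame(label = "S", xmin = 0, ymin = 0, xmax = 10, ymax = 10)),
    classes = c("S", "R"), iou_threshold = 0.5, score_threshold = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eval_csv(rep, path)
  expect_match(readLines(path, n = 1), "iou_threshold=0.5")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(back), 3L)  # two classes + mean row
  expect_equal(back$AP[back$class == "mean"], rep$mAP)
})
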