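# Independent brute-force oracles used to cross-check the package's
# geometry and evaluation code. They deliberately share no code with the
# implementation: IoU is computed by counting pixels on a rasterized grid,
# matching/NMS/AP by explicit loops.

# IoU of two integer-coordinate boxes by pixel counting.
iou_pixel_oracle <- function(a, b) {
  grid_max <- max(a[c(3, 4)], b[c(3, 4)])
  inside <- function(box, x, y) x >= box[1] && x < box[3] && y >= box[2] && y < box[4]
  n_a <- 0; n_b <- 0; n_both <- 0
  for (x in 0:(grid_max - 1)) for (y in 0:(grid_max - 1)) {
    ia <- inside(a, x, y); ib <- inside(b, x, y)
    n_a <- n_a + ia; n_b <- n_b + ib; n_both <- n_both + (ia && ib)
  }
  un <- n_a + n_b - n_both
  if (un == 0) 0 else n_both / un
}

# Greedy confidence-ordered matching by explicit loops.
match_oracle <- function(pred_boxes, conf, gt_boxes, thr) {
  ord <- order(conf, decreasing = TRUE)
  used <- rep(FALSE, nrow(gt_boxes))
  tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    best_iou <- -1; best_j <- NA
    for (j in seq_len(nrow(gt_boxes))) {
      if (used[j]) next
      v <- radicount::iou(pred_boxes[i, ], gt_boxes[j, ])
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (!is.na(best_j) && best_iou > thr) { tp[k] <- TRUE; used[best_j] <- TRUE }
  }
  list(tp = tp, gt_matched = used)
}

# All-points AP by exhaustive cutoff enumeration: for each ranked cutoff,
# precision/recall; then sum recall increments times the maximum precision
# at any cutoff with recall at least as large.
ap_oracle <- function(tp, n_gt) {
  n <- length(tp)
  if (n == 0 || n_gt == 0) return(0)
  prec <- numeric(n); rec <- numeric(n)
  for (k in seq_len(n)) {
    t <- sum(tp[1:k])
    prec[k] <- t / k
    rec[k] <- t / n_gt
  }
  ap <- 0; prev_r <- 0
  for (k in seq_len(n)) {
    if (rec[k] > prev_r) {
      pmax_here <- max(prec[k:n][rec[k:n] >= rec[k]])
      ap <- ap + (rec[k] - prev_r) * pmax_here
      prev_r <- rec[k]
    }
  }
  ap
}

# Greedy NMS by explicit loops (single class).
nms_oracle <- function(boxes, conf, thr) {
  ord <- order(conf, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (radicount::iou(boxes[i, ], boxes[j, ]) > thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# Anchor assignment by explicit all-pairs loops.
assign_oracle <- function(anchors, gts, pos_thr, neg_thr) {
  n <- nrow(anchors); m <- nrow(gts)
  M <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    M[i, j] <- radicount::iou(anchors[i, ], gts[j, ])
  status <- rep("ignore", n)
  for (i in seq_len(n)) {
    mx <- if (m) max(M[i, ]) else 0
    if (m == 0 || mx < neg_thr) status[i] <- "negative"
    if (m > 0 && mx > pos_thr) status[i] <- "positive"
  }
  if (m) for (j in seq_len(m)) {
    mx <- max(M[, j])
    if (mx > 0) status[abs(M[, j] - mx) < 1e-9] <- "positive"
  }
  status
}

# Random box helpers for property tests.
random_boxes <- function(n, lim = 100, min_side = 2) {
  x1 <- runif(n, 0, lim - min_side - 1)
  y1 <- runif(n, 0, lim - min_side - 1)
  cbind(x1, y1,
        x1 + runif(n, min_side, lim / 3),
        y1 + runif(n, min_side, lim / 3))
}

make_detections <- function(boxes, labels, conf) {
  data.frame(label = labels, xmin = boxes[, 1], ymin = boxes[, 2],
             xmax = boxes[, 3], ymax = boxes[, 4], confidence = conf,
             stringsAsFactors = FALSE)
}
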