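#' Match predictions of one class against ground truth
#'
#' Greedy one-to-one matching in confidence order, the standard discipline
#' behind precision--recall evaluation of object detectors: predictions
#' are visited from most to least confident; a prediction is a true
#' positive if its best-IoU *unmatched* ground-truth box has IoU strictly
#' above `iou_threshold` (that box is then consumed), otherwise a false
#' positive. Ground-truth boxes left unmatched are false negatives.
#'
#' @param preds data.frame with box columns and `confidence` (a box matrix
#'   plus a `confidence` column also works); one class only.
#' @param gts ground-truth box matrix / data.frame of the same class.
#' @param iou_threshold IoU above which a prediction can claim a box.
#' @return A list of class `rc_match`: `tp` (logical, per prediction in
#'   decreasing-confidence order), `confidence` (sorted), `matched_gt`
#'   (consumed gt index per TP, `NA` for FP), `gt_matched` (logical per
#'   gt; `FALSE` entries are the false negatives), `n_gt`, and the
#'   threshold used.
#' @export
match_predictions <- function(preds, gts, iou_threshold = 0.5) {
  pm <- if (NROW(preds)) box_matrix(preds) else matrix(numeric(0), 0, 4)
  conf <- if (NROW(preds)) {
    if (is.data.frame(preds)) preds$confidence else attr(preds, "confidence")
  } else numeric(0)
  if (NROW(pm) && is.null(conf)) stop("predictions must carry confidences")
  gm <- if (NROW(gts)) box_matrix(gts) else matrix(numeric(0), 0, 4)
  ord <- order(conf, decreasing = TRUE)
  pm <- pm[ord, , drop = FALSE]
  conf <- conf[ord]
  n_gt <- nrow(gm)
  tp <- logical(nrow(pm))
  matched_gt <- rep(NA_integer_, nrow(pm))
  gt_used <- logical(n_gt)
  if (nrow(pm) && n_gt) {
    M <- iou_matrix(pm, gm)
    for (i in seq_len(nrow(pm))) {
      avail <- which(!gt_used)
      if (!length(avail)) break
      j <- avail[which.max(M[i, avail])]
      if (M[i, j] > iou_threshold) {
        tp[i] <- TRUE
        matched_gt[i] <- j
        gt_used[j] <- TRUE
      }
    }
  }
  structure(list(tp = tp, confidence = conf, matched_gt = matched_gt,
                 gt_matched = gt_used, n_gt = n_gt,
                 iou_threshold = iou_threshold),
            class = "rc_match")
}

#' Precision--recall curve from a match result
#'
#' One point per confidence cutoff in rank order: at cutoff k,
#' `precision = TP_k / k` (TP over TP+FP among the k most confident
#' predictions) and `recall = TP_k / n_gt` (TP over TP+FN). Recall is
#' non-decreasing along the sweep.
#'
#' @param match an [match_predictions()] result, or a logical TP vector in
#'   decreasing-confidence order.
#' @param n_gt number of ground-truth boxes (taken from `match` when
#'   available).
#' @return data.frame of class `rc_pr_curve` with columns `recall`,
#'   `precision`, `confidence`. With `n_gt = 0` and predictions present,
#'   recall is `NA` (undefined). Zero predictions give an empty curve.
#' @export
precision_recall <- function(match, n_gt = NULL) {
  if (inherits(match, "rc_match")) {
    tp <- match$tp
    conf <- match$confidence
    if (is.null(n_gt)) n_gt <- match$n_gt
  } else {
    tp <- as.logical(match)
    conf <- rep(NA_real_, length(tp))
    if (is.null(n_gt)) stop("n_gt required when match is a plain TP vector")
  }
  k <- seq_along(tp)
  ctp <- cumsum(tp)
  curve <- data.frame(
    recall = if (n_gt > 0) ctp / n_gt else rep(NA_real_, length(tp)),
    precision = if (length(tp)) ctp / k else numeric(0),
    confidence = conf)
  class(curve) <- c("rc_pr_curve", "data.frame")
  curve
}

#' Average precision: area under the precision--recall curve
#'
#' All-points interpolation: precision is replaced by its right-continuous
#' envelope (the maximum precision at any recall at least as large) and
#' integrated over recall. Equals the exhaustive sum over every ranked
#' cutoff of (recall increment) x (envelope precision).
#'
#' @param curve a [precision_recall()] result.
#' @return AP in `[0, 1]`; an empty curve gives 0.
#' @export
average_precision <- function(curve) {
  if (!NROW(curve)) return(0)
  r <- curve$recall
  p <- curve$precision
  if (anyNA(r)) return(0)  # undefined recall (no ground truth): no area
  env <- rev(cummax(rev(p)))
  dr <- diff(c(0, r))
  sum(dr * env)
}

#' Mean average precision over classes
#'
#' Unweighted mean of the per-class AP values — the detection-quality
#' summary. By convention a class absent from both ground truth and
#' predictions scores AP 1 (correct silence); that convention is applied
#' by [evaluate_detections()], not here.
#'
#' @param per_class_ap named numeric vector (or list) of per-class AP.
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(per_class_ap) {
  ap <- unlist(per_class_ap)
  if (!length(ap)) stop("at least one class is required")
  mean(ap)
}

#' Per-class relative count error and its mean
#'
#' The counting metric: for each class i with ground-truth count y_i and
#' predicted count t_i, `AE_i = |y_i - t_i| / y_i`, and mAE is the
#' unweighted mean of AE over the N classes. When `y_i = 0` the printed
#' formula is undefined; here `AE_i = t_i` (the absolute miscount, flagged
#' via the `zero_gt` field) and `y_i = t_i = 0` gives `AE_i = 0`.
#'
#' @param y named ground-truth counts.
#' @param t named predicted counts (same classes, any order).
#' @return A list with `ae` (named per-class vector), `mae`, and
#'   `zero_gt` (names of classes where the fallback applied).
#' @export
count_error <- function(y, t) {
  y <- unlist(y); t <- unlist(t)
  if (is.null(names(y)) || is.null(names(t))) {
    if (length(y) != length(t)) stop("count vectors differ in length")
    names(y) <- names(t) <- paste0("class", seq_along(y))
  }
  if (!setequal(names(y), names(t)))
    stop("ground truth and predicted counts cover different classes")
  t <- t[names(y)]
  ae <- ifelse(y > 0, abs(y - t) / y, ifelse(t == 0, 0, t))
  list(ae = ae, mae = mean(ae), zero_gt = names(y)[y == 0 & t > 0])
}

#' Evaluate detections against annotations
#'
#' Core of the two evaluation axes, operating on in-memory predictions:
#' \itemize{
#'   \item Detection quality: per-class AP, matching per image and pooling
#'     the ranked (confidence, TP) pairs across images, with recall
#'     normalized by the total ground-truth count; mAP is the class mean.
#'   \item Counting quality: per-class relative absolute error computed
#'     from score-thresholded detections, either per image and then
#'     averaged (`counting = "per_image"`, the default) or from pooled
#'     counts (`counting = "pooled"`); mAE is the class mean.
#' }
#' A class with no ground truth and no predictions anywhere scores AP 1
#' and is skipped in the counting mean.
#'
#' @param preds list (one per image) of detection data.frames (`label`,
#'   box columns, `confidence`).
#' @param gts list (one per image) of [annotated_image()] objects or
#'   ground-truth data.frames with a `label` column.
#' @param classes character vector of class labels to evaluate.
#' @param iou_threshold IoU threshold for TP/FP decisions.
#' @param score_threshold confidence cutoff applied before counting (AP
#'   integrates over all confidences and ignores it).
#' @param counting `"per_image"` or `"pooled"`.
#' @return An `rc_eval_report`: data.frame `per_class` (class, AP, AE),
#'   `mAP`, `mAE`, and the thresholds used.
#' @export
evaluate_detections <- function(preds, gts, classes, iou_threshold = 0.5,
                                score_threshold = 0.5,
                                counting = c("per_image", "pooled")) {
  counting <- match.arg(counting)
  stopifnot(length(preds) == length(gts))
  gt_objects <- lapply(gts, function(g) if (inherits(g, "rc_annotation")) g$objects else g)
  n_img <- length(preds)
  ap <- stats::setNames(numeric(length(classes)), classes)
  ae <- stats::setNames(numeric(length(classes)), classes)
  skip_ae <- stats::setNames(logical(length(classes)), classes)

  for (cl in classes) {
    tp_all <- logical(0); conf_all <- numeric(0); n_gt_total <- 0L
    ae_img <- numeric(0)
    y_tot <- 0L; t_tot <- 0L
    for (i in seq_len(n_img)) {
      p <- preds[[i]]
      p_cl <- p[p$label == cl, , drop = FALSE]
      g_cl <- gt_objects[[i]][gt_objects[[i]]$label == cl, , drop = FALSE]
      m <- match_predictions(p_cl, g_cl, iou_threshold)
      tp_all <- c(tp_all, m$tp); conf_all <- c(conf_all, m$confidence)
      n_gt_total <- n_gt_total + m$n_gt
      pc <- p_cl[p_cl$confidence >= score_threshold, , drop = FALSE]
      yi <- nrow(g_cl); ti <- nrow(pc)
      y_tot <- y_tot + yi; t_tot <- t_tot + ti
      ae_img <- c(ae_img, if (yi > 0) abs(yi - ti) / yi else if (ti == 0) 0 else ti)
    }
    if (n_gt_total == 0L && !length(tp_all)) {
      ap[cl] <- 1  # correct silence
      skip_ae[cl] <- TRUE
      ae[cl] <- 0
    } else {
      ord <- order(conf_all, decreasing = TRUE)
      curve <- precision_recall(tp_all[ord], n_gt = n_gt_total)
      curve$confidence <- conf_all[ord]
      ap[cl] <- average_precision(curve)
      ae[cl] <- if (counting == "per_image") mean(ae_img) else {
        if (y_tot > 0) abs(y_tot - t_tot) / y_tot else if (t_tot == 0) 0 else t_tot
      }
    }
  }
  use <- !skip_ae
  report <- list(
    per_class = data.frame(class = classes, AP = as.numeric(ap),
                           AE = as.numeric(ae), stringsAsFactors = FALSE),
    mAP = mean(ap),
    mAE = if (any(use)) mean(ae[use]) else 0,
    iou_threshold = iou_threshold, score_threshold = score_threshold,
    counting = counting, n_images = n_img)
  class(report) <- "rc_eval_report"
  report
}

#' Evaluate a trained detector on a dataset split
#'
#' Runs the detector over every image of a manifest split and scores the
#' detections with [evaluate_detections()]. Refuses to evaluate on images
#' the model was trained or validated on.
#'
#' @param model an `rc_detector` from [train_detector()].
#' @param manifest a [read_manifest()] data.frame (or dataset directory).
#' @param split which split to evaluate (default `"test"`).
#' @param iou_threshold IoU threshold for TP/FP decisions.
#' @param score_threshold confidence cutoff for counting; defaults to the
#'   model's configured threshold.
#' @param counting `"per_image"` (default) or `"pooled"` AE aggregation.
#' @return An `rc_eval_report`.
#' @export
evaluate_detector <- function(model, manifest, split = "test",
                              iou_threshold = 0.5, score_threshold = NULL,
                              counting = c("per_image", "pooled")) {
  counting <- match.arg(counting)
  stopifnot(inherits(model, "rc_detector"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir")
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (!nrow(rows)) stop("manifest has no images in split '", split, "'")
  seen <- intersect(rows$image_id, model$trained_on)
  if (length(seen))
    stop("refusing to evaluate: image(s) ", paste(utils::head(seen, 3), collapse = ", "),
         if (length(seen) > 3) ", ..." else "",
         " were used for training/validation")
  if (is.null(score_threshold)) score_threshold <- model$det_cfg$score_threshold
  preds <- vector("list", nrow(rows))
  gts <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    img <- read_image(file.path(dir, rows$image[i]))
    preds[[i]] <- predict_image(model, img, score_threshold = 0)
    gts[[i]] <- read_voc_xml(file.path(dir, rows$annotation[i]),
                             expected_scheme = model$det_cfg$scheme)
  }
  rep <- evaluate_detections(preds, gts, classes = model$det_cfg$classes,
                             iou_threshold = iou_threshold,
                             score_threshold = score_threshold,
                             counting = counting)
  rep$split <- split
  rep
}

#' Write an evaluation report as CSV
#'
#' One row per class (AP, AE) plus a `mean` summary row (mAP, mAE);
#' thresholds are echoed in `#`-prefixed header comments.
#'
#' @param report an `rc_eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# iou_threshold=%g score_threshold=%g counting=%s",
                     report$iou_threshold, report$score_threshold,
                     report$counting), con)
  df <- report$per_class
  df <- rbind(df, data.frame(class = "mean", AP = report$mAP, AE = report$mAE))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @export
print.rc_eval_report <- function(x, ...) {
  cat(sprintf("<rc_eval_report>  %d image(s), IoU threshold %g\n",
              x$n_images, x$iou_threshold))
  print(x$per_class, row.names = FALSE)
  cat(sprintf("  mAP = %.4f   mAE = %.4f (%s, score >= %g)\n",
              x$mAP, x$mAE, x$counting, x$score_threshold))
  invisible(x)
}
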