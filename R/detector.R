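# Two-stage detector: a class-agnostic region-proposal stage over nine
# anchors per feature location, followed by an ROI head that classifies
# each proposal (classes + background, softmax) and refines its box.
# Training minimizes cross-entropy + smooth-L1 losses at both stages.

.rc_cache <- new.env(parent = emptyenv())

# Index permutations linking the anchor list ordering (row-major location,
# scale-major/ratio-minor) to the c(h, w, channel) output arrays of the
# RPN convolutions.
anchor_perms <- function(h, w) {
  key <- paste0(h, "x", w)
  hit <- .rc_cache[[key]]
  if (!is.null(hit)) return(hit)
  Y <- rep(0:(h - 1), each = w * 9L)
  X <- rep(rep(0:(w - 1), each = 9L), times = h)
  K <- rep(1:9, times = h * w)
  cls <- Y + h * X + h * w * (K - 1L) + 1L
  reg <- sapply(1:4, function(d) Y + h * X + h * w * ((K - 1L) * 4L + d - 1L) + 1L)
  out <- list(cls = cls, reg = reg)
  .rc_cache[[key]] <- out
  out
}

# Full forward pass up to the RPN outputs (shared by training/inference).
forward_rpn <- function(params, det_cfg, img) {
  bb <- backbone_def(det_cfg$backbone)
  bo <- backbone_forward(params, bb, img)
  feat <- bo$feat
  r0 <- conv_f(feat, params[["rpn_conv.W"]], params[["rpn_conv.b"]], 1L, 1L)
  r <- relu(r0)
  cls_arr <- conv_f(r, params[["rpn_cls.W"]], params[["rpn_cls.b"]], 1L, 0L)
  reg_arr <- conv_f(r, params[["rpn_reg.W"]], params[["rpn_reg.b"]], 1L, 0L)
  h <- dim(feat)[1]; w <- dim(feat)[2]
  pm <- anchor_perms(h, w)
  anchors <- anchor_set(h, w, det_cfg$anchor)
  list(bb = bb, bb_cache = bo$cache, feat = feat, r0 = r0, r = r,
       cls_arr = cls_arr, reg_arr = reg_arr,
       obj_logits = as.numeric(cls_arr)[pm$cls],
       deltas = matrix(as.numeric(reg_arr)[as.vector(pm$reg)], ncol = 4),
       anchors = anchors, fshape = c(h, w), perms = pm)
}

anchor_set <- function(h, w, acfg) {
  key <- paste0("anch_", h, "x", w, "_", paste(c(acfg$stride, acfg$scales,
                                                 acfg$aspect_ratios), collapse = "_"))
  hit <- .rc_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- generate_anchors(c(h, w), acfg)
  .rc_cache[[key]] <- a
  a
}

# Decode, clip and filter RPN outputs into at most `proposal_count`
# proposal boxes (greedy NMS at IoU 0.7 over the candidate decodes).
# Candidates are the top `pre_nms` anchors by objectness plus every anchor
# scoring at least `score_floor`: with saturated easy objects (seeds) a
# fixed top-k would silently crowd out rarer mid-score objects (radicles).
make_proposals <- function(fwd, det_cfg, width, height, pre_nms = 3000L,
                           min_size = 2, score_floor = 0.3,
                           max_candidates = 15000L,
                           keep = det_cfg$proposal_count) {
  scores <- sigmoid(fwd$obj_logits)
  n <- length(scores)
  ord <- order(scores, decreasing = TRUE)
  n_take <- max(min(pre_nms, n), min(sum(scores >= score_floor), max_candidates))
  take <- ord[seq_len(n_take)]
  boxes <- decode_delta(fwd$anchors[take, , drop = FALSE],
                        fwd$deltas[take, , drop = FALSE])
  boxes <- clip_boxes(boxes, width, height)
  ok <- (boxes[, 3] - boxes[, 1]) >= min_size & (boxes[, 4] - boxes[, 2]) >= min_size
  boxes <- boxes[ok, , drop = FALSE]
  sc <- scores[take][ok]
  if (!nrow(boxes)) return(list(boxes = boxes, scores = sc))
  kept <- nms_indices(boxes, sc, 0.7)
  kept <- utils::head(kept, keep)
  list(boxes = boxes[kept, , drop = FALSE], scores = sc[kept])
}

# ROI head forward: bilinear crop -> fc -> (class logits, box deltas).
head_forward <- function(params, det_cfg, feat, rois) {
  bb_stride <- backbone_def(det_cfg$backbone)$stride
  P <- det_cfg$roi_pool_size
  C <- dim(feat)[3]
  pooled <- roi_crop_forward(feat, rois, bb_stride, P)
  X <- t(array(pooled, c(P * P * C, nrow(rois))))
  z1 <- sweep(X %*% params[["fc1.W"]], 2, params[["fc1.b"]], "+")
  h1 <- relu(z1)
  cls <- sweep(h1 %*% params[["head_cls.W"]], 2, params[["head_cls.b"]], "+")
  reg <- sweep(h1 %*% params[["head_reg.W"]], 2, params[["head_reg.b"]], "+")
  list(X = X, z1 = z1, h1 = h1, class_logits = cls, deltas = reg,
       rois = rois, pool = P, channels = C, stride = bb_stride)
}

head_backward <- function(params, det_cfg, feat, hf, d_cls, d_reg, grads) {
  d_h1 <- d_cls %*% t(params[["head_cls.W"]]) + d_reg %*% t(params[["head_reg.W"]])
  grads[["head_cls.W"]] <- grads[["head_cls.W"]] + t(hf$h1) %*% d_cls
  grads[["head_cls.b"]] <- grads[["head_cls.b"]] + colSums(d_cls)
  grads[["head_reg.W"]] <- grads[["head_reg.W"]] + t(hf$h1) %*% d_reg
  grads[["head_reg.b"]] <- grads[["head_reg.b"]] + colSums(d_reg)
  d_z1 <- relu_bwd(hf$z1, d_h1)
  grads[["fc1.W"]] <- grads[["fc1.W"]] + t(hf$X) %*% d_z1
  grads[["fc1.b"]] <- grads[["fc1.b"]] + colSums(d_z1)
  d_X <- d_z1 %*% t(params[["fc1.W"]])
  d_pooled <- array(t(d_X), c(hf$pool, hf$pool, hf$channels * nrow(hf$rois)))
  dfeat <- roi_crop_backward(feat, hf$rois, hf$stride, hf$pool, d_pooled)
  list(grads = grads, dfeat = dfeat)
}

rpn_backward <- function(params, det_cfg, fwd, d_obj, d_deltas, grads) {
  pm <- fwd$perms
  h <- fwd$fshape[1]; w <- fwd$fshape[2]
  d_cls_arr <- array(0, c(h, w, 9))
  d_cls_arr[pm$cls] <- d_obj
  d_reg_arr <- array(0, c(h, w, 36))
  d_reg_arr[as.vector(pm$reg)] <- as.numeric(d_deltas)
  b1 <- conv_b(fwd$r, params[["rpn_cls.W"]], d_cls_arr, 1L, 0L)
  b2 <- conv_b(fwd$r, params[["rpn_reg.W"]], d_reg_arr, 1L, 0L)
  grads[["rpn_cls.W"]] <- grads[["rpn_cls.W"]] + b1$dW
  grads[["rpn_cls.b"]] <- grads[["rpn_cls.b"]] + b1$db
  grads[["rpn_reg.W"]] <- grads[["rpn_reg.W"]] + b2$dW
  grads[["rpn_reg.b"]] <- grads[["rpn_reg.b"]] + b2$db
  d_r <- relu_bwd(fwd$r0, b1$dX + b2$dX)
  b0 <- conv_b(fwd$feat, params[["rpn_conv.W"]], d_r, 1L, 1L)
  grads[["rpn_conv.W"]] <- grads[["rpn_conv.W"]] + b0$dW
  grads[["rpn_conv.b"]] <- grads[["rpn_conv.b"]] + b0$db
  list(grads = grads, dfeat = b0$dX)
}

stable_bce <- function(z, t01) {
  z <- pmin(pmax(z, -1e6), 1e6)
  pmax(z, 0) - z * t01 + log1p(exp(-abs(z)))
}

#' Detector loss components
#'
#' Computes the four training losses of the two-stage detector from model
#' outputs and assignment targets: the region-proposal objectness
#' cross-entropy (`rpn_cls`) and smooth-L1 box regression over positive
#' anchors (`rpn_reg`), and the head's softmax cross-entropy over classes
#' plus background (`head_cls`) and smooth-L1 regression over foreground
#' proposals (`head_reg`). Classification terms are means over the
#' supplied examples; regression terms are sums of elementwise smooth-L1
#' normalized by the same example count, so they receive contributions
#' only from positives and are exactly zero without any.
#'
#' @param rpn_outputs list with `obj_logits` (length-n numeric) and
#'   `deltas` (n x 4), aligned with the targets.
#' @param head_outputs list with `class_logits` (m x (C+1), background
#'   first) and `deltas` (m x 4), or `NULL` when only the RPN is scored.
#' @param targets list with `rpn_labels` (0/1 per anchor), `rpn_deltas`
#'   (n x 4, rows used only where `rpn_labels == 1`), and, when head
#'   outputs are present, `head_classes` (0 = background, 1..C foreground)
#'   and `head_deltas` (m x 4, rows used only for foreground).
#' @param with_grads also return gradients with respect to the outputs.
#' @return List with `rpn_cls`, `rpn_reg`, `head_cls`, `head_reg`, `total`
#'   and optionally `grads`.
#' @export
detector_losses <- function(rpn_outputs, head_outputs = NULL, targets,
                            with_grads = FALSE) {
  z <- rpn_outputs$obj_logits
  t01 <- as.numeric(targets$rpn_labels)
  n <- length(z)
  if (n != length(t01)) stop("RPN outputs and targets differ in length")
  rpn_cls <- if (n) mean(stable_bce(z, t01)) else 0
  pos <- which(t01 == 1)
  d_obj <- NULL; d_rpn_deltas <- NULL
  if (n && with_grads) d_obj <- (sigmoid(pmin(pmax(z, -50), 50)) - t01) / n
  rpn_reg <- 0
  if (with_grads) d_rpn_deltas <- matrix(0, n, 4)
  if (length(pos)) {
    x <- rpn_outputs$deltas[pos, , drop = FALSE] -
      targets$rpn_deltas[pos, , drop = FALSE]
    rpn_reg <- sum(smooth_l1(x)) / n
    if (with_grads) d_rpn_deltas[pos, ] <- smooth_l1_grad(x) / n
  }
  head_cls <- head_reg <- 0
  d_cls <- d_reg <- NULL
  if (!is.null(head_outputs)) {
    L <- pmin(pmax(head_outputs$class_logits, -1e6), 1e6)
    m <- nrow(L)
    lab <- as.integer(targets$head_classes)
    if (m != length(lab)) stop("head outputs and targets differ in length")
    if (m) {
      p <- softmax_rows(L)
      idx <- cbind(seq_len(m), lab + 1L)
      head_cls <- mean(-log(pmax(p[idx], 1e-300)))
      fg <- which(lab > 0L)
      if (with_grads) {
        d_cls <- p
        d_cls[idx] <- d_cls[idx] - 1
        d_cls <- d_cls / m
        d_reg <- matrix(0, m, 4)
      }
      if (length(fg)) {
        x <- head_outputs$deltas[fg, , drop = FALSE] -
          targets$head_deltas[fg, , drop = FALSE]
        head_reg <- sum(smooth_l1(x)) / m
        if (with_grads) d_reg[fg, ] <- smooth_l1_grad(x) / m
      }
    }
  }
  out <- list(rpn_cls = rpn_cls, rpn_reg = rpn_reg,
              head_cls = head_cls, head_reg = head_reg,
              total = rpn_cls + rpn_reg + head_cls + head_reg)
  if (with_grads)
    out$grads <- list(d_obj = d_obj, d_rpn_deltas = d_rpn_deltas,
                      d_head_cls = d_cls, d_head_reg = d_reg)
  out
}

#' Greedy per-class non-maximum suppression
#'
#' Within each class, keeps the highest-confidence detection and drops any
#' same-class detection whose IoU with an already-kept box exceeds
#' `nms_iou`; repeats down the ranking. Output is sorted by confidence
#' (descending) and the operation is idempotent.
#'
#' @param detections data.frame with `label`, box columns, `confidence`.
#' @param nms_iou suppression IoU threshold.
#' @return Filtered detections, confidence-descending.
#' @export
nms <- function(detections, nms_iou = 0.5) {
  if (!NROW(detections)) return(detections)
  stopifnot(!is.null(detections$confidence))
  keep_rows <- integer(0)
  for (cl in unique(detections$label)) {
    rows <- which(detections$label == cl)
    k <- nms_indices(box_matrix(detections[rows, , drop = FALSE]),
                     detections$confidence[rows], nms_iou)
    keep_rows <- c(keep_rows, rows[k])
  }
  out <- detections[keep_rows, , drop = FALSE]
  out <- out[order(out$confidence, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Training configuration
#'
#' @param iterations optimizer steps (full-scale default 5000; a
#'   fine-tuning run conventionally uses 2000).
#' @param batch_size images per step (default 2).
#' @param learning_rate optimizer learning rate (default 0.01).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param flip_augmentation present each training image also as its
#'   horizontal and vertical mirror, with boxes transformed to match.
#' @param crop_size side of the square random crop taken from each training
#'   image per step (translation augmentation; also the main lever for CPU
#'   training speed, since convolution cost scales with pixel count).
#'   Images smaller than `crop_size` are used whole; inference always runs
#'   at full resolution. `NULL` disables cropping.
#' @param lr_schedule `"constant"`, or `"step"` to divide the learning rate
#'   by 4 after 70\% of the iterations — the usual two-phase recipe
#'   (feature formation, then box refinement at a lower rate).
#' @param rng_seed seed for initialization, sampling and augmentation.
#' @param validation_interval iterations between validation passes.
#' @param init_weights optional checkpoint path whose parameters are used
#'   as the starting point (fine-tuning) instead of random "Xavier"
#'   initialization.
#' @param grad_clip global L2 gradient-norm ceiling (stability guard).
#' @return An object of class `rc_train_config`.
#' @export
train_config <- function(iterations = 5000L, batch_size = 2L,
                         learning_rate = 0.01, optimizer = c("adam", "sgd"),
                         flip_augmentation = TRUE, crop_size = 256L,
                         lr_schedule = c("constant", "step"),
                         rng_seed = 1L,
                         validation_interval = 250L, init_weights = NULL,
                         grad_clip = 10) {
  optimizer <- match.arg(optimizer)
  lr_schedule <- match.arg(lr_schedule)
  if (iterations <= 0 || batch_size < 1 || learning_rate <= 0)
    stop("iterations > 0, batch_size >= 1 and learning_rate > 0 required")
  if (!is.null(crop_size) && crop_size < 64)
    stop("crop_size must be at least 64 px (or NULL)")
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 flip_augmentation = isTRUE(flip_augmentation),
                 crop_size = if (is.null(crop_size)) NULL else as.integer(crop_size),
                 lr_schedule = lr_schedule,
                 rng_seed = as.integer(rng_seed),
                 validation_interval = as.integer(validation_interval),
                 init_weights = init_weights, grad_clip = grad_clip),
            class = "rc_train_config")
}

# Random aligned square crop of a training example: slices the image,
# shifts and clips the boxes, and drops boxes that mostly leave the crop.
# Offsets are multiples of the feature stride so anchor geometry is
# unchanged. Returns NULL boxes when nothing remains.
crop_example <- function(img, objects, crop, stride = 8L) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (crop >= min(H, W))
    return(list(img = img, objects = objects, width = W, height = H))
  ox <- stride * sample.int((W - crop) %/% stride + 1L, 1L) - stride
  oy <- stride * sample.int((H - crop) %/% stride + 1L, 1L) - stride
  sub <- img[(oy + 1):(oy + crop), (ox + 1):(ox + crop), , drop = FALSE]
  ob <- objects
  if (nrow(ob)) {
    area0 <- (ob$xmax - ob$xmin) * (ob$ymax - ob$ymin)
    ob$xmin <- pmin(pmax(ob$xmin - ox, 0), crop)
    ob$xmax <- pmin(pmax(ob$xmax - ox, 0), crop)
    ob$ymin <- pmin(pmax(ob$ymin - oy, 0), crop)
    ob$ymax <- pmin(pmax(ob$ymax - oy, 0), crop)
    area1 <- (ob$xmax - ob$xmin) * (ob$ymax - ob$ymin)
    keep <- (ob$xmax - ob$xmin) >= 3 & (ob$ymax - ob$ymin) >= 3 &
      area1 >= 0.3 * area0
    ob <- ob[keep, , drop = FALSE]
  }
  list(img = sub, objects = ob, width = crop, height = crop)
}

flip_image <- function(img, direction) {
  switch(direction,
         none = img,
         horizontal = img[, dim(img)[2]:1, , drop = FALSE],
         vertical = img[dim(img)[1]:1, , , drop = FALSE])
}

flip_annotation_boxes <- function(objects, width, height, direction) {
  if (direction == "none" || !nrow(objects)) return(objects)
  m <- flip_boxes(objects, width, height, direction)
  objects$xmin <- m[, 1]; objects$ymin <- m[, 2]
  objects$xmax <- m[, 3]; objects$ymax <- m[, 4]
  objects
}

# RPN assignment targets for one (image, flip variant); cached when a
# cache environment and key are supplied.
rpn_targets_for <- function(cache_env, key, anchors, gt_m, det_cfg) {
  hit <- if (!is.null(cache_env)) cache_env[[key]] else NULL
  if (!is.null(hit)) return(hit)
  asg <- assign_anchor_labels(anchors, gt_m, det_cfg)
  pos <- which(asg$status == "positive")
  tdeltas <- matrix(0, length(pos), 4)
  if (length(pos))
    tdeltas <- encode_delta(anchors[pos, , drop = FALSE],
                            gt_m[asg$matched[pos], , drop = FALSE])
  out <- list(pos = pos, pos_gt = asg$matched[pos],
              neg = which(asg$status == "negative"),
              tdeltas = tdeltas)
  if (!is.null(cache_env)) cache_env[[key]] <- out
  out
}

#' Train the two-stage detector
#'
#' Runs seeded minibatch training over the `train` split of a dataset
#' manifest: each step draws `batch_size` images (optionally as
#' horizontal/vertical mirrors when flip augmentation is on), computes the
#' four loss components and their gradients, and updates all parameters.
#' Every `validation_interval` steps the current model is scored on the
#' `val` split (counting error mAE and detection mAP) and the parameters
#' with the best validation counting error are retained as the final
#' model, guarding against overfitting.
#'
#' @param manifest dataset directory or [read_manifest()] result with
#'   nonempty `train` and `val` splits.
#' @param det_cfg a [detector_config()] matching the dataset's annotation
#'   scheme.
#' @param train_cfg a [train_config()].
#' @param quiet suppress progress messages.
#' @return An object of class `rc_detector`: trained parameters, both
#'   configurations, the training log (a data.frame with per-iteration
#'   loss components and interleaved validation scores), the best
#'   iteration, and the ids of the images seen during training/validation.
#' @export
train_detector <- function(manifest, det_cfg, train_cfg = train_config(),
                           quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(det_cfg, "rc_detector_config"),
            inherits(train_cfg, "rc_train_config"))
  dir <- attr(manifest, "dir")
  ds_scheme <- attr(manifest, "scheme")
  if (!is.null(ds_scheme) && !identical(ds_scheme, det_cfg$scheme))
    stop("dataset scheme (", ds_scheme, ") does not match detector config (",
         det_cfg$scheme, ")")
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  va <- manifest[manifest$split == "val", , drop = FALSE]
  if (!nrow(tr)) stop("manifest has an empty train split")
  if (!nrow(va)) stop("manifest has an empty val split")

  load_ann <- function(row) read_voc_xml(file.path(dir, row["annotation"]),
                                         expected_scheme = det_cfg$scheme)
  train_imgs <- lapply(seq_len(nrow(tr)), function(i)
    read_image(file.path(dir, tr$image[i])))
  train_anns <- lapply(seq_len(nrow(tr)), function(i) load_ann(unlist(tr[i, ])))
  val_imgs <- lapply(seq_len(nrow(va)), function(i)
    read_image(file.path(dir, va$image[i])))
  val_anns <- lapply(seq_len(nrow(va)), function(i) load_ann(unlist(va[i, ])))

  with_seed(train_cfg$rng_seed, {
    if (!is.null(train_cfg$init_weights)) {
      prev <- load_checkpoint(train_cfg$init_weights)
      if (!identical(prev$det_cfg$scheme, det_cfg$scheme))
        stop("init_weights checkpoint was trained for scheme ",
             prev$det_cfg$scheme, ", not ", det_cfg$scheme)
      params <- prev$params
    } else {
      params <- init_detector_params(det_cfg)
    }
    opt <- adam_init(params)
    tcache <- new.env(parent = emptyenv())
    variants <- if (train_cfg$flip_augmentation)
      c("none", "horizontal", "vertical") else "none"

    log_rows <- vector("list", train_cfg$iterations)
    best <- list(mae = Inf, map = -Inf, iter = NA_integer_, params = params)
    n_cls <- length(det_cfg$classes)

    validate_now <- function(params, iter) {
      model_tmp <- new_rc_detector(params, det_cfg, train_cfg, NULL, NULL, NULL)
      preds <- lapply(val_imgs, function(im)
        predict_image(model_tmp, im, score_threshold = 0))
      rep <- evaluate_detections(preds, val_anns, det_cfg$classes,
                                 iou_threshold = 0.5,
                                 score_threshold = det_cfg$score_threshold)
      list(mae = rep$mAE, map = rep$mAP)
    }

    for (it in seq_len(train_cfg$iterations)) {
      pick <- sample.int(nrow(tr), train_cfg$batch_size, replace = TRUE)
      var_pick <- sample(variants, train_cfg$batch_size, replace = TRUE)
      grads <- zero_grads(params)
      comp <- c(rpn_cls = 0, rpn_reg = 0, head_cls = 0, head_reg = 0)
      for (bi in seq_len(train_cfg$batch_size)) {
        i <- pick[bi]; vr <- var_pick[bi]
        ann <- train_anns[[i]]
        cropping <- !is.null(train_cfg$crop_size)
        if (cropping) {
          ce <- crop_example(train_imgs[[i]], ann$objects,
                             train_cfg$crop_size)
        } else {
          ce <- list(img = train_imgs[[i]], objects = ann$objects,
                     width = ann$width, height = ann$height)
        }
        img <- flip_image(ce$img, vr)
        obj <- flip_annotation_boxes(ce$objects, ce$width, ce$height, vr)
        gt_m <- box_matrix(obj)
        gt_cls <- match(obj$label, det_cfg$classes)
        fwd <- forward_rpn(params, det_cfg, img)

        tg <- if (cropping) {
          # crops move every step: compute assignment targets directly
          rpn_targets_for(NULL, NULL, fwd$anchors, gt_m, det_cfg)
        } else {
          rpn_targets_for(tcache, paste0(i, "_", vr), fwd$anchors,
                          gt_m, det_cfg)
        }
        pos_s <- sample_positives_balanced(tg$pos, tg$pos_gt, 128L)
        n_pos <- length(pos_s)
        n_neg <- min(length(tg$neg), 256L - n_pos)
        neg_s <- if (length(tg$neg))
          tg$neg[sample.int(length(tg$neg), n_neg)] else integer(0)
        samp <- c(pos_s, neg_s)
        # target deltas aligned with the sampled positives (precomputed)
        td <- matrix(0, length(samp), 4)
        if (length(pos_s))
          td[seq_along(pos_s), ] <- tg$tdeltas[match(pos_s, tg$pos), ,
                                               drop = FALSE]

        # training-time proposals: fixed top-k, no score floor (the head's
        # foreground supply is guaranteed by the appended gt boxes), and a
        # small keep budget — the adaptive floor is an inference-recall
        # device and would slow every iteration here
        props <- make_proposals(fwd, det_cfg, ce$width, ce$height,
                                pre_nms = 2000L, score_floor = Inf,
                                keep = 400L)
        # ROI pool for the head: RPN proposals, the gt boxes themselves,
        # and object-free random boxes (diverse background crops, so the
        # background class sees more than seed-shaped proposals). The
        # random crops are filtered so none substantially contains an
        # object: a crop showing most of a thin radicle rarely exceeds
        # the foreground IoU against its box, and labeling such crops
        # background would teach the head to reject radicle content.
        rnd <- random_rois(60L, ce$width, ce$height)
        rnd <- rnd[containment_free(rnd, gt_m), , drop = FALSE]
        # ... plus a sample of decoded mid-score anchors: inference admits
        # every candidate above the objectness floor, so the head must be
        # trained on that same population, not only on the top proposals
        mid <- mid_score_rois(fwd, det_cfg, ce$width, ce$height, 100L)
        rois <- rbind(props$boxes, gt_m, rnd, mid)
        hw <- rois[, 3] - rois[, 1]; hh <- rois[, 4] - rois[, 2]
        rois <- rois[hw > 0 & hh > 0, , drop = FALSE]
        ht <- head_targets(rois, gt_m, gt_cls, det_cfg)
        rois_s <- rois[ht$sample, , drop = FALSE]
        hf <- head_forward(params, det_cfg, fwd$feat, rois_s)

        targets <- list(
          rpn_labels = c(rep(1, length(pos_s)), rep(0, length(neg_s))),
          rpn_deltas = td,
          head_classes = ht$classes, head_deltas = ht$deltas)
        ls <- detector_losses(
          rpn_outputs = list(obj_logits = fwd$obj_logits[samp],
                             deltas = fwd$deltas[samp, , drop = FALSE]),
          head_outputs = list(class_logits = hf$class_logits,
                              deltas = hf$deltas),
          targets = targets, with_grads = TRUE)
        comp <- comp + c(ls$rpn_cls, ls$rpn_reg, ls$head_cls, ls$head_reg) /
          train_cfg$batch_size

        # scatter sampled-anchor gradients back to the full anchor set
        d_obj_full <- numeric(length(fwd$obj_logits))
        d_obj_full[samp] <- ls$grads$d_obj
        d_del_full <- matrix(0, length(fwd$obj_logits), 4)
        d_del_full[samp, ] <- ls$grads$d_rpn_deltas
        rb <- rpn_backward(params, det_cfg, fwd, d_obj_full, d_del_full, grads)
        hb <- head_backward(params, det_cfg, fwd$feat, hf,
                            ls$grads$d_head_cls, ls$grads$d_head_reg,
                            rb$grads)
        dfeat <- rb$dfeat + hb$dfeat
        grads <- backbone_backward(params, fwd$bb, fwd$bb_cache, dfeat,
                                   hb$grads)
      }
      grads <- lapply(grads, function(g) g / train_cfg$batch_size)
      grads <- clip_gradients(grads, train_cfg$grad_clip)
      lr_now <- train_cfg$learning_rate
      if (identical(train_cfg$lr_schedule, "step") &&
          it > 0.7 * train_cfg$iterations)
        lr_now <- lr_now / 4
      if (train_cfg$optimizer == "adam") {
        st <- adam_step(params, grads, opt, lr_now)
        params <- st$params; opt <- st$state
      } else {
        params <- sgd_step(params, grads, lr_now)
      }

      val_mae <- NA_real_; val_map <- NA_real_
      if (it %% train_cfg$validation_interval == 0L ||
          it == train_cfg$iterations) {
        v <- validate_now(params, it)
        val_mae <- v$mae; val_map <- v$map
        better <- v$mae < best$mae ||
          (v$mae == best$mae && v$map > best$map)
        if (better) best <- list(mae = v$mae, map = v$map, iter = it,
                                 params = params)
        if (!quiet)
          message(sprintf("iter %5d  loss %.4f  val mAE %.4f  val mAP %.4f",
                          it, sum(comp), v$mae, v$map))
      }
      comp <- unname(comp)
      log_rows[[it]] <- data.frame(
        iteration = it, rpn_cls = comp[1], rpn_reg = comp[2],
        head_cls = comp[3], head_reg = comp[4], total = sum(comp),
        val_mAE = val_mae, val_mAP = val_map)
    }
    log <- do.call(rbind, log_rows)
    rownames(log) <- NULL
    new_rc_detector(best$params, det_cfg, train_cfg, log, best$iter,
                    c(tr$image_id, va$image_id),
                    best_val = list(mAE = best$mae, mAP = best$map))
  })
}

# Random scale/offset perturbations of gt boxes (head-training near-misses).
jitter_boxes <- function(gt_m, width, height) {
  if (!nrow(gt_m)) return(gt_m)
  w <- gt_m[, 3] - gt_m[, 1]; h <- gt_m[, 4] - gt_m[, 2]
  n <- nrow(gt_m)
  out <- gt_m + cbind(stats::rnorm(n, 0, 0.15 * w), stats::rnorm(n, 0, 0.15 * h),
                      stats::rnorm(n, 0, 0.15 * w), stats::rnorm(n, 0, 0.15 * h))
  out <- clip_boxes(out, width, height)
  ok <- (out[, 3] - out[, 1]) >= 2 & (out[, 4] - out[, 2]) >= 2
  out[ok, , drop = FALSE]
}

# Random sample of decoded anchors whose objectness clears the proposal
# score floor — the candidate band the inference-time floor admits.
mid_score_rois <- function(fwd, det_cfg, width, height, n, floor = 0.3) {
  sc <- sigmoid(fwd$obj_logits)
  pool <- which(sc >= floor)
  if (!length(pool)) return(matrix(numeric(0), 0, 4))
  pick <- pool[sample.int(length(pool), min(n, length(pool)))]
  boxes <- decode_delta(fwd$anchors[pick, , drop = FALSE],
                        fwd$deltas[pick, , drop = FALSE])
  boxes <- clip_boxes(boxes, width, height)
  ok <- (boxes[, 3] - boxes[, 1]) >= 2 & (boxes[, 4] - boxes[, 2]) >= 2
  boxes[ok, , drop = FALSE]
}

# TRUE for boxes that do not contain a large share of any gt box
# (intersection over gt area below `thr` for every gt).
containment_free <- function(boxes, gt_m, thr = 0.3) {
  if (!nrow(boxes)) return(logical(0))
  if (!nrow(gt_m)) return(rep(TRUE, nrow(boxes)))
  x1 <- outer(boxes[, 1], gt_m[, 1], pmax)
  y1 <- outer(boxes[, 2], gt_m[, 2], pmax)
  x2 <- outer(boxes[, 3], gt_m[, 3], pmin)
  y2 <- outer(boxes[, 4], gt_m[, 4], pmin)
  inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  iof <- sweep(inter, 2, box_area(gt_m), "/")
  apply(iof, 1, max) < thr
}

random_rois <- function(n, width, height) {
  x1 <- stats::runif(n, 0, width - 8)
  y1 <- stats::runif(n, 0, height - 8)
  cbind(x1, y1,
        pmin(x1 + stats::runif(n, 6, 60), width),
        pmin(y1 + stats::runif(n, 6, 60), height))
}

# Sample up to `n` positive anchors, balanced per matched ground-truth box
# (round-robin over boxes): anchor-rich objects (large seeds) otherwise
# crowd anchor-poor ones (thin radicles) out of the objectness loss.
sample_positives_balanced <- function(pos, pos_gt, n) {
  if (!length(pos)) return(integer(0))
  if (length(pos) <= n) return(pos[sample.int(length(pos))])
  groups <- split(pos, pos_gt)
  groups <- lapply(groups, function(g) g[sample.int(length(g))])
  groups <- groups[sample.int(length(groups))]
  out <- integer(0)
  depth <- 1L
  while (length(out) < n) {
    layer <- unlist(lapply(groups, function(g)
      if (length(g) >= depth) g[depth] else NULL), use.names = FALSE)
    if (!length(layer)) break
    out <- c(out, layer)
    depth <- depth + 1L
  }
  out[seq_len(min(n, length(out)))]
}

# Foreground/background assignment for the ROI head. Compact classes
# (seed coats) use the standard IoU rule — foreground at IoU >=
# head_iou_positive, background below — which teaches the head to reject
# loose boxes and keeps counts free of duplicates. Stroke-like classes
# (radicles; det_cfg$stroke_classes) get morphology-aware treatment: a
# radicle's bounding box is mostly background pixels, so (a) a crop that
# contains most of a radicle (intersection over the radicle box >= 0.7,
# some mutual overlap, not grossly larger) is visually equivalent to its
# tight box and becomes a foreground example with regression targets to
# the tight box, and (b) crops containing roughly half a radicle
# (intersection over its box in [0.5, 0.7)) are excluded from the loss as
# ambiguous. Crops with less radicle content are ordinary background:
# with the containment-foreground rule supplying the positive side, the
# full-versus-partial distinction is learnable, and supervising partial
# crops as background is what polices radicle false positives. Without
# the containment rule, background labels on radicle-content crops teach
# the head to reject the class outright and zero its recall.
head_targets <- function(rois, gt_m, gt_cls, det_cfg, n_sample = 128L,
                         fg_fraction = 0.25) {
  m <- nrow(rois)
  if (m == 0L)
    return(list(sample = integer(0), classes = integer(0),
                deltas = matrix(0, 0, 4)))
  if (nrow(gt_m) == 0L) {
    samp <- seq_len(min(m, n_sample))
    return(list(sample = samp, classes = rep(0L, length(samp)),
                deltas = matrix(0, length(samp), 4)))
  }
  M <- iou_matrix(rois, gt_m)
  best <- max.col(M, ties.method = "first")
  best_iou <- M[cbind(seq_len(m), best)]
  target_gt <- best
  is_fg <- best_iou >= det_cfg$head_iou_positive
  is_ignored <- rep(FALSE, m)

  stroke <- gt_cls %in% match(det_cfg$stroke_classes, det_cfg$classes)
  if (any(stroke)) {
    x1 <- outer(rois[, 1], gt_m[, 1], pmax)
    y1 <- outer(rois[, 2], gt_m[, 2], pmax)
    x2 <- outer(rois[, 3], gt_m[, 3], pmin)
    y2 <- outer(rois[, 4], gt_m[, 4], pmin)
    inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
    iof <- sweep(inter, 2, box_area(gt_m), "/")
    iof[, !stroke] <- 0
    best_iof_gt <- max.col(iof, ties.method = "first")
    best_iof <- iof[cbind(seq_len(m), best_iof_gt)]
    area_ratio <- box_area(rois) / box_area(gt_m)[best_iof_gt]
    contain_fg <- !is_fg & best_iof >= 0.7 &
      M[cbind(seq_len(m), best_iof_gt)] >= 0.2 & area_ratio <= 5
    target_gt[contain_fg] <- best_iof_gt[contain_fg]
    is_fg <- is_fg | contain_fg
    is_ignored <- !is_fg & best_iof >= 0.5
  }
  fg <- which(is_fg)
  bg <- which(!is_fg & !is_ignored)
  n_fg <- min(length(fg), round(n_sample * fg_fraction))
  fg_s <- if (length(fg)) fg[sample.int(length(fg), n_fg)] else integer(0)
  n_bg <- min(length(bg), n_sample - n_fg)
  bg_s <- if (length(bg)) bg[sample.int(length(bg), n_bg)] else integer(0)
  samp <- c(fg_s, bg_s)
  classes <- c(gt_cls[target_gt[fg_s]], rep(0L, length(bg_s)))
  deltas <- matrix(0, length(samp), 4)
  if (length(fg_s))
    deltas[seq_along(fg_s), ] <- encode_delta(
      rois[fg_s, , drop = FALSE],
      gt_m[target_gt[fg_s], , drop = FALSE])
  list(sample = samp, classes = classes, deltas = deltas)
}

new_rc_detector <- function(params, det_cfg, train_cfg, log, best_iter,
                            trained_on, best_val = NULL) {
  structure(list(params = params, det_cfg = det_cfg, train_cfg = train_cfg,
                 log = log, best_iteration = best_iter,
                 trained_on = trained_on, best_val = best_val),
            class = "rc_detector")
}

#' Predict detections on one image
#'
#' Full inference pass: backbone features, region proposals, ROI head
#' classification (softmax over classes plus background) and box
#' refinement, per-class non-maximum suppression, and confidence
#' thresholding. The reported confidence is the softmax probability of the
#' predicted class; proposals whose best class is background are dropped,
#' so returned labels are always scheme classes.
#'
#' @param model an `rc_detector`.
#' @param image H x W x 3 array in `[0,1]`, or an image file path.
#' @param score_threshold minimum confidence of reported detections
#'   (default: the model's configured threshold). Raising it can only
#'   shrink the detection list.
#' @return data.frame with `label`, `xmin`, `ymin`, `xmax`, `ymax`,
#'   `confidence`, sorted by decreasing confidence.
#' @export
predict_image <- function(model, image, score_threshold = NULL) {
  stopifnot(inherits(model, "rc_detector"))
  if (is.character(image)) image <- read_image(image)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array (RGB)")
  if (is.null(score_threshold)) score_threshold <- model$det_cfg$score_threshold
  det_cfg <- model$det_cfg
  H <- dim(image)[1]; W <- dim(image)[2]
  fwd <- forward_rpn(model$params, det_cfg, image)
  props <- make_proposals(fwd, det_cfg, W, H, pre_nms = 6000L)
  empty <- data.frame(label = character(0), xmin = numeric(0),
                      ymin = numeric(0), xmax = numeric(0), ymax = numeric(0),
                      confidence = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(props$boxes)) return(empty)
  hf <- head_forward(model$params, det_cfg, fwd$feat, props$boxes)
  p <- softmax_rows(pmin(pmax(hf$class_logits, -500), 500))
  best <- max.col(p, ties.method = "first")
  conf <- p[cbind(seq_len(nrow(p)), best)]
  keep <- best > 1L          # column 1 is background
  if (!any(keep)) return(empty)
  boxes <- decode_delta(props$boxes[keep, , drop = FALSE],
                        hf$deltas[keep, , drop = FALSE])
  boxes <- clip_boxes(boxes, W, H)
  ok <- (boxes[, 3] - boxes[, 1]) > 0 & (boxes[, 4] - boxes[, 2]) > 0
  det <- data.frame(label = det_cfg$classes[best[keep] - 1L][ok],
                    xmin = boxes[ok, 1], ymin = boxes[ok, 2],
                    xmax = boxes[ok, 3], ymax = boxes[ok, 4],
                    confidence = conf[keep][ok], stringsAsFactors = FALSE)
  det <- nms(det, det_cfg$nms_iou)
  det <- det[det$confidence >= score_threshold, , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' @export
predict.rc_detector <- function(object, newdata, score_threshold = NULL, ...) {
  predict_image(object, newdata, score_threshold = score_threshold)
}

#' @export
print.rc_detector <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<rc_detector>  scheme %s (classes: %s), backbone '%s', %s parameters\n",
              x$det_cfg$scheme, paste(x$det_cfg$classes, collapse = "/"),
              x$det_cfg$backbone, format(npar, big.mark = ",")))
  if (!is.null(x$best_iteration) && !is.na(x$best_iteration))
    cat(sprintf("  best validation iteration %d (mAE %.4f, mAP %.4f)\n",
                x$best_iteration, x$best_val$mAE, x$best_val$mAP))
  invisible(x)
}

#' @export
summary.rc_detector <- function(object, ...) {
  log <- object$log
  cat("Training loss (first / last iteration):\n")
  if (!is.null(log) && nrow(log)) {
    print(log[c(1, nrow(log)), c("iteration", "rpn_cls", "rpn_reg",
                                 "head_cls", "head_reg", "total")],
          row.names = FALSE)
    v <- log[!is.na(log$val_mAE), c("iteration", "val_mAE", "val_mAP")]
    if (nrow(v)) { cat("Validation passes:\n"); print(v, row.names = FALSE) }
  } else cat("  (no training log)\n")
  invisible(object)
}

#' Plot detections over an image
#'
#' @param x an `rc_detector`.
#' @param image image array or path.
#' @param detections optional precomputed detections; defaults to
#'   [predict_image()] output at the model's score threshold.
#' @param ... passed to [graphics::rasterImage()].
#' @export
plot.rc_detector <- function(x, image, detections = NULL, ...) {
  if (is.character(image)) image <- read_image(image)
  if (is.null(detections)) detections <- predict_image(x, image)
  H <- dim(image)[1]; W <- dim(image)[2]
  graphics::plot(NA, xlim = c(0, W), ylim = c(H, 0), asp = 1,
                 xlab = "", ylab = "", axes = FALSE)
  graphics::rasterImage(image, 0, H, W, 0, ...)
  if (nrow(detections)) {
    cols <- c("#d62728", "#1f77b4")[match(detections$label,
                                          x$det_cfg$classes) %% 2 + 1]
    graphics::rect(detections$xmin, detections$ymin, detections$xmax,
                   detections$ymax, border = cols, lwd = 1.5)
  }
  invisible(detections)
}

#' Save / load a detector checkpoint
#'
#' Checkpoints are versioned RDS files embedding the full detector object
#' (parameters and both configurations), written at run time.
#'
#' @param model an `rc_detector`.
#' @param path checkpoint file path.
#' @return `load_checkpoint` returns the `rc_detector`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "rc_detector"))
  saveRDS(list(format = "rc_checkpoint", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "rc_checkpoint"))
    stop("not a detector checkpoint: ", path)
  if (obj$version > 1L)
    stop("checkpoint version ", obj$version, " is newer than this package supports")
  obj$model
}
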