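#' Anchor geometry configuration
#'
#' Nine reference boxes ("anchors") are tiled at every feature-map
#' location: all combinations of three scales (box side in pixels, at
#' aspect ratio 1) and three aspect ratios (width/height). An anchor at
#' scale s and ratio r has width `s * sqrt(r)` and height `s / sqrt(r)`,
#' preserving area across ratios.
#'
#' @param stride distance in image pixels between anchor centers (the
#'   feature-map stride of the backbone).
#' @param scales three positive base sizes in pixels.
#' @param aspect_ratios three positive width/height ratios.
#' @return An object of class `rc_anchor_config`.
#' @export
anchor_config <- function(stride = 8, scales = c(16, 24, 36),
                          aspect_ratios = c(0.5, 1, 2)) {
  if (length(scales) != 3L || length(aspect_ratios) != 3L)
    stop("exactly 3 scales and 3 aspect ratios are required (9 anchors per location)")
  if (any(scales <= 0) || any(aspect_ratios <= 0))
    stop("scales and aspect ratios must be positive")
  structure(list(stride = stride, scales = as.numeric(scales),
                 aspect_ratios = as.numeric(aspect_ratios)),
            class = "rc_anchor_config")
}

#' Detector configuration
#'
#' Bundles the anchor geometry, the IoU thresholds used to assign anchors
#' to ground-truth boxes during training (an anchor is positive above
#' `iou_positive`, negative below `iou_negative`, and excluded from the
#' loss in between), the proposal filtering parameters, and the class list
#' of the annotation scheme (background is implicit).
#'
#' @param scheme annotation scheme; determines `classes`.
#' @param anchor an [anchor_config()].
#' @param iou_positive,iou_negative anchor assignment thresholds
#'   (defaults 0.7 and 0.3).
#' @param nms_iou IoU above which overlapping same-class detections are
#'   suppressed.
#' @param proposal_count maximum proposals kept after the region-proposal
#'   stage.
#' @param score_threshold default confidence cutoff for reported detections.
#' @param backbone feature-extractor name; `"tiny"` is the built-in small
#'   convolutional stack (stride 8, 64 channels). The names `"R-50-C4"`,
#'   `"R-50-FPN"`, `"R-101-FPN"` and `"X-101-FPN"` are reserved for heavy
#'   pretrained backbones and are not shipped.
#' @param head_iou_positive IoU above which a proposal is a foreground
#'   example for the second-stage head.
#' @param roi_pool_size side of the square bilinear crop taken from the
#'   feature map for each proposal.
#' @return An object of class `rc_detector_config`. The configuration also
#'   records `stroke_classes` — the classes whose objects are thin strokes
#'   occupying a small fraction of their bounding box (the radicle class
#'   `R` under the `S_R` scheme) — which receive morphology-aware
#'   foreground assignment during training.
#' @export
detector_config <- function(scheme = c("S_R", "NGS_GS"),
                            anchor = anchor_config(),
                            iou_positive = 0.7, iou_negative = 0.3,
                            nms_iou = 0.5, proposal_count = 3000L,
                            score_threshold = 0.5, backbone = "tiny",
                            head_iou_positive = 0.5, roi_pool_size = 5L) {
  scheme <- match.arg(scheme)
  if (!(iou_negative >= 0 && iou_negative < iou_positive && iou_positive <= 1))
    stop("need 0 <= iou_negative < iou_positive <= 1")
  structure(list(scheme = scheme, classes = scheme_labels(scheme),
                 anchor = anchor, iou_positive = iou_positive,
                 iou_negative = iou_negative, nms_iou = nms_iou,
                 proposal_count = as.integer(proposal_count),
                 score_threshold = score_threshold, backbone = backbone,
                 head_iou_positive = head_iou_positive,
                 roi_pool_size = as.integer(roi_pool_size),
                 stroke_classes = intersect("R", scheme_labels(scheme))),
            class = "rc_detector_config")
}

#' Generate the anchor set for a feature map
#'
#' Returns all `H * W * 9` anchors for an `H x W` feature map, as a box
#' matrix in image coordinates. Ordering is deterministic: locations in
#' row-major order (row by row, left to right), and within a location the
#' nine anchors with scale varying slowest and aspect ratio fastest. Each
#' anchor is centered at `(index + 0.5) * stride` of its location. Anchors
#' may extend beyond the image; they are used as-is for assignment and
#' clipped only after decoding.
#'
#' @param feature_shape integer vector `c(H, W)` of feature-map locations.
#' @param cfg an [anchor_config()].
#' @return An `(H*W*9) x 4` matrix with columns xmin, ymin, xmax, ymax.
#' @export
generate_anchors <- function(feature_shape, cfg) {
  stopifnot(inherits(cfg, "rc_anchor_config"),
            length(feature_shape) == 2L, all(feature_shape >= 1))
  H <- feature_shape[1]; W <- feature_shape[2]
  s <- rep(cfg$scales, each = 3L)
  r <- rep(cfg$aspect_ratios, times = 3L)
  aw <- s * sqrt(r); ah <- s / sqrt(r)
  # location grid, row-major: y slow, x fast
  cy <- (rep(seq_len(H) - 1L, each = W) + 0.5) * cfg$stride
  cx <- (rep(seq_len(W) - 1L, times = H) + 0.5) * cfg$stride
  n_loc <- H * W
  CX <- rep(cx, each = 9L); CY <- rep(cy, each = 9L)
  AW <- rep(aw, times = n_loc); AH <- rep(ah, times = n_loc)
  cbind(xmin = CX - AW / 2, ymin = CY - AH / 2,
        xmax = CX + AW / 2, ymax = CY + AH / 2)
}

#' Assign training labels to anchors
#'
#' Implements the assignment rule of the region-proposal stage: each
#' anchor's maximum IoU over the ground-truth boxes decides its label —
#' positive above `iou_positive` (matched to the argmax box), negative
#' below `iou_negative`, and `ignore` in between (such anchors contribute
#' to neither loss term). In addition, for every ground-truth box the
#' anchor(s) with the highest IoU for that box are forced positive even
#' below the threshold, so no ground-truth box is left unmatched. With no
#' ground-truth boxes all anchors are negative.
#'
#' @param anchors box matrix from [generate_anchors()].
#' @param gt_boxes ground-truth box matrix (possibly 0 rows).
#' @param cfg an [rc_detector_config()][detector_config()] (or any list
#'   with `iou_positive` / `iou_negative`).
#' @return A list with `status` (character: `"positive"`, `"negative"`,
#'   `"ignore"`), `matched` (gt row index for positives, `NA` otherwise)
#'   and `max_iou`.
#' @export
assign_anchor_labels <- function(anchors, gt_boxes, cfg) {
  anchors <- box_matrix(anchors)
  gt_boxes <- box_matrix(gt_boxes)
  n <- nrow(anchors)
  if (n == 0L) stop("no anchors to assign")
  if (nrow(gt_boxes) == 0L)
    return(list(status = rep("negative", n), matched = rep(NA_integer_, n),
                max_iou = rep(0, n)))
  M <- iou_matrix(anchors, gt_boxes)
  max_iou <- apply(M, 1L, max)
  matched <- max.col(M, ties.method = "first")
  status <- rep("ignore", n)
  status[max_iou > cfg$iou_positive] <- "positive"
  status[max_iou < cfg$iou_negative] <- "negative"
  # force-match: each gt's best anchor(s) become positive
  gt_best <- apply(M, 2L, max)
  for (g in seq_len(ncol(M))) {
    if (gt_best[g] <= 0) next   # gt untouchable by any anchor
    hit <- which(M[, g] >= gt_best[g] - 1e-9)
    status[hit] <- "positive"
    matched[hit] <- g
  }
  matched[status != "positive"] <- NA_integer_
  list(status = status, matched = matched, max_iou = max_iou)
}

#' Box regression deltas
#'
#' `encode_delta` expresses a target box relative to an anchor as the four
#' regression scalars `(tx, ty, tw, th)`: center offsets normalized by the
#' anchor's width and height, and log size ratios. `decode_delta` is the
#' exact inverse, so `decode_delta(a, encode_delta(a, g))` reproduces `g`
#' and `encode_delta(a, a)` is all zeros.
#'
#' @param anchor,gt,delta box matrices / delta matrices (n x 4); single
#'   boxes (length-4 vectors) are accepted.
#' @return `encode_delta`: n x 4 matrix of `(tx, ty, tw, th)`;
#'   `decode_delta`: n x 4 box matrix.
#' @export
encode_delta <- function(anchor, gt) {
  a <- box_matrix(anchor); g <- box_matrix(gt)
  aw <- a[, 3] - a[, 1]; ah <- a[, 4] - a[, 2]
  gw <- g[, 3] - g[, 1]; gh <- g[, 4] - g[, 2]
  if (any(aw <= 0 | ah <= 0 | gw <= 0 | gh <= 0))
    stop("boxes must have positive width and height")
  cbind(tx = ((g[, 1] + g[, 3]) / 2 - (a[, 1] + a[, 3]) / 2) / aw,
        ty = ((g[, 2] + g[, 4]) / 2 - (a[, 2] + a[, 4]) / 2) / ah,
        tw = log(gw / aw), th = log(gh / ah))
}

#' @rdname encode_delta
#' @export
decode_delta <- function(anchor, delta) {
  a <- box_matrix(anchor)
  d <- matrix(as.numeric(delta), ncol = 4)
  aw <- a[, 3] - a[, 1]; ah <- a[, 4] - a[, 2]
  if (any(aw <= 0 | ah <= 0))
    stop("anchors must have positive width and height")
  cx <- (a[, 1] + a[, 3]) / 2 + d[, 1] * aw
  cy <- (a[, 2] + a[, 4]) / 2 + d[, 2] * ah
  w <- aw * exp(d[, 3]); h <- ah * exp(d[, 4])
  cbind(xmin = cx - w / 2, ymin = cy - h / 2,
        xmax = cx + w / 2, ymax = cy + h / 2)
}

# Smooth L1 (Huber with threshold 1): 0.5 x^2 for |x| < 1, |x| - 0.5
# otherwise. Returns elementwise values; gradient helper alongside.
smooth_l1 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, 0.5 * x^2, ax - 0.5)
}

smooth_l1_grad <- function(x) {
  pmin(pmax(x, -1), 1)
}
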