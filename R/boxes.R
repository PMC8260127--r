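#' Axis-aligned bounding boxes
#'
#' Boxes are stored 0-based and half-open: a box covers pixel columns
#' `xmin .. xmax-1` and rows `ymin .. ymax-1`, so `width = xmax - xmin`.
#' Pascal VOC files use the 1-based inclusive dialect; conversion happens
#' only at the XML boundary (see [read_voc_xml()]).
#'
#' @param xmin,ymin,xmax,ymax box edges in pixels (0-based, half-open).
#' @return A named numeric vector of class `rc_box`.
#' @examples
#' b <- bbox(0, 0, 10, 10)
#' box_area(b) # 100
#' @export
bbox <- function(xmin, ymin, xmax, ymax) {
  b <- c(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (!all(is.finite(b))) stop("box coordinates must be finite")
  if (b["xmax"] <= b["xmin"] || b["ymax"] <= b["ymin"])
    stop("degenerate box: xmax must exceed xmin and ymax must exceed ymin")
  if (any(b < 0)) stop("box coordinates must be non-negative")
  class(b) <- "rc_box"
  b
}

#' @rdname bbox
#' @param box a box (vector of xmin, ymin, xmax, ymax) or a 4-column matrix.
#' @export
box_area <- function(box) {
  m <- box_matrix(box)
  as.numeric((m[, 3] - m[, 1]) * (m[, 4] - m[, 2]))
}

#' @rdname bbox
#' @details `box_matrix()` coerces a single box, a data.frame with
#'   `xmin`/`ymin`/`xmax`/`ymax` columns, or an n x 4 matrix to a plain
#'   numeric box matrix — the vectorized currency of the package.
#' @export
box_matrix <- function(box) {
  if (is.data.frame(box)) {
    m <- as.matrix(box[, c("xmin", "ymin", "xmax", "ymax"), drop = FALSE])
  } else if (is.matrix(box)) {
    m <- box[, 1:4, drop = FALSE]
  } else {
    m <- matrix(as.numeric(box), ncol = 4, byrow = TRUE)
  }
  storage.mode(m) <- "double"
  unname(m)
}

#' Intersection over union of two boxes
#'
#' The ratio of the overlap area to the union area of two axis-aligned
#' boxes: the geometric match criterion used throughout detection
#' assignment and evaluation. Symmetric; 0 for disjoint boxes; 1 only for
#' identical boxes.
#'
#' @param a,b boxes as produced by [bbox()] (or plain length-4 vectors).
#' @return A single number in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10)) # 1/3
#' @export
iou <- function(a, b) {
  as.numeric(iou_matrix(box_matrix(a), box_matrix(b)))
}

#' Pairwise IoU between two sets of boxes
#'
#' @param a an n x 4 box matrix (or data.frame with xmin..ymax columns).
#' @param b an m x 4 box matrix.
#' @return An n x m matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- box_matrix(a); b <- box_matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  x1 <- outer(a[, 1], b[, 1], pmax)
  y1 <- outer(a[, 2], b[, 2], pmax)
  x2 <- outer(a[, 3], b[, 3], pmin)
  y2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  un <- outer(box_area(a), box_area(b), "+") - inter
  out <- inter / un
  out[un == 0] <- 0
  out
}

# Clip boxes to [0,w) x [0,h); drops nothing, callers filter degenerates.
clip_boxes <- function(m, width, height) {
  m <- box_matrix(m)
  m[, 1] <- pmin(pmax(m[, 1], 0), width)
  m[, 3] <- pmin(pmax(m[, 3], 0), width)
  m[, 2] <- pmin(pmax(m[, 2], 0), height)
  m[, 4] <- pmin(pmax(m[, 4], 0), height)
  m
}

#' Flip boxes with their image
#'
#' Transforms boxes consistently with a horizontal (left-right) or vertical
#' (top-bottom) image flip; applying the same flip twice is the identity.
#'
#' @param m boxes (matrix or data.frame).
#' @param width,height image size in pixels.
#' @param direction `"horizontal"` or `"vertical"`.
#' @return A box matrix of the same shape.
#' @examples
#' flip_boxes(bbox(10, 20, 30, 40), 100, 100, "horizontal") # 70,20,90,40
#' @export
flip_boxes <- function(m, width, height, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  m <- box_matrix(m)
  if (nrow(m) == 0L) return(m)
  if (direction == "horizontal") {
    new_xmin <- width - m[, 3]
    new_xmax <- width - m[, 1]
    m[, 1] <- new_xmin; m[, 3] <- new_xmax
  } else {
    new_ymin <- height - m[, 4]
    new_ymax <- height - m[, 2]
    m[, 2] <- new_ymin; m[, 4] <- new_ymax
  }
  m
}

#' @export
print.rc_box <- function(x, ...) {
  cat(sprintf("box [%g, %g) x [%g, %g)  (%g x %g px)\n",
              x["xmin"], x["xmax"], x["ymin"], x["ymax"],
              x["xmax"] - x["xmin"], x["ymax"] - x["ymin"]))
  invisible(x)
}
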