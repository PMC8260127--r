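# Minimal dense/convolutional network machinery backing the detector.
# Parameters are plain R arrays in a named list; convolution and ROI crop
# inner loops run in compiled code (src/nn_ops.cpp). All shapes follow the
# c(H, W, C) array convention.

xavier <- function(dims) {
  # fan counts for conv (kh, kw, cin, cout) or dense (in, out) weights
  if (length(dims) == 4L) {
    fan_in <- dims[1] * dims[2] * dims[3]
    fan_out <- dims[1] * dims[2] * dims[4]
  } else {
    fan_in <- dims[1]; fan_out <- dims[2]
  }
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

relu <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(pre, grad) { grad[pre <= 0] <- 0; grad }

conv_f <- function(x, W, b, stride, pad) {
  d <- dim(W)
  conv2d_forward(x, as.numeric(W), as.numeric(b), d[1], d[2], d[4], stride, pad)
}

conv_b <- function(x, W, dY, stride, pad, need_dx = TRUE) {
  d <- dim(W)
  out <- conv2d_backward(x, as.numeric(W), dY, d[1], d[2], d[4], stride, pad,
                         need_dx)
  out$dW <- array(out$dW, dim = d)
  out$db <- as.numeric(out$db)
  out
}

#' Feature-extractor backbones
#'
#' The detector maps an RGB image to a single-scale feature volume through
#' a named backbone. The built-in `"tiny"` backbone is a three-layer
#' convolutional stack with overall stride 8 and 64 output channels, sized
#' for CPU training on synthetic disks. The ResNet-family names
#' (`"R-50-C4"`, `"R-50-FPN"`, `"R-101-FPN"`, `"X-101-FPN"`) are reserved:
#' they identify large pretrained extractors that this package does not
#' ship, and requesting one raises an error.
#'
#' @param name backbone name.
#' @return A list describing the backbone: `stride`, `channels`, and the
#'   convolution layer definitions.
#' @export
backbone_def <- function(name = "tiny") {
  reserved <- c("R-50-C4", "R-50-FPN", "R-101-FPN", "X-101-FPN")
  if (name %in% reserved)
    stop("backbone '", name, "' is reserved for large pretrained feature ",
         "extractors that are not shipped with this package; use 'tiny'")
  if (name != "tiny") stop("unknown backbone: ", name)
  list(name = "tiny", stride = 8L, channels = 64L,
       layers = list(
         list(name = "conv1", k = 7L, cin = 3L, cout = 16L, stride = 4L, pad = 3L),
         list(name = "conv2", k = 3L, cin = 16L, cout = 32L, stride = 2L, pad = 1L),
         list(name = "conv3", k = 3L, cin = 32L, cout = 64L, stride = 1L, pad = 1L)))
}

# Initialize the full parameter list (backbone + RPN + head) with Xavier
# weights and zero biases. Uses the current RNG stream.
init_detector_params <- function(det_cfg) {
  bb <- backbone_def(det_cfg$backbone)
  C <- length(det_cfg$classes)
  P <- det_cfg$roi_pool_size
  ch <- bb$channels
  params <- list()
  for (ly in bb$layers) {
    params[[paste0(ly$name, ".W")]] <- xavier(c(ly$k, ly$k, ly$cin, ly$cout))
    params[[paste0(ly$name, ".b")]] <- numeric(ly$cout)
  }
  params[["rpn_conv.W"]] <- xavier(c(3, 3, ch, ch))
  params[["rpn_conv.b"]] <- numeric(ch)
  params[["rpn_cls.W"]] <- xavier(c(1, 1, ch, 9))
  params[["rpn_cls.b"]] <- numeric(9)
  params[["rpn_reg.W"]] <- xavier(c(1, 1, ch, 36))
  params[["rpn_reg.b"]] <- numeric(36)
  fc_in <- P * P * ch
  params[["fc1.W"]] <- xavier(c(fc_in, 128))
  params[["fc1.b"]] <- numeric(128)
  params[["head_cls.W"]] <- xavier(c(128, C + 1))
  params[["head_cls.b"]] <- numeric(C + 1)
  params[["head_reg.W"]] <- xavier(c(128, 4))
  params[["head_reg.b"]] <- numeric(4)
  params
}

backbone_forward <- function(params, bb, img) {
  x <- img
  cache <- vector("list", length(bb$layers))
  for (i in seq_along(bb$layers)) {
    ly <- bb$layers[[i]]
    z <- conv_f(x, params[[paste0(ly$name, ".W")]],
                params[[paste0(ly$name, ".b")]], ly$stride, ly$pad)
    cache[[i]] <- list(x = x, z = z)
    x <- relu(z)
  }
  list(feat = x, cache = cache)
}

backbone_backward <- function(params, bb, cache, dfeat, grads) {
  g <- dfeat
  for (i in rev(seq_along(bb$layers))) {
    ly <- bb$layers[[i]]
    g <- relu_bwd(cache[[i]]$z, g)
    bk <- conv_b(cache[[i]]$x, params[[paste0(ly$name, ".W")]], g,
                 ly$stride, ly$pad, need_dx = (i > 1L))
    grads[[paste0(ly$name, ".W")]] <- grads[[paste0(ly$name, ".W")]] + bk$dW
    grads[[paste0(ly$name, ".b")]] <- grads[[paste0(ly$name, ".b")]] + bk$db
    g <- bk$dX
  }
  grads
}

zero_grads <- function(params) {
  lapply(params, function(p)
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p)))
}

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

# Rescale gradients so their global L2 norm is at most `max_norm`.
clip_gradients <- function(grads, max_norm = 10) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / total
    grads <- lapply(grads, function(g) g * sc)
  }
  grads
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
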