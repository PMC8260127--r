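#' Specification of a synthetic germination bioassay disk
#'
#' Describes the generative model for one synthetic disk image: a bright
#' circular glass-fiber disk photographed on a neutral background, carrying
#' 50--100 dark ovoid seeds of which a fraction have germinated. A
#' germinated seed bears a thin, curved, near-white radicle emerging from
#' one pole of the seed coat; radicles have low contrast against the
#' bright disk and may freely cross seeds and other radicles. Optional
#' failure modes reproduce real-world difficulties: unlabeled plant debris,
#' and a small white protuberance on the coat of non-germinated seeds that
#' mimics a very short radicle.
#'
#' @param image_size image side in pixels (square images).
#' @param n_seeds number of seeds, or `NULL` to draw uniformly from
#'   `n_seeds_range` (the 50--100 seeds per disk regime).
#' @param n_seeds_range inclusive integer range used when `n_seeds` is `NULL`.
#' @param germination_fraction probability that a seed has germinated
#'   (default 0.55, the average germination rate per disk).
#' @param exact_germination if `TRUE` the germinated count is forced to
#'   `round(n_seeds * germination_fraction)`; if `FALSE` (default) each seed
#'   germinates independently (binomial sampling).
#' @param seed_axis_range range of the seed ellipse semi-major axis, pixels.
#' @param seed_aspect_range range of semi-minor/semi-major axis ratio.
#' @param radicle_length_range range of radicle lengths, pixels.
#' @param radicle_width_range range of radicle stroke widths, pixels.
#' @param radicle_contrast opacity in `[0,1]` with which the near-white
#'   radicle stroke is blended over the image; low values emulate the poor
#'   contrast of translucent radicles against the white filter disk, and 0
#'   renders radicles invisible.
#' @param overlap_intensity crowding control in `[0,1]`: 0 keeps seed
#'   outlines disjoint, 1 removes the minimum-distance constraint entirely.
#' @param protuberance_probability probability that a non-germinated seed
#'   carries a small white coat protuberance (the radicle-mimicking
#'   artifact; 0 by default).
#' @param debris_count number of unlabeled gray debris blobs.
#' @param rng_seed integer seed; every stochastic choice derives from it.
#' @return An object of class `rc_disk_spec`.
#' @export
disk_spec <- function(image_size = 512,
                      n_seeds = NULL,
                      n_seeds_range = c(50L, 100L),
                      germination_fraction = 0.55,
                      exact_germination = FALSE,
                      seed_axis_range = c(9, 15),
                      seed_aspect_range = c(0.6, 0.85),
                      radicle_length_range = c(15, 60),
                      radicle_width_range = c(2, 4),
                      radicle_contrast = 0.6,
                      overlap_intensity = 0.3,
                      protuberance_probability = 0,
                      debris_count = 0L,
                      rng_seed = 1L) {
  spec <- list(image_size = as.integer(image_size), n_seeds = n_seeds,
               n_seeds_range = as.integer(n_seeds_range),
               germination_fraction = germination_fraction,
               exact_germination = isTRUE(exact_germination),
               seed_axis_range = seed_axis_range,
               seed_aspect_range = seed_aspect_range,
               radicle_length_range = radicle_length_range,
               radicle_width_range = radicle_width_range,
               radicle_contrast = radicle_contrast,
               overlap_intensity = overlap_intensity,
               protuberance_probability = protuberance_probability,
               debris_count = as.integer(debris_count),
               rng_seed = as.integer(rng_seed))
  probs <- c(spec$germination_fraction, spec$radicle_contrast,
             spec$overlap_intensity, spec$protuberance_probability)
  if (any(probs < 0 | probs > 1))
    stop("germination_fraction, radicle_contrast, overlap_intensity and ",
         "protuberance_probability must lie in [0, 1]")
  for (f in c("n_seeds_range", "seed_axis_range", "seed_aspect_range",
              "radicle_length_range", "radicle_width_range")) {
    r <- spec[[f]]
    if (length(r) != 2L || any(r <= 0) || r[2] < r[1])
      stop(f, " must be a positive non-empty range")
  }
  if (spec$image_size < 64) stop("image_size must be at least 64 px")
  if (spec$debris_count < 0) stop("debris_count must be >= 0")
  class(spec) <- "rc_disk_spec"
  spec
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

disk_geometry <- function(spec) {
  half <- spec$image_size / 2
  list(cx = half, cy = half, radius = 0.46 * spec$image_size)
}

#' Sample the ground truth for one synthetic disk
#'
#' Draws seed positions, shapes, germination states and radicle geometry
#' according to a [disk_spec()]. Seed centers are placed by rejection
#' sampling under a minimum-distance constraint that relaxes as
#' `overlap_intensity` approaches 1. Every object's bounding box is the
#' tight axis-aligned box of its rasterized pixel footprint, so boxes agree
#' exactly with what [render_disk()] draws. Deterministic given
#' `spec$rng_seed`.
#'
#' @param spec a [disk_spec()].
#' @return An object of class `rc_disk_truth`: the spec plus a list of seed
#'   instances (ellipse geometry, germination flag, radicle polyline, seed
#'   and radicle boxes) and debris blobs. The seed-radicle pairing is
#'   explicit here, which neither annotation scheme retains.
#' @export
sample_disk <- function(spec) {
  stopifnot(inherits(spec, "rc_disk_spec"))
  with_seed(spec$rng_seed, {
    geom <- disk_geometry(spec)
    n <- spec$n_seeds
    if (is.null(n))
      n <- sample(seq(spec$n_seeds_range[1], spec$n_seeds_range[2]), 1L)
    n <- as.integer(n)
    if (n < 1) stop("need at least one seed")

    if (spec$exact_germination) {
      k <- as.integer(round(n * spec$germination_fraction))
      germ <- rep(FALSE, n)
      if (k > 0) germ[sample.int(n, k)] <- TRUE
    } else {
      germ <- stats::runif(n) < spec$germination_fraction
    }

    a <- stats::runif(n, spec$seed_axis_range[1], spec$seed_axis_range[2])
    b <- a * stats::runif(n, spec$seed_aspect_range[1], spec$seed_aspect_range[2])
    theta <- stats::runif(n, 0, pi)
    eff_r <- sqrt(a * b)

    # sequential placement with a crowding-dependent minimum distance
    centers <- matrix(NA_real_, n, 2)
    relax <- 1 - spec$overlap_intensity
    max_attempts <- 400L
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        rr <- (geom$radius - a[i] - 2) * sqrt(stats::runif(1))
        ang <- stats::runif(1, 0, 2 * pi)
        cand <- c(geom$cx + rr * cos(ang), geom$cy + rr * sin(ang))
        ok <- TRUE
        if (i > 1 && relax > 0) {
          d <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - cand)^2))
          dmin <- relax * (eff_r[seq_len(i - 1)] + eff_r[i])
          ok <- all(d >= dmin)
        }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop(sprintf(
          "infeasible packing: could not place seed %d of %d after %d attempts; ",
          i, n, max_attempts),
          "reduce n_seeds, enlarge image_size, or raise overlap_intensity")
    }

    seeds <- vector("list", n)
    for (i in seq_len(n)) {
      s <- list(center = centers[i, ], orientation = theta[i],
                semi_axes = c(a[i], b[i]), germinated = germ[i],
                protuberance = NULL, radicle_path = NULL, radicle_width = NULL)
      if (!germ[i] && spec$protuberance_probability > 0 &&
          stats::runif(1) < spec$protuberance_probability) {
        pole <- sample(c(0, pi), 1L)
        s$protuberance <- list(angle = pole + stats::rnorm(1, 0, 0.3),
                               radius = stats::runif(1, 1.5, 2.5))
      }
      if (germ[i]) {
        s$radicle_path <- sample_radicle_path(s, spec)
        s$radicle_width <- stats::runif(1, spec$radicle_width_range[1],
                                        spec$radicle_width_range[2])
      }
      seeds[[i]] <- s
    }

    debris <- NULL
    if (spec$debris_count > 0) {
      rr <- (geom$radius - 8) * sqrt(stats::runif(spec$debris_count))
      ang <- stats::runif(spec$debris_count, 0, 2 * pi)
      debris <- data.frame(
        x = geom$cx + rr * cos(ang), y = geom$cy + rr * sin(ang),
        a = stats::runif(spec$debris_count, 2, 6),
        b = stats::runif(spec$debris_count, 1.5, 4),
        theta = stats::runif(spec$debris_count, 0, pi))
      debris$b <- pmin(debris$b, debris$a)
    }

    truth <- structure(list(spec = spec, n_seeds = n, seeds = seeds,
                            debris = debris), class = "rc_disk_truth")
    # tight boxes from the rasterized footprints render_disk() will draw
    for (i in seq_len(n)) {
      sp <- object_pixels(truth, i, "seed")
      if (nrow(sp$px) == 0)
        stop("seed ", i, " rasterized to an empty footprint")
      truth$seeds[[i]]$seed_box <- pixels_tight_box(sp$px)
      if (truth$seeds[[i]]$germinated) {
        rp <- object_pixels(truth, i, "radicle")
        if (nrow(rp$px) == 0) {
          # radicle entirely clipped away (vanishingly rare): treat the
          # seed as non-germinated so the pairing invariant holds
          truth$seeds[[i]]$germinated <- FALSE
          truth$seeds[[i]]$radicle_path <- NULL
          truth$seeds[[i]]$radicle_width <- NULL
        } else {
          truth$seeds[[i]]$radicle_box <- pixels_tight_box(rp$px)
        }
      }
    }
    truth
  })
}

# Curved radicle emerging from a pole of the seed ellipse: a cubic Bezier
# whose initial direction is the outward major-axis direction, with random
# bend. Returned as a dense polyline (~1 sample per 0.5 px).
sample_radicle_path <- function(seed, spec) {
  a <- seed$semi_axes[1]
  th <- seed$orientation
  pole_sign <- sample(c(-1, 1), 1L)
  dir0 <- pole_sign * c(cos(th), sin(th))
  jit <- stats::rnorm(1, 0, 0.25)
  rot <- function(v, ang) c(cos(ang) * v[1] - sin(ang) * v[2],
                            sin(ang) * v[1] + cos(ang) * v[2])
  dir0 <- rot(dir0, jit)
  p0 <- seed$center + dir0 * (a * 0.92)
  len <- stats::runif(1, spec$radicle_length_range[1], spec$radicle_length_range[2])
  b1 <- stats::rnorm(1, 0, 0.5)
  b2 <- b1 + stats::rnorm(1, 0, 0.6)
  p1 <- p0 + rot(dir0, b1 * 0.5) * (len / 3)
  p2 <- p0 + rot(dir0, b2 * 0.7) * (2 * len / 3)
  p3 <- p0 + rot(dir0, b2) * len
  tt <- seq(0, 1, length.out = max(8L, ceiling(2 * len)))
  bez <- function(k) (1 - tt)^3 * p0[k] + 3 * (1 - tt)^2 * tt * p1[k] +
    3 * (1 - tt) * tt^2 * p2[k] + tt^3 * p3[k]
  cbind(x = bez(1), y = bez(2))
}

# --- rasterization ---------------------------------------------------------

# Pixels (0-based x,y) whose centers fall inside a rotated ellipse,
# clipped to the image; also returns the normalized squared radius.
ellipse_pixels <- function(cx, cy, a, b, theta, W, H) {
  r <- max(a, b)
  x0 <- max(0L, floor(cx - r - 1)); x1 <- min(W - 1L, ceiling(cx + r + 1))
  y0 <- max(0L, floor(cy - r - 1)); y1 <- min(H - 1L, ceiling(cy + r + 1))
  if (x1 < x0 || y1 < y0)
    return(list(px = cbind(x = integer(0), y = integer(0)), rho2 = numeric(0)))
  xs <- x0:x1; ys <- y0:y1
  X <- rep(xs, each = length(ys)) + 0.5
  Y <- rep(ys, times = length(xs)) + 0.5
  u <- cos(theta) * (X - cx) + sin(theta) * (Y - cy)
  v <- -sin(theta) * (X - cx) + cos(theta) * (Y - cy)
  rho2 <- (u / a)^2 + (v / b)^2
  keep <- rho2 <= 1
  list(px = cbind(x = as.integer(X[keep] - 0.5), y = as.integer(Y[keep] - 0.5)),
       rho2 = rho2[keep])
}

# Pixels within half the stroke width of a dense polyline, clipped.
stroke_pixels <- function(path, width, W, H) {
  hw <- width / 2
  x0 <- max(0L, floor(min(path[, 1]) - hw - 1))
  x1 <- min(W - 1L, ceiling(max(path[, 1]) + hw + 1))
  y0 <- max(0L, floor(min(path[, 2]) - hw - 1))
  y1 <- min(H - 1L, ceiling(max(path[, 2]) + hw + 1))
  if (x1 < x0 || y1 < y0) return(cbind(x = integer(0), y = integer(0)))
  xs <- x0:x1; ys <- y0:y1
  X <- rep(xs, each = length(ys)) + 0.5
  Y <- rep(ys, times = length(xs)) + 0.5
  # min squared distance of each pixel center to the polyline samples
  d2 <- rep(Inf, length(X))
  for (k in seq_len(nrow(path))) {
    dk <- (X - path[k, 1])^2 + (Y - path[k, 2])^2
    d2 <- pmin(d2, dk)
  }
  keep <- d2 <= hw^2
  cbind(x = as.integer(X[keep] - 0.5), y = as.integer(Y[keep] - 0.5))
}

# Rasterized footprint of one object of a disk truth. The seed footprint
# includes the coat protuberance nub when present, because the nub is part
# of the rendered seed.
object_pixels <- function(truth, i, which = c("seed", "radicle")) {
  which <- match.arg(which)
  spec <- truth$spec
  W <- spec$image_size; H <- spec$image_size
  s <- truth$seeds[[i]]
  if (which == "seed") {
    ep <- ellipse_pixels(s$center[1], s$center[2], s$semi_axes[1],
                         s$semi_axes[2], s$orientation, W, H)
    nub <- cbind(x = integer(0), y = integer(0))
    if (!is.null(s$protuberance)) {
      th <- s$orientation
      pc <- s$center + c(cos(th), sin(th)) * s$semi_axes[1] * cos(s$protuberance$angle) +
        c(-sin(th), cos(th)) * s$semi_axes[2] * sin(s$protuberance$angle)
      nub <- ellipse_pixels(pc[1], pc[2], s$protuberance$radius,
                            s$protuberance$radius, 0, W, H)$px
    }
    px <- ep$px
    if (nrow(nub)) {
      key <- function(m) m[, 1] * H + m[, 2]
      new <- !(key(nub) %in% key(px))
      px <- rbind(px, nub[new, , drop = FALSE])
    }
    list(px = px, ellipse = ep, nub = nub)
  } else {
    if (!isTRUE(s$germinated) || is.null(s$radicle_path))
      return(list(px = cbind(x = integer(0), y = integer(0))))
    list(px = stroke_pixels(s$radicle_path, s$radicle_width, W, H))
  }
}

# Tight half-open box around a set of pixels.
pixels_tight_box <- function(px) {
  c(xmin = min(px[, 1]), ymin = min(px[, 2]),
    xmax = max(px[, 1]) + 1, ymax = max(px[, 2]) + 1)
}

#' Per-object pixel mask of a rendered disk
#'
#' Returns the logical H x W mask of the pixels one object (a seed coat,
#' including any coat protuberance, or a radicle stroke) occupies in the
#' rendered image — the footprint whose tight bounding box is the object's
#' ground-truth box.
#'
#' @param truth an [sample_disk()] result.
#' @param i seed index.
#' @param which `"seed"` or `"radicle"`.
#' @return Logical matrix (rows = y, columns = x).
#' @export
object_mask <- function(truth, i, which = c("seed", "radicle")) {
  which <- match.arg(which)
  n <- truth$spec$image_size
  m <- matrix(FALSE, n, n)
  px <- object_pixels(truth, i, which)$px
  if (nrow(px)) m[cbind(px[, 2] + 1, px[, 1] + 1)] <- TRUE
  m
}

# bilinearly upsampled coarse Gaussian grid: cheap fiber-like texture
smooth_noise <- function(H, W, cell, sd) {
  gh <- ceiling(H / cell) + 2L
  gw <- ceiling(W / cell) + 2L
  g <- matrix(stats::rnorm(gh * gw, 0, sd), gh, gw)
  fy <- (seq_len(H) - 1) / cell; iy <- floor(fy); ty <- fy - iy
  fx <- (seq_len(W) - 1) / cell; ix <- floor(fx); tx <- fx - ix
  A <- g[iy + 1L, ix + 1L]; B <- g[iy + 1L, ix + 2L]
  C <- g[iy + 2L, ix + 1L]; D <- g[iy + 2L, ix + 2L]
  TY <- matrix(ty, H, W); TX <- matrix(tx, H, W, byrow = TRUE)
  (1 - TY) * (1 - TX) * A + (1 - TY) * TX * B + TY * (1 - TX) * C + TY * TX * D
}

#' Render a synthetic disk image
#'
#' Pure deterministic function of the truth: the same `rc_disk_truth`
#' always yields a pixel-identical image (texture noise is seeded from the
#' spec's `rng_seed`). The scene is a bright textured glass-fiber disk on a
#' neutral gray background; seeds are dark brownish textured ellipses;
#' radicles are thin near-white strokes alpha-blended with opacity
#' `radicle_contrast` (0 leaves the image exactly as if the radicles were
#' absent); coat protuberances are small opaque white nubs; debris blobs
#' are opaque gray. Output is quantized to 8-bit levels.
#'
#' @param truth an [sample_disk()] result.
#' @return H x W x 3 numeric array in `[0, 1]` (8-bit quantized), class
#'   `rc_image`.
#' @export
render_disk <- function(truth) {
  stopifnot(inherits(truth, "rc_disk_truth"))
  spec <- truth$spec
  n <- spec$image_size
  with_seed((spec$rng_seed * 48271 + 7919) %% 2147483647, {
    geom <- disk_geometry(spec)
    xs <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)
    ys <- matrix(seq_len(n) - 0.5, n, n)
    inside <- (xs - geom$cx)^2 + (ys - geom$cy)^2 <= geom$radius^2

    base <- matrix(0.42, n, n)
    disk_tex <- 0.84 + smooth_noise(n, n, cell = 12L, sd = 0.035) +
      matrix(stats::rnorm(n * n, 0, 0.012), n, n)
    base[inside] <- disk_tex[inside]
    R <- base * 1.00; G <- base * 0.995; B <- base * 0.965

    lin <- function(px) px[, 1] * n + px[, 2] + 1  # column-major index

    paint_opaque <- function(idx, r, g, b) {
      R[idx] <<- r; G[idx] <<- g; B[idx] <<- b
    }

    if (!is.null(truth$debris)) {
      for (k in seq_len(nrow(truth$debris))) {
        d <- truth$debris[k, ]
        px <- ellipse_pixels(d$x, d$y, d$a, d$b, d$theta, n, n)$px
        if (nrow(px)) {
          idx <- lin(px)
          v <- 0.55 + stats::rnorm(length(idx), 0, 0.03)
          paint_opaque(idx, v, v * 0.98, v * 0.93)
        }
      }
    }

    for (i in seq_len(truth$n_seeds)) {
      op <- object_pixels(truth, i, "seed")
      if (nrow(op$ellipse$px)) {
        idx <- lin(op$ellipse$px)
        v <- 0.20 + 0.10 * (1 - op$ellipse$rho2) +
          stats::rnorm(length(idx), 0, 0.02)
        v <- pmin(pmax(v, 0.05), 0.45)
        paint_opaque(idx, v * 1.25, v * 0.95, v * 0.75)
      }
      if (nrow(op$nub)) {
        idx <- lin(op$nub)
        v <- 0.93 + stats::rnorm(length(idx), 0, 0.01)
        paint_opaque(idx, v, v, v * 0.97)
      }
    }

    cc <- spec$radicle_contrast
    if (cc > 0) {
      for (i in seq_len(truth$n_seeds)) {
        s <- truth$seeds[[i]]
        if (!isTRUE(s$germinated)) next
        px <- object_pixels(truth, i, "radicle")$px
        if (!nrow(px)) next
        idx <- lin(px)
        R[idx] <- (1 - cc) * R[idx] + cc * 0.97
        G[idx] <- (1 - cc) * G[idx] + cc * 0.97
        B[idx] <- (1 - cc) * B[idx] + cc * 0.94
      }
    }

    img <- array(0, dim = c(n, n, 3))
    img[, , 1] <- R; img[, , 2] <- G; img[, , 3] <- B
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255
    class(img) <- c("rc_image", class(img))
    img
  })
}

#' Derive an annotation from simulator ground truth
#'
#' Applies one of the two labeling schemes to a disk truth. Under `S_R`
#' every seed contributes an `S` box (germinated or not) and every radicle
#' an `R` box. Under `NGS_GS` each seed contributes one box: its seed box
#' labeled `NGS` when non-germinated, or the minimal box containing seed
#' and radicle boxes labeled `GS` when germinated.
#'
#' @param truth an [sample_disk()] result.
#' @param scheme `"NGS_GS"` or `"S_R"`.
#' @param image_id identifier for the annotation (defaults to a name
#'   derived from the rng seed).
#' @return An [annotated_image()].
#' @export
truth_to_annotation <- function(truth, scheme = c("S_R", "NGS_GS"),
                                image_id = NULL) {
  scheme <- match.arg(scheme)
  spec <- truth$spec
  if (is.null(image_id)) image_id <- sprintf("disk_%06d", spec$rng_seed)
  rows <- list()
  for (s in truth$seeds) {
    sb <- s$seed_box
    if (scheme == "S_R") {
      rows[[length(rows) + 1L]] <- c(list(label = "S"), as.list(sb))
      if (isTRUE(s$germinated)) {
        rb <- s$radicle_box
        rows[[length(rows) + 1L]] <- c(list(label = "R"), as.list(rb))
      }
    } else {
      if (isTRUE(s$germinated)) {
        rb <- s$radicle_box
        un <- c(xmin = min(sb["xmin"], rb["xmin"]),
                ymin = min(sb["ymin"], rb["ymin"]),
                xmax = max(sb["xmax"], rb["xmax"]),
                ymax = max(sb["ymax"], rb["ymax"]))
        rows[[length(rows) + 1L]] <- c(list(label = "GS"), as.list(un))
      } else {
        rows[[length(rows) + 1L]] <- c(list(label = "NGS"), as.list(sb))
      }
    }
  }
  ob <- if (length(rows)) do.call(rbind.data.frame, rows) else empty_objects()
  names(ob) <- c("label", "xmin", "ymin", "xmax", "ymax")
  annotated_image(image_id, spec$image_size, spec$image_size, scheme, ob)
}

#' Generate a synthetic annotated dataset on disk
#'
#' Writes `n_images` rendered disks (PNG), their Pascal VOC annotations,
#' a `manifest.csv` assigning each image to the train/validation/test
#' splits in 60/20/20 proportions, and a `config.yaml` echoing the
#' resolved generation parameters. Image `i` uses an rng seed derived
#' deterministically from `spec$rng_seed`, so the whole dataset is
#' reproducible byte for byte.
#'
#' @param spec a [disk_spec()]; its `rng_seed` seeds the whole dataset.
#' @param n_images number of disks to generate.
#' @param scheme annotation scheme for the VOC files.
#' @param out_dir output directory (created if missing).
#' @return The manifest data.frame (columns `image_id`, `split`, `image`,
#'   `annotation`, `n_seeds`, `n_germinated`), invisibly; paths relative to
#'   `out_dir`.
#' @export
generate_dataset <- function(spec, n_images, scheme = c("S_R", "NGS_GS"),
                             out_dir) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "rc_disk_spec"), n_images >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "annotations"), recursive = TRUE, showWarnings = FALSE)
  n_train <- max(1L, round(0.6 * n_images))
  n_val <- max(if (n_images >= 3) 1L else 0L, round(0.2 * n_images))
  n_val <- min(n_val, n_images - n_train)
  splits <- c(rep("train", n_train), rep("val", n_val),
              rep("test", n_images - n_train - n_val))
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- (spec$rng_seed * 1000003 + i * 2654435) %% 2147483629 + 1
    sp_i <- spec; sp_i$rng_seed <- as.integer(si)
    truth <- sample_disk(sp_i)
    image_id <- sprintf("disk_%04d", i)
    ann <- truth_to_annotation(truth, scheme, image_id = image_id)
    img <- render_disk(truth)
    img_rel <- file.path("images", paste0(image_id, ".png"))
    ann_rel <- file.path("annotations", paste0(image_id, ".xml"))
    write_image(img, file.path(out_dir, img_rel))
    write_voc_xml(ann, file.path(out_dir, ann_rel))
    rows[[i]] <- data.frame(
      image_id = image_id, split = splits[i], image = img_rel,
      annotation = ann_rel, n_seeds = truth$n_seeds,
      n_germinated = sum(vapply(truth$seeds, function(s) isTRUE(s$germinated), TRUE)),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  cfg <- unclass(spec)
  cfg$n_seeds <- if (is.null(cfg$n_seeds)) "auto" else cfg$n_seeds
  yaml::write_yaml(c(list(scheme = scheme, n_images = n_images), cfg),
                   file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv` (and optionally
#'   `config.yaml`).
#' @return Manifest data.frame with an added `dir` attribute and, when the
#'   config is present, a `scheme` attribute.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv under ", dir)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(m, "dir") <- dir
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path))
    attr(m, "scheme") <- yaml::read_yaml(cfg_path)$scheme
  m
}

#' Write / read images
#'
#' PNG (always) and JPEG (read) support; images are H x W x 3 arrays in
#' `[0, 1]`. Grayscale files are expanded to three channels on read.
#'
#' @param img image array.
#' @param path file path (`.png` for writing).
#' @return `read_image` returns the array; `write_image` returns `path`
#'   invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = , jpeg = jpeg::readJPEG(path),
                stop("unsupported image format: ", path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @export
print.rc_disk_truth <- function(x, ...) {
  ng <- sum(vapply(x$seeds, function(s) isTRUE(s$germinated), TRUE))
  cat(sprintf("<rc_disk_truth> %d seeds (%d germinated, %.0f%%), %d x %d px\n",
              x$n_seeds, ng, 100 * ng / x$n_seeds,
              x$spec$image_size, x$spec$image_size))
  invisible(x)
}
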