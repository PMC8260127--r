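# Training-dependent tests share one tiny dataset and one short training
# run, built once per test file.
tiny_dataset <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      d <- file.path(tempdir(), "rc_tiny_ds")
      unlink(d, recursive = TRUE)
      spec <- disk_spec(image_size = 256, n_seeds = 14, rng_seed = 301,
                        overlap_intensity = 0.1, radicle_contrast = 0.8)
      m <- generate_dataset(spec, 3, "S_R", d)
      m$split <- c("train", "val", "test")
      utils::write.csv(m, file.path(d, "manifest.csv"), row.names = FALSE)
      dir <<- d
    }
    dir
  }
})

test_that("loss components vanish on perfect predictions and stay separable", {
  n <- 6
  rpn <- list(obj_logits = c(rep(1e6, 2), rep(-1e6, 4)),
              deltas = matrix(0, n, 4))
  head <- list(class_logits = rbind(c(-1e6, 1e6, -1e6),
                                    c(-1e6, -1e6, 1e6),
                                    c(1e6, -1e6, -1e6)),
               deltas = matrix(0, 3, 4))
  targets <- list(rpn_labels = c(1, 1, 0, 0, 0, 0),
                  rpn_deltas = matrix(0, n, 4),
                  head_classes = c(1L, 2L, 0L),
                  head_deltas = matrix(0, 3, 4))
  ls <- detector_losses(rpn, head, targets)
  expect_equal(ls$rpn_cls, 0)
  expect_equal(ls$rpn_reg, 0)
  expect_equal(ls$head_cls, 0)
  expect_equal(ls$head_reg, 0)
  expect_equal(ls$total, 0)

  # all components are non-negative on arbitrary outputs
  set.seed(4)
  rpn2 <- list(obj_logits = rnorm(n), deltas = matrix(rnorm(n * 4), n))
  head2 <- list(class_logits = matrix(rnorm(9), 3), deltas = matrix(rnorm(12), 3))
  ls2 <- detector_losses(rpn2, head2, targets)
  expect_true(all(unlist(ls2[c("rpn_cls", "rpn_reg", "head_cls", "head_reg")]) >= 0))

  # head class scores normalize to probabilities summing to 1
  rcns <- asNamespace("radicount")
  p <- rcns$softmax_rows(head2$class_logits)
  expect_equal(rowSums(p), rep(1, 3))
})

test_that("regression losses are zero without positives and quadratic near zero", {
  n <- 5
  mk <- function(err) {
    rpn <- list(obj_logits = rep(0, n), deltas = matrix(err, n, 4))
    targets <- list(rpn_labels = c(1, rep(0, n - 1)),
                    rpn_deltas = matrix(0, n, 4))
    detector_losses(rpn, NULL, targets)
  }
  # no positive anchors: regression exactly zero regardless of deltas
  rpn <- list(obj_logits = rep(0, n), deltas = matrix(99, n, 4))
  ls <- detector_losses(rpn, NULL,
                        list(rpn_labels = rep(0, n),
                             rpn_deltas = matrix(0, n, 4)))
  expect_identical(ls$rpn_reg, 0)

  # smooth L1 is 0.5 x^2 inside |x| < 1: doubling the error quadruples it
  l1 <- mk(0.1)$rpn_reg
  l2 <- mk(0.2)$rpn_reg
  expect_equal(l2 / l1, 4, tolerance = 1e-12)
})

test_that("anchors in the ignore band contribute no loss and no gradient", {
  cfg <- detector_config("S_R")
  anchors <- rbind(c(0, 0, 10, 10),    # IoU 0.5 with gt: ignore band
                   c(0, 0, 10, 5),     # identical to gt: positive
                   c(50, 50, 60, 60))  # disjoint: negative
  gt <- matrix(c(0, 0, 10, 5), 1)
  asg <- assign_anchor_labels(anchors, gt, cfg)
  expect_equal(asg$status, c("ignore", "positive", "negative"))
  sampled <- which(asg$status != "ignore")
  base <- list(obj_logits = c(5, 3, -2), deltas = matrix(0, 3, 4))
  targets <- list(rpn_labels = as.numeric(asg$status[sampled] == "positive"),
                  rpn_deltas = matrix(0, 2, 4))
  with_ign <- base
  with_ign$obj_logits[1] <- -7  # perturb only the ignored anchor
  l0 <- detector_losses(list(obj_logits = base$obj_logits[sampled],
                             deltas = base$deltas[sampled, ]), NULL, targets)
  l1 <- detector_losses(list(obj_logits = with_ign$obj_logits[sampled],
                             deltas = with_ign$deltas[sampled, ]), NULL, targets)
  expect_identical(l0, l1)
})

test_that("nms keeps the confident box, is idempotent, and matches the oracle", {
  one <- make_detections(matrix(c(0, 0, 10, 10), 1), "S", 0.7)
  expect_identical(nms(one, 0.5), one)

  two <- make_detections(rbind(c(0, 0, 10, 10), c(0, 0, 10, 10)),
                         c("S", "S"), c(0.9, 0.8))
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, 0.9)

  # different classes never suppress each other
  mixed <- make_detections(rbind(c(0, 0, 10, 10), c(0, 0, 10, 10)),
                           c("S", "R"), c(0.9, 0.8))
  expect_equal(nrow(nms(mixed, 0.5)), 2L)

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:10, 1)
    det <- make_detections(random_boxes(n, lim = 40), rep("S", n), runif(n))
    out <- nms(det, 0.5)
    oracle_keep <- nms_oracle(box_matrix(det), det$confidence, 0.5)
    expect_setequal(out$confidence, det$confidence[oracle_keep])
    expect_identical(nms(out, 0.5), out)
    expect_false(is.unsorted(rev(out$confidence)))
  }
})

test_that("flip-symmetric weights give flip-equivariant feature maps", {
  rcns <- asNamespace("radicount")
  det_cfg <- detector_config("S_R")
  set.seed(6)
  params <- rcns$init_detector_params(det_cfg)
  # make every convolution kernel constant within its channel slice: such
  # kernels are invariant under spatial mirroring, so the feature map of a
  # flipped image must equal the flipped feature map, making the flipped
  # (image, boxes) pairs used by augmentation exactly loss-equivalent
  for (nm in grep("^conv", names(params), value = TRUE)) {
    if (grepl("\\.W$", nm)) {
      d <- dim(params[[nm]])
      mean_k <- apply(params[[nm]], c(3, 4), mean)
      params[[nm]] <- array(rep(mean_k, each = d[1] * d[2]), dim = d)
    }
  }
  # 65 px: the stride-4 sampling grid is mirror-symmetric at sizes 4m + 1,
  # so equivariance is exact rather than approximate
  img <- array(runif(65 * 65 * 3), c(65, 65, 3))
  bb <- backbone_def("tiny")
  f_orig <- rcns$backbone_forward(params, bb, img)$feat
  f_flip <- rcns$backbone_forward(params, bb,
                                  rcns$flip_image(img, "horizontal"))$feat
  expect_equal(f_flip, f_orig[, dim(f_orig)[2]:1, , drop = FALSE],
               tolerance = 1e-10)
})

test_that("a short training run overfits one image and is reproducible", {
  man <- read_manifest(tiny_dataset())
  det_cfg <- detector_config("S_R")
  tcfg <- train_config(iterations = 300, batch_size = 1,
                       learning_rate = 1e-3, rng_seed = 7,
                       validation_interval = 300, flip_augmentation = FALSE)
  model <- train_detector(man, det_cfg, tcfg, quiet = TRUE)
  log <- model$log
  init <- mean(log$total[1:5])
  final <- mean(log$total[(nrow(log) - 4):nrow(log)])
  expect_lt(final, 0.2 * init)

  # determinism: identical seeds give identical loss sequences
  t2 <- train_config(iterations = 8, batch_size = 1, learning_rate = 1e-3,
                     rng_seed = 11, validation_interval = 8)
  m1 <- train_detector(man, det_cfg, t2, quiet = TRUE)
  m2 <- train_detector(man, det_cfg, t2, quiet = TRUE)
  expect_identical(m1$log$total, m2$log$total)

  # prediction contracts on the training image (easy by construction)
  img <- read_image(file.path(tiny_dataset(),
                              man$image[man$split == "train"][1]))
  d_lo <- predict_image(model, img, score_threshold = 0.5)
  d_hi <- predict_image(model, img, score_threshold = 0.8)
  expect_lte(nrow(d_hi), nrow(d_lo))
  expect_equal(nrow(predict_image(model, img, score_threshold = 1.0)), 0L)
  if (nrow(d_lo)) {
    expect_true(all(d_lo$label %in% c("S", "R")))
    expect_true(all(d_lo$confidence >= 0.5 & d_lo$confidence <= 1))
    expect_false(is.unsorted(rev(d_lo$confidence)))
  }

  # checkpoint round trip preserves behavior
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, ck)
  back <- load_checkpoint(ck)
  expect_identical(predict_image(back, img, 0.5), d_lo)
})

test_that("training rejects empty splits and mismatched schemes", {
  man <- read_manifest(tiny_dataset())
  det_cfg <- detector_config("NGS_GS")
  expect_error(train_detector(man, det_cfg, train_config(iterations = 1)),
               "scheme")
  man2 <- read_manifest(tiny_dataset())
  man2$split[man2$split == "val"] <- "test"
  attr(man2, "dir") <- tiny_dataset()
  expect_error(train_detector(man2, detector_config("S_R"),
                              train_config(iterations = 1)),
               "val split")
})

test_that("reserved heavy backbones are refused with guidance", {
  expect_error(backbone_def("R-50-C4"), "reserved")
  expect_error(backbone_def("nonesuch"), "unknown")
  bb <- backbone_def("tiny")
  expect_equal(bb$stride, 8L)
})
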