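easy_spec <- function(rng_seed = 5, ...) {
  disk_spec(image_size = 192, n_seeds = 12, rng_seed = rng_seed,
            overlap_intensity = 0.1, ...)
}

test_that("sampling is deterministic and honors exact germination counts", {
  spec <- disk_spec(image_size = 320, n_seeds = 60,
                    germination_fraction = 0.5, exact_germination = TRUE,
                    rng_seed = 9)
  t1 <- sample_disk(spec)
  t2 <- sample_disk(spec)
  expect_identical(t1, t2)
  expect_equal(t1$n_seeds, 60L)
  germ <- vapply(t1$seeds, function(s) isTRUE(s$germinated), TRUE)
  expect_equal(sum(germ), 30L)
  # radicle pairing: radicle boxes present iff germinated
  has_rad <- vapply(t1$seeds, function(s) !is.null(s$radicle_box), TRUE)
  expect_identical(has_rad, germ)

  none <- sample_disk(easy_spec(germination_fraction = 0))
  expect_false(any(vapply(none$seeds, function(s) isTRUE(s$germinated), TRUE)))
})

test_that("annotation schemes derive the right boxes from one truth", {
  spec <- disk_spec(image_size = 320, n_seeds = 60,
                    germination_fraction = 0.5, exact_germination = TRUE,
                    rng_seed = 9)
  truth <- sample_disk(spec)
  sr <- truth_to_annotation(truth, "S_R")
  expect_equal(sum(sr$objects$label == "S"), 60L)
  expect_equal(sum(sr$objects$label == "R"), 30L)
  ng <- truth_to_annotation(truth, "NGS_GS")
  expect_equal(nrow(ng$objects), 60L)
  expect_equal(sum(ng$objects$label == "NGS"), 30L)
  expect_equal(sum(ng$objects$label == "GS"), 30L)
  expect_identical(validate_annotation(sr), character(0))
  expect_identical(validate_annotation(ng), character(0))

  # every GS box contains its seed's S box
  gs <- ng$objects[ng$objects$label == "GS", ]
  germ_idx <- which(vapply(truth$seeds, function(s) isTRUE(s$germinated), TRUE))
  for (k in seq_along(germ_idx)) {
    sb <- truth$seeds[[germ_idx[k]]]$seed_box
    expect_true(gs$xmin[k] <= sb["xmin"] && gs$ymin[k] <= sb["ymin"] &&
                gs$xmax[k] >= sb["xmax"] && gs$ymax[k] >= sb["ymax"])
  }
})

test_that("ground-truth boxes are tight around rendered object masks", {
  for (seed in c(21, 22)) {
    truth <- sample_disk(easy_spec(rng_seed = seed,
                                   protuberance_probability = 0.5))
    for (i in seq_len(truth$n_seeds)) {
      for (wh in c("seed", "radicle")) {
        if (wh == "radicle" && !isTRUE(truth$seeds[[i]]$germinated)) next
        m <- object_mask(truth, i, wh)
        px <- which(m, arr.ind = TRUE)
        tight <- c(min(px[, 2]) - 1, min(px[, 1]) - 1, max(px[, 2]), max(px[, 1]))
        box <- if (wh == "seed") truth$seeds[[i]]$seed_box
               else truth$seeds[[i]]$radicle_box
        expect_equal(iou(unname(box), tight), 1.0)
      }
    }
  }
})

test_that("rendering is pure, 8-bit, and radicle contrast scales to zero", {
  truth <- sample_disk(easy_spec(rng_seed = 31, germination_fraction = 0.8))
  img <- render_disk(truth)
  expect_identical(img, render_disk(truth))
  expect_true(all(img >= 0 & img <= 1))
  expect_true(all(abs(img * 255 - round(img * 255)) < 1e-9))

  # seeds are darker than the disk background around them
  s <- truth$seeds[[1]]
  sb <- s$seed_box
  seed_px <- img[(sb["ymin"] + 1):sb["ymax"], (sb["xmin"] + 1):sb["xmax"], 1]
  ctr <- truth$spec$image_size / 2
  bg_px <- img[(ctr - 4):(ctr + 4), (ctr - 4):(ctr + 4), 1]
  # center window may contain a seed; compare against a known-disk ring mean
  expect_lt(mean(seed_px), mean(img[, , 1][img[, , 1] > 0.6]))

  # radicle_contrast 0 renders exactly as if no seed had germinated
  t0 <- truth
  t0$spec$radicle_contrast <- 0
  img0 <- render_disk(t0)
  bare <- truth
  for (i in seq_along(bare$seeds)) {
    bare$seeds[[i]]$germinated <- FALSE
    bare$seeds[[i]]$radicle_path <- NULL
    bare$seeds[[i]]$radicle_box <- NULL
    bare$seeds[[i]]$radicle_width <- NULL
  }
  bare$spec$radicle_contrast <- 0
  expect_identical(img0, render_disk(bare))
})

test_that("pooled germination fraction tracks the configured probability", {
  # modest-n version of the statistical contract (the full 200-disk pooled
  # check runs with the acceptance suite)
  tot <- 0L; germ <- 0L
  for (k in 1:40) {
    tr <- sample_disk(disk_spec(image_size = 160, n_seeds = 10,
                                germination_fraction = 0.55,
                                rng_seed = 1000 + k))
    tot <- tot + tr$n_seeds
    germ <- germ + sum(vapply(tr$seeds, function(s) isTRUE(s$germinated), TRUE))
  }
  p <- 0.55
  se <- sqrt(p * (1 - p) / tot)
  expect_lt(abs(germ / tot - p), 3 * se)
})

test_that("infeasible packings fail with a diagnostic", {
  spec <- disk_spec(image_size = 96, n_seeds = 200, overlap_intensity = 0,
                    rng_seed = 1)
  expect_error(sample_disk(spec), "infeasible packing")
})

test_that("generate_dataset writes a reproducible 60/20/20 dataset", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- easy_spec(rng_seed = 77)
  m1 <- generate_dataset(spec, 10, "S_R", dir1)
  m2 <- generate_dataset(spec, 10, "S_R", dir2)
  expect_equal(as.vector(table(m1$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L))
  expect_identical(m1, m2)
  expect_identical(readBin(file.path(dir1, m1$image[1]), "raw", 1e6),
                   readBin(file.path(dir2, m2$image[1]), "raw", 1e6))
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  # every annotation on disk validates
  for (f in m1$annotation) {
    ann <- read_voc_xml(file.path(dir1, f), "S_R")
    expect_identical(validate_annotation(ann), character(0))
  }
  man <- read_manifest(dir1)
  expect_equal(attr(man, "scheme"), "S_R")
  expect_equal(nrow(man), 10L)
})

test_that("image write/read round trip preserves 8-bit pixel data", {
  truth <- sample_disk(easy_spec(rng_seed = 41))
  img <- render_disk(truth)
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path)
  expect_equal(dim(back), dim(img))
  expect_true(max(abs(back - unclass(img))) < 1e-9)
})
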