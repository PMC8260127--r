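make_ann <- function(n = 3, scheme = "S_R") {
  set.seed(n)
  labs <- sample(scheme_labels(scheme), n, replace = TRUE)
  x <- sample(0:80, n); y <- sample(0:80, n)
  annotated_image("fixture", 120, 100, scheme,
                  data.frame(label = labs, xmin = x, ymin = y,
                             xmax = x + sample(3:20, n),
                             ymax = y + sample(3:18, n)))
}

test_that("VOC write/read round trip is the identity", {
  path <- withr::local_tempfile(fileext = ".xml")
  ann <- make_ann(3)
  write_voc_xml(ann, path)
  back <- read_voc_xml(path, expected_scheme = "S_R")
  expect_equal(back$objects, ann$objects)
  expect_equal(back$width, ann$width)
  expect_equal(back$scheme, ann$scheme)
  expect_equal(back$image_id, ann$image_id)

  # empty object list: valid XML with zero <object> entries
  empty <- annotated_image("none", 50, 50, "NGS_GS")
  write_voc_xml(empty, path)
  expect_length(xml2::xml_find_all(xml2::read_xml(path), "//object"), 0L)
  expect_equal(nrow(read_voc_xml(path, "NGS_GS")$objects), 0L)
})

test_that("coordinates convert between 1-based inclusive and half-open", {
  # a VOC bndbox (1,1,10,10) covers 10x10 pixels -> internal (0,0,10,10)
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><filename>x.png</filename>",
    "<size><width>20</width><height>20</height><depth>3</depth></size>",
    "<object><name>S</name><bndbox>",
    "<xmin>1</xmin><ymin>1</ymin><xmax>10</xmax><ymax>10</ymax>",
    "</bndbox></object></annotation>"), path)
  ann <- read_voc_xml(path, "S_R")
  expect_equal(unlist(ann$objects[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 0, ymin = 0, xmax = 10, ymax = 10))

  # inverse: internal (0,0,10,10) serializes as VOC (1,1,10,10)
  out <- withr::local_tempfile(fileext = ".xml")
  write_voc_xml(annotated_image("x", 20, 20, "S_R",
                                data.frame(label = "S", xmin = 0, ymin = 0,
                                           xmax = 10, ymax = 10)), out)
  doc <- xml2::read_xml(out)
  get1 <- function(xp) xml2::xml_text(xml2::xml_find_first(doc, xp))
  expect_equal(get1("//bndbox/xmin"), "1")
  expect_equal(get1("//bndbox/ymin"), "1")
  expect_equal(get1("//bndbox/xmax"), "10")
  expect_equal(get1("//bndbox/ymax"), "10")
})

test_that("reading rejects foreign labels, degenerate boxes and bad XML", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><filename>x.png</filename>",
    "<size><width>20</width><height>20</height></size>",
    "<object><name>weed</name><bndbox>",
    "<xmin>1</xmin><ymin>1</ymin><xmax>5</xmax><ymax>5</ymax>",
    "</bndbox></object></annotation>"), path)
  expect_error(read_voc_xml(path, "S_R"), "weed")

  writeLines(c(
    "<annotation><filename>x.png</filename>",
    "<size><width>20</width><height>20</height></size>",
    "<object><name>S</name><bndbox>",
    "<xmin>7</xmin><ymin>1</ymin><xmax>6</xmax><ymax>5</ymax>",
    "</bndbox></object></annotation>"), path)
  expect_error(read_voc_xml(path, "S_R"), "degenerate")

  writeLines("<annotation><unclosed>", path)
  expect_error(read_voc_xml(path))
  expect_error(read_voc_xml(file.path(tempdir(), "no_such.xml")), "no such")
})

test_that("validate_annotation reports each violated rule with its object", {
  good <- make_ann(4)
  expect_identical(validate_annotation(good), character(0))

  bad <- good
  bad$objects$xmax[2] <- 500  # past image width
  v <- validate_annotation(bad)
  expect_length(v, 1L)
  expect_match(v, "object 2.*bounds")

  mixed <- good
  mixed$objects$label[3] <- "GS"   # NGS_GS label inside an S_R annotation
  v <- validate_annotation(mixed)
  expect_length(v, 1L)
  expect_match(v, "object 3.*scheme")

  expect_error(write_voc_xml(bad, tempfile()), "refusing")
})
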