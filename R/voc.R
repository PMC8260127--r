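#' Annotation schemes
#'
#' Two labeling schemes are supported for germination bioassay disks:
#' \describe{
#'   \item{`NGS_GS`}{one box per seed: `NGS` (non-germinated seed, seed coat
#'     alone) or `GS` (germinated seed, seed coat together with its radicle).}
#'   \item{`S_R`}{every seed coat is boxed `S` and every radicle is boxed
#'     `R` independently, so a germinated seed contributes two boxes.}
#' }
#' Labels are case-sensitive.
#'
#' @param scheme `"NGS_GS"` or `"S_R"`.
#' @return Character vector of valid labels, in canonical order.
#' @export
scheme_labels <- function(scheme) {
  switch(match.arg(scheme, c("NGS_GS", "S_R")),
         NGS_GS = c("NGS", "GS"),
         S_R    = c("S", "R"))
}

#' Construct an annotated image
#'
#' One disk image plus its ground-truth boxes under a declared annotation
#' scheme. Boxes use the package's 0-based half-open pixel convention.
#'
#' @param image_id image identifier (filename stem).
#' @param width,height image size in pixels.
#' @param scheme annotation scheme, `"NGS_GS"` or `"S_R"`.
#' @param objects data.frame with columns `label`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (zero rows allowed).
#' @param validate if `TRUE` (default), refuse construction when
#'   [validate_annotation()] reports violations.
#' @return An object of class `rc_annotation`.
#' @export
annotated_image <- function(image_id, width, height, scheme,
                            objects = empty_objects(), validate = TRUE) {
  scheme <- match.arg(scheme, c("NGS_GS", "S_R"))
  objects <- as.data.frame(objects)
  if (nrow(objects) == 0L) objects <- empty_objects()
  stopifnot(all(c("label", "xmin", "ymin", "xmax", "ymax") %in% names(objects)))
  objects <- objects[, c("label", "xmin", "ymin", "xmax", "ymax")]
  objects$label <- as.character(objects$label)
  for (cc in c("xmin", "ymin", "xmax", "ymax"))
    objects[[cc]] <- as.numeric(objects[[cc]])
  rownames(objects) <- NULL
  ann <- structure(
    list(image_id = as.character(image_id), width = as.integer(width),
         height = as.integer(height), scheme = scheme, objects = objects),
    class = "rc_annotation")
  if (validate) {
    v <- validate_annotation(ann)
    if (length(v)) stop("invalid annotation:\n  ", paste(v, collapse = "\n  "))
  }
  ann
}

empty_objects <- function() {
  data.frame(label = character(0), xmin = numeric(0), ymin = numeric(0),
             xmax = numeric(0), ymax = numeric(0), stringsAsFactors = FALSE)
}

#' Validate an annotated image
#'
#' Total function: returns a character vector of human-readable violation
#' descriptions (empty when the annotation satisfies all invariants). Each
#' violation names the offending object index and the rule broken.
#'
#' @param ann an `rc_annotation`.
#' @return Character vector of violations, `character(0)` if conforming.
#' @export
validate_annotation <- function(ann) {
  out <- character(0)
  if (!inherits(ann, "rc_annotation")) return("not an rc_annotation object")
  if (!ann$scheme %in% c("NGS_GS", "S_R"))
    out <- c(out, sprintf("unknown scheme '%s'", ann$scheme))
  if (is.na(ann$width) || is.na(ann$height) || ann$width <= 0 || ann$height <= 0)
    out <- c(out, "image size must be positive")
  ok_labels <- tryCatch(scheme_labels(ann$scheme), error = function(e) character(0))
  ob <- ann$objects
  for (i in seq_len(nrow(ob))) {
    if (!ob$label[i] %in% ok_labels)
      out <- c(out, sprintf("object %d: label '%s' not in scheme %s {%s}",
                            i, ob$label[i], ann$scheme, paste(ok_labels, collapse = ", ")))
    if (ob$xmax[i] <= ob$xmin[i] || ob$ymax[i] <= ob$ymin[i])
      out <- c(out, sprintf("object %d: degenerate box (non-positive area)", i))
    if (ob$xmin[i] < 0 || ob$ymin[i] < 0)
      out <- c(out, sprintf("object %d: negative coordinates", i))
    if (ob$xmax[i] > ann$width || ob$ymax[i] > ann$height)
      out <- c(out, sprintf("object %d: box extends past image bounds (%d x %d)",
                            i, ann$width, ann$height))
  }
  out
}

#' Read a Pascal VOC XML annotation file
#'
#' Parses one `<annotation>` document (filename, size, and `<object>`
#' entries with `<name>` and `<bndbox>`). VOC stores boxes 1-based and
#' inclusive; coordinates are converted to the internal 0-based half-open
#' convention, an exact integer bijection: internal `xmin = voc_xmin - 1`,
#' internal `xmax = voc_xmax`, so a VOC box (1,1,10,10) becomes (0,0,10,10)
#' with width 10 in both dialects.
#'
#' @param path XML file path.
#' @param expected_scheme `"NGS_GS"`, `"S_R"`, or `NULL` to infer from the
#'   labels present (empty files default to `S_R`).
#' @return An [annotated_image()] object.
#' @export
read_voc_xml <- function(path, expected_scheme = NULL) {
  if (!file.exists(path)) stop("no such annotation file: ", path)
  doc <- xml2::read_xml(path)  # malformed XML raises here
  if (xml2::xml_name(doc) != "annotation")
    stop("not a VOC annotation file (root element is <",
         xml2::xml_name(doc), ">): ", path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  w <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  h <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  if (is.na(w) || is.na(h)) stop("missing or non-numeric <size> in ", path)
  objs <- xml2::xml_find_all(doc, "./object")
  get1 <- function(node, xp) xml2::xml_text(xml2::xml_find_first(node, xp))
  labels <- vapply(objs, get1, "", "./name")
  num <- function(xp) vapply(objs, function(o) as.numeric(get1(o, xp)), 0)
  if (length(objs)) {
    ob <- data.frame(label = labels,
                     xmin = num("./bndbox/xmin") - 1,
                     ymin = num("./bndbox/ymin") - 1,
                     xmax = num("./bndbox/xmax"),
                     ymax = num("./bndbox/ymax"),
                     stringsAsFactors = FALSE)
  } else ob <- empty_objects()

  scheme <- expected_scheme
  if (is.null(scheme)) {
    scheme <- if (any(labels %in% c("NGS", "GS"))) "NGS_GS" else "S_R"
  }
  bad <- setdiff(unique(ob$label), scheme_labels(scheme))
  if (length(bad))
    stop(sprintf("label(s) %s not valid for scheme %s in %s",
                 paste(sQuote(bad), collapse = ", "), scheme, path))
  deg <- which(ob$xmax <= ob$xmin | ob$ymax <= ob$ymin)
  if (length(deg))
    stop(sprintf("degenerate box for object(s) %s in %s",
                 paste(deg, collapse = ", "), path))
  image_id <- if (is.na(fname) || !nzchar(fname)) {
    tools::file_path_sans_ext(basename(path))
  } else tools::file_path_sans_ext(fname)
  annotated_image(image_id, w, h, scheme, ob)
}

#' Write a Pascal VOC XML annotation file
#'
#' Inverse of [read_voc_xml()]: internal 0-based half-open boxes are
#' serialized 1-based inclusive, and `read_voc_xml(write_voc_xml(ann))`
#' reproduces `ann` exactly. The conventional VOC fields `pose`,
#' `truncated` and `difficult` are written with neutral defaults
#' (`Unspecified`, 0, 0) and ignored on read.
#'
#' @param ann an [annotated_image()] object satisfying its invariants.
#' @param path output file path.
#' @param image_ext extension recorded in the `<filename>` field.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(ann, path, image_ext = "png") {
  v <- validate_annotation(ann)
  if (length(v)) stop("refusing to write invalid annotation:\n  ",
                      paste(v, collapse = "\n  "))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(ann$image_id, ".", image_ext))
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(ann$width))
  xml2::xml_add_child(sz, "height", as.character(ann$height))
  xml2::xml_add_child(sz, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  ob <- ann$objects
  for (i in seq_len(nrow(ob))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", ob$label[i])
    xml2::xml_add_child(o, "pose", "Unspecified")
    xml2::xml_add_child(o, "truncated", "0")
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(ob$xmin[i] + 1, scientific = FALSE))
    xml2::xml_add_child(bb, "ymin", format(ob$ymin[i] + 1, scientific = FALSE))
    xml2::xml_add_child(bb, "xmax", format(ob$xmax[i], scientific = FALSE))
    xml2::xml_add_child(bb, "ymax", format(ob$ymax[i], scientific = FALSE))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @export
print.rc_annotation <- function(x, ...) {
  cat(sprintf("<rc_annotation> %s  %d x %d px, scheme %s\n",
              x$image_id, x$width, x$height, x$scheme))
  tab <- table(factor(x$objects$label, levels = scheme_labels(x$scheme)))
  cat("  objects:", nrow(x$objects),
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
  invisible(x)
}
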