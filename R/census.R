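#' Count detections per class
#'
#' @param detections detection data.frame (or annotation `objects`) with a
#'   `label` column; every label must belong to the scheme.
#' @param scheme `"NGS_GS"` or `"S_R"`.
#' @return Named integer vector of class `rc_class_counts`, one entry per
#'   scheme label (zeros included), with the scheme as an attribute.
#' @examples
#' count_detections(data.frame(label = c("S", "S", "R")), "S_R") # S=2 R=1
#' @export
count_detections <- function(detections, scheme = c("S_R", "NGS_GS")) {
  scheme <- match.arg(scheme)
  labels <- scheme_labels(scheme)
  det_labels <- if (NROW(detections)) as.character(detections$label) else character(0)
  foreign <- setdiff(unique(det_labels), labels)
  if (length(foreign))
    stop("label(s) ", paste(sQuote(foreign), collapse = ", "),
         " do not belong to scheme ", scheme)
  counts <- table(factor(det_labels, levels = labels))
  structure(stats::setNames(as.integer(counts), labels),
            scheme = scheme, class = "rc_class_counts")
}

#' @export
print.rc_class_counts <- function(x, ...) {
  cat(sprintf("<class counts, scheme %s>  %s\n", attr(x, "scheme"),
              paste(names(x), unclass(x), sep = "=", collapse = "  ")))
  invisible(x)
}

#' Germination rate from class counts
#'
#' Converts per-class object counts into the biological readout, the
#' fraction of seeds on the disk that germinated. Under the `S_R` scheme
#' every seed retains a visible coat (counted as `S`) and every germinated
#' seed additionally shows a radicle (`R`), so the rate is `R / S`, capped
#' at 1; it is undefined when no seed was counted. Under `NGS_GS` the rate
#' is `GS / (GS + NGS)`, undefined when both counts are zero. Undefined
#' rates are returned as `NA` (a flagged value, not an error).
#'
#' @param counts an [count_detections()] result.
#' @return Fraction in `[0, 1]`, or `NA_real_` when undefined.
#' @export
germination_rate <- function(counts) {
  scheme <- attr(counts, "scheme")
  if (is.null(scheme)) stop("counts must come from count_detections()")
  if (scheme == "S_R") {
    if (counts[["S"]] == 0) return(NA_real_)
    min(1, counts[["R"]] / counts[["S"]])
  } else {
    tot <- counts[["GS"]] + counts[["NGS"]]
    if (tot == 0) return(NA_real_)
    counts[["GS"]] / tot
  }
}

#' Batch census of disk images
#'
#' Runs the detector over a set of images and reports, per image, the
#' per-class object counts and the germination rate. A failure on one
#' image (unreadable file, wrong format) is recorded in that image's
#' `error_message` field and does not abort the batch.
#'
#' @param image_paths character vector of image files (PNG/JPEG).
#' @param model an `rc_detector`.
#' @param score_threshold confidence cutoff (default: model's configured).
#' @param quiet suppress per-image progress messages.
#' @return data.frame with `image_name`, one `count_<label>` column per
#'   scheme class, `germination_rate` (fraction, `NA` when undefined or
#'   errored) and `error_message` (empty string when the image processed
#'   cleanly). Row order follows `image_paths`.
#' @export
census_batch <- function(image_paths, model, score_threshold = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(model, "rc_detector"))
  scheme <- model$det_cfg$scheme
  labels <- scheme_labels(scheme)
  rows <- vector("list", length(image_paths))
  for (i in seq_along(image_paths)) {
    path <- image_paths[i]
    res <- tryCatch({
      det <- predict_image(model, path, score_threshold = score_threshold)
      counts <- count_detections(det, scheme)
      list(counts = as.integer(counts), rate = germination_rate(counts),
           err = "")
    }, error = function(e) {
      list(counts = rep(NA_integer_, length(labels)), rate = NA_real_,
           err = conditionMessage(e))
    })
    if (!quiet)
      message(sprintf("%s: %s%s", basename(path),
                      if (nzchar(res$err)) "ERROR " else "",
                      if (nzchar(res$err)) res$err else
                        paste(labels, res$counts, sep = "=", collapse = " ")))
    row <- data.frame(image_name = basename(path), stringsAsFactors = FALSE)
    for (k in seq_along(labels)) row[[paste0("count_", labels[k])]] <- res$counts[k]
    row$germination_rate <- res$rate
    row$error_message <- res$err
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(image_name = character(0))
  attr(out, "scheme") <- scheme
  out
}

#' Write a census report as CSV
#'
#' One row per image: the image name, the per-class counts, the
#' germination rate as a percentage with two decimals (empty when
#' undefined) and any error message. The file reads back losslessly with
#' standard CSV readers.
#'
#' @param records a [census_batch()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(records, path) {
  df <- records
  df$germination_rate_percent <- ifelse(
    is.na(df$germination_rate), "",
    sprintf("%.2f", 100 * df$germination_rate))
  df$germination_rate <- NULL
  count_cols <- grep("^count_", names(df), value = TRUE)
  df <- df[, c("image_name", count_cols, "germination_rate_percent",
               "error_message")]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_census_csv
#' @export
read_census_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_name = "character"))
  pct <- suppressWarnings(as.numeric(df$germination_rate_percent))
  df$germination_rate <- pct / 100
  df$germination_rate_percent <- NULL
  df$error_message[is.na(df$error_message)] <- ""
  df
}
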