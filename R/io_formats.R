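#' Blood cell label schema
#'
#' The fixed 10-class label schema used throughout the pipeline. Class ids
#' are contiguous from 0 and classes are ordered alphabetically, so that
#' basophil = 0, eosinophil = 1, ..., rbc = 9.
#'
#' @return Character vector of 10 class names; ids are \code{seq_along - 1}.
#' @examples
#' label_schema()          # 10 names
#' match("rbc", label_schema()) - 1L  # id 9
#' @export
label_schema <- function() {
  c("basophil", "eosinophil", "erythroblast", "intrusion", "lymphocyte",
    "monocyte", "myelocyte", "neutrophil", "platelet", "rbc")
}

#' @rdname label_schema
#' @param name class name
#' @export
class_id <- function(name) {
  i <- match(name, label_schema())
  if (anyNA(i)) stop("unknown class name: ", paste(name[is.na(i)], collapse = ", "))
  i - 1L
}

#' @rdname label_schema
#' @param id integer class id in 0..9
#' @export
class_name <- function(id) {
  if (any(id < 0L | id > 9L)) stop("class id outside schema (0..9)")
  label_schema()[id + 1L]
}

#' Micron-per-pixel calibration
#'
#' @param microns_per_pixel positive finite scalar, micrometres per pixel.
#' @return An object of class \code{calibration}.
#' @export
calibration <- function(microns_per_pixel) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be a finite positive scalar")
  structure(list(microns_per_pixel = microns_per_pixel), class = "calibration")
}

mpp <- function(cal) {
  if (inherits(cal, "calibration")) cal$microns_per_pixel else as.numeric(cal)
}

#' Create annotation records in the normalized center-box dialect
#'
#' @param class_id integer vector, ids in 0..9.
#' @param x_center,y_center,width,height fractions of the image dimensions
#'   in \code{[0,1]}; width and height strictly positive.
#' @return data.frame of validated records.
#' @export
yolo_records <- function(class_id, x_center, y_center, width, height) {
  rec <- data.frame(class_id = as.integer(class_id), x_center = x_center,
                    y_center = y_center, width = width, height = height)
  validate_yolo_records(rec)
  rec
}

validate_yolo_records <- function(records) {
  req <- c("class_id", "x_center", "y_center", "width", "height")
  if (!all(req %in% names(records))) stop("records must have fields: ",
                                          paste(req, collapse = ", "))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (is.na(r$class_id) || r$class_id < 0L || r$class_id > 9L)
      stop(sprintf("record %d: class_id %s outside schema", i, r$class_id))
    co <- c(r$x_center, r$y_center, r$width, r$height)
    if (any(!is.finite(co)) || any(co < 0) || any(co > 1))
      stop(sprintf("record %d: coordinate outside [0,1]", i))
    if (r$width <= 0 || r$height <= 0)
      stop(sprintf("record %d: non-positive box extent", i))
  }
  invisible(records)
}

#' Serialize annotation records to label text
#'
#' One line per record, five space-separated fields
#' \code{class_id x_center y_center width height}, coordinates written with
#' six decimal places, in input order.
#'
#' @param records data.frame as returned by \code{\link{yolo_records}}.
#' @return A single character string ("" for an empty record set).
#' @examples
#' write_yolo_labels(yolo_records(9L, 0.5, 0.5, 0.1, 0.2))
#' @export
write_yolo_labels <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return("")
  validate_yolo_records(records)
  paste(sprintf("%d %.6f %.6f %.6f %.6f", records$class_id,
                records$x_center, records$y_center,
                records$width, records$height), collapse = "\n")
}

#' Parse label text into annotation records
#'
#' @param text label text (or vector of lines); blank lines are ignored.
#' @return data.frame of records; inverse of \code{\link{write_yolo_labels}}
#'   to within 1e-6 per coordinate.
#' @export
read_yolo_labels <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) != 5L)
      stop(sprintf("parse error at line %d: expected 5 fields, got %d",
                   i, length(parts)))
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d: non-numeric field", i))
    out[[i]] <- data.frame(class_id = as.integer(vals[1]), x_center = vals[2],
                           y_center = vals[3], width = vals[4], height = vals[5])
  }
  recs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(recs))
    recs <- data.frame(class_id = integer(), x_center = numeric(),
                       y_center = numeric(), width = numeric(),
                       height = numeric())
  validate_yolo_records(recs)
  rownames(recs) <- NULL
  recs
}

#' Convert between pixel boxes and normalized center boxes
#'
#' Pixel boxes are \code{(x, y, w, h)} with \code{x, y} the 0-based top-left
#' pixel and integer extents; normalized boxes are center format fractions.
#' Denormalization rounds to the nearest pixel, so
#' \code{denormalize_box(normalize_box(b))} is the identity for any pixel box.
#'
#' @param box pixel box \code{c(x, y, w, h)} (for \code{normalize_box}) or
#'   normalized center box (for \code{denormalize_box}).
#' @param image_width,image_height image dimensions in pixels.
#' @return the converted box.
#' @export
normalize_box <- function(box, image_width, image_height) {
  c(x_center = (box[[1]] + box[[3]] / 2) / image_width,
    y_center = (box[[2]] + box[[4]] / 2) / image_height,
    width = box[[3]] / image_width, height = box[[4]] / image_height)
}

#' @rdname normalize_box
#' @export
denormalize_box <- function(box, image_width, image_height) {
  w <- round(box[[3]] * image_width)
  h <- round(box[[4]] * image_height)
  x <- round(box[[1]] * image_width - box[[3]] * image_width / 2)
  y <- round(box[[2]] * image_height - box[[4]] * image_height / 2)
  if (w <= 0 || h <= 0) stop("box implies non-positive pixel extent")
  c(x = x, y = y, w = w, h = h)
}

#' Write a machine-readable pipeline report
#'
#' Serializes pipeline results (per-cell classes, anomaly calls, summary
#' counts, model metrics) as JSON. Output is deterministic: identical inputs
#' produce byte-identical files.
#'
#' @param results a list with any of \code{cells} (data.frame or list),
#'   \code{anomalies}, \code{metrics}; counts are derived.
#' @param path output file path; if NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
write_report <- function(results, path = NULL) {
  cells <- results$cells
  n_cells <- if (is.null(cells)) 0L else
    if (is.data.frame(cells)) nrow(cells) else length(cells)
  anomalies <- results$anomalies
  n_anom <- 0L
  if (!is.null(anomalies)) {
    labs <- if (is.data.frame(anomalies)) anomalies$label else
      vapply(anomalies, function(a) a$label, character(1))
    n_anom <- sum(labs != "Normal")
  }
  report <- list(
    schema = label_schema(),
    counts = list(cells = n_cells, anomalies = n_anom),
    cells = cells %||% list(),
    anomalies = anomalies %||% list(),
    metrics = results$metrics %||% list())
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "list")
  if (!is.null(path)) {
    con <- try(file(path, "wb"), silent = TRUE)
    if (inherits(con, "try-error")) stop("cannot write report to ", path)
    writeBin(charToRaw(paste0(as.character(json), "\n")), con)
    close(con)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Read / write smear images
#'
#' Thin wrappers over EBImage supporting PNG, TIFF and JPEG. Images are
#' arrays with dimensions (width, height, 3) and values in \code{[0,1]}.
#'
#' @param path image file path.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3]
  a
}

#' @rdname read_image
#' @param image array (width, height, 3) in \code{[0,1]}.
#' @export
write_image <- function(image, path) {
  EBImage::writeImage(EBImage::Image(clamp(image), colormode = "Color"), path)
  invisible(path)
}
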