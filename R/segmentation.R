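#' Construct a detection triple
#'
#' A detection is the triple (bounding box, mask, class) plus a confidence:
#' the box is always recomputed as the tight box of the mask.
#'
#' @param mask nonempty logical matrix (image-sized).
#' @param class_id integer class id 0..9.
#' @param confidence finite value in [0, 1].
#' @return list of class \code{detection}: \code{box} (pixel tight box),
#'   \code{record} (normalized center box), \code{mask}, \code{class_id},
#'   \code{confidence}.
#' @export
detection <- function(mask, class_id, confidence = 1) {
  if (!any(mask != 0)) stop("detection mask is empty")
  if (!is.finite(confidence) || confidence < 0 || confidence > 1)
    stop("confidence must be finite in [0,1]")
  box <- mask_bbox(mask)
  structure(list(box = box,
                 record = normalize_box(box, nrow(mask), ncol(mask)),
                 mask = mask != 0, class_id = as.integer(class_id),
                 confidence = confidence),
            class = "detection")
}

#' Run a detector over an image
#'
#' Validates the detector's output against the detection contract and sorts
#' detections by descending confidence (stable).
#'
#' @param image array (width, height, 3) normalized to [0, 1].
#' @param detector a function \code{image -> list of detection}, e.g.
#'   \code{\link{baseline_detector}}.
#' @param ... passed to the detector.
#' @return list of \code{detection}, sorted by descending confidence.
#' @export
detect_cells <- function(image, detector = baseline_detector, ...) {
  dets <- tryCatch(detector(image, ...),
                   error = function(e) stop("detector failed: ",
                                            conditionMessage(e)))
  for (d in dets) {
    if (!inherits(d, "detection")) stop("detector returned a non-detection")
    if (!identical(unname(d$box), unname(mask_bbox(d$mask))))
      stop("detection box is not the tight box of its mask")
  }
  ord <- order(-vapply(dets, `[[`, numeric(1), "confidence"),
               seq_along(dets))
  dets[ord]
}

#' Classical watershed baseline detector
#'
#' Otsu threshold on the background-subtracted luminance channel, hole
#' filling, connected components, and a distance-transform watershed to
#' split touching cells; each component is assigned a class by a size/color
#' heuristic (platelet < 4 um^2; dark blue-purple nucleus fraction marks a
#' WBC; low saturation marks an intrusion artifact; otherwise rbc).
#' Deterministic; confidence is the component's mean foreground contrast.
#'
#' @param image array (width, height, 3) in [0, 1].
#' @param calibration um/px used by the size heuristic.
#' @param min_area_px discard components smaller than this (default 30).
#' @return list of \code{detection}.
#' @export
baseline_detector <- function(image, calibration = 0.1, min_area_px = 30L) {
  u <- mpp(calibration)
  g <- luminance(image)
  bg <- median(c(g[1, ], g[nrow(g), ], g[, 1], g[, ncol(g)]))  # border estimate
  dark <- clamp(bg - g, 0, 1)
  if (diff(range(dark)) < 1e-9) return(list())
  thr <- EBImage::otsu(EBImage::Image(dark / max(dark)),
                       range = c(0, 1)) * max(dark)
  fg <- dark > pmax(thr, 0.04)
  if (!any(fg)) return(list())
  fgI <- EBImage::fillHull(EBImage::Image(fg + 0))
  dm <- EBImage::distmap(fgI)
  ws <- EBImage::watershed(dm, tolerance = 2)
  labm <- matrix(EBImage::imageData(ws), nrow(g), ncol(g))
  dets <- list()
  for (id in setdiff(sort(unique(as.vector(labm))), 0)) {
    comp <- labm == id
    if (sum(comp) < min_area_px) next
    area_um2 <- sum(comp) * u^2
    rch <- mean(image[, , 1][comp]); gch <- mean(image[, , 2][comp])
    bch <- mean(image[, , 3][comp])
    sat <- 1 - min(rch, gch, bch) / max(rch, gch, bch, 1e-9)
    dark_frac <- mean(g[comp] < 0.4)
    cls <- if (area_um2 < 4) "platelet"
      else if (dark_frac > 0.15 && bch > rch) "lymphocyte"
      else if (sat < 0.12) "intrusion"
      else "rbc"
    conf <- clamp(mean(dark[comp]) / max(thr, 1e-9) / 3, 0.05, 1)
    dets[[length(dets) + 1L]] <- detection(comp, class_id(cls), conf)
  }
  dets
}

#' Intersection-over-union of two boxes
#'
#' Boxes are \code{(x, y, w, h)} in any consistent unit. Symmetric, 1 iff
#' identical, 0 iff disjoint.
#'
#' @param boxA,boxB boxes with positive area.
#' @return IoU in [0, 1].
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 2, 2))  # 1/7
#' @export
iou <- function(boxA, boxB) {
  if (boxA[[3]] <= 0 || boxA[[4]] <= 0 || boxB[[3]] <= 0 || boxB[[4]] <= 0)
    stop("degenerate zero-area box")
  ix <- max(0, min(boxA[[1]] + boxA[[3]], boxB[[1]] + boxB[[3]]) -
              max(boxA[[1]], boxB[[1]]))
  iy <- max(0, min(boxA[[2]] + boxA[[4]], boxB[[2]] + boxB[[4]]) -
              max(boxA[[2]], boxB[[2]]))
  inter <- ix * iy
  inter / (boxA[[3]] * boxA[[4]] + boxB[[3]] * boxB[[4]] - inter)
}

#' @rdname iou
#' @param mA,mB nonempty binary masks of identical dimensions.
#' @export
mask_iou <- function(mA, mB) {
  a <- mA != 0; b <- mB != 0
  if (!any(a) || !any(b)) stop("degenerate empty mask")
  sum(a & b) / sum(a | b)
}

#' Match predictions to ground truth by IoU
#'
#' Greedy matching in descending confidence order: each prediction claims
#' the unused truth with the highest IoU at or above the threshold. Ties on
#' confidence break by higher IoU, then lower prediction index.
#'
#' @param preds list of \code{detection} (any order; sorted internally).
#' @param truths list of \code{detection}-like ground truth (mask + class).
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @param class_aware require equal class for a match (default TRUE).
#' @param use_masks match on mask IoU (default) or box IoU.
#' @return list with \code{matches} (data.frame pred, truth, iou),
#'   \code{fp} (unmatched pred indices), \code{fn} (unmatched truth indices).
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5,
                             class_aware = TRUE, use_masks = TRUE) {
  np <- length(preds); nt <- length(truths)
  conf <- vapply(preds, function(p) p$confidence %||% 1, numeric(1))
  used <- logical(nt)
  rows <- list()
  pair_iou <- function(p, t) {
    if (use_masks && !is.null(p$mask) && !is.null(t$mask))
      mask_iou(p$mask, t$mask)
    else iou(p$box, t$box)
  }
  # confidence ties break by the prediction's best achievable IoU, then index
  best_iou <- vapply(seq_len(np), function(pi) {
    if (nt == 0L) return(0)
    max(vapply(seq_len(nt), function(ti)
      pair_iou(preds[[pi]], truths[[ti]]), numeric(1)))
  }, numeric(1))
  ord <- order(-conf, -best_iou, seq_len(max(np, 0L)))
  for (pi in ord) {
    best <- 0; bi <- 0L
    for (ti in seq_len(nt)) {
      if (used[ti]) next
      if (class_aware && !identical(as.integer(preds[[pi]]$class_id),
                                    as.integer(truths[[ti]]$class_id))) next
      ov <- pair_iou(preds[[pi]], truths[[ti]])
      if (ov > best) { best <- ov; bi <- ti }
    }
    if (bi > 0L && best >= iou_threshold) {
      used[bi] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(pred = pi, truth = bi,
                                              iou = best)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pred = integer(), truth = integer(), iou = numeric())
  list(matches = matches,
       fp = setdiff(seq_len(np), matches$pred),
       fn = setdiff(seq_len(nt), matches$truth))
}

# Average precision for one class: all-point interpolated area under the
# precision-recall curve at a fixed IoU threshold.
ap_for_class <- function(preds_by_img, truths_by_img, cls, iou_threshold,
                         use_masks = TRUE) {
  n_truth <- 0L
  conf <- numeric(); tp <- logical()
  for (i in seq_along(truths_by_img)) {
    tr <- Filter(function(t) t$class_id == cls, truths_by_img[[i]])
    pr <- Filter(function(p) p$class_id == cls,
                 if (i <= length(preds_by_img)) preds_by_img[[i]] else list())
    n_truth <- n_truth + length(tr)
    if (length(pr) == 0L) next
    mm <- match_detections(pr, tr, iou_threshold, class_aware = TRUE,
                           use_masks = use_masks)
    flags <- seq_along(pr) %in% mm$matches$pred
    conf <- c(conf, vapply(pr, `[[`, numeric(1), "confidence"))
    tp <- c(tp, flags)
  }
  if (n_truth == 0L) return(NA_real_)
  if (length(conf) == 0L) return(0)
  ord <- order(-conf)
  tpc <- cumsum(tp[ord]); fpc <- cumsum(!tp[ord])
  recall <- tpc / n_truth
  precision <- tpc / (tpc + fpc)
  # precision envelope, integrate over recall
  for (k in rev(seq_along(precision))[-1])
    precision[k] <- max(precision[k], precision[k + 1])
  r_prev <- 0; ap <- 0
  for (k in seq_along(recall)) {
    ap <- ap + (recall[k] - r_prev) * precision[k]
    r_prev <- recall[k]
  }
  ap
}

#' Detection metrics over a dataset
#'
#' Micro-averaged precision, recall and F1 from greedy class-aware matching,
#' plus mAP at IoU 0.5 (mean over classes present in the ground truth of the
#' all-point interpolated average precision) and mAP@@50:95 (mean over IoU
#' thresholds 0.5 to 0.95 in steps of 0.05).
#'
#' Conventions for empty denominators: with no predictions but existing
#' truths, precision = recall = F1 = 0; with both sets empty, precision =
#' recall = F1 = 1.
#'
#' @param preds_by_img,truths_by_img lists (one element per image) of lists
#'   of detections.
#' @param iou_threshold match threshold for P/R/F1 (default 0.5).
#' @param use_masks match on masks (default) or boxes.
#' @return list: \code{precision}, \code{recall}, \code{f1}, \code{map50},
#'   \code{map50_95}, \code{per_class_ap}, \code{tp}, \code{fp}, \code{fn}.
#' @export
detection_metrics <- function(preds_by_img, truths_by_img,
                              iou_threshold = 0.5, use_masks = TRUE) {
  if (length(truths_by_img) == 0L) stop("need at least one evaluated image")
  TP <- FP <- FN <- 0L
  for (i in seq_along(truths_by_img)) {
    pr <- if (i <= length(preds_by_img)) preds_by_img[[i]] else list()
    mm <- match_detections(pr, truths_by_img[[i]], iou_threshold,
                           class_aware = TRUE, use_masks = use_masks)
    TP <- TP + nrow(mm$matches); FP <- FP + length(mm$fp)
    FN <- FN + length(mm$fn)
  }
  if (TP + FP + FN == 0L) {
    precision <- recall <- f1 <- 1
  } else {
    precision <- if (TP + FP > 0) TP / (TP + FP) else 0
    recall <- if (TP + FN > 0) TP / (TP + FN) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
  }
  classes <- sort(unique(unlist(lapply(truths_by_img, function(ts)
    vapply(ts, `[[`, integer(1), "class_id")))))
  ap50 <- vapply(classes, function(cl)
    ap_for_class(preds_by_img, truths_by_img, cl, 0.5, use_masks), numeric(1))
  map50 <- if (length(ap50)) mean(ap50, na.rm = TRUE) else NA_real_
  thr_seq <- seq(0.5, 0.95, by = 0.05)
  map_all <- mean(vapply(thr_seq, function(th) {
    aps <- vapply(classes, function(cl)
      ap_for_class(preds_by_img, truths_by_img, cl, th, use_masks),
      numeric(1))
    if (length(aps)) mean(aps, na.rm = TRUE) else NA_real_
  }, numeric(1)))
  list(precision = precision, recall = recall, f1 = f1, map50 = map50,
       map50_95 = map_all,
       per_class_ap = stats::setNames(ap50, as.character(classes)),
       tp = TP, fp = FP, fn = FN)
}

#' Normalized detection confusion matrix
#'
#' (K+1) x (K+1) matrix over the 10 classes plus background: matching is
#' class-agnostic at IoU >= 0.5, then entry (i, j) is the fraction of
#' true-class-i objects predicted as class j; unmatched truths fall in the
#' background column, unmatched predictions in the background row. Each
#' non-empty row sums to 1.
#'
#' @param preds_by_img,truths_by_img per-image detection lists.
#' @param iou_threshold class-agnostic match threshold.
#' @param normalize "row" (default) or "none" (counts).
#' @param use_masks match on masks (default) or boxes.
#' @return 11 x 11 matrix with dimnames from the schema plus "background".
#' @export
confusion_matrix_detections <- function(preds_by_img, truths_by_img,
                                        iou_threshold = 0.5,
                                        normalize = c("row", "none"),
                                        use_masks = TRUE) {
  normalize <- match.arg(normalize)
  K <- 10L
  cm <- matrix(0, K + 1L, K + 1L,
               dimnames = list(truth = c(label_schema(), "background"),
                               prediction = c(label_schema(), "background")))
  for (i in seq_along(truths_by_img)) {
    pr <- if (i <= length(preds_by_img)) preds_by_img[[i]] else list()
    tr <- truths_by_img[[i]]
    mm <- match_detections(pr, tr, iou_threshold, class_aware = FALSE,
                           use_masks = use_masks)
    if (nrow(mm$matches)) for (k in seq_len(nrow(mm$matches))) {
      ti <- tr[[mm$matches$truth[k]]]$class_id + 1L
      pi <- pr[[mm$matches$pred[k]]]$class_id + 1L
      cm[ti, pi] <- cm[ti, pi] + 1
    }
    for (ti in mm$fn) cm[tr[[ti]]$class_id + 1L, K + 1L] <-
        cm[tr[[ti]]$class_id + 1L, K + 1L] + 1
    for (pi in mm$fp) cm[K + 1L, pr[[pi]]$class_id + 1L] <-
        cm[K + 1L, pr[[pi]]$class_id + 1L] + 1
  }
  if (normalize == "row") {
    rs <- rowSums(cm)
    nz <- rs > 0
    cm[nz, ] <- cm[nz, , drop = FALSE] / rs[nz]
  }
  cm
}

#' Oracle detector from generator ground truth
#'
#' Wraps a rendered scene's ground-truth cells as perfect detections with
#' confidence 1; useful to verify that evaluation machinery reports exact
#' metrics on perfect input.
#'
#' @param scene a \code{\link{render_smear}} result.
#' @return list of \code{detection}.
#' @export
oracle_detections <- function(scene) {
  lapply(scene$cells, function(cl) detection(cl$mask, cl$class_id, 1))
}
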