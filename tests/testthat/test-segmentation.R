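test_that("box and mask IoU follow set arithmetic", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(5, 5, 2, 2)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 2, 2)), 1 / 7, tolerance = 1e-9)
  expect_equal(iou(c(1, 1, 2, 2), c(0, 0, 2, 2)), 1 / 7, tolerance = 1e-9)
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "degenerate")
  a <- matrix(0, 6, 6); a[1:3, 1:3] <- 1
  b <- matrix(0, 6, 6); b[2:4, 1:3] <- 1
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, b), 6 / 12)
  expect_error(mask_iou(a, matrix(0, 6, 6)), "empty")
})

test_that("greedy matching resolves competition by confidence", {
  m <- matrix(0, 20, 20); m[5:12, 5:12] <- 1
  truth <- list(detection(m, 9L, 1))
  m2 <- m; m2[5, 5] <- 0
  preds <- list(detection(m2, 9L, 0.9), detection(m, 9L, 0.7))
  mm <- match_detections(preds, truth)
  expect_identical(nrow(mm$matches), 1L)
  expect_identical(mm$matches$pred, 1L)   # higher confidence wins
  expect_identical(mm$fp, 2L)
  # perfect predictions: all TP
  mm2 <- match_detections(truth, truth)
  expect_identical(nrow(mm2$matches), 1L)
  expect_length(mm2$fp, 0L); expect_length(mm2$fn, 0L)
  # no predictions: all FN
  mm3 <- match_detections(list(), truth)
  expect_identical(mm3$fn, 1L)
})

test_that("detection metrics follow their definitions and conventions", {
  mk <- function(x0, y0 = 10L, cls = 9L, conf = 1, n = 96L) {
    m <- matrix(0, n, n); m[x0:(x0 + 5), y0:(y0 + 5)] <- 1
    detection(m, cls, conf)
  }
  # TP=8, FP=2, FN=2 arithmetic: 8 exact hits, 2 far-off predictions
  truths <- lapply(seq(1, by = 9, length.out = 10), mk)
  preds <- c(truths[1:8], list(mk(1, y0 = 60L), mk(20, y0 = 60L)))
  m <- detection_metrics(list(preds), list(truths))
  expect_equal(m$tp, 8L); expect_equal(m$fp, 2L); expect_equal(m$fn, 2L)
  expect_equal(m$precision, 0.8); expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  # conventions
  conv <- detection_metrics(list(list()), list(list(mk(1))))
  expect_equal(conv$precision, 0); expect_equal(conv$recall, 0)
  expect_equal(conv$f1, 0)
  both_empty <- detection_metrics(list(list()), list(list()))
  expect_equal(both_empty$precision, 1); expect_equal(both_empty$recall, 1)
})

test_that("an oracle detector scores exactly 1 on all metrics", {
  mf <- generate_dataset(c(rbc = 8L, lymphocyte = 2L, platelet = 2L),
                         seed = 17L, cells_per_image = 6L)
  truths <- lapply(mf$scenes, oracle_detections)
  m <- detection_metrics(truths, truths)
  expect_identical(m$precision, 1)
  expect_identical(m$recall, 1)
  expect_identical(m$f1, 1)
  expect_identical(m$map50, 1)
  expect_identical(m$map50_95, 1)
  cm <- confusion_matrix_detections(truths, truths)
  for (cl in c("rbc", "lymphocyte", "platelet"))
    expect_equal(cm[cl, cl], 1)
  rs <- rowSums(cm)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
})

test_that("mAP@50 never increases as the IoU threshold tightens", {
  mf <- generate_dataset(c(rbc = 10L), seed = 23L, cells_per_image = 5L)
  truths <- lapply(mf$scenes, oracle_detections)
  # degrade predictions: erode masks, jitter confidence
  preds <- lapply(truths, function(ts) lapply(seq_along(ts), function(i) {
    t <- ts[[i]]
    m <- hemamorph:::erode1(t$mask)
    detection(m, t$class_id, 1 - 0.05 * i)
  }))
  maps <- vapply(c(0.5, 0.7, 0.9, 0.95), function(th)
    detection_metrics(preds, truths, iou_threshold = th)$map50, numeric(1))
  expect_true(all(diff(maps) <= 1e-12))
})

test_that("metrics are invariant to image permutation", {
  mf <- generate_dataset(c(rbc = 9L, platelet = 3L), seed = 29L,
                         cells_per_image = 4L)
  truths <- lapply(mf$scenes, oracle_detections)
  m1 <- detection_metrics(truths, truths)
  perm <- rev(seq_along(truths))
  m2 <- detection_metrics(truths[perm], truths[perm])
  expect_equal(m1[c("precision", "recall", "f1", "map50")],
               m2[c("precision", "recall", "f1", "map50")])
})

test_that("the baseline detector finds separated and touching cells", {
  blank <- hemamorph:::smear_background(96L, 96L)
  expect_length(detect_cells(blank, baseline_detector, calibration = 0.2), 0L)
  one <- render_smear(list(cell_spec(class = "rbc", center = c(48, 48),
                                     pallor_ratio = 0)),
                      image_dims = c(96L, 96L), calibration = 0.2, seed = 2L)
  d1 <- detect_cells(one$image, baseline_detector, calibration = 0.2)
  expect_length(d1, 1L)
  # five well-separated cells, each matching its truth at IoU >= 0.5
  specs <- lapply(1:5, function(i) {
    ang <- 2 * pi * i / 5
    cell_spec(class = "rbc",
              center = c(128 + 70 * cos(ang), 128 + 70 * sin(ang)))
  })
  sc <- render_smear(specs, image_dims = c(256L, 256L), calibration = 0.2,
                     seed = 5L)
  dets <- detect_cells(sc$image, baseline_detector, calibration = 0.2)
  expect_length(dets, 5L)
  mm <- match_detections(dets, oracle_detections(sc), class_aware = FALSE)
  expect_identical(nrow(mm$matches), 5L)
  expect_true(all(mm$matches$iou >= 0.5))
  # tight-box contract
  for (d in dets)
    expect_identical(unname(d$box), unname(hemamorph:::mask_bbox(d$mask)))
  # two ellipses overlapping ~30% by area are split by the watershed
  s1 <- cell_spec(class = "rbc", center = c(55, 64), pallor_ratio = 0)
  s2 <- cell_spec(class = "rbc", center = c(75, 64), pallor_ratio = 0)
  tw <- render_smear(list(s1, s2), image_dims = c(128L, 128L),
                     calibration = 0.2, seed = 3L, max_overlap = 0.6)
  expect_length(detect_cells(tw$image, baseline_detector, calibration = 0.2),
                2L)
})

test_that("missed truths land in the background column of the confusion matrix", {
  mf <- generate_dataset(c(rbc = 10L), seed = 31L, cells_per_image = 5L)
  truths <- lapply(mf$scenes, oracle_detections)
  # predictions: keep 7 of the 10 rbc truths
  flat <- unlist(truths, recursive = FALSE)
  keep <- 7L
  preds <- truths
  dropped <- 0L
  for (i in seq_along(preds)) {
    ps <- preds[[i]]
    while (length(ps) > 0L && dropped < length(flat) - keep) {
      ps <- ps[-length(ps)]; dropped <- dropped + 1L
    }
    preds[[i]] <- ps
  }
  cm <- confusion_matrix_detections(preds, truths)
  expect_equal(cm["rbc", "rbc"], 0.7)
  expect_equal(cm["rbc", "background"], 0.3)
})
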