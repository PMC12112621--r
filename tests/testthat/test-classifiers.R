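test_that("binary cross-entropy matches its closed forms", {
  expect_lt(binary_cross_entropy(1, 1 - 1e-12), 1e-9)
  expect_equal(binary_cross_entropy(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(binary_cross_entropy(c(1, 0), c(0.9, 0.1)),
               -0.5 * (log(0.9) + log(0.9)), tolerance = 1e-9)
  expect_error(binary_cross_entropy(c(1, 0), 0.5), "length")
})

test_that("the mono/poly classifier separates by nuclear lobation", {
  mono <- c("lymphocyte", "monocyte")
  poly <- c("neutrophil", "eosinophil", "basophil")
  set.seed(42)
  cells <- data.frame(class = c(sample(mono, 30, TRUE),
                                sample(poly, 30, TRUE)))
  cells$y <- rep(c("mono", "poly"), each = 30)
  seeds <- sample.int(1e6, nrow(cells))
  feats <- t(vapply(seq_len(nrow(cells)), function(i) {
    sc <- render_cell_patch(cells$class[i], seed = seeds[i])
    cl <- sc$cells[[1]]
    as.numeric(extract_descriptors(sc$image, cl$mask, cl$nucleus_mask, 0.1))
  }, numeric(50)))
  colnames(feats) <- descriptor_names()
  tr <- c(1:24, 31:54); te <- setdiff(seq_len(nrow(cells)), tr)
  mod <- train_mono_poly(feats[tr, ], cells$y[tr], seed = 42L)
  p <- predict_mono_poly(mod, feats[te, ])
  acc <- mean((p > 0.5) == (cells$y[te] == "poly"))
  expect_gte(acc, 0.95)
  # untrained model predicts the prior
  m0 <- train_mono_poly(feats[tr, ], cells$y[tr], epochs = 0L)
  expect_equal(stats::var(predict_mono_poly(m0, feats[te, ])), 0)
  expect_error(train_mono_poly(feats[1:5, ], rep("mono", 5)), "both classes")
})

test_that("the embedding backbone honors the 2048-dim contract", {
  bb <- create_feature_backbone(seed = 42L)
  sc1 <- render_cell_patch("lymphocyte", seed = 3L)
  sc2 <- render_cell_patch("Normal", seed = 4L)
  f1 <- deep_features(sc1$image, bb)
  expect_length(f1, 2048L)
  expect_identical(deep_features(sc1$image, bb), f1)
  f2 <- deep_features(sc2$image, bb)
  expect_gt(sum(f1 != f2), 0L)
  expect_error(deep_features(array(0, c(2, 2, 2, 2)), bb), "invalid patch")
})

test_that("outlier filters isolate a gross outlier and respect contamination", {
  set.seed(3)
  X <- rbind(matrix(rnorm(99 * 4, 0, 0.5), 99), rep(50, 4))
  for (method in c("isolation_forest", "elliptic_envelope")) {
    keep <- outlier_filter(X, method, contamination = 0.01, seed = 5L)
    expect_identical(which(!keep), 100L)
  }
  expect_true(all(outlier_filter(X, "isolation_forest", 0, seed = 1L)))
  # duplicated rows receive identical masks
  X2 <- rbind(matrix(rnorm(99 * 3, 0, 0.5), 99), rep(30, 3))
  Xdup <- rbind(X2, X2)
  keep2 <- outlier_filter(Xdup, "isolation_forest", 0.01, seed = 9L)
  expect_identical(keep2[1:100], keep2[101:200])
  expect_identical(which(!keep2), c(100L, 200L))
  expect_error(outlier_filter(X[1:5, ], "isolation_forest"), "10 rows")
  expect_error(outlier_filter(cbind(X, 1), "elliptic_envelope", 0.01),
               "degenerate")
})

test_that("k-means binning is monotone and exact on separated values", {
  out <- discretize(data.frame(v = c(0, 0, 5, 5, 10, 10)), 3L)
  expect_identical(out$v, c(0L, 0L, 1L, 1L, 2L, 2L))
  set.seed(4)
  x <- runif(60)
  b <- discretize(data.frame(x = x), 4L)$x
  ord <- order(x)
  expect_true(all(diff(b[ord]) >= 0))
  # n_bins equal to the number of distinct values is a bijection
  xb <- discretize(data.frame(x = c(3, 1, 2)), 3L)$x
  expect_identical(xb, c(2L, 0L, 1L))
  expect_error(discretize(data.frame(bad = c(1, 1, 2, 2)), 3L), "bad")
})

test_that("the eight-family harness is complete, strong and reproducible", {
  expect_length(classifier_families(), 8L)
  d <- separable_table(n = 120L, seed = 7L)
  hr <- compare_classifiers(d$X, d$y, seed = 42L)
  expect_setequal(hr$results$model, classifier_families())
  expect_true(all(hr$results$precision >= 0.95))
  expect_length(hr$top3, 3L)
  hr2 <- compare_classifiers(d$X, d$y, seed = 42L)
  expect_identical(hr$results[c("model", "precision", "f1")],
                   hr2$results[c("model", "precision", "f1")])
  expect_error(compare_classifiers(d$X, d$y, preprocessing = "pca"),
               "unknown preprocessing")
  expect_error(compare_classifiers(d$X, rep("one", nrow(d$X))),
               "two classes")
})

test_that("preprocessing composes without disturbing columns", {
  d <- separable_table(n = 80L, seed = 9L)
  keep <- outlier_filter(d$X, "isolation_forest", 0.05, seed = 1L)
  expect_lte(sum(keep), nrow(d$X))
  filtered <- d$X[keep, ]
  disc <- discretize(filtered, 4L, seed = 1L)
  expect_identical(names(disc), names(d$X))
  expect_identical(nrow(disc), sum(keep))
  hr <- compare_classifiers(d$X, d$y,
                            preprocessing = "outlier:isolation_forest",
                            seed = 42L)
  expect_true(all(hr$results$precision >= 0.9))
  hd <- compare_classifiers(d$X, d$y, preprocessing = "discretize",
                            n_bins = 6L, seed = 42L)
  expect_true(all(hd$results$f1 > 0.8))
})

test_that("the report stage fits its three ensembles and tallies anomalies", {
  d <- separable_table(n = 100L, seed = 11L)
  calls <- list(list(label = "Normal"), list(label = "Elliptocyte"),
                list(label = "Normal"))
  rep1 <- generate_report(calls, d$X, d$y, wbc_flags = c(TRUE, FALSE),
                          seed = 42L)
  expect_setequal(names(rep1$counts), rbc_archetypes())
  expect_identical(rep1$counts$Elliptocyte, 1L)
  expect_identical(rep1$counts$Macrocyte, 0L)
  expect_lte(rep1$metrics$random_forest$ensemble_misclassification, 0.05)
  expect_identical(rep1$wbc_flagged, 1L)
  rep2 <- generate_report(calls, d$X, d$y, wbc_flags = c(TRUE, FALSE),
                          seed = 42L)
  expect_identical(rep1$json, rep2$json)
  expect_error(generate_report(calls, d$X[0, ], character()), "empty input")
})
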