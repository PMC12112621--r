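test_that("compatibility is the bilinear form (Wx)'a_y", {
  kb <- orthogonal_kb()
  a <- kb$attributes["C1", ]
  expect_equal(compatibility(a, diag(50), a), sum(a^2))
  expect_equal(compatibility(a, matrix(0, 50, 50), a), 0)
  x <- c(1, rep(0, 49))
  aA <- c(1, rep(0, 49)); aB <- c(0, 1, rep(0, 48))
  expect_equal(compatibility(x, diag(50), aA), 1)
  expect_equal(compatibility(x, diag(50), aB), 0)
  expect_error(compatibility(x[1:10], diag(50), aA), "dimension")
})

test_that("fitting separates seen classes and recovers parameters", {
  kb <- orthogonal_kb()
  tr <- kb_features(kb, kb$seen, n = 200L, sigma = 0.05, seed = 42L)
  mod <- fit_compatibility(tr$X, tr$labels, kb,
                           zsl_config(epochs = 30L), seed = 42L)
  acc <- top1_accuracy(predict_zsl(tr$X, mod, kb, candidates = kb$seen),
                       tr$labels)
  expect_gte(acc, 0.95)
  # exact features, no noise: training top-1 is 1
  ex <- kb_features(kb, kb$seen, n = 80L, sigma = 0, seed = 7L)
  mex <- fit_compatibility(ex$X, ex$labels, kb,
                           zsl_config(epochs = 10L, dropout = 0), seed = 7L)
  expect_identical(top1_accuracy(predict_zsl(ex$X, mex, kb,
                                             candidates = kb$seen),
                                 ex$labels), 1)
  # determinism
  mod2 <- fit_compatibility(tr$X, tr$labels, kb,
                            zsl_config(epochs = 30L), seed = 42L)
  expect_identical(mod$W, mod2$W)
  expect_error(fit_compatibility(tr$X, rep("nope", 200L), kb),
               "outside the knowledge base")
})

test_that("zero-initialized softmax starts at log K and descends", {
  kb <- orthogonal_kb()
  tr <- kb_features(kb, kb$seen, n = 8L, sigma = 0.02, seed = 1L)
  mod <- fit_compatibility(tr$X, tr$labels, kb,
                           zsl_config(epochs = 1L, dropout = 0,
                                      init = "zero"), seed = 1L)
  expect_lt(mod$trace$train[1], log(length(kb$seen)))
})

test_that("unseen orthogonal classes are recovered zero-shot", {
  kb <- orthogonal_kb(4L, 2L)
  tr <- kb_features(kb, kb$seen, n = 200L, sigma = 0.05, seed = 42L)
  mod <- fit_compatibility(tr$X, tr$labels, kb,
                           zsl_config(epochs = 30L), seed = 42L)
  un <- kb_features(kb, kb$unseen, n = 100L, sigma = 0.05, seed = 43L)
  acc <- top1_accuracy(predict_zsl(un$X, mod, kb, candidates = kb$unseen),
                       un$labels)
  expect_gte(acc, 0.9)
})

test_that("prediction respects candidate sets, ties and scale equivariance", {
  kb <- orthogonal_kb()
  x <- kb$attributes["C2", ]
  expect_identical(predict_zsl(x, diag(50), kb, candidates = "C3")$class,
                   "C3")
  # all-zero W: ranking equals KB order
  r0 <- predict_zsl(x, matrix(0, 50, 50), kb)
  expect_identical(r0$class, rownames(kb$attributes))
  expect_error(predict_zsl(x, diag(50), kb, candidates = character()),
               "empty")
  # positive scaling of W preserves rankings; extra candidates keep order
  set.seed(3)
  W <- matrix(rnorm(2500, 0, 0.1), 50)
  xs <- kb$attributes["C1", ] + rnorm(50, 0, 0.05)
  r1 <- predict_zsl(xs, W, kb, candidates = paste0("C", 1:4))
  r2 <- predict_zsl(xs, 3.7 * W, kb, candidates = paste0("C", 1:4))
  expect_identical(r1$class, r2$class)
  r3 <- predict_zsl(xs, W, kb, candidates = paste0("C", 1:6))
  expect_identical(r3$class[r3$class %in% r1$class], r1$class)
})

test_that("top-1 accuracy counts rank-1 agreement", {
  expect_identical(top1_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_identical(top1_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(top1_accuracy(c(rep("a", 7), rep("b", 3)), rep("a", 10)), 0.7)
  expect_error(top1_accuracy("a", c("a", "b")), "equal length")
})

test_that("the default knowledge base is deterministic and complete", {
  kb <- default_attribute_kb()
  expect_identical(kb$seen, label_schema())
  expect_setequal(kb$unseen, c("Lymphocyte T", "Promyelocyte-N"))
  expect_identical(dim(kb$attributes), c(12L, 50L))
  kb2 <- default_attribute_kb()
  expect_identical(kb$attributes, kb2$attributes)
})
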