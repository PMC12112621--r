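test_that("stratified folds reproduce the 80:20 protocol arithmetic", {
  proto <- reference_protocol()
  n <- proto$partitions[["train"]]
  labels <- rep(label_schema(), length.out = n)
  plan <- stratified_kfold(labels, k = 5L, seed = 42L)
  expect_identical(vapply(plan$folds, length, integer(1)), rep(1676L, 5L))
  expect_identical(length(train_indices(plan, 1L)), 6704L)
  # folds partition all indices in the validation role
  expect_identical(sort(unlist(plan$folds)), seq_len(n))
})

test_that("stratification keeps per-fold class proportions within one item", {
  labels <- rep(c("a", "b"), c(5L, 5L))
  plan <- stratified_kfold(labels, k = 5L, seed = 42L)
  for (f in plan$folds) {
    expect_length(f, 2L)
    expect_identical(sort(labels[f]), c("a", "b"))
  }
  set.seed(2)
  labels2 <- sample(rep(c("x", "y", "z"), c(23L, 11L, 7L)))
  plan2 <- stratified_kfold(labels2, k = 5L, seed = 1L)
  sizes <- vapply(plan2$folds, length, integer(1))
  expect_lte(max(sizes) - min(sizes), 1L)
  for (cls in c("x", "y", "z")) {
    per <- vapply(plan2$folds, function(f) sum(labels2[f] == cls),
                  integer(1))
    expect_lte(max(per) - min(per), 1L)
  }
  expect_error(stratified_kfold(c("a", rep("b", 9)), k = 5L), "class")
})

test_that("split plans are reproducible from their seed", {
  labels <- rep(label_schema(), length.out = 200L)
  p1 <- stratified_kfold(labels, seed = 42L)
  p2 <- stratified_kfold(labels, seed = 42L)
  expect_identical(p1$folds, p2$folds)
  p3 <- stratified_kfold(labels, seed = 43L)
  expect_false(identical(p1$folds, p3$folds))
})

test_that("held-out arithmetic rounds half up", {
  expect_identical(holdout_split(260, 0.2)$held_out, 52L)
  expect_identical(holdout_split(108, 0.2)$held_out, 22L)
  expect_identical(holdout_split(10, 0.2)$held_out, 2L)
  expect_identical(holdout_split(10, 0.2)$remaining, 8L)
  expect_error(holdout_split(0), ">= 1")
  expect_error(holdout_split(10, 1.2), "fraction")
})

test_that("paired t statistics match hand computation and brute force", {
  tt <- paired_ttest(c(1, 2, 4), c(2, 3, 3))
  expect_equal(tt$t, -0.5, tolerance = 1e-9)
  z <- paired_ttest(c(2, 1), c(1, 2))  # diffs {1,-1}
  expect_equal(z$t, 0, tolerance = 1e-12)
  expect_equal(z$p, 1, tolerance = 1e-9)
  deg <- paired_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  # brute-force recomputation from the definition on random instances
  set.seed(6)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- a - b
    if (sd(d) < 1e-12) next
    t_manual <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(paired_ttest(a, b)$t, t_manual, tolerance = 1e-9)
  }
})

test_that("Bonferroni adjustment dominates the raw p and caps at one", {
  set.seed(9)
  for (k in 1:30) {
    a <- rnorm(6); b <- rnorm(6)
    m <- sample(1:10, 1)
    tt <- paired_ttest(a, b, n_comparisons = m)
    expect_gte(tt$p_adjusted, tt$p)
    expect_lte(tt$p_adjusted, 1)
  }
})

test_that("the paired effect size is the standardized mean difference", {
  expect_equal(cohens_d(c(2, 1), c(1, 2)), 0)
  expect_equal(cohens_d(c(3, 5), c(1, 1)), 3 / sqrt(2), tolerance = 1e-9)
  set.seed(12)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(cohens_d(3 * a, 3 * b), cohens_d(a, b), tolerance = 1e-12)
  expect_warning(d <- cohens_d(c(2, 3), c(1, 2)), "degenerate")
  expect_true(is.na(d))
})

test_that("the stat report applies a shared correction across comparisons", {
  set.seed(21)
  cmp <- list(m1 = list(a = rnorm(5, 1), b = rnorm(5)),
              m2 = list(a = rnorm(5, 0.2), b = rnorm(5)))
  rep <- stat_report(cmp)
  expect_identical(nrow(rep), 2L)
  expect_true(all(rep$p_adjusted >= rep$p, na.rm = TRUE))
  expect_true(all(abs(pmin(1, rep$p * 2) - rep$p_adjusted) < 1e-12,
                  na.rm = TRUE))
})
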