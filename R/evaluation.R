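#' Stratified k-fold split plan
#'
#' Deterministic stratified k-fold construction: members of each class are
#' shuffled with the seed and dealt into folds by largest-remainder
#' allocation, with each class's remainder items going to the currently
#' smallest folds; validation fold sizes therefore differ by at most one
#' and class proportions per fold are within one item of the global
#' proportions. With k = 5 every fold is an 80:20 train/validation split.
#'
#' @param labels class label per item.
#' @param k number of folds (default 5).
#' @param seed integer seed (default 42).
#' @return object of class \code{split_plan}: \code{folds} (list of
#'   validation index vectors), \code{k}, \code{seed}, \code{n};
#'   \code{train_indices(plan, i)} gives the complementary train set.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 42L) {
  n <- length(labels)
  tab <- table(labels)
  small <- names(tab)[tab < k]
  if (length(small))
    stop("class smaller than k folds: ", paste(small, collapse = ", "))
  folds <- vector("list", k)
  sizes <- integer(k)
  local_seed(seed, {
    for (cls in names(tab)) {
      idx <- sample(which(labels == cls))
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      # remainder items go to the currently smallest folds (stable order)
      recipients <- order(sizes, seq_len(k))[seq_len(extra)]
      take <- 0L
      for (f in seq_len(k)) {
        m <- base + as.integer(f %in% recipients)
        if (m > 0L) {
          folds[[f]] <- c(folds[[f]], idx[take + seq_len(m)])
          take <- take + m
        }
        sizes[f] <- sizes[f] + m
      }
    }
  })
  folds <- lapply(folds, sort)
  structure(list(folds = folds, k = k, seed = seed, n = n),
            class = "split_plan")
}

#' @rdname stratified_kfold
#' @param plan a \code{split_plan}.
#' @param i fold number.
#' @export
train_indices <- function(plan, i) {
  setdiff(seq_len(plan$n), plan$folds[[i]])
}

#' Held-out split arithmetic
#'
#' \code{held_out = round-half-up(n * fraction)}; validated against the
#' benchmark subset sizes 108 -> 22 and 260 -> 52 at 20\%.
#'
#' @param n number of items (>= 1).
#' @param fraction held-out fraction in (0, 1).
#' @return list with \code{held_out} and \code{remaining}.
#' @export
holdout_split <- function(n, fraction = 0.2) {
  if (n < 1) stop("n must be >= 1")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  h <- floor(n * fraction + 0.5)
  list(held_out = as.integer(h), remaining = as.integer(n - h))
}

#' Paired t-test with Bonferroni correction
#'
#' Two-sided paired t-test on fold-wise metrics, with the adjusted p-value
#' \code{min(1, p * n_comparisons)} and a significance decision at
#' \code{alpha}. Zero-variance differences are degenerate: no p-value is
#' reported and the entry is flagged.
#'
#' @param metricsA,metricsB equal-length numeric vectors (>= 2).
#' @param alpha significance level (default 0.05).
#' @param n_comparisons number of simultaneous comparisons for Bonferroni.
#' @return list: \code{t}, \code{df}, \code{p}, \code{p_adjusted},
#'   \code{significant}, \code{degenerate}.
#' @export
paired_ttest <- function(metricsA, metricsB, alpha = 0.05,
                         n_comparisons = 1L) {
  if (length(metricsA) != length(metricsB) || length(metricsA) < 2L)
    stop("need equal-length vectors of length >= 2")
  d <- metricsA - metricsB
  if (stats::sd(d) < 1e-15)
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                p_adjusted = NA_real_, significant = NA, degenerate = TRUE))
  tt <- stats::t.test(metricsA, metricsB, paired = TRUE)
  p_adj <- min(1, tt$p.value * n_comparisons)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       p_adjusted = p_adj, significant = p_adj < alpha, degenerate = FALSE)
}

#' Cohen's d for paired designs
#'
#' The d_z form: mean of the differences over their sample (n - 1) standard
#' deviation; the sign carries the direction of the effect.
#'
#' @param metricsA,metricsB equal-length numeric vectors (>= 2).
#' @return scalar d, or NA with a degenerate warning when sd(diff) = 0.
#' @export
cohens_d <- function(metricsA, metricsB) {
  if (length(metricsA) != length(metricsB) || length(metricsA) < 2L)
    stop("need equal-length vectors of length >= 2")
  d <- metricsA - metricsB
  s <- stats::sd(d)
  if (s < 1e-15) {
    warning("degenerate: zero-variance differences")
    return(NA_real_)
  }
  mean(d) / s
}

#' Fold-wise statistical comparison report
#'
#' Runs \code{\link{paired_ttest}} and \code{\link{cohens_d}} for a set of
#' named model-vs-baseline metric series under a shared Bonferroni
#' correction.
#'
#' @param comparisons named list of \code{list(a =, b =)} metric pairs.
#' @param alpha significance level.
#' @return data.frame with one row per comparison: t, p, adjusted p,
#'   significance, Cohen's d, degeneracy flag.
#' @export
stat_report <- function(comparisons, alpha = 0.05) {
  m <- length(comparisons)
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    tt <- paired_ttest(cmp$a, cmp$b, alpha = alpha, n_comparisons = m)
    d <- if (tt$degenerate) NA_real_ else cohens_d(cmp$a, cmp$b)
    data.frame(comparison = nm, t = tt$t, p = tt$p,
               p_adjusted = tt$p_adjusted, significant = tt$significant,
               cohens_d = d, degenerate = tt$degenerate)
  })
  do.call(rbind, rows)
}

#' Reference study-protocol sizes
#'
#' The dataset partition and held-out arithmetic the evaluation protocol is
#' designed around: a multi-class primary set of 8380 training, 2600
#' validation and 1100 test images (12080 pre-augmentation, 28532 after
#' augmentation), and a two-part public benchmark (108 + 260 images) from
#' which 20\% per part is held out.
#'
#' @return nested list of integer constants.
#' @export
reference_protocol <- function() {
  list(partitions = c(train = 8380L, validation = 2600L, test = 1100L),
       pre_augmentation_total = 12080L,
       post_augmentation_total = 28532L,
       benchmark = list(part1 = 108L, part2 = 260L, holdout_fraction = 0.2),
       kfold = list(k = 5L, seed = 42L, ratio = c(train = 0.8, validation = 0.2)))
}
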