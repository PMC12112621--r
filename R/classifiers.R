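#' Binary cross-entropy
#'
#' \code{-(1/N) sum(y log p + (1 - y) log(1 - p))} with probabilities
#' clipped to \code{[eps, 1 - eps]}.
#'
#' @param y 0/1 labels.
#' @param p predicted probabilities, same length.
#' @param eps clipping constant.
#' @return scalar loss (>= 0).
#' @examples
#' binary_cross_entropy(1, 0.5)  # log(2)
#' @export
binary_cross_entropy <- function(y, p, eps = 1e-12) {
  if (length(y) != length(p)) stop("length mismatch")
  p <- clamp(p, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the mononuclear/polynuclear classifier
#'
#' Feature-mode model: an L2-regularized logistic model (ridge) on
#' lobe-count-bearing morphometric features distinguishing mononuclear
#' (1 nuclear lobe) from polymorphonuclear (>= 2 lobes) leukocytes.
#' Deterministic given the seed.
#'
#' @param features n x p numeric matrix/data.frame.
#' @param labels factor/character with exactly two levels, or 0/1 (1 =
#'   polynuclear).
#' @param lambda ridge penalty (default 0.01).
#' @param epochs IRLS iteration cap (default 50; 0 returns the untrained
#'   prior model).
#' @param seed integer seed.
#' @return object of class \code{mono_poly_model} with \code{predict}able
#'   coefficients; \code{predict_mono_poly} returns probabilities of the
#'   positive (polynuclear) class.
#' @export
train_mono_poly <- function(features, labels, lambda = 0.01, epochs = 50L,
                            seed = 42L) {
  X <- as.matrix(features)
  y <- if (is.numeric(labels)) as.integer(labels != 0) else
    as.integer(factor(labels)) - 1L
  if (length(unique(y)) < 2L) stop("both classes must be present")
  mu <- colMeans(X); sg <- apply(X, 2, stats::sd); sg[sg < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  Xa <- cbind(1, Xs)
  beta <- rep(0, ncol(Xa))
  if (epochs >= 1) {
    # ridge-penalized IRLS (intercept unpenalized)
    for (it in seq_len(epochs)) {
      eta <- as.vector(Xa %*% beta)
      p <- 1 / (1 + exp(-eta))
      wts <- pmax(p * (1 - p), 1e-6)
      z <- eta + (y - p) / wts
      pen <- diag(c(0, rep(lambda * nrow(Xa), ncol(Xs))))
      beta_new <- solve(crossprod(Xa, Xa * wts) + pen,
                        crossprod(Xa, wts * z))
      if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
      beta <- beta_new
    }
  } else {
    beta[1] <- stats::qlogis(clamp(mean(y), 1e-6, 1 - 1e-6))
  }
  structure(list(beta = as.vector(beta), center = mu, scale = sg,
                 levels = if (is.numeric(labels)) c("0", "1") else
                   levels(factor(labels)), lambda = lambda, seed = seed),
            class = "mono_poly_model")
}

#' @rdname train_mono_poly
#' @param model a \code{mono_poly_model}.
#' @param newdata feature matrix.
#' @export
predict_mono_poly <- function(model, newdata) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.vector(1 / (1 + exp(-(cbind(1, Xs) %*% model$beta))))
}

#' Random-weight embedding backbone (2048-d feature contract)
#'
#' A fixed, seeded two-layer nonlinear projection emitting length-2048
#' embeddings from 32 x 32 RGB patches: the transfer-learning feature
#' contract of the pipeline. Weights are random by default (no downloads);
#' any module honoring the \code{patch -> R^2048} contract can stand behind
#' it.
#'
#' @param seed integer seed for the weights.
#' @param input_size patch side length after resizing (default 32).
#' @param hidden hidden width (default 512).
#' @return object of class \code{feature_backbone}.
#' @export
create_feature_backbone <- function(seed = 42L, input_size = 32L,
                                    hidden = 512L) {
  d_in <- input_size^2 * 3L
  local_seed(seed, {
    structure(list(
      input_size = input_size,
      W1 = matrix(stats::rnorm(d_in * hidden, 0, 1 / sqrt(d_in)), d_in, hidden),
      b1 = stats::rnorm(hidden, 0, 0.01),
      W2 = matrix(stats::rnorm(hidden * 2048L, 0, 1 / sqrt(hidden)),
                  hidden, 2048L),
      b2 = stats::rnorm(2048L, 0, 0.01), seed = seed),
      class = "feature_backbone")
  })
}

#' Extract the 2048-dimensional embedding of a patch
#'
#' @param patch image array (w, h, 3) or grayscale matrix in [0, 1].
#' @param backbone from \code{\link{create_feature_backbone}}.
#' @return numeric vector of length 2048; deterministic given the backbone.
#' @export
deep_features <- function(patch, backbone = create_feature_backbone()) {
  if (is.null(dim(patch)) || length(dim(patch)) > 3L)
    stop("invalid patch dimensions")
  if (length(dim(patch)) == 2L)
    patch <- array(rep(patch, 3L), dim = c(dim(patch), 3L))
  s <- backbone$input_size
  res <- EBImage::resize(EBImage::Image(patch, colormode = "Color"), s, s)
  x <- as.vector(EBImage::imageData(res))
  if (length(x) != nrow(backbone$W1)) stop("invalid patch dimensions")
  h <- tanh(as.vector(x %*% backbone$W1) + backbone$b1)
  as.vector(tanh(as.vector(h %*% backbone$W2) + backbone$b2))
}

# ---- outlier filtering ----------------------------------------------------

# Isolation forest: random-split trees on a subsample; anomaly score
# 2^(-E[path length]/c(psi)). Written in-package (no installed provider).
iforest_ctree <- function(X, height_limit, depth = 0L) {
  n <- nrow(X)
  if (n <= 1L || depth >= height_limit ||
      all(apply(X, 2, function(cc) diff(range(cc)) < 1e-12)))
    return(list(leaf = TRUE, size = n))
  repeat {
    f <- sample.int(ncol(X), 1L)
    rng <- range(X[, f])
    if (diff(rng) > 1e-12) break
  }
  sp <- stats::runif(1, rng[1], rng[2])
  left <- X[, f] < sp
  list(leaf = FALSE, feature = f, split = sp,
       left = iforest_ctree(X[left, , drop = FALSE], height_limit, depth + 1L),
       right = iforest_ctree(X[!left, , drop = FALSE], height_limit, depth + 1L))
}

iforest_path <- function(tree, x, depth = 0L) {
  if (tree$leaf) {
    return(depth + if (tree$size > 1L) harmonic_c(tree$size) else 0)
  }
  if (x[tree$feature] < tree$split)
    iforest_path(tree$left, x, depth + 1L)
  else iforest_path(tree$right, x, depth + 1L)
}

harmonic_c <- function(n) {
  if (n <= 1L) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

isolation_forest_scores <- function(X, n_trees = 100L, sample_size = 256L,
                                    seed = 1L) {
  X <- as.matrix(X)
  psi <- min(sample_size, nrow(X))
  hl <- ceiling(log2(max(psi, 2L)))
  local_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(k)
      iforest_ctree(X[sample.int(nrow(X), psi), , drop = FALSE], hl))
    pl <- vapply(seq_len(nrow(X)), function(i)
      mean(vapply(trees, iforest_path, numeric(1), x = X[i, ])), numeric(1))
    2^(-pl / harmonic_c(psi))
  })
}

#' Unsupervised outlier filtering of a feature table
#'
#' Isolation Forest (random isolation trees, average path length) or
#' Elliptic Envelope (robust MCD covariance and Mahalanobis distance) flag
#' the most anomalous \code{round(contamination * n)} rows.
#'
#' @param table numeric data.frame/matrix with >= 10 rows.
#' @param method "isolation_forest" or "elliptic_envelope".
#' @param contamination fraction of rows to flag (0 keeps everything).
#' @param seed integer seed.
#' @return logical keep mask of length \code{nrow(table)} (TRUE = inlier).
#' @export
outlier_filter <- function(table,
                           method = c("isolation_forest", "elliptic_envelope"),
                           contamination = 0.05, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(table)
  if (nrow(X) < 10L) stop("need at least 10 rows")
  if (contamination < 0 || contamination >= 1)
    stop("contamination must be in [0, 1)")
  k <- round(contamination * nrow(X))
  if (k == 0L) return(rep(TRUE, nrow(X)))
  score <- if (method == "isolation_forest") {
    isolation_forest_scores(X, seed = seed)
  } else {
    if (any(apply(X, 2, function(cc) diff(range(cc)) < 1e-12)))
      stop("degenerate covariance: constant feature column")
    rc <- local_seed(seed, MASS::cov.rob(X, method = "mcd"))
    stats::mahalanobis(X, rc$center, rc$cov)
  }
  thr <- sort(score, decreasing = TRUE)[k]
  flag <- score >= thr
  if (sum(flag) > k) {  # break score ties by row order
    extra <- which(flag & score == thr)
    flag[utils::tail(extra, sum(flag) - k)] <- FALSE
  }
  !flag
}

#' K-means feature discretization
#'
#' Maps each numeric column to integer bin ids 0..n_bins-1 by seeded 1-d
#' k-means; bins are relabeled in increasing centroid order so the mapping
#' is monotone in the feature value.
#'
#' @param table numeric data.frame/matrix.
#' @param n_bins number of bins (>= 2).
#' @param strategy only "kmeans".
#' @param seed integer seed for centroid initialization.
#' @return object of the same shape with integer bin ids.
#' @export
discretize <- function(table, n_bins = 5L, strategy = "kmeans", seed = 1L) {
  if (!identical(strategy, "kmeans")) stop("unknown strategy: ", strategy)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  X <- as.data.frame(table)
  out <- X
  local_seed(seed, {
    for (cn in names(X)) {
      x <- X[[cn]]
      if (!is.numeric(x)) next
      ux <- sort(unique(x))
      if (length(ux) < n_bins)
        stop("column ", cn, " has fewer than ", n_bins, " distinct values")
      if (length(ux) == n_bins) {
        # one distinct value per bin: the binning is a bijection
        out[[cn]] <- as.integer(match(x, ux) - 1L)
      } else {
        km <- stats::kmeans(x, centers = n_bins, nstart = 5L, iter.max = 50L)
        relabel <- rank(km$centers)  # ascending centroid order
        out[[cn]] <- as.integer(relabel[km$cluster] - 1L)
      }
    }
  })
  out
}

# ---- eight-family comparison harness -------------------------------------

#' The eight registered classifier families
#' @return character vector of family keys.
#' @export
classifier_families <- function() {
  c("knn", "decision_tree", "random_forest", "svm", "gaussian_nb",
    "gradient_boosting", "adaboost", "mlp")
}

# AdaBoost.M1 (SAMME) over depth-1 rpart stumps; written in-package.
adaboost_fit <- function(X, y, n_rounds = 50L) {
  df <- data.frame(X, .y = y)
  n <- nrow(df); K <- nlevels(y)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric()
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, xval = 0,
                                                       minsplit = 2))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-8) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

adaboost_predict <- function(model, X) {
  votes <- matrix(0, nrow(X), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (i in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[i]], data.frame(X), type = "class")
    votes[cbind(seq_len(nrow(X)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(X)), as.integer(pred))] + model$alphas[i]
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}

macro_precision_f1 <- function(truth, pred) {
  lev <- levels(truth)
  prec <- rec <- f1 <- numeric(length(lev))
  for (i in seq_along(lev)) {
    tp <- sum(pred == lev[i] & truth == lev[i])
    prec[i] <- if (sum(pred == lev[i]) > 0) tp / sum(pred == lev[i]) else 0
    rec[i] <- if (sum(truth == lev[i]) > 0) tp / sum(truth == lev[i]) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  c(precision = mean(prec), f1 = mean(f1))
}

fit_family <- function(family, Xtr, ytr, seed) {
  local_seed(seed, switch(family,
    knn = list(kind = "knn", X = Xtr, y = ytr),
    decision_tree = list(kind = "rpart",
                         fit = rpart::rpart(.y ~ ., data.frame(Xtr, .y = ytr),
                                            method = "class")),
    random_forest = list(kind = "rf",
                         fit = randomForest::randomForest(Xtr, ytr,
                                                          ntree = 100L)),
    svm = list(kind = "svm", fit = e1071::svm(Xtr, ytr, kernel = "radial",
                                              probability = FALSE)),
    gaussian_nb = list(kind = "nb", fit = e1071::naiveBayes(Xtr, ytr)),
    gradient_boosting = {
      num_class <- nlevels(ytr)
      dtr <- xgboost::xgb.DMatrix(as.matrix(Xtr),
                                  label = as.integer(ytr) - 1L)
      prm <- if (num_class > 2L)
        list(objective = "multi:softmax", num_class = num_class,
             max_depth = 3, eta = 0.3, nthread = 1)
      else list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                nthread = 1)
      list(kind = "xgb",
           fit = xgboost::xgb.train(prm, dtr, nrounds = 50L),
           levels = levels(ytr), multi = num_class > 2L)
    },
    adaboost = list(kind = "ada", fit = adaboost_fit(Xtr, ytr)),
    mlp = list(kind = "mlp",
               fit = nnet::nnet(Xtr, stats::model.matrix(~ ytr - 1),
                                size = 8, decay = 0.01, maxit = 200,
                                softmax = TRUE, trace = FALSE),
               levels = levels(ytr)),
    stop("unknown family: ", family)))
}

predict_family <- function(model, Xte) {
  switch(model$kind,
    knn = class::knn(model$X, Xte, model$y, k = 5),
    rpart = predict(model$fit, data.frame(Xte), type = "class"),
    rf = predict(model$fit, Xte),
    svm = predict(model$fit, Xte),
    nb = predict(model$fit, Xte),
    xgb = {
      pr <- predict(model$fit, xgboost::xgb.DMatrix(as.matrix(Xte)))
      idx <- if (model$multi) as.integer(pr) + 1L else as.integer(pr > 0.5) + 1L
      factor(model$levels[idx], levels = model$levels)
    },
    ada = adaboost_predict(model$fit, Xte),
    mlp = {
      pr <- predict(model$fit, Xte)
      factor(model$levels[max.col(pr, ties.method = "first")],
             levels = model$levels)
    })
}

#' Compare the eight classifier families on a feature table
#'
#' Trains k-nearest neighbors, decision tree, random forest, SVM, Gaussian
#' naive Bayes, gradient boosting, AdaBoost and a multilayer perceptron on
#' a seeded stratified 80:20 split, after optional preprocessing (outlier
#' filtering of the training rows or k-means discretization of all rows).
#' Reports macro precision, macro F1 and decision (prediction) time per
#' family, and the top-3 ranking by precision then F1. Decision time is
#' informational and excluded from determinism guarantees.
#'
#' @param table numeric feature data.frame.
#' @param labels class labels (>= 2 classes).
#' @param preprocessing "none", "outlier:isolation_forest",
#'   "outlier:elliptic_envelope", or "discretize".
#' @param contamination for outlier preprocessing.
#' @param n_bins for discretization.
#' @param seed integer seed.
#' @return object of class \code{harness_result}: \code{results} data.frame
#'   (model, precision, f1, decision_time), \code{ranking}, \code{top3}.
#' @export
compare_classifiers <- function(table, labels, preprocessing = "none",
                                contamination = 0.05, n_bins = 5L,
                                seed = 42L) {
  X <- as.data.frame(table)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes")
  if (!preprocessing %in% c("none", "outlier:isolation_forest",
                            "outlier:elliptic_envelope", "discretize"))
    stop("unknown preprocessing: ", preprocessing)
  if (preprocessing == "discretize")
    X <- discretize(X, n_bins = n_bins, seed = seed)
  # stratified 80:20 split
  split <- local_seed(seed, {
    te <- unlist(lapply(split(seq_along(y), y), function(idx)
      sample(idx, max(1L, round(0.2 * length(idx))))))
    list(test = sort(te), train = setdiff(seq_along(y), te))
  })
  Xtr <- X[split$train, , drop = FALSE]; ytr <- droplevels(y[split$train])
  Xte <- X[split$test, , drop = FALSE]; yte <- factor(y[split$test],
                                                      levels = levels(ytr))
  if (startsWith(preprocessing, "outlier:")) {
    keep <- outlier_filter(Xtr, sub("outlier:", "", preprocessing),
                           contamination, seed)
    Xtr <- Xtr[keep, , drop = FALSE]; ytr <- droplevels(ytr[keep])
  }
  fams <- classifier_families()
  rows <- list()
  for (fm in fams) {
    model <- fit_family(fm, Xtr, ytr, seed)
    t0 <- proc.time()[["elapsed"]]
    pred <- predict_family(model, Xte)
    dt <- proc.time()[["elapsed"]] - t0
    pred <- factor(as.character(pred), levels = levels(ytr))
    mp <- macro_precision_f1(factor(as.character(yte), levels = levels(ytr)),
                             pred)
    rows[[fm]] <- data.frame(model = fm, precision = mp[["precision"]],
                             f1 = mp[["f1"]], decision_time = dt)
  }
  res <- do.call(rbind, rows); rownames(res) <- NULL
  ranking <- res[order(-res$precision, -res$f1, res$model), ]
  structure(list(results = res, ranking = ranking,
                 top3 = utils::head(ranking$model, 3L), seed = seed),
            class = "harness_result")
}

#' Generate the diagnostic report stage
#'
#' Fits the three report-stage ensemble models (random forest and gradient
#' boosting with 100 estimators, plus a single decision tree) on the feature
#' table, measures held-out precision/F1 for each, records the empirical
#' mean per-tree misclassification rate of the random forest on held-out
#' data, and summarizes RBC anomaly counts (all 15 labels, zero-filled) and
#' WBC activity flags.
#'
#' @param anomaly_calls list/data.frame of RBC anomaly calls (labels).
#' @param table feature table for the ensemble models.
#' @param labels class labels aligned with \code{table}.
#' @param wbc_flags optional logical vector of WBC anomaly flags.
#' @param seed integer seed.
#' @param path optional output path for the JSON report.
#' @return report list (also written when \code{path} given).
#' @export
generate_report <- function(anomaly_calls, table, labels, wbc_flags = NULL,
                            seed = 42L, path = NULL) {
  if (is.null(table) || nrow(as.data.frame(table)) == 0L)
    stop("empty input: no cells to report on")
  X <- as.data.frame(table)
  y <- factor(labels)
  split <- local_seed(seed, {
    te <- unlist(lapply(split(seq_along(y), y), function(idx)
      sample(idx, max(1L, round(0.2 * length(idx))))))
    list(test = sort(te), train = setdiff(seq_along(y), te))
  })
  Xtr <- X[split$train, , drop = FALSE]; ytr <- droplevels(y[split$train])
  Xte <- X[split$test, , drop = FALSE]
  yte <- factor(as.character(y[split$test]), levels = levels(ytr))
  metrics <- list()
  rf <- local_seed(seed, randomForest::randomForest(Xtr, ytr, ntree = 100L))
  pr <- predict(rf, Xte)
  metrics$random_forest <- as.list(macro_precision_f1(yte, pr))
  # empirical ensemble loss: mean over trees of the misclassification rate
  all_tr <- predict(rf, Xte, predict.all = TRUE)$individual
  metrics$random_forest$ensemble_misclassification <-
    mean(all_tr != matrix(as.character(yte), nrow(all_tr), ncol(all_tr)))
  dt <- local_seed(seed, rpart::rpart(.y ~ ., data.frame(Xtr, .y = ytr),
                                      method = "class"))
  metrics$decision_tree <-
    as.list(macro_precision_f1(yte, predict(dt, data.frame(Xte),
                                            type = "class")))
  gbm <- local_seed(seed, {
    num_class <- nlevels(ytr)
    dtr <- xgboost::xgb.DMatrix(as.matrix(Xtr), label = as.integer(ytr) - 1L)
    prm <- if (num_class > 2L)
      list(objective = "multi:softmax", num_class = num_class,
           max_depth = 3, eta = 0.3, nthread = 1)
    else list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
              nthread = 1)
    list(kind = "xgb", fit = xgboost::xgb.train(prm, dtr, nrounds = 100L),
         levels = levels(ytr), multi = num_class > 2L)
  })
  metrics$gradient_boosting <-
    as.list(macro_precision_f1(yte, predict_family(gbm, Xte)))
  # anomaly label counts, zero-filled over the full taxonomy
  labs <- if (is.null(anomaly_calls)) character() else
    if (is.data.frame(anomaly_calls)) anomaly_calls$label else
      vapply(anomaly_calls, function(a) a$label, character(1))
  counts <- as.list(table(factor(labs, levels = rbc_archetypes())))
  report <- list(
    cells = data.frame(label = labs),
    anomalies = if (length(labs)) data.frame(label = labs) else list(),
    metrics = c(metrics, list(
      anomaly_counts = counts,
      wbc_flagged = if (is.null(wbc_flags)) 0L else sum(wbc_flags),
      seed = seed)))
  json <- write_report(report, path)
  out <- list(counts = counts, metrics = metrics,
              wbc_flagged = if (is.null(wbc_flags)) 0L else sum(wbc_flags),
              json = json)
  invisible(out)
}
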