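#' Attribute knowledge base
#'
#' Maps each class (or subclass) name to a 50-long attribute vector in
#' registry order, with a seen/unseen partition. Attribute space equals the
#' descriptor registry, so a class's attribute vector is its prototypical
#' morphometric profile.
#'
#' @param attributes numeric matrix, rows = classes (rownames required),
#'   50 columns in registry order (column names checked when present).
#' @param seen character vector of seen class names (subset of rows).
#' @return object of class \code{attribute_kb}.
#' @export
attribute_kb <- function(attributes, seen) {
  if (is.null(rownames(attributes))) stop("attribute rows must be named")
  if (ncol(attributes) != 50L) stop("attribute vectors must have length 50")
  if (!is.null(colnames(attributes)) &&
      !identical(colnames(attributes), descriptor_names()))
    stop("attribute columns must follow the descriptor registry order")
  if (!all(is.finite(attributes))) stop("non-finite attribute values")
  if (!all(seen %in% rownames(attributes)))
    stop("seen classes missing from the attribute matrix")
  if (length(seen) < 1L) stop("need at least one seen class")
  colnames(attributes) <- descriptor_names()
  structure(list(attributes = attributes, seen = seen,
                 unseen = setdiff(rownames(attributes), seen)),
            class = "attribute_kb")
}

#' Default knowledge base from generator prototypes
#'
#' Builds attribute vectors by rendering one noise-free exemplar of each
#' cell class (and two documented lymphoid/myeloid subclasses as unseen
#' entries) at a fixed seed and measuring its 50 descriptors. Deterministic.
#'
#' @param calibration um/px.
#' @return an \code{attribute_kb} with the 10 schema classes seen and the
#'   subclasses "Lymphocyte T" and "Promyelocyte-N" unseen.
#' @export
default_attribute_kb <- function(calibration = 0.1) {
  proto <- function(name, seed) {
    sc <- render_cell_patch(name, calibration = calibration, seed = seed,
                            jitter = FALSE)
    cl <- sc$cells[[1]]
    as.numeric(extract_descriptors(sc$image, cl$mask, cl$nucleus_mask,
                                   calibration))
  }
  classes <- label_schema()
  base <- t(vapply(classes, function(cl) {
    arch <- if (cl == "rbc") "Normal" else cl
    proto(arch, seed = 1000L + class_id(cl))
  }, numeric(50)))
  # synthetic subclass prototypes: small perturbations of their parents
  lt <- base["lymphocyte", ]
  lt[descriptor_names() == "cell_area"] <- lt[descriptor_names() == "cell_area"] * 0.8
  lt[descriptor_names() == "nuclear_cytoplasmic_ratio"] <-
    lt[descriptor_names() == "nuclear_cytoplasmic_ratio"] * 1.2
  pn <- base["myelocyte", ]
  pn[descriptor_names() == "granularity_index"] <-
    pn[descriptor_names() == "granularity_index"] * 2 + 0.01
  pn[descriptor_names() == "cell_area"] <- pn[descriptor_names() == "cell_area"] * 1.1
  mat <- rbind(base, "Lymphocyte T" = lt, "Promyelocyte-N" = pn)
  colnames(mat) <- descriptor_names()
  attribute_kb(mat, seen = classes)
}

#' Linear compatibility score
#'
#' \code{f(x, y) = (W x)' a_y}: bilinear in the feature vector \code{x} and
#' the class attribute vector \code{a_y}.
#'
#' @param x feature vector of length 50 (a morphometry vector).
#' @param model a \code{compatibility_model} (or a bare 50 x 50 matrix W).
#' @param a_y attribute vector of length 50.
#' @return scalar score.
#' @export
compatibility <- function(x, model, a_y) {
  W <- if (is.matrix(model)) model else model$W
  x <- as.numeric(x); a_y <- as.numeric(a_y)
  if (length(x) != ncol(W) || length(a_y) != nrow(W))
    stop("dimension mismatch with the compatibility matrix")
  sum((W %*% x) * a_y)
}

#' Zero-shot training configuration (semantic embedding defaults)
#' @param learning_rate,batch_size,epochs,dropout,lambda,patience training
#'   hyperparameters; defaults: 0.001, 16, 100, 0.3, 0.01 (L2), 5.
#' @param init \code{"identity"} (default) or \code{"zero"} initialization
#'   of W.
#' @return config list.
#' @export
zsl_config <- function(learning_rate = 0.001, batch_size = 16L,
                       epochs = 100L, dropout = 0.3, lambda = 0.01,
                       patience = 5L, init = c("identity", "zero")) {
  list(learning_rate = learning_rate, batch_size = batch_size,
       epochs = epochs, dropout = dropout, lambda = lambda,
       patience = patience, init = match.arg(init))
}

#' Fit the compatibility model on seen classes
#'
#' Minimizes the mean softmax cross-entropy of \code{f(x, .)} over the seen
#' classes plus an L2 penalty \code{lambda * ||W||^2}, by seeded minibatch
#' Adam with inverted dropout on the input features. Early stopping monitors
#' a held-out 20\% validation split (patience per config); the best-loss W
#' is returned. W starts at the identity by default: feature and attribute
#' space coincide by construction, and gradient updates only span the seen
#' attribute directions, so the identity component is what carries scores
#' for unseen classes orthogonal to the seen ones.
#'
#' @param features n x 50 matrix of morphometry vectors.
#' @param labels character vector of seen-class names.
#' @param kb an \code{\link{attribute_kb}}.
#' @param config from \code{\link{zsl_config}}.
#' @param seed integer seed.
#' @return object of class \code{compatibility_model}: \code{W},
#'   \code{trace} (train/validation loss per epoch), config, kb order.
#' @export
fit_compatibility <- function(features, labels, kb, config = zsl_config(),
                              seed = 42L) {
  features <- as.matrix(features)
  if (ncol(features) != 50L) stop("features must have 50 columns")
  if (!all(labels %in% kb$seen))
    stop("labels outside the knowledge base's seen classes: ",
         paste(setdiff(labels, kb$seen), collapse = ", "))
  if (length(unique(labels)) < 2L) stop("need at least two seen classes")
  A <- kb$attributes[kb$seen, , drop = FALSE]   # S x 50
  yidx <- match(labels, kb$seen)
  n <- nrow(features)
  local_seed(seed, {
    W <- if (config$init == "identity") diag(50) else matrix(0, 50, 50)
    n_val <- max(1L, floor(0.2 * n))
    vidx <- if (n > 1L) sample.int(n, n_val) else integer()
    tidx <- setdiff(seq_len(n), vidx)
    if (length(tidx) == 0L) { tidx <- seq_len(n); vidx <- seq_len(n) }
    ce_loss <- function(W, idx, drop_mask = NULL) {
      X <- features[idx, , drop = FALSE]
      S <- (X %*% t(W)) %*% t(A)           # n x S scores
      S <- S - apply(S, 1, max)
      P <- exp(S) / rowSums(exp(S))
      -mean(log(pmax(P[cbind(seq_along(idx), yidx[idx])], 1e-300))) +
        config$lambda * sum(W^2)
    }
    m <- W * 0; v <- W * 0; t_adam <- 0
    best_W <- W; best_val <- ce_loss(W, vidx)
    wait <- 0L
    trace <- data.frame(epoch = integer(), train = numeric(),
                        validation = numeric())
    if (config$epochs >= 1) for (ep in seq_len(config$epochs)) {
      perm <- sample(tidx)
      for (start in seq(1, length(perm), by = config$batch_size)) {
        bidx <- perm[start:min(start + config$batch_size - 1L, length(perm))]
        X <- features[bidx, , drop = FALSE]
        if (config$dropout > 0) {
          keep <- matrix(stats::runif(length(X)) >= config$dropout,
                         nrow(X), ncol(X))
          X <- X * keep / (1 - config$dropout)
        }
        S <- (X %*% t(W)) %*% t(A)
        S <- S - apply(S, 1, max)
        P <- exp(S) / rowSums(exp(S))
        Tgt <- matrix(0, nrow(X), nrow(A))
        Tgt[cbind(seq_len(nrow(X)), yidx[bidx])] <- 1
        grad <- (t(A) %*% t(P - Tgt) %*% X) / nrow(X) +
          2 * config$lambda * W
        t_adam <- t_adam + 1
        m <- 0.9 * m + 0.1 * grad
        v <- 0.999 * v + 0.001 * grad^2
        W <- W - config$learning_rate *
          (m / (1 - 0.9^t_adam)) / (sqrt(v / (1 - 0.999^t_adam)) + 1e-8)
      }
      tr_l <- ce_loss(W, tidx); va_l <- ce_loss(W, vidx)
      trace <- rbind(trace, data.frame(epoch = ep, train = tr_l,
                                       validation = va_l))
      if (va_l < best_val - 1e-9) {
        best_val <- va_l; best_W <- W; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(W = best_W, trace = trace, config = config,
                   classes = rownames(kb$attributes), seed = seed),
              class = "compatibility_model")
  })
}

#' Rank candidate classes for a feature vector
#'
#' Scores every candidate with \code{\link{compatibility}} and returns them
#' in descending score order; exact ties break by knowledge-base order.
#' Candidates may include classes unseen during fitting.
#'
#' @param x feature vector of length 50 (or n x 50 matrix: a list of
#'   rankings is returned).
#' @param model a fitted \code{compatibility_model} (or matrix W).
#' @param kb the \code{\link{attribute_kb}}.
#' @param candidates nonempty character vector of KB class names.
#' @return data.frame \code{class}, \code{score} sorted by rank (or a list
#'   of them for matrix input).
#' @export
predict_zsl <- function(x, model, kb, candidates = rownames(kb$attributes)) {
  if (length(candidates) == 0L) stop("empty candidate set")
  if (!all(candidates %in% rownames(kb$attributes)))
    stop("candidates missing from the knowledge base")
  if (is.matrix(x) && nrow(x) > 1L)
    return(lapply(seq_len(nrow(x)), function(i)
      predict_zsl(x[i, ], model, kb, candidates)))
  scores <- vapply(candidates, function(cl)
    compatibility(x, model, kb$attributes[cl, ]), numeric(1))
  kbord <- match(candidates, rownames(kb$attributes))
  ord <- order(-scores, kbord)
  data.frame(class = candidates[ord], score = unname(scores[ord]))
}

#' Top-1 accuracy
#'
#' @param predictions character vector of rank-1 classes (or list of
#'   \code{\link{predict_zsl}} rankings).
#' @param truths character vector of true classes, same length.
#' @return fraction of rank-1 matches in [0, 1].
#' @export
top1_accuracy <- function(predictions, truths) {
  if (is.list(predictions) && !is.character(predictions))
    predictions <- vapply(predictions, function(p) p$class[1], character(1))
  if (length(predictions) != length(truths) || length(truths) == 0L)
    stop("predictions and truths must be nonempty and of equal length")
  mean(predictions == truths)
}
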