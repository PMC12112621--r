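#' Standardize pixel intensities
#'
#' \code{x_pre = (x - mean(x)) / sd(x)} with the population standard
#' deviation, giving output mean 0 and population sd 1.
#'
#' @param x numeric array/matrix/vector with positive spread.
#' @return standardized object of the same shape.
#' @export
standardize <- function(x) {
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma < 1e-12) stop("degenerate input: constant intensities")
  (x - mu) / sigma
}

#' Adversarial virtual-staining objective
#'
#' \code{mean(log D(y)) + mean(log(1 - D(G(x)))) + lambda * mean(|G(x) - y|)}
#' with natural logarithms; discriminator outputs are clipped to
#' \code{[eps, 1 - eps]} before the logs. The L1 weight default is 10.
#'
#' @param d_real discriminator outputs on real stained patches, in (0, 1).
#' @param d_fake discriminator outputs on generated patches.
#' @param g_out generated patch(es).
#' @param y real stained patch(es), same shape as \code{g_out}.
#' @param lambda_l1 L1 reconstruction weight (>= 0), default 10.
#' @param eps clipping constant.
#' @return scalar objective value.
#' @export
gan_objective <- function(d_real, d_fake, g_out, y, lambda_l1 = 10,
                          eps = 1e-12) {
  if (lambda_l1 < 0) stop("lambda_l1 must be >= 0")
  if (!identical(dim(g_out) %||% length(g_out), dim(y) %||% length(y)))
    stop("shape mismatch between g_out and y")
  dr <- clamp(d_real, eps, 1 - eps)
  df <- clamp(d_fake, eps, 1 - eps)
  mean(log(dr)) + mean(log(1 - df)) + lambda_l1 * mean(abs(g_out - y))
}

#' Pixel-wise transformation loss
#'
#' Mean absolute per-pixel difference \code{mean(|G(x) - y|)}; non-negative
#' and zero iff the patches are equal.
#'
#' @param g_out,y arrays of identical dimensions.
#' @return scalar loss.
#' @export
transform_loss <- function(g_out, y) {
  if (!identical(dim(g_out) %||% length(g_out), dim(y) %||% length(y)))
    stop("shape mismatch between g_out and y")
  mean(abs(g_out - y))
}

#' Virtual-staining training configuration
#'
#' @param lambda_l1 adversarial/L1 balance (default 10).
#' @param learning_rate Adam step size (default 2e-4).
#' @param batch_size pixel minibatch size per generator step (default 32
#'   patches' worth is emulated with \code{batch_size * 8} pixel samples).
#' @param epochs training epochs (default 100; desk-scale runs override).
#' @param hidden hidden width of the per-pixel generator (default 8).
#' @param steps_per_epoch generator steps per epoch (default 100).
#' @return config list.
#' @export
stain_config <- function(lambda_l1 = 10, learning_rate = 2e-4,
                         batch_size = 32L, epochs = 100L, hidden = 8L,
                         steps_per_epoch = 100L) {
  if (lambda_l1 < 0) stop("lambda_l1 must be >= 0")
  list(lambda_l1 = lambda_l1, learning_rate = learning_rate,
       batch_size = batch_size, epochs = epochs, hidden = hidden,
       steps_per_epoch = steps_per_epoch)
}

# forward pass of the per-pixel colorization generator: 1 -> hidden -> 3
gen_forward <- function(par, x) {
  h <- tanh(outer(x, par$w1) + matrix(par$b1, length(x), length(par$b1),
                                      byrow = TRUE))
  h %*% par$w2 + matrix(par$b2, nrow(h), 3, byrow = TRUE)
}

disc_stats <- function(patch3) {
  c(apply(patch3, 3, mean), apply(patch3, 3, stats::sd))
}

#' Train a desk-scale virtual stainer
#'
#' Adversarial training of a small per-pixel colorization generator (a
#' 1-hidden-layer tone-mapping network applied at every pixel, i.e. a 1x1
#' convolutional generator) against a logistic patch discriminator over
#' channel statistics, under \code{\link{gan_objective}}. Adam updates; data
#' order, initialization and dropout are seeded, so loss traces are
#' reproducible.
#'
#' @param pairs list of \code{list(x = grayscale matrix, y = stained array
#'   (w, h, 3))} with matching spatial dims.
#' @param config from \code{\link{stain_config}}.
#' @param seed integer seed.
#' @return object of class \code{virtual_stainer}: parameters, per-epoch
#'   \code{trace} (training transform loss), config.
#' @export
train_virtual_stainer <- function(pairs, config = stain_config(), seed = 1L) {
  if (length(pairs) == 0L) stop("need at least one paired patch")
  for (p in pairs)
    if (!identical(dim(p$x), dim(p$y)[1:2]))
      stop("mismatched pair dimensions")
  xs <- unlist(lapply(pairs, function(p) as.vector(p$x)))
  ys <- do.call(rbind, lapply(pairs, function(p)
    cbind(as.vector(p$y[, , 1]), as.vector(p$y[, , 2]),
          as.vector(p$y[, , 3]))))
  H <- config$hidden
  local_seed(seed, {
    par <- list(w1 = stats::rnorm(H, 0, 0.5), b1 = stats::rnorm(H, 0, 0.1),
                w2 = matrix(stats::rnorm(H * 3, 0, 0.3), H, 3),
                b2 = rep(0.5, 3))
    dw <- stats::rnorm(6, 0, 0.1); db <- 0
    m <- lapply(par, function(z) z * 0); v <- lapply(par, function(z) z * 0)
    t_adam <- 0
    lr <- config$learning_rate; lam <- config$lambda_l1
    bsz <- max(64L, config$batch_size * 8L)
    trace <- numeric(0)
    init_loss <- transform_loss(gen_forward(par, xs), ys)
    if (config$epochs >= 1) for (ep in seq_len(config$epochs)) {
      # --- discriminator step: logistic regression on channel statistics
      gpred <- gen_forward(par, xs)
      real_s <- t(vapply(pairs, function(p) disc_stats(p$y), numeric(6)))
      off <- 0L
      fake_s <- matrix(0, length(pairs), 6)
      for (pi in seq_along(pairs)) {
        npx <- length(pairs[[pi]]$x)
        blk <- gpred[(off + 1):(off + npx), , drop = FALSE]
        fake_s[pi, ] <- c(colMeans(blk), apply(blk, 2, stats::sd))
        off <- off + npx
      }
      X <- rbind(real_s, fake_s)
      lab <- c(rep(1, nrow(real_s)), rep(0, nrow(fake_s)))
      pr <- 1 / (1 + exp(-(X %*% dw + db)))
      gw <- crossprod(X, lab - pr) / nrow(X)
      dw <- dw + 0.05 * as.vector(gw)
      db <- db + 0.05 * mean(lab - pr)
      # --- generator steps: lambda * L1 + non-saturating adversarial term
      for (s in seq_len(config$steps_per_epoch)) {
        idx <- sample.int(length(xs), min(bsz, length(xs)))
        xb <- xs[idx]; yb <- ys[idx, , drop = FALSE]
        hb <- tanh(outer(xb, par$w1) +
                     matrix(par$b1, length(xb), H, byrow = TRUE))
        gb <- hb %*% par$w2 + matrix(par$b2, length(xb), 3, byrow = TRUE)
        # dL/dG: L1 subgradient + adversarial push through the mean stats
        dfake <- as.numeric(1 / (1 + exp(-(disc_stats(
          array(gb, c(nrow(gb), 1, 3))) %*% dw + db))))
        dG <- lam * sign(gb - yb) / length(gb) -
          (1 - dfake) * matrix(dw[1:3] / length(xb), length(xb), 3,
                               byrow = TRUE)
        g_w2 <- crossprod(hb, dG)
        g_b2 <- colSums(dG)
        dH <- (dG %*% t(par$w2)) * (1 - hb^2)
        g_w1 <- as.vector(crossprod(dH, xb))
        g_b1 <- colSums(dH)
        grads <- list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
        t_adam <- t_adam + 1
        for (nm in names(par)) {
          m[[nm]] <- 0.9 * m[[nm]] + 0.1 * grads[[nm]]
          v[[nm]] <- 0.999 * v[[nm]] + 0.001 * grads[[nm]]^2
          mh <- m[[nm]] / (1 - 0.9^t_adam)
          vh <- v[[nm]] / (1 - 0.999^t_adam)
          par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
        }
      }
      trace <- c(trace, transform_loss(gen_forward(par, xs), ys))
    }
    structure(list(par = par, disc = list(w = dw, b = db),
                   trace = c(initial = init_loss, trace), config = config,
                   seed = seed),
              class = "virtual_stainer")
  })
}

#' Apply a trained virtual stainer
#'
#' @param model a \code{virtual_stainer}.
#' @param x grayscale matrix.
#' @return stained array (w, h, 3), clipped to [0, 1].
#' @export
predict_stain <- function(model, x) {
  g <- gen_forward(model$par, as.vector(x))
  array(clamp(g), dim = c(dim(x), 3L))
}
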