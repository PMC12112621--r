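# Shared fixtures, all generated in code at test time.

# Linearly separable two-class feature table.
separable_table <- function(n = 120L, seed = 7L, gap = 4) {
  set.seed(seed)
  y <- rep(c("normal", "abnormal"), each = n %/% 2L)
  X <- data.frame(a = stats::rnorm(n, ifelse(y == "normal", 0, gap)),
                  b = stats::rnorm(n, ifelse(y == "normal", 0, gap)),
                  c = stats::rnorm(n), d = stats::rnorm(n))
  list(X = X, y = y)
}

# Orthogonal attribute KB with `seen` seen classes and `unseen` held out.
orthogonal_kb <- function(n_seen = 4L, n_unseen = 2L) {
  K <- n_seen + n_unseen
  A <- matrix(0, K, 50)
  for (i in seq_len(K)) A[i, i] <- 1
  rownames(A) <- paste0("C", seq_len(K))
  colnames(A) <- descriptor_names()
  attribute_kb(A, seen = paste0("C", seq_len(n_seen)))
}

# Features drawn at the attribute vectors plus isotropic noise.
kb_features <- function(kb, classes, n, sigma = 0.05, seed = 42L) {
  set.seed(seed)
  lab <- sample(classes, n, replace = TRUE)
  X <- kb$attributes[lab, , drop = FALSE] +
    matrix(stats::rnorm(n * 50, 0, sigma), n)
  list(X = X, labels = lab)
}

# Deterministic synthetic colormap stain pairs: y_c = alpha_c x + beta_c.
colormap_pairs <- function(n, seed = 1L, side = 32L) {
  set.seed(seed)
  al <- c(0.8, 0.5, 0.3); be <- c(0.1, 0.2, 0.05)
  replicate(n, {
    x <- matrix(stats::runif(side * side), side)
    y <- array(0, c(side, side, 3))
    for (ch in 1:3) y[, , ch] <- al[ch] * x + be[ch]
    list(x = x, y = y)
  }, simplify = FALSE)
}

# A rendered disk mask of radius r px centered in an n x n patch.
disk_mask <- function(r, n = 2L * r + 21L) {
  c0 <- (n + 1) / 2
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  m <- matrix(0, n, n)
  m[sqrt((xy$x - c0)^2 + (xy$y - c0)^2) <= r] <- 1
  m
}
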