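#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans mahalanobis median quantile rnorm runif sd t.test var predict setNames binomial coef
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# route through this so that seeds never leak between stages.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Rec. 601 luma of a width x height x 3 array (or pass-through for matrices).
luminance <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Tight pixel bounding box of a logical mask, as (x, y, w, h) with x, y the
# 0-based top-left pixel index (x along dim 1 = image width).
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  x0 <- min(idx[, 1]); x1 <- max(idx[, 1])
  y0 <- min(idx[, 2]); y1 <- max(idx[, 2])
  c(x = x0 - 1L, y = y0 - 1L, w = x1 - x0 + 1L, h = y1 - y0 + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
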