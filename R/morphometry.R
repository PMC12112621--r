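#' Ellipse eccentricity
#'
#' \code{e = sqrt(1 - (b/a)^2)} for semi-major axis \code{a} and semi-minor
#' axis \code{b}: 0 for a circle, 1 for a degenerate segment. Strictly
#' increasing in the axis ratio \code{a/b}.
#'
#' @param a semi-major axis (> 0).
#' @param b semi-minor axis (0 <= b <= a).
#' @return eccentricity in \code{[0, 1]}.
#' @examples
#' eccentricity(2, 1)   # sqrt(3)/2
#' @export
eccentricity <- function(a, b) {
  if (any(a <= 0)) stop("semi-major axis must be positive")
  if (any(b < 0) || any(a < b)) stop("require a >= b >= 0")
  sqrt(1 - (b / a)^2)
}

#' Isoperimetric circularity
#'
#' \code{4 * pi * area / perimeter^2}; 1 for an ideal circle, below 1 for any
#' other simple shape (up to discretization tolerance on rasterized masks).
#'
#' @param area enclosed area (> 0).
#' @param perimeter boundary length (> 0), same length unit squared for area.
#' @return circularity value.
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

# ---- mask geometry helpers ------------------------------------------------

# Sub-pixel outer contour of a binary mask via marching squares
# (grDevices::contourLines at level 0.5) with a 5-point circular
# moving-average smoothing of the vertices. Returns list(x, y) of the closed
# polygon (longest contour), in pixel coordinates.
mask_contour <- function(mask, smooth = 5L) {
  m <- matrix(0, nrow(mask) + 4L, ncol(mask) + 4L)
  m[3:(nrow(mask) + 2L), 3:(ncol(mask) + 2L)] <- (mask != 0) + 0
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  if (length(cl) == 0L) stop("mask is empty")
  lens <- vapply(cl, function(cc) length(cc$x), numeric(1))
  cc <- cl[[which.max(lens)]]
  x <- cc$x - 2; y <- cc$y - 2
  n <- length(x)
  if (n >= smooth && smooth > 1L) {
    # closed-curve moving average
    k <- smooth %/% 2L
    idx <- outer(seq_len(n), -k:k, "+")
    idx <- (idx - 1L) %% n + 1L
    x <- rowMeans(matrix(x[idx], n))
    y <- rowMeans(matrix(y[idx], n))
  }
  list(x = x, y = y)
}

poly_length <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# Perimeter of a binary mask (pixels) from the smoothed marching-squares
# contour. Validated to within ~1% of the true perimeter on digital disks.
mask_perimeter <- function(mask) {
  cc <- mask_contour(mask)
  poly_length(cc$x, cc$y)
}

# Central-moment ellipse of a mask: centroid, semi-axes (a >= b), orientation
# and eccentricity. Semi-axes are those of the solid ellipse with matching
# second moments: a = 2*sqrt(lambda1).
mask_moments <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  u <- idx[, 1] - cx; v <- idx[, 2] - cy
  n <- nrow(idx)
  # + 1/12 for the pixel's own spread (exact for axis-aligned unit pixels)
  mxx <- sum(u * u) / n + 1 / 12
  myy <- sum(v * v) / n + 1 / 12
  mxy <- sum(u * v) / n
  tr <- mxx + myy; det <- mxx * myy - mxy * mxy
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
  l2 <- max(l2, 1e-12)
  theta <- 0.5 * atan2(2 * mxy, mxx - myy)
  list(cx = cx, cy = cy, a = 2 * sqrt(l1), b = 2 * sqrt(l2),
       theta = theta, eccentricity = sqrt(max(0, 1 - l2 / l1)), n = n)
}

shoelace_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Convex hull of mask pixel centers (+/- 0.5 padding via corner points).
mask_convex_hull <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  # use pixel corners so hull area covers full pixels
  px <- c(idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5)
  py <- c(idx[, 2] - 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] + 0.5)
  h <- grDevices::chull(px, py)
  list(x = px[h], y = py[h])
}

# Maximum and minimum Feret diameters from the convex hull
# (min via rotating-calipers width over hull edge orientations).
feret_diameters <- function(hull) {
  x <- hull$x; y <- hull$y; n <- length(x)
  if (n == 1L) return(c(max = 1, min = 1))
  dmax <- 0
  for (i in seq_len(n - 1L)) {
    d <- sqrt((x[(i + 1L):n] - x[i])^2 + (y[(i + 1L):n] - y[i])^2)
    dmax <- max(dmax, d)
  }
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- x[j] - x[i]; ey <- y[j] - y[i]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    # width perpendicular to this edge
    proj <- (-(ey) * x + ex * y) / len
    dmin <- min(dmin, diff(range(proj)))
  }
  c(max = dmax, min = if (is.finite(dmin)) dmin else dmax)
}

# Gray-level co-occurrence matrix statistics (32 levels, symmetric,
# horizontal + vertical offsets averaged) restricted to a mask.
glcm_stats <- function(gray, mask, levels = 32L) {
  vals <- gray[mask != 0]
  if (length(vals) == 0L) stop("mask is empty")
  rng <- range(vals)
  q <- if (diff(rng) < 1e-12) rep(1L, length(gray)) else
    pmin(levels, 1L + floor((gray - rng[1]) / (diff(rng) + 1e-12) * levels))
  q <- matrix(as.integer(q), nrow(gray), ncol(gray))
  nx <- nrow(q); ny <- ncol(q)
  inm <- mask != 0
  cooc <- matrix(0, levels, levels)
  # horizontal pairs
  a <- q[-nx, ]; b <- q[-1, ]; ok <- inm[-nx, ] & inm[-1, ]
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = 1:levels), factor(b[ok], levels = 1:levels))
    cooc <- cooc + tab + t(tab)
  }
  a <- q[, -ny]; b <- q[, -1]; ok <- inm[, -ny] & inm[, -1]
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = 1:levels), factor(b[ok], levels = 1:levels))
    cooc <- cooc + tab + t(tab)
  }
  s <- sum(cooc)
  if (s == 0) cooc[1, 1] <- s <- 1
  p <- cooc / s
  i <- row(p); j <- col(p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  pos <- p > 0
  corr <- if (sd_i < 1e-12 || sd_j < 1e-12) 0 else
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  list(entropy = -sum(p[pos] * log2(p[pos])),
       contrast = sum((i - j)^2 * p),
       correlation = corr,
       energy = sum(p^2),
       homogeneity = sum(p / (1 + abs(i - j))))
}

# Simple central-difference gradient magnitude of a matrix.
gradient_magnitude <- function(g) {
  nx <- nrow(g); ny <- ncol(g)
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (g[3:nx, ] - g[1:(nx - 2), ]) / 2
  gy[, 2:(ny - 1)] <- (g[, 3:ny] - g[, 1:(ny - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

erode1 <- function(mask) {
  m <- (mask != 0) + 0
  EBImage::imageData(EBImage::erode(EBImage::Image(m),
                                    EBImage::makeBrush(3, "box"))) != 0
}

# ---- main extractor -------------------------------------------------------

#' Extract the 50-descriptor morphometric vector of a cell
#'
#' Computes every descriptor of \code{\link{descriptor_registry}} from a
#' cell's image patch, binary mask and (optional) nucleus mask. Geometry uses
#' central-moment ellipse axes and a smoothed marching-squares sub-pixel
#' contour for perimeters; texture uses 32-level co-occurrence statistics
#' within the mask; physical units come from the calibration.
#'
#' Auxiliary measurements consumed by the anomaly rule engine (central pallor
#' eccentricity, radial intensity inversions, inclusion geometry, interior
#' intensity) are attached as the \code{aux} attribute.
#'
#' @param image array (width, height, 3) in \code{[0,1]} (a matrix is treated
#'   as grayscale).
#' @param cell_mask logical/0-1 matrix, nonempty, same spatial dims.
#' @param nucleus_mask optional nucleus mask, subset of \code{cell_mask};
#'   when NULL, a nucleus is segmented by Otsu thresholding of the
#'   dominant-stain (blue-excess) channel within the cell, and treated as
#'   absent if it covers under 5\% of the cell.
#' @param calibration a \code{\link{calibration}} object or scalar um/px.
#' @param pallor_delta luminance excess over the interior median defining
#'   central pallor pixels (default 0.06).
#' @param inclusion_delta luminance deficit under the interior median
#'   defining inclusion pixels (default 0.18).
#' @return Named numeric vector of length 50 (class
#'   \code{morphometry_vector}) with attribute \code{aux}.
#' @export
extract_descriptors <- function(image, cell_mask, nucleus_mask = NULL,
                                calibration = 0.1, pallor_delta = 0.06,
                                inclusion_delta = 0.18) {
  u <- mpp(calibration)
  if (length(dim(image)) == 2L)
    image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  mask <- cell_mask != 0
  if (!any(mask)) stop("empty mask")
  if (!is.null(nucleus_mask)) {
    nucleus_mask <- nucleus_mask != 0
    if (any(nucleus_mask & !mask)) stop("nucleus mask outside cell mask")
  }
  gray <- luminance(image)

  # --- cell geometry
  area_px <- sum(mask)
  per_px <- mask_perimeter(mask)
  mom <- mask_moments(mask)
  hull <- mask_convex_hull(mask)
  hull_area_px <- shoelace_area(hull$x, hull$y)
  hull_per_px <- poly_length(hull$x, hull$y)
  fer <- feret_diameters(hull)
  area <- area_px * u^2
  per <- per_px * u
  circ <- circularity(area, per)
  a_um <- mom$a * u; b_um <- mom$b * u

  # --- nucleus
  if (is.null(nucleus_mask)) {
    # basophilic nuclei are the dark-stained compartment: Otsu on darkness
    # within the cell, gated so that a moderately dark cytoplasm is not
    # mistaken for a nucleus
    dark <- 1 - gray
    sv <- dark[mask]
    if (diff(range(sv)) > 1e-6) {
      thr <- EBImage::otsu(matrix(sv, ncol = 1),
                           range = range(sv) + c(-1e-6, 1e-6))
      nucleus_mask <- mask & dark > thr
      if (sum(nucleus_mask) < 0.05 * area_px ||
          mean(gray[nucleus_mask]) > 0.5)
        nucleus_mask <- mask & FALSE
    } else nucleus_mask <- mask & FALSE
  }
  has_nuc <- any(nucleus_mask)
  if (has_nuc) {
    n_area_px <- sum(nucleus_mask)
    n_per_px <- mask_perimeter(nucleus_mask)
    n_mom <- mask_moments(nucleus_mask)
    n_area <- n_area_px * u^2
    n_per <- n_per_px * u
    n_circ <- circularity(n_area, n_per)
    n_ecc <- n_mom$eccentricity
    n_shape <- n_mom$a / n_mom$b
    n_hull <- mask_convex_hull(nucleus_mask)
    n_solidity <- n_area_px / max(shoelace_area(n_hull$x, n_hull$y), 1)
    er <- erode1(nucleus_mask)
    lobes <- if (any(er)) max(EBImage::bwlabel(EBImage::Image(er + 0))) else 1
    chromatin <- mean(1 - gray[nucleus_mask])
    n_tex_var <- var(gray[nucleus_mask])
    if (!is.finite(n_tex_var)) n_tex_var <- 0
    n_vol <- 4 / 3 * pi * (n_mom$a * u) * (n_mom$b * u)^2
  } else {
    n_area <- n_per <- n_circ <- n_ecc <- n_shape <- 0
    n_solidity <- 0; lobes <- 0; chromatin <- 0; n_tex_var <- 0; n_vol <- 0
    nucleus_mask <- mask & FALSE
  }
  cyto_mask <- mask & !nucleus_mask
  cyto_area <- sum(cyto_mask) * u^2

  # --- symmetry: overlap with 180-degree rotation about the centroid
  idx <- which(mask, arr.ind = TRUE)
  rx <- round(2 * mom$cx - idx[, 1]); ry <- round(2 * mom$cy - idx[, 2])
  ok <- rx >= 1 & rx <= nrow(mask) & ry >= 1 & ry <= ncol(mask)
  symmetry <- sum(mask[cbind(rx[ok], ry[ok])]) / nrow(idx)

  # --- texture
  tex <- glcm_stats(gray, mask)
  grad <- gradient_magnitude(gray)
  interior <- erode1(mask)
  boundary <- mask & !interior
  edge_gradient <- if (any(boundary)) mean(grad[boundary]) else 0
  membrane <- if (any(boundary)) mean(grad[boundary] > 0.05) else 0
  roughness <- per_px / max(hull_per_px, 1e-9)
  if (has_nuc) {
    ring <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(nucleus_mask + 0), EBImage::makeBrush(5, "disc"))) != 0
    ring <- ring & cyto_mask
    nec <- if (any(ring)) abs(mean(gray[ring]) - mean(gray[nucleus_mask])) else 0
  } else nec <- 0

  # --- color
  rv <- image[, , 1][mask]; gv <- image[, , 2][mask]; bv <- image[, , 3][mask]
  hsv <- grDevices::rgb2hsv(rbind(rv, gv, bv) * 255, maxColorValue = 255)

  # --- specialized + aux
  med_int <- median(gray[mask])
  lap <- matrix(0, nrow(gray), ncol(gray))
  nx <- nrow(gray); ny <- ncol(gray)
  lap[2:(nx - 1), 2:(ny - 1)] <- gray[1:(nx - 2), 2:(ny - 1)] +
    gray[3:nx, 2:(ny - 1)] + gray[2:(nx - 1), 1:(ny - 2)] +
    gray[2:(nx - 1), 3:ny] - 4 * gray[2:(nx - 1), 2:(ny - 1)]
  gran <- if (any(cyto_mask)) var(lap[cyto_mask]) else 0
  if (!is.finite(gran)) gran <- 0
  cyto_energy <- if (sum(cyto_mask) > 4) glcm_stats(gray, cyto_mask)$energy else 1

  # pallor: bright interior components whose centroid lies in the central
  # region of the cell (rim highlights are not pallor)
  r_eq <- sqrt(area_px / pi)
  pall_px <- interior & gray > med_int + pallor_delta
  pallor_ratio <- 0; pallor_ecc <- 0
  if (any(pall_px)) {
    labm <- matrix(EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(pall_px + 0))), nrow(gray), ncol(gray))
    pm <- matrix(FALSE, nrow(gray), ncol(gray))
    for (id in setdiff(unique(as.vector(labm)), 0)) {
      comp <- labm == id
      if (sum(comp) < 4) next
      cm <- mask_moments(comp)
      if (sqrt((cm$cx - mom$cx)^2 + (cm$cy - mom$cy)^2) < 0.6 * r_eq)
        pm <- pm | comp
    }
    if (sum(pm) >= 4) {
      pallor_ratio <- sum(pm) / area_px
      pallor_ecc <- mask_moments(pm)$eccentricity
    }
  }
  vacuolation <- if (any(cyto_mask))
    mean(gray[cyto_mask] > med_int + pallor_delta) else 0

  # inclusions: dark blobs >= 2 px inside the cell (nucleus excluded)
  incl_px <- cyto_mask & gray < med_int - inclusion_delta
  incl_count <- 0; incl_ecc_max <- 0; incl_peripheral <- 0
  if (any(incl_px)) {
    lab <- EBImage::bwlabel(EBImage::Image(incl_px + 0))
    labm <- matrix(EBImage::imageData(lab), nrow(gray), ncol(gray))
    for (id in setdiff(unique(as.vector(labm)), 0)) {
      comp <- labm == id
      if (sum(comp) < 2) next
      incl_count <- incl_count + 1
      cm <- mask_moments(comp)
      incl_ecc_max <- max(incl_ecc_max, cm$eccentricity)
      dcen <- sqrt((cm$cx - mom$cx)^2 + (cm$cy - mom$cy)^2)
      if (dcen > 0.7 * r_eq) incl_peripheral <- 1
    }
  }

  # radial intensity profile: ring means from center, count significant
  # direction changes (the first significant step counts as one inversion).
  # Measured over the eroded interior: boundary pixels blend with the
  # background under anti-aliasing and would contaminate the outer ring.
  prof_mask <- if (sum(interior) >= 16L) interior else mask
  pidx <- which(prof_mask, arr.ind = TRUE)
  rr <- sqrt((pidx[, 1] - mom$cx)^2 + (pidx[, 2] - mom$cy)^2)
  rmax <- max(rr)
  nring <- 8L
  ring_id <- pmin(nring, 1L + floor(rr / (rmax + 1e-9) * nring))
  ring_mean <- tapply(gray[prof_mask], ring_id, mean)
  dif <- diff(as.numeric(ring_mean))
  sig <- dif[abs(dif) > 0.02]
  inversions <- if (length(sig) == 0) 0 else 1 + sum(diff(sign(sig)) != 0)
  interior_intensity <- mean(gray[if (any(interior)) interior else mask])

  v <- c(
    cell_area = area, cell_perimeter = per, circularity = circ,
    eccentricity = mom$eccentricity,
    nucleus_area = n_area, nucleus_perimeter = n_per,
    nucleus_circularity = n_circ, nucleus_eccentricity = n_ecc,
    cytoplasm_area = cyto_area,
    cytoplasm_thickness = max(0, sqrt(area / pi) - sqrt(n_area / pi)),
    aspect_ratio = mom$a / mom$b, elongation = 1 - mom$b / mom$a,
    compactness = 1 / circ, convex_hull_area = hull_area_px * u^2,
    solidity = area_px / max(hull_area_px, 1),
    feret_diameter = fer[["max"]] * u, min_feret_diameter = fer[["min"]] * u,
    major_axis_length = 2 * a_um, minor_axis_length = 2 * b_um,
    orientation_angle = mom$theta,
    chromatin_density = chromatin, nuclear_shape_factor = n_shape,
    nuclear_cytoplasmic_ratio = if (cyto_area > 0) n_area / cyto_area else 0,
    lobe_count = lobes, nuclear_texture_variance = n_tex_var,
    cell_volume_estimate = 4 / 3 * pi * a_um * b_um^2,
    nuclear_volume_estimate = n_vol,
    symmetry = symmetry, roundness = 4 * area / (pi * (2 * a_um)^2),
    nuclear_solidity = n_solidity,
    texture_entropy = tex$entropy, texture_contrast = tex$contrast,
    texture_correlation = tex$correlation, texture_energy = tex$energy,
    texture_homogeneity = tex$homogeneity, edge_gradient = edge_gradient,
    boundary_roughness = roughness, nuclear_edge_contrast = nec,
    mean_red = mean(rv), mean_green = mean(gv), mean_blue = mean(bv),
    mean_hue = mean(hsv[1, ]), mean_saturation = mean(hsv[2, ]),
    mean_value = mean(hsv[3, ]),
    granularity_index = gran, vacuolation_level = vacuolation,
    inclusion_count = incl_count, membrane_integrity = membrane,
    cytoplasmic_granularity = cyto_energy,
    central_pallor_ratio = pallor_ratio)
  v <- v[descriptor_names()]
  attr(v, "aux") <- list(
    pallor_eccentricity = pallor_ecc, radial_inversions = inversions,
    inclusion_max_eccentricity = incl_ecc_max,
    inclusion_peripheral = incl_peripheral,
    interior_intensity = interior_intensity)
  class(v) <- c("morphometry_vector", "numeric")
  v
}
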