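#' The 15 erythrocyte shape archetypes
#'
#' Names of the shape categories the rule engine can emit, in alphabetical
#' order: Elliptocyte, Fragments, Heinz bodies, Hemoglobin-C, Howell-Jolly,
#' Hyperchromasia, Macrocyte, Microcircle, Normal, Oval, Pencil, Pikilocyte,
#' Spleen, Stomatocyte, Target.
#'
#' @return Character vector of 15 names.
#' @export
rbc_archetypes <- function() {
  c("Elliptocyte", "Fragments", "Heinz bodies", "Hemoglobin-C",
    "Howell-Jolly", "Hyperchromasia", "Macrocyte", "Microcircle", "Normal",
    "Oval", "Pencil", "Pikilocyte", "Spleen", "Stomatocyte", "Target")
}

wbc_classes <- function() {
  c("basophil", "eosinophil", "lymphocyte", "monocyte", "myelocyte",
    "neutrophil")
}

#' Cell specification for the renderer
#'
#' @param archetype one of \code{\link{rbc_archetypes}} (class rbc only), or
#'   NA for non-RBC classes.
#' @param class one of \code{\link{label_schema}}.
#' @param center pixel coordinates c(x, y).
#' @param a_um,b_um semi-major/minor axes in micrometres (a >= b > 0).
#' @param rotation radians.
#' @param pallor_ratio target central-pallor area fraction in [0, 1).
#' @param inclusion_count integer >= 0.
#' @param nucleus_lobes integer >= 0.
#' @param color per-channel means in [0, 1].
#' @return A validated list of class \code{cell_spec}.
#' @export
cell_spec <- function(archetype = NA_character_, class = "rbc",
                      center = c(0, 0), a_um = 3.5, b_um = 3.5,
                      rotation = 0, pallor_ratio = 0.25,
                      inclusion_count = 0L, nucleus_lobes = 0L,
                      color = c(0.80, 0.45, 0.45)) {
  if (!class %in% label_schema()) stop("unknown class: ", class)
  if (!is.na(archetype)) {
    if (!archetype %in% rbc_archetypes())
      stop("unknown archetype: ", archetype)
    if (class != "rbc") stop("RBC archetypes only allowed on class rbc")
  }
  if (!(a_um >= b_um && b_um > 0)) stop("require a_um >= b_um > 0")
  if (pallor_ratio < 0 || pallor_ratio >= 1) stop("pallor_ratio must be in [0,1)")
  if (inclusion_count < 0 || nucleus_lobes < 0) stop("negative count")
  structure(list(archetype = archetype, class = class, center = center,
                 a_um = a_um, b_um = b_um, rotation = rotation,
                 pallor_ratio = pallor_ratio,
                 inclusion_count = as.integer(inclusion_count),
                 nucleus_lobes = as.integer(nucleus_lobes), color = color),
            class = "cell_spec")
}

# Draw jittered rendering parameters for one archetype. Geometry means sit
# at least two rule-margins from every rule threshold (see the methods
# vignette); jitter is small relative to those margins.
archetype_spec <- function(archetype, center = c(0, 0), jitter = TRUE) {
  j <- function(m, s) if (jitter) m + stats::rnorm(1, 0, s) else m
  rot <- if (jitter) stats::runif(1, 0, pi) else 0
  base <- list(center = center, rotation = rot, class = "rbc",
               color = c(0.80, 0.45, 0.45), style = "plain",
               pallor = list(kind = "disc", frac = 0.35, delta = 0.13),
               inclusions = list())
  p <- switch(archetype,
    "Normal" = list(r = j(3.5, 0.1), ab = 1.02),
    "Macrocyte" = list(r = j(4.9, 0.12), ab = 1.02),
    "Microcircle" = list(r = j(2.5, 0.08), ab = 1.02),
    "Elliptocyte" = list(r = j(3.5, 0.1), ab = j(1.42, 0.04)),
    "Oval" = list(r = j(3.5, 0.1), ab = j(1.12, 0.012)),
    "Pencil" = list(r = j(3.4, 0.1), ab = j(3.4, 0.1)),
    "Stomatocyte" = list(r = j(3.5, 0.1), ab = 1.02),
    "Spleen" = list(r = j(3.4, 0.1), ab = 1.02),
    "Hyperchromasia" = list(r = j(3.5, 0.1), ab = 1.02),
    "Target" = list(r = j(3.5, 0.1), ab = 1.02),
    "Howell-Jolly" = list(r = j(3.5, 0.1), ab = 1.02),
    "Heinz bodies" = list(r = j(3.5, 0.1), ab = 1.02),
    "Hemoglobin-C" = list(r = j(3.5, 0.1), ab = 1.02),
    "Fragments" = list(r = j(2.0, 0.08), ab = 1.05),
    "Pikilocyte" = list(r = j(3.5, 0.1), ab = 1.05),
    stop("unknown archetype: ", archetype))
  # semi-axes preserving equivalent radius r: a*b = r^2, a/b = ab
  base$a_um <- p$r * sqrt(p$ab)
  base$b_um <- p$r / sqrt(p$ab)
  # hemoglobin-dense or fragmented forms lack a visible central pallor
  if (archetype %in% c("Spleen", "Hyperchromasia", "Target", "Pencil",
                       "Fragments")) base$pallor <- NULL
  if (archetype == "Hyperchromasia") base$color <- c(0.55, 0.22, 0.25)
  if (archetype == "Stomatocyte")
    base$pallor <- list(kind = "slit", frac = 0.25, delta = 0.13,
                        ecc = j(0.93, 0.005))
  if (archetype == "Target") base$style <- "target"
  if (archetype == "Fragments") base$style <- "star3"
  if (archetype == "Pikilocyte") base$style <- "spiculated"
  if (archetype == "Howell-Jolly")
    base$inclusions <- list(list(r_um = 0.7, at = 0.3, ecc = 0, ang = rot))
  if (archetype == "Heinz bodies")
    base$inclusions <- list(list(r_um = 0.6, at = 0.88, ecc = 0, ang = rot))
  if (archetype == "Hemoglobin-C")
    base$inclusions <- list(list(r_um = 1.0, at = 0, ecc = 0.985, ang = rot))
  base$archetype <- archetype
  base
}

# Parameters for WBC / platelet / intrusion / erythroblast rendering.
nonrbc_spec <- function(class, center = c(0, 0), jitter = TRUE) {
  j <- function(m, s) if (jitter) m + stats::rnorm(1, 0, s) else m
  rot <- if (jitter) stats::runif(1, 0, pi) else 0
  sp <- switch(class,
    lymphocyte = list(r = j(4.5, 0.2), lobes = 1L, nfrac = 0.82,
                      cyto = c(0.70, 0.75, 0.92)),
    monocyte   = list(r = j(7.5, 0.3), lobes = 1L, nfrac = 0.55,
                      cyto = c(0.72, 0.74, 0.90)),
    myelocyte  = list(r = j(7.0, 0.3), lobes = 1L, nfrac = 0.65,
                      cyto = c(0.75, 0.72, 0.90)),
    neutrophil = list(r = j(6.0, 0.25), lobes = 3L, nfrac = 0.45,
                      cyto = c(0.80, 0.76, 0.88)),
    eosinophil = list(r = j(6.0, 0.25), lobes = 2L, nfrac = 0.45,
                      cyto = c(0.88, 0.62, 0.60)),
    basophil   = list(r = j(5.5, 0.25), lobes = 2L, nfrac = 0.5,
                      cyto = c(0.62, 0.55, 0.85)),
    erythroblast = list(r = j(4.2, 0.2), lobes = 1L, nfrac = 0.6,
                        cyto = c(0.82, 0.5, 0.5)),
    platelet   = list(r = j(1.3, 0.1), lobes = 0L, nfrac = 0,
                      cyto = c(0.55, 0.40, 0.70)),
    intrusion  = list(r = j(2.5, 0.4), lobes = 0L, nfrac = 0,
                      cyto = c(0.60, 0.60, 0.62)),
    stop("unsupported class: ", class))
  list(archetype = NA_character_, class = class, center = center,
       rotation = rot, a_um = sp$r * 1.04, b_um = sp$r / 1.04,
       color = sp$cyto, style = "plain", pallor = NULL, inclusions = list(),
       lobes = sp$lobes, nfrac = sp$nfrac)
}

# Render one cell into per-cell layers. Returns list(mask, nucleus_mask,
# color (3-channel delta field), alpha) over the full canvas window.
render_cell_field <- function(sp, nx, ny, u) {
  cx <- sp$center[1]; cy <- sp$center[2]
  a_px <- sp$a_um / u; b_px <- sp$b_um / u
  xs <- seq_len(nx); ys <- seq_len(ny)
  X <- matrix(xs, nx, ny) - cx
  Y <- matrix(ys, nx, ny, byrow = TRUE) - cy
  ct <- cos(sp$rotation); st <- sin(sp$rotation)
  U <- (X * ct + Y * st) / a_px
  V <- (-X * st + Y * ct) / b_px
  r <- sqrt(U^2 + V^2)
  style <- sp$style %||% "plain"
  if (style %in% c("star3", "spiculated")) {
    phi <- atan2(V, U)
    fac <- if (style == "star3") 1 + 0.45 * cos(3 * phi) else
      1 + 0.16 * cos(7 * phi)
    rr <- r / pmax(fac, 0.2)
  } else rr <- r
  mask <- rr <= 1
  edge <- 0.9 / min(a_px, b_px)  # ~1 px anti-aliasing band
  alpha <- clamp((1 - rr) / edge + 0.5)
  col <- array(0, dim = c(nx, ny, 3))
  lum_delta <- matrix(0, nx, ny)
  # central pallor / target profile modulate luminance additively
  if (!is.null(sp$pallor)) {
    pk <- sp$pallor
    if (identical(pk$kind, "slit")) {
      pe <- pk$ecc; ratio <- 1 / sqrt(1 - pe^2)  # a/b of the pallor ellipse
      pa <- sqrt(pk$frac) * sqrt(ratio); pb <- sqrt(pk$frac) / sqrt(ratio)
      pr <- sqrt((U / pa)^2 + (V / pb)^2)
    } else {
      pr <- r / sqrt(pk$frac)
    }
    lum_delta <- lum_delta + pk$delta * clamp((1 - pr) / 0.15 + 0.5)
  }
  if (identical(style, "target")) {
    # dark central spot, bright ring, plain rim: two radial inversions
    lum_delta <- lum_delta - 0.10 * clamp((0.33 - r) / 0.08 + 0.5) +
      0.14 * clamp((0.68 - r) / 0.08 + 0.5) * clamp((r - 0.36) / 0.08 + 0.5)
  }
  nucleus <- matrix(FALSE, nx, ny)
  lobes <- sp$lobes %||% 0L
  if (lobes > 0L) {
    nfrac <- sp$nfrac %||% 0.5
    nr <- sqrt(nfrac)  # nucleus radius fraction of the cell
    if (lobes == 1L) {
      nucleus <- r <= nr
    } else {
      # disjoint lobes so the lobe count is morphologically recoverable
      lr <- nr * 0.40
      off <- nr * 0.55
      for (k in seq_len(lobes)) {
        ang <- sp$rotation + 2 * pi * (k - 1) / lobes
        ox <- off * cos(ang); oy <- off * sin(ang)
        nucleus <- nucleus | sqrt((U - ox)^2 + (V - oy)^2) <= lr
      }
    }
    nucleus <- nucleus & mask
  }
  incl_mask <- matrix(FALSE, nx, ny)
  for (inc in sp$inclusions) {
    ia <- inc$r_um / u / sqrt(1 - inc$ecc^2)^0.5
    ib <- inc$r_um / u * sqrt(1 - inc$ecc^2)^0.5
    # inclusion center at fraction `at` of the mean radius, along rotation
    d <- inc$at * sqrt(a_px * b_px)
    icx <- cx + d * cos(inc$ang); icy <- cy + d * sin(inc$ang)
    ic <- cos(inc$ang); is <- sin(inc$ang)
    IX <- X + cx - icx; IY <- Y + cy - icy
    IU <- (IX * ic + IY * is) / ia
    IV <- (-IX * is + IY * ic) / ib
    incl_mask <- incl_mask | (IU^2 + IV^2 <= 1)
  }
  incl_mask <- incl_mask & mask
  list(mask = mask, alpha = alpha, nucleus = nucleus, incl = incl_mask,
       lum_delta = lum_delta, color = sp$color)
}

smear_background <- function(nx, ny, noise_sd = 0.012) {
  base <- c(0.93, 0.89, 0.91)
  # low-frequency seeded texture: coarse grid, bilinear upscale
  gx <- max(4L, nx %/% 32L); gy <- max(4L, ny %/% 32L)
  coarse <- matrix(stats::rnorm(gx * gy, 0, 0.02), gx, gy)
  fx <- seq(1, gx, length.out = nx); fy <- seq(1, gy, length.out = ny)
  x0 <- pmin(floor(fx), gx - 1L); y0 <- pmin(floor(fy), gy - 1L)
  wx <- fx - x0; wy <- fy - y0
  up <- (coarse[cbind(rep(x0, ny), rep(y0, each = nx))] * (1 - wx) * rep(1 - wy, each = nx) +
         coarse[cbind(rep(x0 + 1L, ny), rep(y0, each = nx))] * wx * rep(1 - wy, each = nx) +
         coarse[cbind(rep(x0, ny), rep(y0 + 1L, each = nx))] * (1 - wx) * rep(wy, each = nx) +
         coarse[cbind(rep(x0 + 1L, ny), rep(y0 + 1L, each = nx))] * wx * rep(wy, each = nx))
  tex <- matrix(up, nx, ny) + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
  img <- array(0, dim = c(nx, ny, 3))
  for (ch in 1:3) img[, , ch] <- clamp(base[ch] + tex)
  img
}

#' Render a synthetic smear image with ground truth
#'
#' Renders each cell as an anti-aliased ellipse-derived shape implementing
#' its archetype (elongation for elliptocytes/pencil forms, central pallor
#' discs or slits, planted dark inclusions, concave fragment polygons,
#' spiculated catch-all forms, lobed nuclei for polymorphonuclear WBCs) on a
#' seeded textured background. Returned masks are pixel-exact and
#' annotations are recomputed from the rendered masks.
#'
#' @param specs list of \code{\link{cell_spec}} objects, or of parameter
#'   lists as produced internally by \code{archetype_spec}.
#' @param image_dims c(width, height) in pixels.
#' @param calibration \code{\link{calibration}} or um/px scalar.
#' @param seed integer seed for background noise (rendering is otherwise
#'   deterministic given the specs).
#' @param max_overlap maximum allowed pairwise mask overlap fraction before
#'   generation fails.
#' @return list with \code{image} (width x height x 3), \code{cells} (list of
#'   \code{mask}, \code{nucleus_mask}, \code{box} (pixel), \code{record}
#'   (normalized), \code{class}, \code{class_id}, \code{archetype}),
#'   \code{annotations} (data.frame of YOLO records), \code{calibration},
#'   \code{seed}.
#' @export
render_smear <- function(specs, image_dims = c(256L, 256L),
                         calibration = 0.1, seed = 1L, max_overlap = 0.15) {
  u <- mpp(calibration)
  nx <- image_dims[1]; ny <- image_dims[2]
  local_seed(seed, {
    img <- smear_background(nx, ny)
    occupied <- matrix(FALSE, nx, ny)
    cells <- list()
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      if (inherits(sp, "cell_spec")) sp <- spec_to_params(sp)
      fld <- render_cell_field(sp, nx, ny, u)
      if (!any(fld$mask)) stop(sprintf("cell %d renders outside the image", i))
      ov <- sum(fld$mask & occupied) / sum(fld$mask)
      if (ov > max_overlap)
        stop(sprintf("cell %d overlaps existing cells by %.0f%% (max %.0f%%)",
                     i, 100 * ov, 100 * max_overlap))
      # composite: body color, luminance modulation, nucleus, inclusions
      a <- fld$alpha
      for (ch in 1:3) {
        layer <- fld$color[ch] + fld$lum_delta
        img[, , ch] <- img[, , ch] * (1 - a) + clamp(layer) * a
      }
      if (any(fld$nucleus)) {
        ncol_ <- c(0.38, 0.22, 0.52)
        for (ch in 1:3) {
          pix <- img[, , ch]; pix[fld$nucleus] <- ncol_[ch]
          img[, , ch] <- pix
        }
      }
      if (any(fld$incl)) {
        icol <- c(0.25, 0.13, 0.33)
        for (ch in 1:3) {
          pix <- img[, , ch]; pix[fld$incl] <- icol[ch]
          img[, , ch] <- pix
        }
      }
      occupied <- occupied | fld$mask
      box <- mask_bbox(fld$mask)
      cells[[i]] <- list(
        mask = fld$mask, nucleus_mask = fld$nucleus, box = box,
        record = normalize_box(box, nx, ny),
        class = sp$class, class_id = class_id(sp$class),
        archetype = sp$archetype)
    }
    ann <- if (length(cells) == 0L)
      data.frame(class_id = integer(), x_center = numeric(),
                 y_center = numeric(), width = numeric(), height = numeric())
    else do.call(rbind, lapply(cells, function(cl)
      data.frame(class_id = cl$class_id, x_center = cl$record[[1]],
                 y_center = cl$record[[2]], width = cl$record[[3]],
                 height = cl$record[[4]])))
    list(image = img, cells = cells, annotations = ann,
         calibration = calibration(u), seed = seed)
  })
}

# Map a user-facing cell_spec to renderer parameters.
spec_to_params <- function(s) {
  list(archetype = s$archetype, class = s$class, center = s$center,
       rotation = s$rotation, a_um = s$a_um, b_um = s$b_um, color = s$color,
       style = "plain",
       pallor = if (s$pallor_ratio > 0)
         list(kind = "disc", frac = s$pallor_ratio, delta = 0.13) else NULL,
       inclusions = if (s$inclusion_count > 0)
         lapply(seq_len(s$inclusion_count), function(k)
           list(r_um = 0.7, at = 0.3, ecc = 0,
                ang = s$rotation + 2 * pi * k / max(1, s$inclusion_count)))
       else list(),
       lobes = s$nucleus_lobes,
       nfrac = if (s$nucleus_lobes > 0) 0.5 else 0)
}

#' Render a single cell on its own patch
#'
#' Convenience wrapper around \code{\link{render_smear}} for one archetype or
#' class, used by surveys and tests.
#'
#' @param archetype an RBC archetype name, or a non-RBC class name from the
#'   label schema.
#' @param calibration um/px.
#' @param seed integer seed (drives geometry jitter and background noise).
#' @param patch_px patch side length in pixels (default fits the cell).
#' @param jitter randomize geometry around the archetype means.
#' @return as \code{\link{render_smear}}, single-cell.
#' @export
render_cell_patch <- function(archetype, calibration = 0.1, seed = 1L,
                              patch_px = NULL, jitter = TRUE) {
  u <- mpp(calibration)
  local_seed(seed, {
    sp <- if (archetype %in% rbc_archetypes())
      archetype_spec(archetype, jitter = jitter)
    else nonrbc_spec(archetype, jitter = jitter)
    if (is.null(patch_px))
      patch_px <- max(48L, 2L * ceiling(sp$a_um / u * 2.0) + 9L)
    sp$center <- c((patch_px + 1) / 2, (patch_px + 1) / 2)
    inner_seed <- sample.int(2^31 - 2, 1)
    render_smear(list(sp), image_dims = c(patch_px, patch_px),
                 calibration = u, seed = inner_seed)
  })
}

#' Per-channel min-max normalization to [0, 1]
#'
#' \code{x_norm = (x - min) / (max - min)} applied per channel. A constant
#' channel has a degenerate denominator and raises an error.
#'
#' @param image array (width, height, channels) or matrix.
#' @return normalized image, per-channel min 0 and max 1.
#' @export
normalize_pixels <- function(image) {
  if (length(dim(image)) == 2L) image <- array(image, dim = c(dim(image), 1L))
  out <- image
  for (ch in seq_len(dim(image)[3])) {
    v <- image[, , ch]
    rng <- range(v)
    if (diff(rng) < 1e-12)
      stop("degenerate input: channel ", ch, " is constant")
    out[, , ch] <- (v - rng[1]) / (rng[2] - rng[1])
  }
  if (dim(out)[3] == 1L) out <- out[, , 1] else out
}

# ---- augmentation ---------------------------------------------------------

#' Geometric augmentation with consistent annotations
#'
#' Applies a horizontal/vertical flip, a rotation (within +/- 15 degrees) or
#' a shear (within +/- 0.2 rad) to an image and its ground-truth cells.
#' Rotation and shear use nearest-neighbor inverse mapping about the image
#' center, so \code{augment(x, "rotate", angle = 0)} is the identity. Boxes
#' are recomputed from the transformed masks; cells whose transformed mask
#' retains under 20\% of its original area are dropped.
#'
#' @param scene a \code{\link{render_smear}} result (image + cells).
#' @param op one of "hflip", "vflip", "rotate", "shear".
#' @param angle rotation angle in degrees, in [-15, 15].
#' @param shear shear factor in rad, in [-0.2, 0.2].
#' @return a scene of the same structure with transformed image, masks and
#'   recomputed annotations.
#' @export
augment <- function(scene, op = c("hflip", "vflip", "rotate", "shear"),
                    angle = 0, shear = 0) {
  op <- match.arg(op)
  img <- scene$image
  nx <- dim(img)[1]; ny <- dim(img)[2]
  if (op == "rotate" && abs(angle) > 15)
    stop("rotation angle outside [-15, 15] degrees")
  if (op == "shear" && abs(shear) > 0.2)
    stop("shear outside [-0.2, 0.2] rad")
  tr_mat <- function(m, fun) fun(m)
  if (op == "hflip") {
    fi <- function(a) a[nx:1, , drop = FALSE]
    fimg <- function(a) a[nx:1, , ]
  } else if (op == "vflip") {
    fi <- function(a) a[, ny:1, drop = FALSE]
    fimg <- function(a) a[, ny:1, ]
  } else {
    th <- angle * pi / 180
    cxy <- c((nx + 1) / 2, (ny + 1) / 2)
    XY <- cbind(rep(seq_len(nx), ny) - cxy[1],
                rep(seq_len(ny), each = nx) - cxy[2])
    # inverse map: source = A^{-1} %*% target
    A <- if (op == "rotate")
      matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    else matrix(c(1, 0, shear, 1), 2)
    Ainv <- solve(A)
    src <- XY %*% t(Ainv)
    sx <- round(src[, 1] + cxy[1]); sy <- round(src[, 2] + cxy[2])
    ok <- sx >= 1 & sx <= nx & sy >= 1 & sy <= ny
    lin <- ifelse(ok, (sy - 1L) * nx + sx, NA_integer_)
    fi <- function(a) {
      out <- matrix(0, nx, ny)
      out[!is.na(lin)] <- a[lin[!is.na(lin)]]
      matrix(out, nx, ny)
    }
    fimg <- function(a) {
      out <- array(0, dim(a))
      for (ch in seq_len(dim(a)[3])) {
        pl <- matrix(1, nx, ny)  # background fill: white-ish
        v <- a[, , ch]
        pl[] <- 1
        pl[!is.na(lin)] <- v[lin[!is.na(lin)]]
        out[, , ch] <- pl
      }
      out
    }
  }
  new_img <- fimg(img)
  new_cells <- list()
  for (cl in scene$cells) {
    m0 <- sum(cl$mask)
    nm <- fi(cl$mask) != 0
    if (sum(nm) < 0.2 * m0) next
    nn <- if (any(cl$nucleus_mask)) fi(cl$nucleus_mask) != 0 else
      cl$nucleus_mask & FALSE
    box <- mask_bbox(nm)
    cl$mask <- nm; cl$nucleus_mask <- nn; cl$box <- box
    cl$record <- normalize_box(box, nx, ny)
    new_cells[[length(new_cells) + 1L]] <- cl
  }
  ann <- if (length(new_cells) == 0L) scene$annotations[0, ] else
    do.call(rbind, lapply(new_cells, function(cl)
      data.frame(class_id = cl$class_id, x_center = cl$record[[1]],
                 y_center = cl$record[[2]], width = cl$record[[3]],
                 height = cl$record[[4]])))
  scene$image <- new_img; scene$cells <- new_cells; scene$annotations <- ann
  scene
}

# ---- perceptual hashing / dedup ------------------------------------------

#' Average perceptual hash of an image
#'
#' 64-bit average hash: the luminance channel is mean-pooled to 8 x 8 and
#' each block is compared to the global block mean.
#'
#' @param image image array or grayscale matrix.
#' @return logical vector of length 64.
#' @export
perceptual_hash <- function(image) {
  g <- luminance(image)
  nx <- nrow(g); ny <- ncol(g)
  bx <- cut(seq_len(nx), 8L, labels = FALSE)
  by <- cut(seq_len(ny), 8L, labels = FALSE)
  sums <- rowsum(t(rowsum(g, bx)), by)            # 8 x 8 sums (y, x)
  cnt <- outer(tabulate(by, 8L), tabulate(bx, 8L))
  pooled <- t(sums / cnt)
  as.vector(pooled > mean(pooled))
}

#' Remove perceptual-hash duplicates
#'
#' Scans images in order and drops any whose Hamming distance to an earlier
#' retained image's hash is \code{<= threshold} (default 0 = exact hash
#' match). The earliest representative of each duplicate group is retained.
#'
#' @param images list of image arrays.
#' @param threshold Hamming distance threshold in bits.
#' @return integer vector of retained indices.
#' @export
deduplicate <- function(images, threshold = 0L) {
  if (length(images) == 0L) return(integer())
  hashes <- lapply(images, perceptual_hash)
  keep <- integer()
  for (i in seq_along(images)) {
    dup <- FALSE
    for (k in keep) {
      if (sum(hashes[[i]] != hashes[[k]]) <= threshold) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  keep
}

# ---- dataset generation ---------------------------------------------------

#' Generate a labeled synthetic smear dataset
#'
#' Renders images with the requested number of cells per class, writes one
#' PNG and one label .txt per image, and returns (and writes) a manifest.
#'
#' @param class_counts named integer vector over \code{\link{label_schema}}
#'   classes (missing classes default to 0).
#' @param archetype_mix named numeric vector over RBC archetypes summing to
#'   1; defaults to uniform over all 15.
#' @param dir output directory (created); NULL keeps everything in memory.
#' @param image_dims canvas size in pixels.
#' @param calibration um/px (default 0.2 so a dozen cells fit per canvas).
#' @param cells_per_image target number of cells per image.
#' @param seed integer seed.
#' @param max_tries placement attempts per cell before giving up.
#' @return manifest list: \code{images} data.frame, \code{cells} data.frame
#'   (per-cell ground truth incl. archetypes), \code{class_counts},
#'   \code{seed}, \code{params}; plus \code{scenes} when \code{dir} is NULL.
#' @export
generate_dataset <- function(class_counts, archetype_mix = NULL, dir = NULL,
                             image_dims = c(384L, 384L), calibration = 0.2,
                             cells_per_image = 10L, seed = 1L,
                             max_tries = 200L) {
  if (any(class_counts < 0)) stop("counts must be >= 0")
  unknown <- setdiff(names(class_counts), label_schema())
  if (length(unknown)) stop("unknown classes: ", paste(unknown, collapse = ", "))
  if (is.null(archetype_mix)) {
    archetype_mix <- stats::setNames(rep(1 / 15, 15), rbc_archetypes())
  }
  if (abs(sum(archetype_mix) - 1) > 1e-6)
    stop("archetype_mix must sum to 1")
  u <- mpp(calibration)
  local_seed(seed, {
    # draw the full cell roster
    classes <- rep(names(class_counts), class_counts)
    arch <- rep(NA_character_, length(classes))
    n_rbc <- sum(classes == "rbc")
    if (n_rbc > 0) {
      draws <- sample(names(archetype_mix), n_rbc, replace = TRUE,
                      prob = archetype_mix)
      arch[classes == "rbc"] <- draws
    }
    ord <- sample.int(length(classes))
    classes <- classes[ord]; arch <- arch[ord]
    n_img <- max(1L, ceiling(length(classes) / cells_per_image))
    groups <- split(seq_along(classes),
                    rep(seq_len(n_img), each = cells_per_image,
                        length.out = length(classes)))
    scenes <- list(); img_rows <- list(); cell_rows <- list()
    if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (gi in seq_along(groups)) {
      members <- groups[[gi]]
      specs <- list(); occupied <- matrix(FALSE, image_dims[1], image_dims[2])
      for (ci in members) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          sp <- if (!is.na(arch[ci])) archetype_spec(arch[ci]) else
            nonrbc_spec(classes[ci])
          rad <- sp$a_um / u + 3
          cx <- stats::runif(1, rad + 1, image_dims[1] - rad - 1)
          cy <- stats::runif(1, rad + 1, image_dims[2] - rad - 1)
          sp$center <- c(cx, cy)
          # coarse disc collision check
          xs <- pmax(1, round(cx - rad)):pmin(image_dims[1], round(cx + rad))
          ys <- pmax(1, round(cy - rad)):pmin(image_dims[2], round(cy + rad))
          if (!any(occupied[xs, ys])) {
            occupied[xs, ys] <- TRUE
            specs[[length(specs) + 1L]] <- sp
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("impossible packing: could not place a ", classes[ci],
               " after ", max_tries, " tries; lower cells_per_image")
      }
      sc_seed <- sample.int(2^31 - 2, 1)
      sc <- render_smear(specs, image_dims = image_dims, calibration = u,
                         seed = sc_seed)
      name <- sprintf("img_%04d", gi)
      if (!is.null(dir)) {
        img_path <- file.path(dir, paste0(name, ".png"))
        lab_path <- file.path(dir, paste0(name, ".txt"))
        write_image(sc$image, img_path)
        writeLines(write_yolo_labels(sc$annotations), lab_path)
      } else {
        img_path <- lab_path <- NA_character_
        scenes[[gi]] <- sc
      }
      img_rows[[gi]] <- data.frame(image = name, path = img_path,
                                   label_path = lab_path,
                                   n_cells = length(sc$cells))
      cell_rows[[gi]] <- do.call(rbind, lapply(seq_along(sc$cells), function(k) {
        cl <- sc$cells[[k]]
        data.frame(image = name, cell = k, class = cl$class,
                   class_id = cl$class_id,
                   archetype = cl$archetype %||% NA_character_,
                   x_center = cl$record[[1]], y_center = cl$record[[2]],
                   width = cl$record[[3]], height = cl$record[[4]])
      }))
    }
    cells_df <- do.call(rbind, cell_rows)
    manifest <- list(
      images = do.call(rbind, img_rows),
      cells = cells_df,
      class_counts = as.list(table(cells_df$class)),
      archetype_counts = as.list(table(cells_df$archetype[!is.na(cells_df$archetype)])),
      seed = seed,
      params = list(image_dims = image_dims, microns_per_pixel = u,
                    cells_per_image = cells_per_image))
    if (!is.null(dir)) {
      jsonlite::write_json(manifest[c("images", "class_counts",
                                      "archetype_counts", "seed", "params")],
                           file.path(dir, "manifest.json"),
                           auto_unbox = TRUE, digits = 10)
    } else manifest$scenes <- scenes
    manifest
  })
}

#' Oversample minority classes in a generated dataset
#'
#' Brings per-class cell counts up to \code{target_counts} by seeded
#' duplication of existing cells with geometric augmentation (the synthetic
#' analogue of minority oversampling): source cells are re-rendered as
#' single-cell patches with fresh jitter and a random flip, so oversampled
#' items differ pixel-wise from their sources while keeping the class label.
#'
#' @param manifest a \code{\link{generate_dataset}} manifest (in-memory form,
#'   i.e. generated with \code{dir = NULL}).
#' @param target_counts named integer vector of per-class targets; every
#'   target must be >= the current count.
#' @param seed integer seed.
#' @return manifest with appended synthetic cells (and patches in
#'   \code{oversampled}).
#' @export
rebalance <- function(manifest, target_counts, seed = 1L) {
  cur <- table(manifest$cells$class)
  local_seed(seed, {
    extra_rows <- list(); patches <- list()
    for (cls in names(target_counts)) {
      have <- if (cls %in% names(cur)) as.integer(cur[[cls]]) else 0L
      want <- as.integer(target_counts[[cls]])
      if (want < have)
        stop("target for ", cls, " (", want, ") below current count (", have, ")")
      if (want == have) next
      src <- manifest$cells[manifest$cells$class == cls, , drop = FALSE]
      if (nrow(src) == 0L) stop("no source cells of class ", cls)
      for (k in seq_len(want - have)) {
        si <- src[sample.int(nrow(src), 1L), ]
        aname <- if (!is.na(si$archetype)) si$archetype else si$class
        pseed <- sample.int(2^31 - 2, 1)
        patch <- render_cell_patch(aname, calibration =
                                     manifest$params$microns_per_pixel,
                                   seed = pseed)
        if (stats::runif(1) < 0.5) patch <- augment(patch, "hflip")
        id <- length(patches) + 1L
        patches[[id]] <- patch
        extra_rows[[id]] <- data.frame(
          image = sprintf("oversample_%04d", id), cell = 1L, class = cls,
          class_id = class_id(cls), archetype = si$archetype,
          x_center = patch$cells[[1]]$record[[1]],
          y_center = patch$cells[[1]]$record[[2]],
          width = patch$cells[[1]]$record[[3]],
          height = patch$cells[[1]]$record[[4]])
      }
    }
    if (length(extra_rows)) {
      manifest$cells <- rbind(manifest$cells, do.call(rbind, extra_rows))
      manifest$oversampled <- patches
    }
    manifest$class_counts <- as.list(table(manifest$cells$class))
    manifest
  })
}
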