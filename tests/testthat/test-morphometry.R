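test_that("eccentricity follows the ellipse closed form", {
  expect_equal(eccentricity(3, 3), 0)
  expect_equal(eccentricity(1, 0), 1)
  expect_equal(eccentricity(2, 1), sqrt(3) / 2, tolerance = 1e-9)
  # strictly increasing in the axis ratio
  ratios <- seq(1, 4, by = 0.25)
  es <- vapply(ratios, function(r) eccentricity(r, 1), numeric(1))
  expect_true(all(diff(es) > 0))
  expect_error(eccentricity(1, 2), "a >= b")
  expect_error(eccentricity(0, 0), "positive")
})

test_that("circularity matches analytic shapes and rasterized disks", {
  r <- 3; expect_equal(circularity(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  s <- 2; expect_equal(circularity(s^2, 4 * s), pi / 4, tolerance = 1e-12)
  expect_error(circularity(0, 1), "positive")
  m <- disk_mask(40L)
  circ <- circularity(sum(m), hemamorph:::mask_perimeter(m))
  expect_gt(circ, 0.92); expect_lt(circ, 1.02)
})

test_that("descriptor extraction reproduces analytic geometry of a disc", {
  sp <- cell_spec(class = "rbc", center = c(51, 51), a_um = 3.5, b_um = 3.5,
                  pallor_ratio = 0)
  sc <- render_smear(list(sp), image_dims = c(101L, 101L),
                     calibration = 0.1, seed = 2L)
  v <- extract_descriptors(sc$image, sc$cells[[1]]$mask,
                           sc$cells[[1]]$nucleus_mask, calibration = 0.1)
  expect_lt(abs(v[["cell_area"]] - pi * 3.5^2) / (pi * 3.5^2), 0.02)
  expect_lt(v[["eccentricity"]], 0.1)
  expect_gt(v[["solidity"]], 0.97)
  expect_gt(v[["circularity"]], 0.92)
})

test_that("the vector is complete, ordered and registry-sized", {
  reg <- descriptor_registry()
  expect_identical(nrow(reg), 50L)
  expect_identical(anyDuplicated(reg$name), 0L)
  expect_identical(as.vector(table(reg$group)[c("geometric", "nuclear",
                                                "texture", "color",
                                                "specialized")]),
                   c(20L, 10L, 8L, 6L, 6L))
  sc <- render_cell_patch("Normal", seed = 3L)
  v <- extract_descriptors(sc$image, sc$cells[[1]]$mask,
                           sc$cells[[1]]$nucleus_mask, 0.1)
  expect_identical(names(v), reg$name)
  expect_true(all(is.finite(v)))
})

test_that("a uniform-intensity cell has degenerate co-occurrence texture", {
  img <- array(0.5, c(41, 41, 3))
  m <- disk_mask(15L, 41L)
  v <- extract_descriptors(img, m, m & FALSE, 0.1)
  expect_equal(v[["texture_entropy"]], 0, tolerance = 1e-12)
  expect_equal(v[["texture_energy"]], 1, tolerance = 1e-12)
  expect_equal(v[["texture_contrast"]], 0, tolerance = 1e-12)
})

test_that("empty or inconsistent masks are rejected", {
  img <- array(0.5, c(20, 20, 3))
  expect_error(extract_descriptors(img, matrix(0, 20, 20), NULL, 0.1),
               "empty")
  cm <- matrix(0, 20, 20); cm[8:12, 8:12] <- 1
  nm <- matrix(0, 20, 20); nm[1:3, 1:3] <- 1
  expect_error(extract_descriptors(img, cm, nm, 0.1), "outside")
})

test_that("scale-free descriptors are robust to 90-degree rotation", {
  sc <- render_cell_patch("Elliptocyte", seed = 6L, jitter = FALSE)
  m <- sc$cells[[1]]$mask
  img <- sc$image
  v1 <- extract_descriptors(img, m, m & FALSE, 0.1)
  img90 <- aperm(img, c(2, 1, 3))[, dim(img)[1]:1, ]
  m90 <- t(m)[, nrow(m):1]
  v2 <- extract_descriptors(img90, m90, m90 & FALSE, 0.1)
  for (f in c("circularity", "eccentricity", "solidity"))
    expect_lt(abs(v1[[f]] - v2[[f]]) / max(v1[[f]], 1e-9), 0.02)
})

test_that("descriptors are covariant in the calibration scale", {
  sc <- render_cell_patch("Normal", seed = 4L)
  m <- sc$cells[[1]]$mask
  v1 <- extract_descriptors(sc$image, m, m & FALSE, 0.1)
  v2 <- extract_descriptors(sc$image, m, m & FALSE, 0.2)
  reg <- descriptor_registry()
  for (f in reg$name[reg$unit == "um"])
    expect_equal(v2[[f]], 2 * v1[[f]], tolerance = 1e-9)
  for (f in reg$name[reg$unit == "um2"])
    expect_equal(v2[[f]], 4 * v1[[f]], tolerance = 1e-9)
  for (f in c("circularity", "eccentricity", "solidity", "aspect_ratio"))
    expect_equal(v2[[f]], v1[[f]], tolerance = 1e-9)
})
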