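test_that("a rendered circular RBC matches analytic ellipse geometry", {
  sp <- cell_spec(class = "rbc", center = c(51, 51), a_um = 3.5, b_um = 3.5,
                  pallor_ratio = 0)
  sc <- render_smear(list(sp), image_dims = c(101L, 101L),
                     calibration = 0.1, seed = 2L)
  m <- sc$cells[[1]]$mask
  expect_lt(abs(sum(m) - pi * 35^2) / (pi * 35^2), 0.02)
  mom <- hemamorph:::mask_moments(m)
  expect_lt(mom$eccentricity, 0.1)
})

test_that("rendering is deterministic and annotations match masks", {
  specs <- list(cell_spec(class = "rbc", center = c(40, 40)),
                cell_spec(class = "rbc", archetype = "Macrocyte",
                          center = c(120, 110), a_um = 4.8, b_um = 4.7))
  a <- render_smear(specs, image_dims = c(160L, 160L), seed = 9L)
  b <- render_smear(specs, image_dims = c(160L, 160L), seed = 9L)
  expect_identical(a$image, b$image)
  for (cl in a$cells) {
    expect_identical(unname(cl$box), unname(hemamorph:::mask_bbox(cl$mask)))
    expect_equal(unname(cl$record),
                 unname(normalize_box(cl$box, 160L, 160L)))
  }
  empty <- render_smear(list(), image_dims = c(64L, 64L), seed = 1L)
  expect_length(empty$cells, 0L)
  expect_identical(nrow(empty$annotations), 0L)
})

test_that("excessive overlap aborts generation", {
  specs <- list(cell_spec(class = "rbc", center = c(50, 50)),
                cell_spec(class = "rbc", center = c(54, 50)))
  expect_error(render_smear(specs, image_dims = c(101L, 101L), seed = 1L),
               "overlaps")
})

test_that("min-max normalization hits the closed form and guards constants", {
  img <- array(0, c(2, 2, 1)); img[, , 1] <- c(0, 128, 255, 128) / 255
  out <- normalize_pixels(img[, , 1] * 255)
  expect_equal(sort(unique(as.vector(out))), c(0, 128 / 255, 1),
               tolerance = 1e-9)
  spanning <- matrix(c(0, 0.4, 1, 0.6), 2)
  expect_equal(normalize_pixels(spanning), spanning)
  expect_error(normalize_pixels(matrix(0.5, 3, 3)), "constant")
})

test_that("augmentation transforms pixels and annotations consistently", {
  specs <- list(cell_spec(class = "rbc", center = c(48, 80)))
  sc <- render_smear(specs, image_dims = c(160L, 160L), seed = 3L)
  # closed-form coordinate map under hflip
  x0 <- sc$annotations$x_center
  hf <- augment(sc, "hflip")
  expect_equal(hf$annotations$x_center, 1 - x0, tolerance = 1e-9)
  expect_equal(hf$annotations$y_center, sc$annotations$y_center,
               tolerance = 1e-9)
  # involution
  back <- augment(hf, "hflip")
  expect_identical(back$image, sc$image)
  expect_identical(back$cells[[1]]$mask, sc$cells[[1]]$mask)
  # zero rotation is the identity under nearest-neighbor mapping
  rot0 <- augment(sc, "rotate", angle = 0)
  expect_lt(max(abs(rot0$image - sc$image)), 1e-6)
  # parameter range guards
  expect_error(augment(sc, "rotate", angle = 20), "15")
  expect_error(augment(sc, "shear", shear = 0.3), "0.2")
  # boxes recomputed from transformed masks
  rot <- augment(sc, "rotate", angle = 10)
  for (cl in rot$cells)
    expect_identical(unname(cl$box), unname(hemamorph:::mask_bbox(cl$mask)))
})

test_that("perceptual-hash deduplication keeps earliest representatives", {
  sc1 <- render_smear(list(cell_spec(class = "rbc", center = c(40, 40))),
                      image_dims = c(96L, 96L), seed = 5L)
  sc2 <- render_smear(list(cell_spec(class = "rbc", center = c(60, 56))),
                      image_dims = c(96L, 96L), seed = 6L)
  sc3 <- render_smear(list(), image_dims = c(96L, 96L), seed = 7L)
  imgs <- c(replicate(5, sc1$image, simplify = FALSE),
            list(sc2$image, sc3$image, sc2$image))
  kept <- deduplicate(imgs)
  expect_identical(kept, c(1L, 6L, 7L))
  expect_identical(deduplicate(list()), integer())
  # all-distinct seeded images are all retained
  distinct <- lapply(1:6, function(s)
    render_smear(list(cell_spec(class = "rbc",
                                center = c(30 + 6 * s, 40 + 4 * s))),
                 image_dims = c(96L, 96L), seed = 100L + s)$image)
  expect_identical(deduplicate(distinct), 1:6)
})

test_that("dataset generation matches requested counts and is seeded", {
  mf <- generate_dataset(c(rbc = 20L, lymphocyte = 5L), seed = 21L,
                         cells_per_image = 6L)
  expect_identical(mf$class_counts$rbc, 20L)
  expect_identical(mf$class_counts$lymphocyte, 5L)
  mf2 <- generate_dataset(c(rbc = 20L, lymphocyte = 5L), seed = 21L,
                          cells_per_image = 6L)
  expect_identical(mf$cells, mf2$cells)
  expect_identical(mf$images$n_cells, mf2$images$n_cells)
  expect_error(generate_dataset(c(rbc = -1L)), ">= 0")
})

test_that("requesting every archetype yields 15 distinct ground-truth labels", {
  mix <- stats::setNames(rep(1 / 15, 15), rbc_archetypes())
  mf <- generate_dataset(c(rbc = 60L), archetype_mix = mix, seed = 33L,
                         cells_per_image = 5L)
  expect_identical(sort(unique(mf$cells$archetype)), sort(rbc_archetypes()))
})

test_that("dataset files round-trip through disk", {
  dir <- withr::local_tempdir()
  mf <- generate_dataset(c(rbc = 6L, platelet = 2L), dir = dir, seed = 8L,
                         cells_per_image = 4L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  first <- mf$images$path[1]
  expect_true(file.exists(first))
  labs <- read_yolo_labels(readLines(mf$images$label_path[1]))
  expect_identical(nrow(labs), mf$images$n_cells[1])
})

test_that("rebalancing tops up minorities with augmented, distinct items", {
  mf <- generate_dataset(c(rbc = 10L, platelet = 2L), seed = 13L,
                         cells_per_image = 6L)
  up <- rebalance(mf, c(platelet = 8L), seed = 14L)
  expect_identical(up$class_counts$platelet, 8L)
  expect_identical(up$class_counts$rbc, 10L)
  # oversampled items are augmented: pixel content differs from any source
  h_new <- lapply(up$oversampled, function(p) perceptual_hash(p$image))
  expect_gt(length(unique(lapply(h_new, paste, collapse = ""))), 1L)
  same <- rebalance(mf, c(rbc = 10L, platelet = 2L), seed = 3L)
  expect_identical(same$cells, mf$cells)
  expect_error(rebalance(mf, c(platelet = 1L)), "below current")
})
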