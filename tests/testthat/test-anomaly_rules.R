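test_that("the published shape criteria drive the expected labels", {
  # normal disc: 6-8 um diameter, circularity > 0.9
  r <- 3.5
  normal <- make_morphometry_vector(cell_area = pi * r^2, circularity = 0.95,
                                    eccentricity = 0.2)
  expect_identical(classify_rbc_shape(normal)$label, "Normal")
  # elliptocyte: eccentricity > 0.5
  ell <- make_morphometry_vector(eccentricity = 0.6, circularity = 0.8)
  expect_identical(classify_rbc_shape(ell)$label, "Elliptocyte")
  # stomatocyte: circularity < 0.7
  sto <- make_morphometry_vector(circularity = 0.65, eccentricity = 0.3,
                                 central_pallor_ratio = 0.08)
  expect_identical(classify_rbc_shape(sto)$label, "Stomatocyte")
  # macrocyte: oversized but round
  r2 <- 9.5 / 2
  mac <- make_morphometry_vector(cell_area = pi * r2^2, circularity = 0.93,
                                 eccentricity = 0.2)
  expect_identical(classify_rbc_shape(mac)$label, "Macrocyte")
})

test_that("the rule table is total, 15-labeled and priority-ordered", {
  rules <- rbc_rule_table()
  expect_length(rules, 15L)
  labels <- vapply(rules, `[[`, character(1), "label")
  expect_setequal(labels, rbc_archetypes())
  expect_identical(vapply(rules, `[[`, integer(1), "priority"), 1:15)
  # totality: random syntactically valid vectors always get exactly one label
  set.seed(19)
  for (k in 1:60) {
    v <- make_morphometry_vector(
      cell_area = runif(1, 5, 90), circularity = runif(1, 0.3, 1.02),
      eccentricity = runif(1, 0, 0.99), solidity = runif(1, 0.5, 1),
      aspect_ratio = runif(1, 1, 4), inclusion_count = sample(0:2, 1),
      central_pallor_ratio = runif(1, 0, 0.7),
      radial_inversions = sample(0:3, 1),
      interior_intensity = runif(1, 0.2, 0.8))
    call <- classify_rbc_shape(v)
    expect_true(call$label %in% rbc_archetypes())
  }
  expect_error(classify_rbc_shape(c(eccentricity = 0.5)), "incomplete")
})

test_that("growing eccentricity never falls back from Elliptocyte to Normal", {
  labs <- vapply(seq(0.05, 0.95, by = 0.05), function(e)
    classify_rbc_shape(make_morphometry_vector(eccentricity = e,
                                               aspect_ratio = 1 / sqrt(1 - e^2)))$label,
    character(1))
  seen_ell <- FALSE
  for (l in labs) {
    if (l == "Elliptocyte" || l == "Pencil") seen_ell <- TRUE
    if (seen_ell) expect_false(l == "Normal")
  }
})

test_that("WBC flagging uses the strict e > 0.8 boundary and gradients", {
  hi <- make_morphometry_vector(eccentricity = 0.85)
  out <- flag_wbc_anomaly(hi)
  expect_true(out$flagged)
  expect_match(out$evidence[1], "eccentricity")
  at <- make_morphometry_vector(eccentricity = 0.80)
  expect_false(flag_wbc_anomaly(at)$flagged)
  lo <- make_morphometry_vector(eccentricity = 0.1, edge_gradient = 0.05)
  expect_false(flag_wbc_anomaly(lo)$flagged)
  grad <- make_morphometry_vector(eccentricity = 0.1, edge_gradient = 0.5)
  out2 <- flag_wbc_anomaly(grad)
  expect_true(out2$flagged)
  expect_match(out2$evidence[1], "gradient")
  expect_error(flag_wbc_anomaly(hi, is_wbc = FALSE), "WBC")
})

test_that("the survey recovers every archetype with high per-type recall", {
  sv <- anomaly_survey(n_per_type = 8L, seed = 42L)
  expect_identical(sv$n_distinct_predicted, 15L)
  expect_true(all(sv$per_type$n == 8L))
  expect_gte(sv$accuracy, 0.95)
  expect_true(all(sv$per_type$recall >= 0.75))
})
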