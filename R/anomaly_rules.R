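#' Parameters of the RBC shape rule table
#'
#' Every threshold of the geometric rule engine, overridable by the user.
#' The published criteria are: normal diameter 6-8 um with circularity > 0.9,
#' elliptocyte eccentricity > 0.5, stomatocyte circularity < 0.7. The
#' remaining thresholds complete the 15-class taxonomy and are documented in
#' the methods vignette. All inequalities are strict.
#'
#' @param ... named overrides of the defaults.
#' @return named list of rule parameters.
#' @export
anomaly_rule_params <- function(...) {
  p <- list(
    normal_diameter = c(6, 8),        # um
    normal_circularity = 0.9,
    normal_pallor_band = c(0.05, 0.6),
    elliptocyte_eccentricity = 0.5,
    oval_eccentricity = c(0.35, 0.5),
    pencil_eccentricity = 0.85,
    pencil_aspect = 3,
    macrocyte_diameter = 8.5,         # um
    microcircle_diameter = 6,         # um
    stomatocyte_circularity = 0.7,
    stomatocyte_pallor_ecc = 0.7,
    fragment_area_fraction = 0.5,     # of the normal RBC area
    normal_rbc_area = pi * 3.5^2,     # um^2 (7 um disc)
    fragment_solidity = 0.85,
    target_inversions = 2,
    hyperchromic_intensity = 0.45,
    pallor_present = 0.05,
    inclusion_ecc = 0.8,
    pikilocyte_solidity = 0.9)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown rule parameters: ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

# Auxiliary measurements with conservative defaults for vectors constructed
# without an extractor run.
aux_of <- function(v) {
  aux <- attr(v, "aux")
  def <- list(pallor_eccentricity = 0, radial_inversions = 1,
              inclusion_max_eccentricity = 0, inclusion_peripheral = 0,
              interior_intensity = 0.55)
  for (nm in names(def)) if (is.null(aux[[nm]])) aux[[nm]] <- def[[nm]]
  aux
}

#' The ordered RBC shape rule table
#'
#' Fifteen prioritized rules over a morphometry vector. Inclusion-based
#' rules precede size rules, size rules precede shape rules, Normal is
#' second-to-last and an irregular catch-all (Pikilocyte) guarantees that
#' every vector receives exactly one label.
#'
#' @param params from \code{\link{anomaly_rule_params}}.
#' @return list of rules: \code{label}, \code{id}, \code{priority},
#'   \code{predicate(v, d, aux)} where \code{d} is the equivalent diameter in
#'   micrometres.
#' @export
rbc_rule_table <- function(params = anomaly_rule_params()) {
  p <- params
  mk <- function(label, id, pred) list(label = label, id = id, predicate = pred)
  rules <- list(
    mk("Hemoglobin-C", "hbc_crystal", function(v, d, aux)
      v[["inclusion_count"]] >= 1 &&
        aux$inclusion_max_eccentricity > p$inclusion_ecc),
    mk("Heinz bodies", "heinz_peripheral_inclusion", function(v, d, aux)
      v[["inclusion_count"]] >= 1 && aux$inclusion_peripheral > 0),
    mk("Howell-Jolly", "howell_jolly_single_inclusion", function(v, d, aux)
      v[["inclusion_count"]] == 1),
    mk("Target", "target_radial_inversions", function(v, d, aux)
      aux$radial_inversions >= p$target_inversions),
    mk("Fragments", "fragment_small_irregular", function(v, d, aux)
      v[["cell_area"]] < p$fragment_area_fraction * p$normal_rbc_area &&
        v[["solidity"]] < p$fragment_solidity),
    mk("Pencil", "pencil_extreme_elongation", function(v, d, aux)
      v[["eccentricity"]] > p$pencil_eccentricity &&
        v[["aspect_ratio"]] > p$pencil_aspect),
    mk("Elliptocyte", "elliptocyte_eccentricity", function(v, d, aux)
      v[["eccentricity"]] > p$elliptocyte_eccentricity),
    mk("Oval", "oval_moderate_eccentricity", function(v, d, aux)
      v[["eccentricity"]] > p$oval_eccentricity[1] &&
        v[["eccentricity"]] <= p$oval_eccentricity[2]),
    mk("Macrocyte", "macrocyte_diameter", function(v, d, aux)
      d > p$macrocyte_diameter),
    mk("Microcircle", "microcircle_diameter", function(v, d, aux)
      d < p$microcircle_diameter &&
        v[["circularity"]] > p$normal_circularity),
    mk("Hyperchromasia", "hyperchromic_dense", function(v, d, aux)
      aux$interior_intensity < p$hyperchromic_intensity &&
        v[["central_pallor_ratio"]] < p$pallor_present),
    mk("Stomatocyte", "stomatocyte_slit_or_low_circularity", function(v, d, aux)
      (v[["central_pallor_ratio"]] >= p$pallor_present &&
         aux$pallor_eccentricity > p$stomatocyte_pallor_ecc) ||
        (v[["circularity"]] < p$stomatocyte_circularity &&
           v[["solidity"]] >= p$pikilocyte_solidity)),
    mk("Spleen", "spherocyte_like_no_pallor", function(v, d, aux)
      v[["central_pallor_ratio"]] < p$pallor_present &&
        d > p$normal_diameter[1] && d < p$normal_diameter[2] &&
        v[["circularity"]] > p$normal_circularity),
    mk("Normal", "normal_biconcave_disc", function(v, d, aux)
      d > p$normal_diameter[1] && d < p$normal_diameter[2] &&
        v[["circularity"]] > p$normal_circularity &&
        v[["inclusion_count"]] == 0 &&
        v[["central_pallor_ratio"]] >= p$normal_pallor_band[1] &&
        v[["central_pallor_ratio"]] <= p$normal_pallor_band[2]),
    mk("Pikilocyte", "irregular_catch_all", function(v, d, aux) TRUE))
  for (i in seq_along(rules)) rules[[i]]$priority <- i
  stopifnot(length(unique(vapply(rules, `[[`, character(1), "label"))) == 15L)
  rules
}

#' Classify an erythrocyte's shape
#'
#' Evaluates the ordered rule table on a complete morphometry vector; the
#' first matching rule wins. Total: every valid vector receives exactly one
#' of the 15 labels.
#'
#' @param v a morphometry vector (all 50 registry descriptors).
#' @param rules from \code{\link{rbc_rule_table}}.
#' @return An anomaly call: list with \code{label}, \code{rule_id},
#'   \code{priority} and \code{measured} (the values the decision used).
#' @examples
#' v <- make_morphometry_vector(eccentricity = 0.6, circularity = 0.8)
#' classify_rbc_shape(v)$label   # "Elliptocyte"
#' @export
classify_rbc_shape <- function(v, rules = rbc_rule_table()) {
  check_morphometry_vector(v)
  aux <- aux_of(v)
  d <- 2 * sqrt(v[["cell_area"]] / pi)  # equivalent diameter, um
  for (r in rules) {
    if (isTRUE(r$predicate(v, d, aux))) {
      return(structure(list(
        label = r$label, rule_id = r$id, priority = r$priority,
        measured = list(
          equivalent_diameter_um = d,
          eccentricity = unname(v[["eccentricity"]]),
          circularity = unname(v[["circularity"]]),
          solidity = unname(v[["solidity"]]),
          aspect_ratio = unname(v[["aspect_ratio"]]),
          central_pallor_ratio = unname(v[["central_pallor_ratio"]]),
          inclusion_count = unname(v[["inclusion_count"]]),
          pallor_eccentricity = aux$pallor_eccentricity,
          radial_inversions = aux$radial_inversions,
          interior_intensity = aux$interior_intensity)),
        class = "anomaly_call"))
    }
  }
  stop("rule table is not total")  # unreachable: catch-all present
}

#' Flag a leukocyte anomaly
#'
#' A WBC is flagged when its eccentricity strictly exceeds 0.8 or its
#' boundary intensity-gradient score exceeds the configured threshold.
#'
#' @param v morphometry vector of a WBC-class cell.
#' @param ecc_threshold eccentricity threshold (strict; default 0.8).
#' @param gradient_threshold boundary gradient score threshold (strict);
#'   the score is the \code{edge_gradient} descriptor.
#' @param is_wbc assertion that the vector comes from a WBC; passing FALSE
#'   raises an error.
#' @return list with \code{flagged} and \code{evidence} (character vector of
#'   the conditions that fired).
#' @export
flag_wbc_anomaly <- function(v, ecc_threshold = 0.8,
                             gradient_threshold = 0.35, is_wbc = TRUE) {
  if (!isTRUE(is_wbc)) stop("flag_wbc_anomaly expects a WBC-class cell")
  check_morphometry_vector(v)
  evidence <- character()
  if (v[["eccentricity"]] > ecc_threshold)
    evidence <- c(evidence, sprintf("eccentricity %.3f > %.2f",
                                    v[["eccentricity"]], ecc_threshold))
  if (v[["edge_gradient"]] > gradient_threshold)
    evidence <- c(evidence, sprintf("boundary gradient %.3f > %.2f",
                                    v[["edge_gradient"]], gradient_threshold))
  list(flagged = length(evidence) > 0, evidence = evidence)
}

#' Survey the rule engine against generated ground truth
#'
#' Renders \code{n_per_type} seeded single-cell patches of each of the 15
#' archetypes, measures them, classifies them with the rule engine, and
#' reports per-type precision/recall, the confusion table and overall
#' accuracy.
#'
#' @param n_per_type cells per archetype.
#' @param calibration um/px.
#' @param seed integer seed.
#' @param rules rule table.
#' @return list with \code{confusion} (15 x 15 table truth x prediction),
#'   \code{per_type} data.frame (n, recall, precision), \code{accuracy},
#'   \code{n_distinct_predicted}, \code{calls}.
#' @export
anomaly_survey <- function(n_per_type = 20L, calibration = 0.1, seed = 42L,
                           rules = rbc_rule_table()) {
  types <- rbc_archetypes()
  truth <- character(); pred <- character()
  local_seed(seed, {
    seeds <- matrix(sample.int(2^31 - 2, n_per_type * length(types)),
                    nrow = length(types))
    for (ti in seq_along(types)) {
      for (k in seq_len(n_per_type)) {
        sc <- render_cell_patch(types[ti], calibration = calibration,
                                seed = seeds[ti, k])
        cl <- sc$cells[[1]]
        v <- extract_descriptors(sc$image, cl$mask,
                                 nucleus_mask = cl$nucleus_mask,
                                 calibration = calibration)
        truth <- c(truth, types[ti])
        pred <- c(pred, classify_rbc_shape(v, rules)$label)
      }
    }
  })
  conf <- table(factor(truth, levels = types), factor(pred, levels = types))
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  precision <- diag(conf) / pmax(colSums(conf), 1)
  list(confusion = conf,
       per_type = data.frame(type = types, n = as.integer(rowSums(conf)),
                             recall = as.numeric(recall),
                             precision = as.numeric(precision)),
       accuracy = mean(truth == pred),
       n_distinct_predicted = length(unique(pred)),
       calls = data.frame(truth = truth, predicted = pred))
}
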