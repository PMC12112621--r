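#' The 50-descriptor morphometric registry
#'
#' Ordered registry of the 50 morphological descriptors measured for every
#' cell. The registry is the single source of truth for descriptor names,
#' grouping and units: every morphometry vector, attribute knowledge base and
#' feature table column set in the package is ordered by it.
#'
#' Groups: geometric (20), nuclear/cytoplasmic (10), texture (8), color (6)
#' and specialized hematology (6). Length-type descriptors are reported in
#' micrometres, area-type in square micrometres, volume estimates in cubic
#' micrometres; the remainder are dimensionless.
#'
#' @return A data.frame with columns \code{name}, \code{group}, \code{unit}
#'   and exactly 50 rows.
#' @examples
#' reg <- descriptor_registry()
#' nrow(reg)          # 50
#' table(reg$group)
#' @export
descriptor_registry <- function() {
  geometric <- c(
    "cell_area"         = "um2",
    "cell_perimeter"    = "um",
    "circularity"       = "1",
    "eccentricity"      = "1",
    "nucleus_area"      = "um2",
    "nucleus_perimeter" = "um",
    "nucleus_circularity" = "1",
    "nucleus_eccentricity" = "1",
    "cytoplasm_area"    = "um2",
    "cytoplasm_thickness" = "um",
    "aspect_ratio"      = "1",
    "elongation"        = "1",
    "compactness"       = "1",
    "convex_hull_area"  = "um2",
    "solidity"          = "1",
    "feret_diameter"    = "um",
    "min_feret_diameter" = "um",
    "major_axis_length" = "um",
    "minor_axis_length" = "um",
    "orientation_angle" = "rad")
  nuclear <- c(
    "chromatin_density" = "1",
    "nuclear_shape_factor" = "1",
    "nuclear_cytoplasmic_ratio" = "1",
    "lobe_count"        = "count",
    "nuclear_texture_variance" = "1",
    "cell_volume_estimate" = "um3",
    "nuclear_volume_estimate" = "um3",
    "symmetry"          = "1",
    "roundness"         = "1",
    "nuclear_solidity"  = "1")
  texture <- c(
    "texture_entropy"   = "bit",
    "texture_contrast"  = "1",
    "texture_correlation" = "1",
    "texture_energy"    = "1",
    "texture_homogeneity" = "1",
    "edge_gradient"     = "1",
    "boundary_roughness" = "1",
    "nuclear_edge_contrast" = "1")
  color <- c(
    "mean_red"   = "1", "mean_green" = "1", "mean_blue" = "1",
    "mean_hue"   = "1", "mean_saturation" = "1", "mean_value" = "1")
  specialized <- c(
    "granularity_index" = "1",
    "vacuolation_level" = "1",
    "inclusion_count"   = "count",
    "membrane_integrity" = "1",
    "cytoplasmic_granularity" = "1",
    "central_pallor_ratio" = "1")
  groups <- rep(c("geometric", "nuclear", "texture", "color", "specialized"),
                c(length(geometric), length(nuclear), length(texture),
                  length(color), length(specialized)))
  all <- c(geometric, nuclear, texture, color, specialized)
  data.frame(name = names(all), group = groups, unit = unname(all),
             stringsAsFactors = FALSE)
}

#' Descriptor names in registry order
#' @return Character vector of length 50.
#' @export
descriptor_names <- function() descriptor_registry()$name

# Validate that `v` is a complete morphometry vector (all 50 registry names,
# finite values). Returns v invisibly or stops.
check_morphometry_vector <- function(v) {
  nm <- descriptor_names()
  missing <- setdiff(nm, names(v))
  if (length(missing) > 0L)
    stop("incomplete morphometry vector; missing: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (!all(is.finite(v[nm]))) stop("non-finite descriptor values")
  invisible(v)
}

#' Build a morphometry vector from named values
#'
#' Convenience constructor filling unspecified descriptors with neutral
#' defaults of a normal erythrocyte profile. Intended for constructing test
#' vectors and knowledge-base prototypes; measured vectors come from
#' \code{\link{extract_descriptors}}.
#'
#' @param ... named descriptor values overriding the defaults (must be
#'   registry names), plus optional auxiliary measurements \code{pallor_eccentricity},
#'   \code{radial_inversions}, \code{inclusion_max_eccentricity},
#'   \code{inclusion_peripheral}, \code{interior_intensity}.
#' @return Named numeric vector of length 50 with an \code{aux} attribute.
#' @export
make_morphometry_vector <- function(...) {
  args <- list(...)
  aux_names <- c("pallor_eccentricity", "radial_inversions",
                 "inclusion_max_eccentricity", "inclusion_peripheral",
                 "interior_intensity")
  aux <- list(pallor_eccentricity = 0.2, radial_inversions = 1,
              inclusion_max_eccentricity = 0, inclusion_peripheral = 0,
              interior_intensity = 0.55)
  # normal RBC defaults: 7 um diameter disc, mild pallor, smooth boundary
  r <- 3.5; area <- pi * r^2; per <- 2 * pi * r
  v <- c(cell_area = area, cell_perimeter = per, circularity = 1,
         eccentricity = 0.1, nucleus_area = 0, nucleus_perimeter = 0,
         nucleus_circularity = 0, nucleus_eccentricity = 0,
         cytoplasm_area = area, cytoplasm_thickness = r, aspect_ratio = 1.02,
         elongation = 0.02, compactness = 1, convex_hull_area = area,
         solidity = 0.99, feret_diameter = 2 * r, min_feret_diameter = 2 * r,
         major_axis_length = 2 * r, minor_axis_length = 2 * r,
         orientation_angle = 0, chromatin_density = 0,
         nuclear_shape_factor = 0, nuclear_cytoplasmic_ratio = 0,
         lobe_count = 0, nuclear_texture_variance = 0,
         cell_volume_estimate = 4 / 3 * pi * r^3,
         nuclear_volume_estimate = 0, symmetry = 0.98, roundness = 0.98,
         nuclear_solidity = 0, texture_entropy = 1, texture_contrast = 0.1,
         texture_correlation = 0.5, texture_energy = 0.5,
         texture_homogeneity = 0.9, edge_gradient = 0.15,
         boundary_roughness = 1.02, nuclear_edge_contrast = 0,
         mean_red = 0.8, mean_green = 0.45, mean_blue = 0.45,
         mean_hue = 0, mean_saturation = 0.45, mean_value = 0.8,
         granularity_index = 0.001, vacuolation_level = 0.05,
         inclusion_count = 0, membrane_integrity = 0.95,
         cytoplasmic_granularity = 0.5, central_pallor_ratio = 0.25)
  for (nm in names(args)) {
    if (nm %in% aux_names) aux[[nm]] <- args[[nm]]
    else if (nm %in% names(v)) v[nm] <- args[[nm]]
    else stop("unknown descriptor: ", nm)
  }
  v <- v[descriptor_names()]
  attr(v, "aux") <- aux
  class(v) <- c("morphometry_vector", "numeric")
  v
}
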