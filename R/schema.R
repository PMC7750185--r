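# Variable vocabularies for the per-sample colostrum table. Level vectors are
# ordered with the reference level FIRST; all model matrices in the package
# use treatment contrasts, so the first level is the baseline of every
# reported coefficient. "Not applicable" is a structural level: it encodes
# that a covariate is undefined for a record (e.g. feeding-equipment cleaning
# for a sample taken straight from the cow's teat), not a missing value.

.cleaning_methods <- c("Water", "Hypochlorite", "Parlor wash",
                       "Peracetic acid", "Soap", "Not applicable")

.colstab_schema <- list(
  variables = list(
    collection_point = list(
      type = "categorical",
      levels = c("Cows teat", "Colostrum collection bucket",
                 "Feeding teat", "Esophageal tube")),
    calving_pen_days = list(type = "continuous", unit = "days"),
    premilk_disinfection = list(type = "categorical", levels = c("No", "Yes")),
    teat_dry_wiped = list(type = "categorical", levels = c("No", "Yes")),
    # reference is the structural level: machine-harvest coefficients are
    # read against samples collected directly from the cow's teat
    milking_system = list(
      type = "categorical",
      levels = c("Not applicable", "Parlor", "Robot")),
    collection_clean_freq = list(
      type = "categorical",
      levels = c("Each use", "Less than each use", "Not applicable")),
    collection_clean_method = list(type = "categorical",
                                   levels = .cleaning_methods),
    collection_hot_water = list(
      type = "categorical",
      levels = c("No", "Yes", "Not applicable")),
    feeding_clean_freq = list(
      type = "categorical",
      levels = c("Each calf", "Less than each calf", "Not applicable")),
    feeding_clean_method = list(type = "categorical",
                                levels = .cleaning_methods),
    feeding_hot_water = list(
      type = "categorical",
      levels = c("No", "Yes", "Not applicable")),
    colostrum_frozen = list(
      type = "categorical",
      levels = c("No", "Yes", "Not applicable")),
    pasteuriser_used = list(
      type = "categorical",
      levels = c("No", "Yes", "Not applicable"))
  ),
  # Applicability is decided by where the sample was taken. Teat-collected
  # samples never touch milking, collection or feeding equipment; samples
  # taken from the collection bucket never touch feeding equipment.
  structural_rules = list(
    list(when = c(collection_point = "Cows teat"),
         set_not_applicable = c("milking_system",
                                "collection_clean_freq",
                                "collection_clean_method",
                                "collection_hot_water",
                                "feeding_clean_freq",
                                "feeding_clean_method",
                                "feeding_hot_water",
                                "colostrum_frozen",
                                "pasteuriser_used")),
    list(when = c(collection_point = "Colostrum collection bucket"),
         set_not_applicable = c("feeding_clean_freq",
                                "feeding_clean_method",
                                "feeding_hot_water"))
  ),
  outcomes = list(
    tbc = list(count = "tbc", log = "log_tbc", threshold = 1e5),
    cc  = list(count = "cc",  log = "log_cc",  threshold = 1e4)
  ),
  id_columns = c("farm_id", "cow_id")
)

#' Variable schema of the colostrum sample table
#'
#' Returns the machine-readable schema used throughout the package: for every
#' management variable its type and (for categorical variables) the complete
#' level set with the reference level first, the structural-applicability
#' rules tied to the sample collection point, and the outcome columns with
#' their conventional failure thresholds (counts strictly above
#' 100,000 cfu/ml for TBC and 10,000 cfu/ml for CC fail).
#'
#' @return A list with elements `variables`, `structural_rules`, `outcomes`
#'   and `id_columns`. A JSON copy of the same schema ships in
#'   `system.file("extdata", "colostrum_schema.json", package = "colstab")`.
#' @export
#' @examples
#' names(colostrum_schema()$variables)
colostrum_schema <- function() .colstab_schema

#' Candidate model terms
#'
#' The thirteen variables offered to model building: the sample collection
#' point plus the twelve management covariates, in schema order.
#'
#' @return Character vector of variable names.
#' @export
candidate_terms <- function() names(.colstab_schema$variables)

# internal helpers -----------------------------------------------------------

.schema_levels <- function(var) .colstab_schema$variables[[var]]$levels

.categorical_vars <- function() {
  v <- .colstab_schema$variables
  names(v)[vapply(v, function(x) x$type == "categorical", logical(1))]
}

.continuous_vars <- function() {
  v <- .colstab_schema$variables
  names(v)[vapply(v, function(x) x$type == "continuous", logical(1))]
}

#' Write the schema as JSON
#'
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_schema_json <- function(path) {
  jsonlite::write_json(.colstab_schema, path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
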