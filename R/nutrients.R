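#' @keywords internal
"_PACKAGE"

# Fixed package-wide unit conventions. Every nutrient amount is per 100 g
# edible portion; all unit conversions happen at read time, never downstream.

.NUTRIENTS <- c(
  "protein", "total_fat", "saturated_fat", "omega3", "sodium",
  "iron", "zinc", "calcium", "potassium", "magnesium",
  "selenium", "folate", "vitamin_b12", "vitamin_a", "vitamin_d"
)

.NUTRIENT_UNITS <- c(
  protein = "g", total_fat = "g", saturated_fat = "g", omega3 = "g",
  sodium = "mg", iron = "mg", zinc = "mg", calcium = "mg",
  potassium = "mg", magnesium = "mg",
  selenium = "ug", folate = "ug", vitamin_b12 = "ug",
  vitamin_a = "ug_rae", vitamin_d = "ug"
)

# CSV column names carry the unit suffix so a file is self-describing.
.NUTRIENT_COLUMNS <- paste(.NUTRIENTS, .NUTRIENT_UNITS[.NUTRIENTS], sep = "_")
names(.NUTRIENT_COLUMNS) <- .NUTRIENTS

.PROVENANCE_LEVELS <- c("primary", "fallback_1", "fallback_2", "unresolved")
.PROVENANCE_COLUMNS <- paste0("provenance_", .NUTRIENTS)
names(.PROVENANCE_COLUMNS) <- .NUTRIENTS

#' Modeled nutrients and their fixed units
#'
#' The package models 15 nutrients per 100 g edible portion with fixed units:
#' grams for protein, total fat, saturated fat and total omega-3 fatty acids;
#' milligrams for sodium, iron, zinc, calcium, potassium and magnesium;
#' micrograms for selenium, folate, vitamin B12 and vitamin D; and micrograms
#' of retinol activity equivalents (RAE) for vitamin A.
#'
#' @return A data frame with columns `nutrient`, `unit` and `column` (the
#'   unit-suffixed CSV column name, e.g. `selenium_ug`).
#' @export
#' @examples
#' nutrient_units()
nutrient_units <- function() {
  data.frame(
    nutrient = .NUTRIENTS,
    unit = unname(.NUTRIENT_UNITS[.NUTRIENTS]),
    column = unname(.NUTRIENT_COLUMNS[.NUTRIENTS]),
    stringsAsFactors = FALSE
  )
}
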