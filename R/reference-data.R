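# Bundled reference tables: the October-2024 market price/yield rows for
# the 21 species groups and the published group-mean NRF scores for the
# uFISH database. These are transcriptions of printed summary tables; the
# per-item source data are not redistributed.

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "aquanrf")
  if (!nzchar(path)) stop("bundled file not found: ", file, call. = FALSE)
  path
}

#' Reference price and yield rows (October 2024)
#'
#' Market prices per kg of whole/landed product (already in USD) and USDA
#' edible-yield fractions for the 21 species groups. Abalone and crayfish
#' carry no price (none was available in the source report).
#'
#' @return A data frame with columns `species_group`, `price_per_kg`,
#'   `currency`, `yield_fraction`.
#' @export
reference_price_rows <- function() {
  df <- utils::read.csv(extdata_path("globefish_prices_oct2024.csv"),
                        stringsAsFactors = FALSE)
  df$price_per_kg <- suppressWarnings(as.numeric(df$price_per_kg))
  df
}

#' Reference price table
#'
#' [reference_price_rows()] wrapped as a validated `price_table`.
#'
#' @return A `price_table` with 21 rows (19 priced, 2 unpriced).
#' @export
reference_price_table <- function() {
  price_table(reference_price_rows())
}

#' Published group-mean NRF scores for the uFISH database
#'
#' Group-level NRF6.2 and NRF9.2 means, SDs (where printed), group sizes
#' and SEMs from the published uFISH nutrient-profiling analysis. The
#' `source` column distinguishes the ranked summary table (`"ranking"`)
#' from the per-nutrient group tables (`"group_table"`), which print two
#' values at different precision for a couple of cells. These reference
#' means are what species-level affordability indices were published from;
#' the package cannot regenerate them without the real per-item database.
#'
#' @param source Optional filter on the `source` column.
#' @return Data frame `group`, `metric`, `source`, `mean`, `sd`, `n`,
#'   `sem`.
#' @export
reference_group_scores <- function(source = NULL) {
  df <- utils::read.csv(extdata_path("ufish_reference_group_scores.csv"),
                        stringsAsFactors = FALSE)
  if (!is.null(source)) df <- df[df$source %in% source, , drop = FALSE]
  df
}

#' Reference group-mean protein content
#'
#' Group-mean protein (g per 100 g edible portion) per taxonomic group,
#' read off the shipped generator moments (which transcribe the published
#' group tables). Used as the protein summary when reproducing the
#' published cost-per-protein column.
#'
#' @return Data frame `group`, `mean`.
#' @export
reference_protein_means <- function() {
  cfg <- default_generator_config()
  data.frame(
    group = names(cfg$groups),
    mean = vapply(cfg$groups, function(g) g$mean[["protein"]], numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
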