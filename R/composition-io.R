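# Food composition tables: one row per food item, nutrient amounts per
# 100 g edible portion, taxonomy/state/habitat labels and per-nutrient
# provenance. Missing amounts are NA; provenance records where each value
# came from (primary | fallback_1 | fallback_2 | unresolved).

#' Construct and validate a food composition table
#'
#' @param df A data frame with columns `item_id`, `species_group`, `state`,
#'   `habitat`, `salinity` and one numeric column per nutrient named by the
#'   plain nutrient name (see [nutrient_units()]). `taxon_group` and
#'   `broad_group` are derived from `species_group` if absent. Provenance
#'   columns `provenance_<nutrient>` default to `"primary"` for non-missing
#'   amounts and `"unresolved"` for missing ones.
#' @return A data frame of class `food_table`.
#' @export
food_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("item_id", "species_group")) {
    if (!col %in% names(df)) {
      stop("mandatory column missing from composition table: '", col, "'",
           call. = FALSE)
    }
  }
  if (anyDuplicated(df$item_id)) {
    stop("duplicated item_id values in composition table", call. = FALSE)
  }
  tax <- species_to_taxon(df$species_group)
  df$taxon_group <- tax$taxon_group
  df$broad_group <- tax$broad_group
  if (!"state" %in% names(df)) df$state <- "raw"
  if (!"habitat" %in% names(df)) df$habitat <- "unknown"
  if (!"salinity" %in% names(df)) df$salinity <- "unknown"
  df$state <- match_vocab(df$state, .STATES, "state")
  df$habitat <- match_vocab(df$habitat, .HABITATS, "habitat")
  df$salinity <- match_vocab(df$salinity, .SALINITIES, "salinity")

  for (nut in .NUTRIENTS) {
    if (!nut %in% names(df)) df[[nut]] <- NA_real_
    df[[nut]] <- as.numeric(df[[nut]])
    pcol <- .PROVENANCE_COLUMNS[[nut]]
    if (!pcol %in% names(df)) {
      df[[pcol]] <- ifelse(is.na(df[[nut]]), "unresolved", "primary")
    }
    df[[pcol]] <- match_vocab(df[[pcol]], .PROVENANCE_LEVELS, "provenance")
  }
  validate_food_table(df)
  ord <- c("item_id", "species_group", "taxon_group", "broad_group",
           "state", "habitat", "salinity", .NUTRIENTS,
           unname(.PROVENANCE_COLUMNS))
  df <- df[, c(ord, setdiff(names(df), ord)), drop = FALSE]
  class(df) <- c("food_table", "data.frame")
  df
}

validate_food_table <- function(df) {
  for (nut in .NUTRIENTS) {
    bad <- which(!is.na(df[[nut]]) & df[[nut]] < 0)
    if (length(bad) > 0) {
      stop("negative ", nut, " amount for item(s): ",
           paste(utils::head(df$item_id[bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  both <- !is.na(df$saturated_fat) & !is.na(df$total_fat)
  if (any(df$saturated_fat[both] > df$total_fat[both] + 1e-9)) {
    stop("saturated_fat exceeds total_fat for item(s): ",
         paste(utils::head(df$item_id[which(both)[
           df$saturated_fat[both] > df$total_fat[both] + 1e-9]], 5),
           collapse = ", "), call. = FALSE)
  }
  both <- !is.na(df$omega3) & !is.na(df$total_fat)
  if (any(df$omega3[both] > df$total_fat[both] + 1e-9)) {
    stop("omega3 exceeds total_fat for item(s): ",
         paste(utils::head(df$item_id[which(both)[
           df$omega3[both] > df$total_fat[both] + 1e-9]], 5),
           collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a food composition CSV
#'
#' The on-disk schema uses unit-suffixed nutrient columns (`selenium_ug`,
#' `vitamin_a_ug_rae`, ...); empty or unparseable numeric cells become
#' missing values with provenance `"unresolved"`. Row count is preserved:
#' every CSV row becomes one food item.
#'
#' @param path Path to the CSV file.
#' @return A `food_table`.
#' @export
read_composition_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (col in c("item_id", "species_group")) {
    if (!col %in% names(raw)) {
      stop("mandatory column missing from '", path, "': '", col, "'",
           call. = FALSE)
    }
  }
  df <- raw[, intersect(c("item_id", "species_group", "state", "habitat",
                          "salinity"), names(raw)), drop = FALSE]
  for (nut in .NUTRIENTS) {
    col <- .NUTRIENT_COLUMNS[[nut]]
    if (col %in% names(raw)) {
      vals <- suppressWarnings(as.numeric(raw[[col]]))
      vals[!nzchar(trimws(raw[[col]]))] <- NA_real_
      df[[nut]] <- vals
    } else {
      df[[nut]] <- NA_real_
    }
    pcol <- .PROVENANCE_COLUMNS[[nut]]
    if (pcol %in% names(raw)) {
      prov <- raw[[pcol]]
      prov[is.na(df[[nut]])] <- "unresolved"
      df[[pcol]] <- prov
    }
  }
  food_table(df)
}

#' Write a food composition CSV
#'
#' Inverse of [read_composition_table()]: numeric content round-trips at
#' full double precision and provenance tags are preserved.
#'
#' @param items A `food_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(items, path) {
  out <- data.frame(
    item_id = items$item_id, species_group = items$species_group,
    state = items$state, habitat = items$habitat, salinity = items$salinity,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (nut in .NUTRIENTS) {
    out[[.NUTRIENT_COLUMNS[[nut]]]] <- format_num(items[[nut]])
    out[[.PROVENANCE_COLUMNS[[nut]]]] <- items[[.PROVENANCE_COLUMNS[[nut]]]]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Full-precision decimal formatting (digits = 17 survives the round trip).
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE)
  }, character(1))
  out
}

#' Read a price table CSV
#'
#' Schema: `species_group`, `price_per_kg` (whole/landed product; empty =
#' no price available), `currency` (EUR or USD), `yield_fraction` (edible
#' fraction of purchased weight, in (0, 1]).
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `price_table`.
#' @export
read_price_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  price_table(raw)
}

#' Construct and validate a price table
#'
#' @param df Data frame with columns `species_group`, `price_per_kg`,
#'   `currency`, `yield_fraction`.
#' @return A data frame of class `price_table`.
#' @export
price_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("species_group", "price_per_kg", "currency",
                "yield_fraction")) {
    if (!col %in% names(df)) {
      stop("mandatory column missing from price table: '", col, "'",
           call. = FALSE)
    }
  }
  species_to_taxon(df$species_group)  # vocabulary check
  df$price_per_kg <- suppressWarnings(as.numeric(df$price_per_kg))
  df$yield_fraction <- as.numeric(df$yield_fraction)
  df$currency <- match_vocab(df$currency, c("EUR", "USD"), "currency")
  if (any(!is.na(df$price_per_kg) & df$price_per_kg <= 0)) {
    stop("price_per_kg must be positive where present", call. = FALSE)
  }
  if (any(is.na(df$yield_fraction) | df$yield_fraction <= 0 |
          df$yield_fraction > 1)) {
    stop("yield_fraction must lie in (0, 1]", call. = FALSE)
  }
  class(df) <- c("price_table", "data.frame")
  df
}
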