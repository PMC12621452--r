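# Daily-value reference table and NRF nutrient profiles.

# FDA daily values (ages >= 4, 2,000 kcal reference diet). Total omega-3
# fatty acids have no FDA daily value; 1.6 g (the adult male ALA adequate
# intake) is shipped as the default denominator and is config-overridable.
.DEFAULT_DV <- c(
  protein = 50, total_fat = 78, saturated_fat = 20, omega3 = 1.6,
  sodium = 2300, iron = 18, zinc = 11, calcium = 1300, potassium = 4700,
  magnesium = 420, selenium = 55, folate = 400, vitamin_b12 = 2.4,
  vitamin_a = 900, vitamin_d = 20
)

#' Daily-value reference table
#'
#' Builds the table of reference daily values (DVs) used as the denominator
#' of every percent-daily-value computation. With no arguments the shipped
#' FDA-style defaults are returned (15 entries, one per modeled nutrient).
#' A config file (YAML or JSON, keys = nutrient names) can override any
#' subset of values; units are fixed package-wide and a config that declares
#' a different unit is rejected.
#'
#' @param path Optional path to a YAML/JSON config. Entries may be plain
#'   numbers (`omega3: 0.25`) or maps with `value` and optional `unit`
#'   (`selenium: {value: 70, unit: ug}`).
#' @param overrides Optional named list of numeric overrides, applied after
#'   the file.
#' @return An object of class `dv_table`: a named numeric vector of daily
#'   values with a `units` attribute.
#' @export
#' @examples
#' dv <- load_dv_table()
#' dv[["iron"]]
load_dv_table <- function(path = NULL, overrides = NULL) {
  dv <- .DEFAULT_DV
  apply_entries <- function(dv, entries, where) {
    for (nm in names(entries)) {
      if (!nm %in% .NUTRIENTS) {
        stop("unknown nutrient '", nm, "' in DV config ", where, call. = FALSE)
      }
      entry <- entries[[nm]]
      if (is.list(entry)) {
        if (!is.null(entry$unit) &&
            !identical(as.character(entry$unit), unname(.NUTRIENT_UNITS[nm]))) {
          stop(
            "unit mismatch for '", nm, "': config declares '", entry$unit,
            "' but the package models it in '", .NUTRIENT_UNITS[nm], "'",
            call. = FALSE
          )
        }
        entry <- entry$value
      }
      val <- suppressWarnings(as.numeric(entry))
      if (length(val) != 1 || is.na(val) || val <= 0) {
        stop("daily value for '", nm, "' must be a single positive number",
             call. = FALSE)
      }
      dv[[nm]] <- val
    }
    dv
  }
  if (!is.null(path)) {
    cfg <- read_config(path)
    entries <- if (!is.null(cfg$daily_values)) cfg$daily_values else cfg
    dv <- apply_entries(dv, entries, paste0("'", path, "'"))
  }
  if (!is.null(overrides)) dv <- apply_entries(dv, overrides, "(overrides)")
  structure(dv, units = .NUTRIENT_UNITS[.NUTRIENTS], class = "dv_table")
}

#' Define an NRF nutrient profile
#'
#' A profile names an ordered list of nutrients to encourage (the "n" of
#' NRn) and a list of nutrients to limit, together with the capping policy
#' applied to each percent daily value before summation.
#'
#' @param name Profile name.
#' @param encourage Ordered character vector of nutrients to encourage.
#' @param limit Ordered character vector of nutrients to limit.
#' @param cap_encourage Cap (percent) applied to each encourage %DV;
#'   default 100. Use `Inf` (or the string "uncapped") to disable.
#' @param cap_limit Cap applied to each limit %DV; default 100.
#' @param zero_if_absent Nutrients in `encourage` that are outside the
#'   modeled vector and contribute 0 (used by the classic NRF9.2 profile,
#'   whose fiber and vitamin C are negligible in aquatic foods).
#' @return An object of class `nutrient_profile`.
#' @export
nutrient_profile <- function(name, encourage, limit,
                             cap_encourage = 100, cap_limit = 100,
                             zero_if_absent = character()) {
  norm_cap <- function(cap) {
    if (identical(cap, "uncapped")) return(Inf)
    cap <- as.numeric(cap)
    if (length(cap) != 1 || is.na(cap) || cap <= 0) {
      stop("cap must be a positive number, Inf, or 'uncapped'", call. = FALSE)
    }
    cap
  }
  encourage <- as.character(encourage)
  limit <- as.character(limit)
  if (length(intersect(encourage, limit)) > 0) {
    stop("encourage and limit lists must be disjoint", call. = FALSE)
  }
  modeled <- setdiff(encourage, zero_if_absent)
  bad <- setdiff(c(modeled, limit), .NUTRIENTS)
  if (length(bad) > 0) {
    stop("profile '", name, "' references unknown nutrient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      name = name, encourage = encourage, limit = limit,
      cap_encourage = norm_cap(cap_encourage), cap_limit = norm_cap(cap_limit),
      zero_if_absent = zero_if_absent
    ),
    class = "nutrient_profile"
  )
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat("<nutrient_profile> ", x$name, "\n", sep = "")
  cat("  encourage (n=", length(x$encourage), "): ",
      paste(x$encourage, collapse = ", "), "\n", sep = "")
  cat("  limit: ", paste(x$limit, collapse = ", "), "\n", sep = "")
  cat("  cap encourage/limit: ", x$cap_encourage, "/", x$cap_limit,
      "\n", sep = "")
  invisible(x)
}

#' Shipped NRF profiles
#'
#' Three named profiles are shipped:
#' \describe{
#'   \item{`NRF6.2`}{Six priority micronutrients widely lacking in low- and
#'     middle-income-country diets — iron, zinc, calcium, vitamin A,
#'     vitamin B12 and folate — minus the two limit nutrients.}
#'   \item{`NRF9.2`}{The aquatic-food variant (the package default):
#'     protein, selenium, calcium, iron, potassium, magnesium, vitamin A,
#'     vitamin D and total omega-3 fatty acids.}
#'   \item{`NRF9.2-classic`}{The classic land-food nine (protein, fiber,
#'     calcium, iron, potassium, magnesium, vitamin A, vitamin C,
#'     vitamin D); fiber and vitamin C are not modeled for aquatic foods
#'     and contribute 0.}
#' }
#' Both limit lists are sodium and saturated fat; every %DV is capped at
#' 100 by default, limit nutrients included.
#'
#' @param name Profile name; with `NULL`, all shipped profiles are returned
#'   as a named list.
#' @return A `nutrient_profile`, or a named list of them.
#' @export
#' @examples
#' nrf_profile("NRF6.2")
nrf_profile <- function(name = NULL) {
  profiles <- list(
    "NRF6.2" = nutrient_profile(
      "NRF6.2",
      encourage = c("iron", "zinc", "calcium", "vitamin_a", "vitamin_b12",
                    "folate"),
      limit = c("sodium", "saturated_fat")
    ),
    "NRF9.2" = nutrient_profile(
      "NRF9.2",
      encourage = c("protein", "selenium", "calcium", "iron", "potassium",
                    "magnesium", "vitamin_a", "vitamin_d", "omega3"),
      limit = c("sodium", "saturated_fat")
    ),
    "NRF9.2-classic" = nutrient_profile(
      "NRF9.2-classic",
      encourage = c("protein", "fiber", "calcium", "iron", "potassium",
                    "magnesium", "vitamin_a", "vitamin_c", "vitamin_d"),
      limit = c("sodium", "saturated_fat"),
      zero_if_absent = c("fiber", "vitamin_c")
    )
  )
  if (is.null(name)) return(profiles)
  if (!name %in% names(profiles)) {
    stop("unknown profile '", name, "'. Shipped profiles: ",
         paste(names(profiles), collapse = ", "), call. = FALSE)
  }
  profiles[[name]]
}

# Read a YAML or JSON config file into a list, dispatching on extension.
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    # YAML 1.1 would otherwise read the bare key/value "n" as FALSE
    handlers <- list(
      "bool#yes" = function(x) {
        if (toupper(x) %in% c("TRUE", "YES", "ON")) TRUE else x
      },
      "bool#no" = function(x) {
        if (toupper(x) %in% c("FALSE", "NO", "OFF")) FALSE else x
      }
    )
    yaml::read_yaml(path, handlers = handlers)
  } else {
    stop("config must be .yaml, .yml or .json: ", path, call. = FALSE)
  }
}
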