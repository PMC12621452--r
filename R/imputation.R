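# Hierarchical lookup imputation: missing nutrient amounts are filled from
# an ordered cascade of fallback composition tables (emulating a
# primary-database -> national-database -> secondary-database lookup),
# per nutrient, recording which source supplied each value. No statistical
# imputation is performed — this is donor-record substitution only.

#' Declare a fallback composition source
#'
#' @param name Source name; `"fallback_1"`, `"fallback_2"`, ... by cascade
#'   position are the provenance tags recorded on filled values.
#' @param table A `food_table` of donor records.
#' @param priority Rank in the cascade (1 = consulted first).
#' @return An object of class `fallback_source`.
#' @export
fallback_source <- function(name, table, priority = 1L) {
  stopifnot(inherits(table, "data.frame"))
  if (!inherits(table, "food_table")) table <- food_table(table)
  priority <- as.integer(priority)
  if (is.na(priority) || priority < 1L) {
    stop("priority must be a positive integer", call. = FALSE)
  }
  structure(list(name = name, table = table, priority = priority),
            class = "fallback_source")
}

check_sources <- function(sources) {
  stopifnot(length(sources) > 0)
  sources <- lapply(sources, function(s) {
    if (!inherits(s, "fallback_source")) {
      stop("sources must be fallback_source objects", call. = FALSE)
    }
    s
  })
  pr <- vapply(sources, function(s) s$priority, integer(1))
  if (anyDuplicated(pr) || !setequal(pr, seq_along(sources))) {
    stop("source priorities must be unique and contiguous from 1",
         call. = FALSE)
  }
  sources[order(pr)]
}

#' Find the donor record for an item in one fallback source
#'
#' Matching is conservative and auditable: an exact
#' `(species_group, state)` match is preferred; failing that, any record of
#' the same `species_group` is accepted with the state requirement relaxed;
#' donors are never taken across species. Among tied candidates the donor
#' with the most non-missing nutrient fields wins, remaining ties broken by
#' lexicographic `item_id`.
#'
#' @param item One-row `food_table` (or list with `species_group`, `state`).
#' @param source A [fallback_source()].
#' @return A list with `donor` (one-row `food_table` or `NULL`) and
#'   `state_relaxed` (logical).
#' @export
match_candidate <- function(item, source) {
  tab <- source$table
  cand <- tab[tab$species_group == item$species_group, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(donor = NULL, state_relaxed = FALSE))
  }
  exact <- cand[cand$state == item$state, , drop = FALSE]
  state_relaxed <- nrow(exact) == 0
  pool <- if (state_relaxed) cand else exact
  n_filled <- rowSums(!is.na(as.matrix(pool[, .NUTRIENTS, drop = FALSE])))
  pool <- pool[order(-n_filled, pool$item_id), , drop = FALSE]
  list(donor = pool[1, , drop = FALSE], state_relaxed = state_relaxed)
}

# Donor values come from a different food record, so an imputed saturated
# fat or omega-3 can exceed the item's total fat (or an imputed total fat
# can undercut primary fat fractions). Imputed values are adjusted to
# restore the compositional invariants; primary values are never touched.
reconcile_fats <- function(row) {
  prov <- function(nut) row[[.PROVENANCE_COLUMNS[[nut]]]]
  imputed <- function(nut) {
    !is.na(row[[nut]]) && startsWith(prov(nut), "fallback")
  }
  tf <- row$total_fat
  parts <- c(row$saturated_fat, row$omega3)
  if (!is.na(tf) && imputed("total_fat")) {
    floor_tf <- max(parts, 0, na.rm = TRUE)
    if (tf < floor_tf) row$total_fat <- floor_tf
  }
  for (nut in c("saturated_fat", "omega3")) {
    if (!is.na(row[[nut]]) && !is.na(row$total_fat) && imputed(nut) &&
        row[[nut]] > row$total_fat) {
      row[[nut]] <- row$total_fat
    }
  }
  row
}

#' Fill missing nutrient values from a cascade of fallback sources
#'
#' Each missing field is filled from the first source (by priority) whose
#' matched donor has it non-missing; its provenance becomes
#' `"fallback_<priority>"`. Originally non-missing values are never
#' overwritten, and fields missing in every source stay missing with
#' provenance `"unresolved"`. The operation is idempotent.
#'
#' @param items A `food_table`.
#' @param sources List of [fallback_source()] objects (any order; sorted by
#'   priority internally).
#' @return List of class `imputation_result`: `items` (the filled
#'   `food_table`), `report` (data frame: `nutrient`, `source`, `fills`,
#'   plus an `unresolved` count per nutrient) and `unresolved_cells`
#'   (data frame of item/nutrient pairs still missing).
#' @export
impute_dataset <- function(items, sources) {
  stopifnot(inherits(items, "data.frame"))
  sources <- check_sources(sources)
  src_tags <- paste0("fallback_", vapply(sources, `[[`, integer(1),
                                         "priority"))
  fills <- matrix(0L, nrow = length(.NUTRIENTS), ncol = length(sources),
                  dimnames = list(.NUTRIENTS, src_tags))
  for (i in seq_len(nrow(items))) {
    missing_nuts <- .NUTRIENTS[is.na(unlist(items[i, .NUTRIENTS]))]
    if (length(missing_nuts) == 0) next
    for (s in seq_along(sources)) {
      m <- match_candidate(items[i, , drop = FALSE], sources[[s]])
      if (is.null(m$donor)) next
      for (nut in missing_nuts) {
        if (!is.na(items[i, nut])) next
        val <- m$donor[[nut]]
        if (!is.na(val)) {
          items[i, nut] <- val
          items[i, .PROVENANCE_COLUMNS[[nut]]] <- src_tags[s]
          fills[nut, s] <- fills[nut, s] + 1L
        }
      }
      if (!anyNA(unlist(items[i, missing_nuts]))) break
    }
    items[i, ] <- reconcile_fats(items[i, , drop = FALSE])
  }
  validate_food_table(items)
  unresolved <- do.call(rbind, lapply(.NUTRIENTS, function(nut) {
    idx <- which(is.na(items[[nut]]))
    if (length(idx) == 0) return(NULL)
    data.frame(item_id = items$item_id[idx], nutrient = nut,
               stringsAsFactors = FALSE)
  }))
  if (is.null(unresolved)) {
    unresolved <- data.frame(item_id = character(), nutrient = character(),
                             stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, lapply(.NUTRIENTS, function(nut) {
    data.frame(
      nutrient = nut, source = src_tags, fills = unname(fills[nut, ]),
      unresolved = sum(unresolved$nutrient == nut),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(items = items, report = report, unresolved_cells = unresolved),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("<imputation_result> ", sum(x$report$fills), " fills, ",
      nrow(x$unresolved_cells), " unresolved cells\n", sep = "")
  invisible(x)
}

#' Write an imputation report CSV
#'
#' @param result An [impute_dataset()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imputation_report <- function(result, path) {
  utils::write.csv(result$report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
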