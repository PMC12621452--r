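# Nutrient Rich Food (NRF) scoring. Scores are built from percent daily
# values computed per 100 g edible portion and capped (at 100% by default):
# NRn is the sum of capped %DV over the n nutrients to encourage, LIM the
# sum over the nutrients to limit, and NRFn.2 = NRn - LIM. Scores are
# computed per item and then averaged; because the cap acts per item this
# is not the same as scoring the group-mean nutrient vector.

#' Percent daily value of a nutrient amount
#'
#' @param amount Nutrient amount per 100 g edible portion (same unit as the
#'   daily value). Must be non-missing; apply an imputation or
#'   missing-value policy first.
#' @param dv Daily value (> 0).
#' @param cap Cap in percent; `Inf` disables capping.
#' @return `min(100 * amount / dv, cap)`, vectorised.
#' @export
#' @examples
#' percent_dv(65.96, 55)          # capped at 100
#' percent_dv(4.38, 18)           # 24.33
percent_dv <- function(amount, dv, cap = 100) {
  if (any(is.na(amount))) {
    stop("missing nutrient amount: impute or apply a missing-value policy ",
         "before computing %DV", call. = FALSE)
  }
  if (any(dv <= 0)) stop("daily value must be positive", call. = FALSE)
  if (any(amount < 0)) stop("amounts must be non-negative", call. = FALSE)
  pmin(100 * amount / dv, cap)
}

item_amounts <- function(item, nutrients, profile, missing_policy) {
  amounts <- numeric(length(nutrients))
  names(amounts) <- nutrients
  for (nut in nutrients) {
    if (nut %in% profile$zero_if_absent) {
      amounts[[nut]] <- 0
      next
    }
    val <- item[[nut]]
    if (is.na(val)) {
      if (missing_policy == "zero") {
        val <- 0
      } else {
        stop("item '", item$item_id, "' has no value for '", nut,
             "' (strict missing policy); impute first or use ",
             "missing_policy = \"zero\"", call. = FALSE)
      }
    }
    amounts[[nut]] <- val
  }
  amounts
}

subscore <- function(item, nutrients, cap, profile, dv, missing_policy) {
  amounts <- item_amounts(item, nutrients, profile, missing_policy)
  pdv <- numeric(length(nutrients))
  names(pdv) <- nutrients
  for (nut in nutrients) {
    ref <- if (nut %in% profile$zero_if_absent) 1 else dv[[nut]]
    pdv[[nut]] <- percent_dv(amounts[[nut]], ref, cap)
  }
  pdv
}

#' NR subscore: sum of capped %DV over nutrients to encourage
#'
#' @param item A one-row `food_table` (or list-like with nutrient fields
#'   and `item_id`).
#' @param profile A [nutrient_profile()]; default the aquatic NRF9.2.
#' @param dv A [load_dv_table()] table.
#' @param missing_policy `"strict"` (error on missing amounts, the default —
#'   faithful to a pipeline that imputes before scoring) or `"zero"`
#'   (missing amounts contribute 0, biasing scores downward).
#' @return Sum of capped %DV over the profile's encourage list
#'   (percent-points, bounded by `n * cap_encourage`).
#' @export
nr_subscore <- function(item, profile = nrf_profile("NRF9.2"),
                        dv = load_dv_table(), missing_policy = "strict") {
  sum(subscore(item, profile$encourage, profile$cap_encourage, profile, dv,
               missing_policy))
}

#' LIM subscore: sum of capped %DV over nutrients to limit
#'
#' @inheritParams nr_subscore
#' @return Sum of capped %DV over the profile's limit list.
#' @export
lim_subscore <- function(item, profile = nrf_profile("NRF9.2"),
                         dv = load_dv_table(), missing_policy = "strict") {
  sum(subscore(item, profile$limit, profile$cap_limit, profile, dv,
               missing_policy))
}

#' NRF score of one food item
#'
#' `NRFn.2 = NRn - LIM` with the per-nutrient %DV breakdown retained.
#'
#' @inheritParams nr_subscore
#' @return An object of class `nrf_score`: list with `item_id`, `profile`,
#'   `nr`, `lim`, `nrf` and `breakdown` (named %DV vector).
#' @export
#' @examples
#' item <- list(item_id = "x", protein = 23.8, calcium = 38.4, iron = 1.24,
#'              potassium = 433, magnesium = 35.2, selenium = 66.2,
#'              vitamin_a = 4.80, vitamin_d = 30.1, omega3 = 1.56,
#'              saturated_fat = 3, sodium = 90)
#' nrf_score(item)$nrf
nrf_score <- function(item, profile = nrf_profile("NRF9.2"),
                      dv = load_dv_table(), missing_policy = "strict") {
  enc <- subscore(item, profile$encourage, profile$cap_encourage, profile,
                  dv, missing_policy)
  lim <- subscore(item, profile$limit, profile$cap_limit, profile, dv,
                  missing_policy)
  structure(
    list(
      item_id = item$item_id, profile = profile$name,
      nr = sum(enc), lim = sum(lim), nrf = sum(enc) - sum(lim),
      breakdown = c(enc, lim)
    ),
    class = "nrf_score"
  )
}

#' @export
print.nrf_score <- function(x, ...) {
  cat("<nrf_score> ", x$profile, " item ", x$item_id, ": NR ",
      round(x$nr, 2), " - LIM ", round(x$lim, 2), " = ",
      round(x$nrf, 2), "\n", sep = "")
  invisible(x)
}

#' Score a whole composition table and summarise by group
#'
#' Computes one score per item, then per-group N, mean, sample SD (n-1
#' denominator) and SEM (= SD/sqrt(N)) of the NRF score. Empty groups are
#' dropped with a warning.
#'
#' @param items A `food_table`.
#' @param profile A [nutrient_profile()] or shipped profile name.
#' @param dv A [load_dv_table()] table.
#' @param group_by Column(s) of `items` to group the summary by
#'   (e.g. `"broad_group"`, `"taxon_group"`, `"species_group"`,
#'   `"habitat"`).
#' @param missing_policy See [nr_subscore()].
#' @return List of class `nrf_scoreset` with elements `scores` (data frame:
#'   `item_id`, group columns, `nr`, `lim`, `nrf`, one column per %DV) and
#'   `summary` (data frame: group, `metric`, `n`, `mean`, `sd`, `sem`).
#' @export
score_dataset <- function(items, profile = nrf_profile("NRF9.2"),
                          dv = load_dv_table(), group_by = "taxon_group",
                          missing_policy = "strict") {
  if (is.character(profile)) profile <- nrf_profile(profile)
  stopifnot(inherits(items, "data.frame"), nrow(items) > 0)
  missing_cols <- setdiff(group_by, names(items))
  if (length(missing_cols) > 0) {
    stop("grouping column(s) not in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(items)), function(i) {
    s <- nrf_score(items[i, , drop = FALSE], profile, dv, missing_policy)
    c(list(item_id = s$item_id, nr = s$nr, lim = s$lim, nrf = s$nrf),
      as.list(s$breakdown))
  })
  scores <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  names(scores)[-(1:4)] <- paste0("pdv_", names(scores)[-(1:4)])
  for (g in group_by) scores[[g]] <- items[[g]]
  scores <- scores[, c("item_id", group_by,
                       setdiff(names(scores), c("item_id", group_by)))]
  summary <- summarise_metric(scores$nrf, scores[, group_by, drop = FALSE],
                              metric = profile$name)
  structure(list(scores = scores, summary = summary, profile = profile$name),
            class = "nrf_scoreset")
}

# Group summary of a numeric metric: N, mean, sample SD, SEM.
summarise_metric <- function(values, groups, metric = "metric") {
  key <- interaction(groups, drop = TRUE, lex.order = TRUE, sep = ":")
  keep <- !is.na(values)
  if (!all(keep)) {
    warning(sum(!keep), " missing metric value(s) dropped from summary")
  }
  values <- values[keep]
  key <- droplevels(key[keep])
  if (nlevels(key) == 0) {
    warning("no non-empty groups to summarise")
  }
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    v <- values[key == lv]
    data.frame(
      group = lv, metric = metric, n = length(v), mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  out$sem <- out$sd / sqrt(out$n)
  out
}

#' @export
print.nrf_scoreset <- function(x, ...) {
  cat("<nrf_scoreset> ", x$profile, ": ", nrow(x$scores), " items, ",
      nrow(x$summary), " groups\n", sep = "")
  print(x$summary)
  invisible(x)
}
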