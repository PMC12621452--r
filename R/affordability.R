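# Price processing and the NRF affordability index. Prices arrive per kg of
# whole/landed product; dividing by the edible yield fraction gives the
# price per kg edible portion, which is the denominator of the
# affordability index (mean NRF score per USD/kg edible) and of the cost
# per 100 g protein.

#' Convert a price to USD
#'
#' @param price Price per kg.
#' @param currency `"EUR"` or `"USD"` (vectorised).
#' @param rate_eur_to_usd EUR->USD exchange rate; the October-2024 reference
#'   rate 1.09 is the default.
#' @return Price in USD per kg.
#' @export
convert_currency <- function(price, currency, rate_eur_to_usd = 1.09) {
  if (!is.numeric(rate_eur_to_usd) || length(rate_eur_to_usd) != 1 ||
      is.na(rate_eur_to_usd) || rate_eur_to_usd <= 0) {
    stop("exchange rate must be a positive number", call. = FALSE)
  }
  currency <- match_vocab(currency, c("EUR", "USD"), "currency")
  ifelse(currency == "EUR", price * rate_eur_to_usd, price)
}

#' Price per kg of edible portion
#'
#' @param price_usd_per_kg_whole Price per kg of whole/landed product (USD).
#' @param yield_fraction Edible fraction of purchased weight, in (0, 1].
#' @return `price / yield`, in USD per kg edible portion.
#' @export
#' @examples
#' edible_price(4.44, 0.54)  # 8.22 USD/kg edible
edible_price <- function(price_usd_per_kg_whole, yield_fraction) {
  if (any(is.na(yield_fraction) | yield_fraction <= 0 |
          yield_fraction > 1)) {
    stop("yield_fraction must lie in (0, 1]", call. = FALSE)
  }
  price_usd_per_kg_whole / yield_fraction
}

#' Cost of 100 g of protein
#'
#' Cost per 100 g edible portion divided by protein content per 100 g,
#' scaled to 100 g protein: `10 * price_per_kg_edible / protein`.
#'
#' @param price_usd_per_kg_edible Edible-portion price (USD/kg).
#' @param protein_g_per_100g Protein content (g per 100 g edible portion).
#' @return USD per 100 g protein.
#' @export
#' @examples
#' cost_per_100g_protein(edible_price(4.44, 0.54), 23.8)  # 3.45
cost_per_100g_protein <- function(price_usd_per_kg_edible,
                                  protein_g_per_100g) {
  if (any(is.na(protein_g_per_100g) | protein_g_per_100g <= 0)) {
    stop("protein content must be positive", call. = FALSE)
  }
  (price_usd_per_kg_edible / 10) / protein_g_per_100g * 100
}

#' NRF affordability index
#'
#' Mean NRF score divided by the edible-portion price: NRF points per
#' (USD/kg edible). A negative mean NRF yields a negative index.
#'
#' @param mean_nrf Mean NRF score of the species group (points).
#' @param price_usd_per_kg_edible Edible-portion price (USD/kg, > 0).
#' @return Score points per USD/kg edible.
#' @export
#' @examples
#' affordability_index(288.80, edible_price(4.44, 0.54))  # ~35.1
affordability_index <- function(mean_nrf, price_usd_per_kg_edible) {
  if (any(is.na(price_usd_per_kg_edible) | price_usd_per_kg_edible <= 0)) {
    stop("edible-portion price must be positive", call. = FALSE)
  }
  mean_nrf / price_usd_per_kg_edible
}

lookup_group_mean <- function(summaries, species, taxon) {
  hit <- summaries$mean[summaries$group == species]
  if (length(hit) == 0) hit <- summaries$mean[summaries$group == taxon]
  if (length(hit) == 0) NA_real_ else hit[[1]]
}

#' Build the affordability ranking table
#'
#' Joins a price table with NRF score summaries and protein summaries into
#' one record per priced species group: edible-portion price, cost per
#' 100 g protein, NRF6.2 and NRF9.2 affordability indices, and ranks.
#' Species with no price are kept as explicit not-available rows. Summary
#' groups may be keyed by species group or by taxonomic group; species-level
#' entries win.
#'
#' @param prices A `price_table`.
#' @param nrf6_summaries,nrf9_summaries Data frames with columns `group` and
#'   `mean` (as produced by [score_dataset()]'s `summary`).
#' @param protein_summaries Data frame with columns `group` and `mean`
#'   protein (g/100 g).
#' @param rate_eur_to_usd EUR->USD rate applied to EUR rows.
#' @return Data frame of class `affordability_table`, sorted by descending
#'   NRF9.2 affordability (unpriced rows last), with columns
#'   `species_group`, `taxon_group`, `price_usd_per_kg_whole`,
#'   `yield_fraction`, `price_usd_per_kg_edible`,
#'   `cost_usd_per_100g_protein`, `nrf6_2_affordability`,
#'   `nrf9_2_affordability`, `rank_nrf6_2`, `rank_nrf9_2`.
#' @export
build_affordability_table <- function(prices, nrf6_summaries,
                                      nrf9_summaries, protein_summaries,
                                      rate_eur_to_usd = 1.09) {
  stopifnot(inherits(prices, "data.frame"))
  tax <- species_to_taxon(prices$species_group)
  out <- data.frame(
    species_group = prices$species_group,
    taxon_group = tax$taxon_group,
    price_usd_per_kg_whole = NA_real_, yield_fraction = prices$yield_fraction,
    price_usd_per_kg_edible = NA_real_, cost_usd_per_100g_protein = NA_real_,
    nrf6_2_affordability = NA_real_, nrf9_2_affordability = NA_real_,
    stringsAsFactors = FALSE
  )
  priced <- !is.na(prices$price_per_kg)
  out$price_usd_per_kg_whole[priced] <- convert_currency(
    prices$price_per_kg[priced], prices$currency[priced], rate_eur_to_usd
  )
  out$price_usd_per_kg_edible[priced] <- edible_price(
    out$price_usd_per_kg_whole[priced], out$yield_fraction[priced]
  )
  drop <- logical(nrow(out))
  for (i in which(priced)) {
    sp <- out$species_group[i]
    tg <- out$taxon_group[i]
    protein <- lookup_group_mean(protein_summaries, sp, tg)
    m6 <- lookup_group_mean(nrf6_summaries, sp, tg)
    m9 <- lookup_group_mean(nrf9_summaries, sp, tg)
    if (is.na(protein) || is.na(m6) || is.na(m9)) {
      warning("no score/protein summary for priced group '", sp,
              "'; skipped")
      drop[i] <- TRUE
      next
    }
    out$cost_usd_per_100g_protein[i] <-
      cost_per_100g_protein(out$price_usd_per_kg_edible[i], protein)
    out$nrf6_2_affordability[i] <-
      affordability_index(m6, out$price_usd_per_kg_edible[i])
    out$nrf9_2_affordability[i] <-
      affordability_index(m9, out$price_usd_per_kg_edible[i])
  }
  out <- out[!drop, , drop = FALSE]
  out$rank_nrf6_2 <- rank(-out$nrf6_2_affordability, na.last = "keep",
                          ties.method = "min")
  out$rank_nrf9_2 <- rank(-out$nrf9_2_affordability, na.last = "keep",
                          ties.method = "min")
  out <- out[order(-out$nrf9_2_affordability, out$species_group,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("affordability_table", "data.frame")
  out
}

#' Write an affordability table CSV
#'
#' Money and index columns are rounded to 2 decimal places for reporting
#' (internal arithmetic is unrounded); unpriced groups print `NA`.
#'
#' @param table An [build_affordability_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affordability_table <- function(table, path) {
  out <- as.data.frame(table)
  money <- c("price_usd_per_kg_whole", "price_usd_per_kg_edible",
             "cost_usd_per_100g_protein", "nrf6_2_affordability",
             "nrf9_2_affordability")
  for (col in money) out[[col]] <- round(out[[col]], 2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
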