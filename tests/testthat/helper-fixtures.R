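# In-code fixtures shared across the suite. All data are generated here or
# by the package's own synthetic-data module; nothing is read from outside
# the repository.

# A fully populated nutrient row (per 100 g) with plausible finfish values.
complete_nutrients <- function() {
  list(
    protein = 20, total_fat = 5, saturated_fat = 1.2, omega3 = 0.8,
    sodium = 90, iron = 1.0, zinc = 1.5, calcium = 30, potassium = 350,
    magnesium = 30, selenium = 40, folate = 10, vitamin_b12 = 3,
    vitamin_a = 12, vitamin_d = 5
  )
}

# Small composition table: n items cycling through a few species groups.
make_items <- function(n = 3, species = c("mackerel", "mussel", "tilapia"),
                       state = "raw", overrides = list()) {
  base <- complete_nutrients()
  rows <- lapply(seq_len(n), function(i) {
    r <- c(list(item_id = sprintf("item_%02d", i),
                species_group = species[(i - 1) %% length(species) + 1],
                state = state, habitat = "wild", salinity = "saltwater"),
           base)
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  for (nm in names(overrides)) df[[nm]] <- overrides[[nm]]
  food_table(df)
}

# The worked small-pelagic-like item used by the scoring oracle tests.
mackerel_like_item <- function() {
  list(
    item_id = "mackerel_like", protein = 23.8, calcium = 38.4, iron = 1.24,
    potassium = 433, magnesium = 35.2, selenium = 66.2, vitamin_a = 4.80,
    vitamin_d = 30.1, omega3 = 1.56, saturated_fat = 3, sodium = 90,
    total_fat = 12, zinc = 0.52, vitamin_b12 = 7.81, folate = 2.13
  )
}

# Random grouped samples for the ANOVA/Tukey oracle-equivalence loops.
random_grouped <- function(k = 3, n_min = 3, n_max = 8) {
  n_i <- sample(n_min:n_max, k, replace = TRUE)
  groups <- rep(paste0("g", seq_len(k)), times = n_i)
  values <- stats::rnorm(sum(n_i), mean = rep(stats::runif(k, 0, 5),
                                              times = n_i))
  list(values = values, groups = groups)
}

expect_sorted_desc <- function(x) {
  expect_true(all(diff(x[!is.na(x)]) <= 1e-12))
}
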