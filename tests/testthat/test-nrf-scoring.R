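dv <- load_dv_table()

test_that("percent_dv caps, zeroes, errors and scale-equivariance", {
  expect_equal(percent_dv(0, 55), 0)
  expect_equal(percent_dv(65.96, 55), 100)           # uncapped 119.93
  expect_equal(percent_dv(65.96, 55, cap = Inf), 119.9273, tolerance = 1e-6)
  expect_equal(percent_dv(4.38, 18), 24.3333, tolerance = 1e-4)
  expect_error(percent_dv(NA_real_, 55), "impute")
  expect_error(percent_dv(1, 0), "positive")
  expect_error(percent_dv(-1, 55), "non-negative")
  # doubling both amount and DV leaves %DV unchanged
  for (amt in c(0.3, 7, 120)) {
    expect_equal(percent_dv(amt, 55), percent_dv(2 * amt, 110))
  }
})

test_that("subscores reproduce hand-computed values", {
  item <- mackerel_like_item()
  p9 <- nrf_profile("NRF9.2")
  # 47.60 + 2.95 + 6.89 + 9.21 + 8.38 + 100 + 0.53 + 100 + 97.50 = 373.07
  expect_equal(nr_subscore(item, p9, dv), 373.0698, tolerance = 1e-4)
  # satfat 3 g -> 15.00, sodium 90 mg -> 3.91
  expect_equal(lim_subscore(item, p9, dv), 18.913, tolerance = 1e-3)
  s <- nrf_score(item, p9, dv)
  expect_equal(s$nrf, 354.157, tolerance = 1e-3)
  expect_equal(s$nrf, s$nr - s$lim)
  expect_named(s$breakdown, c(p9$encourage, p9$limit))
})

test_that("ceiling, zero and cap-forced cases", {
  p6 <- nrf_profile("NRF6.2")
  at_dv <- list(item_id = "at_dv", iron = 18, zinc = 11, calcium = 1300,
                vitamin_a = 900, vitamin_b12 = 2.4, folate = 400,
                sodium = 0, saturated_fat = 0)
  expect_equal(nr_subscore(at_dv, p6, dv), 600)
  expect_equal(nrf_score(at_dv, p6, dv)$nrf, 600)
  zero <- as.list(setNames(rep(0, 15), nutrient_units()$nutrient))
  zero$item_id <- "zero"
  expect_equal(nrf_score(zero, p6, dv)$nrf, 0)
  expect_equal(nrf_score(zero, nrf_profile("NRF9.2"), dv)$nrf, 0)
  over <- list(item_id = "over", saturated_fat = 40, sodium = 5000)
  expect_equal(lim_subscore(over, p6, dv), 200)
})

test_that("missing policy: strict errors name item and nutrient, zero-fill biases down", {
  p6 <- nrf_profile("NRF6.2")
  items <- make_items(2, overrides = list(zinc = c(NA, 1.5)))
  expect_error(nrf_score(items[1, ], p6, dv), "item_01.*zinc")
  strict <- nrf_score(items[2, ], p6, dv)$nrf
  zeroed <- nrf_score(items[1, ], p6, dv, missing_policy = "zero")$nrf
  expect_lt(zeroed, strict)
})

test_that("classic NRF9.2 profile zero-fills fiber and vitamin C", {
  pc <- nrf_profile("NRF9.2-classic")
  item <- make_items(1)[1, ]
  s <- nrf_score(item, pc, dv)
  expect_equal(unname(s$breakdown[["fiber"]]), 0)
  expect_equal(unname(s$breakdown[["vitamin_c"]]), 0)
  # equals the same profile without the absent nutrients
  p7 <- nutrient_profile("seven", setdiff(pc$encourage, pc$zero_if_absent),
                         pc$limit)
  expect_equal(s$nrf, nrf_score(item, p7, dv)$nrf)
})

test_that("score_dataset summaries: two-point formulas and SEM identity", {
  # two items engineered to score 100 and 200 on a single-nutrient profile
  p <- nutrient_profile("iron_only", "iron", "sodium", cap_encourage = Inf)
  items <- make_items(2, species = "cod",
                      overrides = list(iron = c(18, 36), sodium = c(0, 0)))
  ss <- score_dataset(items, p, dv, group_by = "taxon_group")
  expect_equal(sort(ss$scores$nrf), c(100, 200))
  expect_equal(ss$summary$mean, 150)
  expect_equal(ss$summary$sd, 70.7107, tolerance = 1e-4)
  expect_equal(ss$summary$sem, 50)
  expect_equal(ss$summary$n, 2)
})

test_that("published SD/N pairs reproduce the printed SEM column", {
  ref <- reference_group_scores("ranking")
  ref <- ref[!is.na(ref$sd), ]
  expect_gt(nrow(ref), 10)
  expect_equal(round(ref$sd / sqrt(ref$n), 2), ref$sem, tolerance = 5e-3)
  # the crustacean NRF6.2 row specifically: 33.83/sqrt(152) = 2.744 -> 2.74
  cr <- ref[ref$group == "crustacean" & ref$metric == "NRF6.2", ]
  expect_equal(cr$sd / sqrt(cr$n), 2.744, tolerance = 1e-3)
  expect_equal(round(cr$sd / sqrt(cr$n), 2), 2.74)
})

test_that("monotonicity: encourage up never lowers NRF, limit up never raises it", {
  set.seed(11)
  p9 <- nrf_profile("NRF9.2")
  for (rep in 1:20) {
    base <- complete_nutrients()
    for (nm in names(base)) base[[nm]] <- base[[nm]] * runif(1, 0.2, 3)
    base$saturated_fat <- min(base$saturated_fat, base$total_fat)
    base$omega3 <- min(base$omega3, base$total_fat)
    base$item_id <- "m"
    s0 <- nrf_score(base, p9, dv)$nrf
    nut_up <- sample(p9$encourage, 1)
    up <- base
    up[[nut_up]] <- up[[nut_up]] + runif(1, 0.1, 50)
    expect_gte(nrf_score(up, p9, dv)$nrf, s0)
    lim_up <- sample(p9$limit, 1)
    worse <- base
    worse[[lim_up]] <- worse[[lim_up]] + runif(1, 0.1, 50)
    if (lim_up == "saturated_fat") worse$total_fat <- worse$saturated_fat + 1
    expect_lte(nrf_score(worse, p9, dv)$nrf, s0)
  }
})

test_that("linearity in the cap-free regime: mean of scores = score of mean vector", {
  set.seed(12)
  p_free <- nutrient_profile("free", nrf_profile("NRF9.2")$encourage,
                             nrf_profile("NRF9.2")$limit,
                             cap_encourage = Inf, cap_limit = Inf)
  for (rep in 1:5) {
    n <- 8
    df <- make_items(n, species = "salmon")
    for (nut in nutrient_units()$nutrient) {
      df[[nut]] <- runif(n, 0, 5)
    }
    df$total_fat <- df$total_fat + df$saturated_fat + df$omega3
    df <- food_table(as.data.frame(df))
    ss <- score_dataset(df, p_free, dv, group_by = "species_group")
    mean_vec <- as.list(colMeans(as.data.frame(df)[nutrient_units()$nutrient]))
    mean_vec$item_id <- "mean_vector"
    expect_equal(mean(ss$scores$nrf),
                 nrf_score(mean_vec, p_free, dv)$nrf, tolerance = 1e-10)
  }
})

test_that("score bounds hold on random items", {
  set.seed(13)
  p6 <- nrf_profile("NRF6.2")
  p9 <- nrf_profile("NRF9.2")
  for (rep in 1:30) {
    item <- lapply(complete_nutrients(), function(v) v * runif(1, 0, 10))
    item$saturated_fat <- min(item$saturated_fat, item$total_fat)
    item$omega3 <- min(item$omega3, item$total_fat)
    item$item_id <- "b"
    s6 <- nrf_score(item, p6, dv)
    s9 <- nrf_score(item, p9, dv)
    expect_true(s6$nrf >= -200 && s6$nrf <= 600)
    expect_true(s9$nrf >= -200 && s9$nrf <= 900)
    expect_true(all(s6$breakdown >= 0 & s6$breakdown <= 100))
  }
})

test_that("empty groups are dropped with a warning", {
  items <- make_items(3, species = "cod")
  items$nrf_dummy <- c(1, NA, 2)
  expect_warning(
    aquanrf:::summarise_metric(items$nrf_dummy,
                               items[, "taxon_group", drop = FALSE]),
    "dropped"
  )
})
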