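test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  # groups {1,2,3}, {2,3,4}, {3,4,5}: SSB = 6, SSW = 6, F = 3 on (2, 6) df
  fit <- one_way_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(fit$ss_between, 6)
  expect_equal(fit$ss_within, 6)
  expect_equal(fit$F, 3)
  expect_equal(fit$df_between, 2)
  expect_equal(fit$df_within, 6)
  expect_equal(fit$p, pf(3, 2, 6, lower.tail = FALSE))
})

test_that("degenerate inputs: identical groups, tiny groups", {
  fit <- one_way_anova(rep(c(5, 6), 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(fit$F, 0)
  expect_equal(fit$p, 1)
  expect_error(one_way_anova(1:5, c("a", "a", "a", "a", "b")),
               "at least 2 observations")
  expect_error(one_way_anova(1:4, rep("a", 4)), "at least 2 groups")
})

test_that("ANOVA agrees with the reference implementation on random fixtures", {
  set.seed(31)
  for (rep in 1:100) {
    d <- random_grouped(k = sample(2:5, 1))
    fit <- one_way_anova(d$values, d$groups)
    ref <- anova(stats::aov(d$values ~ factor(d$groups)))
    expect_equal(fit$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(fit$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(fit$df_within, ref$Df[2])
  }
})

test_that("ANOVA is invariant to shifts and F invariant to scaling", {
  set.seed(32)
  d <- random_grouped(k = 4)
  f0 <- one_way_anova(d$values, d$groups)$F
  expect_equal(one_way_anova(d$values + 100, d$groups)$F, f0,
               tolerance = 1e-9)
  expect_equal(one_way_anova(d$values * 7.5, d$groups)$F, f0,
               tolerance = 1e-9)
})

test_that("Tukey HSD adjusted p agrees with the reference implementation", {
  set.seed(33)
  for (rep in 1:30) {
    d <- random_grouped(k = 3)
    tk <- tukey_hsd(d$values, d$groups)
    ref <- stats::TukeyHSD(stats::aov(d$values ~ factor(d$groups)))[[1]]
    ref_pairs <- do.call(rbind, strsplit(rownames(ref), "-"))
    for (i in seq_len(nrow(ref))) {
      j <- which((tk$pairs$group_a == ref_pairs[i, 2] &
                    tk$pairs$group_b == ref_pairs[i, 1]) |
                   (tk$pairs$group_a == ref_pairs[i, 1] &
                      tk$pairs$group_b == ref_pairs[i, 2]))
      expect_equal(tk$pairs$p_adj[j], ref[i, "p adj"], tolerance = 1e-8)
      expect_equal(abs(tk$pairs$diff[j]), abs(ref[i, "diff"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("Tukey adjusted p agrees with a brute-force studentized-range oracle", {
  # independent oracle: adjusted p = P(range of k studentized means > q),
  # estimated by Monte Carlo simulation under the null
  set.seed(34)
  d <- list(values = c(rnorm(6, 0), rnorm(6, 1.2), rnorm(6, 2.4)),
            groups = rep(c("a", "b", "c"), each = 6))
  tk <- tukey_hsd(d$values, d$groups)
  k <- 3
  df <- tk$anova$df_within
  nsim <- 40000
  sim_range <- replicate(nsim, {
    z <- rnorm(k)
    s <- sqrt(rchisq(1, df) / df)
    (max(z) - min(z)) / s
  })
  for (i in seq_len(nrow(tk$pairs))) {
    q_obs <- abs(tk$pairs$diff[i]) / tk$pairs$se[i]
    p_mc <- mean(sim_range > q_obs)
    expect_equal(tk$pairs$p_adj[i], p_mc, tolerance = 0.02)
  }
})

test_that("compact letters: identical groups share, separated groups differ", {
  same <- tukey_hsd(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(same$letters == "a"))
  expect_true(all(!same$pairs$significant))

  set.seed(35)
  far <- tukey_hsd(c(rnorm(10, 0, 1), rnorm(10, 100, 1)),
                   rep(c("lo", "hi"), each = 10))
  expect_true(all(far$pairs$significant))
  expect_equal(unname(far$letters[c("hi", "lo")]), c("a", "b"))
})

test_that("letters never contradict the pairwise significance table", {
  set.seed(36)
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    sep <- runif(1, 0, 3)
    n_i <- sample(3:7, k, replace = TRUE)
    values <- unlist(lapply(seq_len(k), function(i) {
      rnorm(n_i[i], mean = i * sep)
    }))
    groups <- rep(paste0("g", seq_len(k)), times = n_i)
    tk <- tukey_hsd(values, groups)
    share <- function(a, b) {
      any(strsplit(tk$letters[[a]], "")[[1]] %in%
            strsplit(tk$letters[[b]], "")[[1]])
    }
    for (i in seq_len(nrow(tk$pairs))) {
      a <- tk$pairs$group_a[i]
      b <- tk$pairs$group_b[i]
      # sharing a letter <=> the pair is not significantly different
      expect_identical(share(a, b), !tk$pairs$significant[i])
    }
    expect_true(all(nzchar(tk$letters)))
  }
})

test_that("two-group comparison: identity cases, F = t^2, published ratio", {
  items <- make_items(8, species = "salmon")
  items$habitat <- rep(c("farmed", "wild"), each = 4)
  same <- compare_wild_farmed(items, metric = "protein")
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)

  # mean omega-3 0.88 over mean total fat 6.90 -> ratio 0.128
  expect_equal(0.88 / 6.90, 0.1275, tolerance = 1e-3)
  items$omega3[items$habitat == "farmed"] <- 0.88
  items$total_fat[items$habitat == "farmed"] <- 6.90
  cmp <- compare_wild_farmed(items, metric = "protein")
  expect_equal(unname(cmp$omega3_fat_ratio[["farmed"]]), 0.1275,
               tolerance = 1e-3)

  set.seed(37)
  for (rep in 1:25) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    vals <- c(rnorm(n1), rnorm(n2, 1))
    hab <- c(rep("farmed", n1), rep("wild", n2))
    df <- make_items(n1 + n2, species = "trout")
    df$habitat <- hab
    df$protein <- vals
    cmp <- compare_wild_farmed(df, metric = "protein")
    fit <- one_way_anova(vals, hab)
    expect_equal(cmp$t^2, fit$F, tolerance = 1e-10)
    expect_equal(cmp$p, fit$p, tolerance = 1e-10)
  }
  expect_error(compare_wild_farmed(make_items(3), metric = "protein"),
               "absent")
})

test_that("letter_summary renders mean^letters (SD) strings", {
  set.seed(38)
  values <- c(rnorm(10, 0), rnorm(10, 50))
  groups <- rep(c("lo", "hi"), each = 10)
  ls <- letter_summary(values, groups)
  expect_equal(ls$group, c("hi", "lo"))  # descending mean
  expect_equal(ls$letters, c("a", "b"))
  expect_match(ls$label[1], "^-?[0-9.]+\\^a \\(")
})

test_that("mollusk-vs-finfish iron difference is detected on synthetic data", {
  # large-n groups drawn with the published moments: significance at 0.05
  # in (at least) 19 of 20 seeded replicates
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    iron <- c(rnorm(114, 4.38, 2.84), rnorm(249, 0.59, 0.58))
    grp <- c(rep("mollusk", 114), rep("finfish", 249))
    tk <- tukey_hsd(pmax(iron, 0), grp)
    tk$pairs$significant[1]
  }, logical(1))
  expect_gte(sum(hits), 19)
})
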