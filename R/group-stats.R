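# Classical one-way ANOVA and Tukey HSD with a compact-letter display,
# reproducing the superscript-letter semantics of food-composition group
# tables: groups that share a letter are not significantly different at
# the chosen alpha. Pooled-variance (homoscedastic) machinery throughout,
# as Tukey's HSD presumes.

check_groups <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  n_i <- table(groups)
  if (nlevels(groups) < 2) {
    stop("need at least 2 groups with data", call. = FALSE)
  }
  if (any(n_i < 2)) {
    stop("every group needs at least 2 observations; too small: ",
         paste(names(n_i)[n_i < 2], collapse = ", "), call. = FALSE)
  }
  list(values = values, groups = groups)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition: the F statistic is the
#' between-group mean square over the pooled within-group mean square, with
#' k - 1 and N - k degrees of freedom.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @return Object of class `anova_result`: `metric`-free list with `F`,
#'   `df_between`, `df_within`, `p`, `ss_between`, `ss_within`,
#'   `group_means`, `group_n`, `ms_within`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'               rep(c("a", "b", "c"), each = 3))
one_way_anova <- function(values, groups) {
  d <- check_groups(values, groups)
  values <- d$values
  groups <- d$groups
  k <- nlevels(groups)
  n <- length(values)
  means <- tapply(values, groups, mean)
  n_i <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df_b <- k - 1L
  df_w <- n - k
  msw <- ssw / df_w
  f <- if (ssw == 0 && ssb == 0) {
    0
  } else if (msw == 0) {
    Inf
  } else {
    (ssb / df_b) / msw
  }
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(
    list(F = f, df_between = df_b, df_within = df_w, p = p,
         ss_between = ssb, ss_within = ssw, ms_within = msw,
         group_means = means, group_n = n_i),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> F(", x$df_between, ", ", x$df_within, ") = ",
      signif(x$F, 5), ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Tukey HSD pairwise comparisons with compact letters
#'
#' All k(k-1)/2 pairwise mean comparisons using the studentized-range
#' distribution with the pooled within-group variance (the Tukey-Kramer
#' statistic for unbalanced designs). Letters are assigned by the standard
#' insert-and-absorb algorithm, processing groups in descending mean order,
#' so that two groups share a letter if and only if their adjusted p-value
#' is at least `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level; default 0.05.
#' @return Object of class `tukey_result`: `pairs` (data frame `group_a`,
#'   `group_b`, `diff`, `se`, `p_adj`, `significant`), `letters` (named
#'   character vector, groups in descending mean order), `alpha`, and the
#'   underlying `anova` fit.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  fit <- one_way_anova(values, groups)
  means <- fit$group_means
  n_i <- fit$group_n
  k <- length(means)
  labs <- names(means)
  combs <- utils::combn(k, 2)
  pairs <- data.frame(
    group_a = labs[combs[1, ]], group_b = labs[combs[2, ]],
    diff = means[combs[2, ]] - means[combs[1, ]],
    stringsAsFactors = FALSE
  )
  se <- sqrt(fit$ms_within / 2 *
               (1 / n_i[combs[1, ]] + 1 / n_i[combs[2, ]]))
  q <- abs(pairs$diff) / se
  p_adj <- stats::ptukey(q, nmeans = k, df = fit$df_within,
                         lower.tail = FALSE)
  p_adj[se == 0 & abs(pairs$diff) > 0] <- 0
  p_adj[se == 0 & abs(pairs$diff) == 0] <- 1
  pairs$diff <- as.vector(pairs$diff)
  pairs$se <- as.vector(se)
  pairs$p_adj <- as.vector(p_adj)
  pairs$significant <- pairs$p_adj < alpha
  rownames(pairs) <- NULL
  letters_out <- compact_letters(labs[order(-means)], pairs)
  structure(
    list(pairs = pairs, letters = letters_out, alpha = alpha, anova = fit),
    class = "tukey_result"
  )
}

# Insert-and-absorb compact letter display. `order` lists groups in the
# order letters should be seeded (descending mean); `pairs` must contain
# group_a, group_b, significant.
compact_letters <- function(order, pairs) {
  cols <- list(order)  # start: one column holding every group
  sig <- pairs[pairs$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group_a[i]
    b <- sig$group_b[i]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(new_cols))
    for (x in seq_along(new_cols)) {
      for (y in seq_along(new_cols)) {
        if (x != y && keep[x] && keep[y] &&
            all(new_cols[[x]] %in% new_cols[[y]]) &&
            !(all(new_cols[[y]] %in% new_cols[[x]]) && x < y)) {
          keep[x] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by first (highest-mean) member for stable letter names
  first_pos <- vapply(cols, function(col) min(match(col, order)),
                      numeric(1))
  cols <- cols[order(first_pos)]
  out <- stats::setNames(rep("", length(order)), order)
  for (j in seq_along(cols)) {
    letter <- make_letter(j)
    for (g in cols[[j]]) out[[g]] <- paste0(out[[g]], letter)
  }
  out
}

make_letter <- function(j) {
  # a, b, ..., z, aa, ab, ... for pathological numbers of classes
  out <- ""
  j <- j - 1L
  repeat {
    out <- paste0(letters[j %% 26L + 1L], out)
    j <- j %/% 26L - 1L
    if (j < 0) break
  }
  out
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("<tukey_result> alpha = ", x$alpha, "\n", sep = "")
  print(x$pairs)
  cat("letters: ",
      paste(names(x$letters), x$letters, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Two-group comparison of wild versus farmed items
#'
#' Pooled-variance two-sample comparison of a nutrient or score between two
#' habitat classes (equivalent to a 2-group ANOVA: F = t^2). Also reports
#' each group's mean omega-3 to total-fat ratio, a fat-quality metric that
#' separates lean wild fish from fattier farmed fish.
#'
#' @param items A `food_table`.
#' @param metric Column of `items` to compare (nutrient or score column).
#' @param group_col Grouping column; default `"habitat"`.
#' @param groups The two labels to compare; default wild vs farmed.
#' @return List of class `two_group_comparison`: per-group `n`, `mean`,
#'   `sd`, the mean `difference`, `t`, `df`, `p` (two-sided), and
#'   `omega3_fat_ratio` per group (NA when total fat is unavailable).
#' @export
compare_wild_farmed <- function(items, metric = "nrf",
                                group_col = "habitat",
                                groups = c("farmed", "wild")) {
  stopifnot(length(groups) == 2)
  g <- items[[group_col]]
  present <- groups %in% g
  if (!all(present)) {
    stop("group(s) absent from '", group_col, "': ",
         paste(groups[!present], collapse = ", "), call. = FALSE)
  }
  x <- items[[metric]][g == groups[1]]
  y <- items[[metric]][g == groups[2]]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  diff <- mean(y) - mean(x)
  t_stat <- if (se == 0) {
    if (diff == 0) 0 else Inf
  } else {
    diff / se
  }
  df <- nx + ny - 2
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  ratio <- function(sel) {
    o <- items$omega3[sel]
    f <- items$total_fat[sel]
    ok <- !is.na(o) & !is.na(f) & f > 0
    if (!any(ok)) return(NA_real_)
    mean(o[ok]) / mean(f[ok])
  }
  structure(
    list(
      metric = metric, groups = groups,
      n = stats::setNames(c(nx, ny), groups),
      mean = stats::setNames(c(mean(x), mean(y)), groups),
      sd = stats::setNames(c(stats::sd(x), stats::sd(y)), groups),
      difference = diff, t = t_stat, df = df, p = p,
      omega3_fat_ratio = stats::setNames(
        c(ratio(g == groups[1]), ratio(g == groups[2])), groups)
    ),
    class = "two_group_comparison"
  )
}

#' @export
print.two_group_comparison <- function(x, ...) {
  cat("<two_group_comparison> ", x$metric, ": ",
      x$groups[1], " ", signif(x$mean[1], 4), " vs ",
      x$groups[2], " ", signif(x$mean[2], 4),
      "; t(", x$df, ") = ", signif(x$t, 4),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Summary strings in "mean^letters (SD)" style
#'
#' Convenience formatter reproducing composition-table cells: the group
#' mean with its Tukey letters as a superscript marker and the SD in
#' parentheses.
#'
#' @param values,groups As in [one_way_anova()].
#' @param alpha Significance level for the letters.
#' @param digits Rounding for mean and SD.
#' @return Data frame `group`, `n`, `mean`, `sd`, `letters`, `label`.
#' @export
letter_summary <- function(values, groups, alpha = 0.05, digits = 2) {
  tk <- tukey_hsd(values, groups, alpha)
  means <- tk$anova$group_means
  n_i <- tk$anova$group_n
  sds <- tapply(values[!is.na(values)],
                droplevels(factor(groups[!is.na(values)])), stats::sd)
  labs <- names(tk$letters)
  data.frame(
    group = labs, n = as.integer(n_i[labs]),
    mean = unname(means[labs]), sd = unname(sds[labs]),
    letters = unname(tk$letters),
    label = sprintf("%s^%s (%s)", round(means[labs], digits),
                    tk$letters, round(sds[labs], digits)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
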