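#' Significance star codes
#'
#' Maps adjusted p-values to the assay's convention: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001, `ns` otherwise.
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return character vector.
#' @export
star_code <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Per-group mean, SEM and sample sizes
#'
#' SEM is the sample standard deviation divided by `sqrt(n_larvae)`;
#' undefined (`NA`) for singleton groups. `n_batches` counts distinct
#' batches contributing to each group.
#'
#' @param values numeric vector, one value per larva.
#' @param groups treatment label per value.
#' @param batches optional batch label per value.
#' @return data.frame: `treatment, n_larvae, n_batches, mean, sem`.
#' @export
summarize_groups <- function(values, groups, batches = NULL) {
  stopifnot(length(values) == length(groups))
  if (is.null(batches)) batches <- rep(NA_character_, length(values))
  groups <- as.character(groups)
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    v <- values[groups == g]
    b <- batches[groups == g]
    data.frame(treatment = g,
               n_larvae = length(v),
               n_batches = length(unique(b[!is.na(b)])),
               mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                     else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

new_test_result <- function(method, global_stat, global_p, comparisons) {
  comparisons$stars <- star_code(comparisons$p_adj)
  structure(list(method = method, global_stat = global_stat,
                 global_p = global_p, comparisons = comparisons),
            class = "staz_test")
}

#' @export
print.staz_test <- function(x, ...) {
  cat(sprintf("<staz_test> %s: global statistic %.4g, p = %.4g\n",
              x$method, x$global_stat, x$global_p))
  if (nrow(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Kruskal-Wallis test with Dunn's compare-to-control post-test
#'
#' The global test is the tie-corrected Kruskal-Wallis H. Dunn's post-test
#' compares each treated group to the control on the pooled ranks:
#' `z = (Rbar_i - Rbar_c) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_c))` with tie
#' correction `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p-values,
#' Bonferroni-adjusted over the set of comparisons performed (treated vs
#' control by default, matching the compare-to-control convention; all
#' pairs optionally).
#'
#' @param values numeric vector of larva values.
#' @param groups group label per value.
#' @param control_label label of the control group.
#' @param all_pairs if `TRUE`, all pairwise comparisons are run instead of
#'   treated-vs-control only.
#' @return a `staz_test` with `comparisons` columns
#'   `group, statistic, p_raw, p_adj, stars`.
#' @export
kruskal_dunn <- function(values, groups, control_label = "DMSO",
                         all_pairs = FALSE) {
  groups <- as.character(groups)
  check_groups(values, groups, control_label, min_per_group = 2L)
  if (stats::var(values) == 0) {   # all observations identical: null path
    cmp <- dunn_frame(setdiff(unique(groups), control_label),
                      control_label, all_pairs, groups)
    cmp$statistic <- 0; cmp$p_raw <- 1; cmp$p_adj <- 1
    cmp$.a <- cmp$.b <- NULL
    return(new_test_result("kruskal_dunn", 0, 1, cmp))
  }
  kw <- stats::kruskal.test(values, factor(groups))

  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  cmp <- dunn_frame(setdiff(unique(groups), control_label),
                    control_label, all_pairs, groups)
  z <- mapply(function(a, b) {
    (rbar[[a]] - rbar[[b]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
  }, cmp$.a, cmp$.b)
  cmp$statistic <- as.numeric(z)
  cmp$p_raw <- 2 * stats::pnorm(-abs(cmp$statistic))
  cmp$p_adj <- pmin(1, cmp$p_raw * nrow(cmp))
  cmp$.a <- cmp$.b <- NULL
  new_test_result("kruskal_dunn", unname(kw$statistic), kw$p.value, cmp)
}

dunn_frame <- function(treated, control_label, all_pairs, groups) {
  if (all_pairs) {
    u <- unique(groups)
    pairs <- utils::combn(u, 2)
    data.frame(group = paste(pairs[1, ], pairs[2, ], sep = " vs "),
               .a = pairs[1, ], .b = pairs[2, ])
  } else {
    data.frame(group = treated, .a = treated,
               .b = rep(control_label, length(treated)))
  }
}

check_groups <- function(values, groups, control_label, min_per_group) {
  if (length(values) != length(groups))
    staz_error("staz_config_error", "values and groups lengths differ")
  n <- table(groups)
  if (length(n) < 2L)
    staz_error("staz_config_error", "need at least 2 groups")
  if (any(n < min_per_group))
    staz_error("staz_config_error",
               sprintf("every group needs >= %d values", min_per_group))
  if (!control_label %in% names(n))
    staz_error("staz_missing_control_error",
               sprintf("control group '%s' not present", control_label))
}

#' One-way ANOVA with Dunnett's many-to-one post-test
#'
#' Global one-way ANOVA F-test, then Dunnett's comparisons of every treated
#' group against the control with single-step multivariate-t adjusted
#' p-values (via \pkg{multcomp}).
#'
#' @inheritParams kruskal_dunn
#' @return a `staz_test`.
#' @export
anova_dunnett <- function(values, groups, control_label = "DMSO") {
  groups <- as.character(groups)
  check_groups(values, groups, control_label, min_per_group = 2L)
  treated <- setdiff(unique(groups), control_label)
  if (stats::var(values) == 0) {  # identical observations: degenerate null
    cmp <- data.frame(group = treated, statistic = 0, p_raw = 1, p_adj = 1)
    return(new_test_result("anova_dunnett", 0, 1, cmp))
  }
  within_var <- tapply(values, groups, stats::var)
  if (all(within_var == 0))
    staz_error("staz_degenerate_variance_error",
               "zero within-group variance in every group")
  g <- stats::relevel(factor(groups), ref = control_label)
  d <- data.frame(y = values, g = g)
  fit <- stats::aov(y ~ g, data = d)
  tab <- summary(fit)[[1]]
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  s <- summary(glht_fit)
  df_res <- fit$df.residual
  tstat <- as.numeric(s$test$tstat)
  cmp <- data.frame(group = sub(" - .*$", "", names(s$test$tstat)),
                    statistic = tstat,
                    p_raw = 2 * stats::pt(-abs(tstat), df_res),
                    p_adj = pmin(1, as.numeric(s$test$pvalues)))
  cmp$p_adj <- pmax(cmp$p_adj, cmp$p_raw)  # single-step adj >= raw
  new_test_result("anova_dunnett", tab[["F value"]][1], tab[["Pr(>F)"]][1],
                  cmp)
}

#' Two-way ANOVA with Bonferroni-adjusted cell contrasts
#'
#' Fits the two-factor linear model with interaction, reports main-effect
#' and interaction F-tests, and tests the requested cell-pair contrasts
#' with pooled-variance t-tests on the residual mean square, Bonferroni-
#' adjusted over the list.
#'
#' @param values numeric vector of observations.
#' @param factor_a,factor_b factor level per observation.
#' @param comparisons list of cell pairs; each element is
#'   `list(c(a1, b1), c(a2, b2))` naming the two cells to contrast. Empty
#'   list = global tests only.
#' @return a `staz_test`; the global slot holds the interaction F/p, and the
#'   full ANOVA table is attached as attribute `"anova_table"`.
#' @export
two_way_anova_bonferroni <- function(values, factor_a, factor_b,
                                     comparisons = list()) {
  factor_a <- as.character(factor_a); factor_b <- as.character(factor_b)
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b))
  cells <- table(factor_a, factor_b)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    staz_error("staz_unbalanced_design_error",
               sprintf("empty design cell (%s, %s)",
                       rownames(cells)[idx[1]], colnames(cells)[idx[2]]))
  }
  cell_of <- paste(factor_a, factor_b, sep = "\r")
  if (stats::var(values) == 0) {  # constant response: all-null path
    cmp <- bonf_frame(comparisons)
    if (nrow(cmp)) { cmp$statistic <- 0; cmp$p_raw <- 1; cmp$p_adj <- 1 }
    res <- new_test_result("two_way_anova_bonferroni", 0, 1, cmp)
    attr(res, "anova_table") <-
      data.frame(term = c("A", "B", "A:B"), F = 0, p = 1)
    return(res)
  }
  d <- data.frame(y = values, A = factor(factor_a), B = factor(factor_b))
  fit <- stats::aov(y ~ A * B, data = d)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]]; Pv <- tab[["Pr(>F)"]]
  mse <- tab[["Mean Sq"]][nrow(tab)]
  df_res <- tab[["Df"]][nrow(tab)]
  cmp <- bonf_frame(comparisons)
  if (nrow(cmp)) {
    stat <- praw <- numeric(nrow(cmp))
    for (i in seq_len(nrow(cmp))) {
      c1 <- paste(cmp$.a1[i], cmp$.b1[i], sep = "\r")
      c2 <- paste(cmp$.a2[i], cmp$.b2[i], sep = "\r")
      if (!c1 %in% cell_of || !c2 %in% cell_of)
        staz_error("staz_config_error",
                   sprintf("comparison %d names a cell not in the design", i))
      v1 <- values[cell_of == c1]; v2 <- values[cell_of == c2]
      se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
      stat[i] <- (mean(v1) - mean(v2)) / se
      praw[i] <- 2 * stats::pt(-abs(stat[i]), df_res)
    }
    cmp$statistic <- stat
    cmp$p_raw <- praw
    cmp$p_adj <- pmin(1, praw * nrow(cmp))
  }
  cmp$.a1 <- cmp$.b1 <- cmp$.a2 <- cmp$.b2 <- NULL
  res <- new_test_result("two_way_anova_bonferroni",
                         Fv[3], Pv[3], cmp)
  attr(res, "anova_table") <-
    data.frame(term = trimws(rownames(tab))[1:3], F = Fv[1:3], p = Pv[1:3])
  res
}

bonf_frame <- function(comparisons) {
  if (length(comparisons) == 0L)
    return(data.frame(group = character(), statistic = numeric(),
                      p_raw = numeric(), p_adj = numeric()))
  do.call(rbind, lapply(comparisons, function(cp) {
    stopifnot(length(cp) == 2L, length(cp[[1]]) == 2L, length(cp[[2]]) == 2L)
    data.frame(group = sprintf("(%s,%s) vs (%s,%s)",
                               cp[[1]][1], cp[[1]][2],
                               cp[[2]][1], cp[[2]][2]),
               .a1 = cp[[1]][1], .b1 = cp[[1]][2],
               .a2 = cp[[2]][1], .b2 = cp[[2]][2])
  }))
}

#' Flatten a `staz_test` into a tidy rows-per-comparison table
#'
#' @param test a `staz_test`.
#' @return data.frame: `method, comparison, statistic, raw_p, adj_p, stars`,
#'   with the global test as the first row.
#' @export
test_result_table <- function(test) {
  stopifnot(inherits(test, "staz_test"))
  global <- data.frame(method = test$method, comparison = "(global)",
                       statistic = test$global_stat, raw_p = test$global_p,
                       adj_p = test$global_p,
                       stars = star_code(test$global_p))
  if (!nrow(test$comparisons)) return(global)
  rows <- data.frame(method = test$method,
                     comparison = test$comparisons$group,
                     statistic = test$comparisons$statistic,
                     raw_p = test$comparisons$p_raw,
                     adj_p = test$comparisons$p_adj,
                     stars = test$comparisons$stars)
  rbind(global, rows)
}
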