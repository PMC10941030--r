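#' Prevalence of a binary condition
#'
#' @param flags logical vector (no missing values).
#' @return tibble with `n` (count true), `total`, `proportion`, `percent`
#'   (unrounded; round only at presentation).
#' @export
#' @examples
#' prevalence(rep(c(TRUE, FALSE), c(153, 108)))
prevalence <- function(flags) {
  if (length(flags) == 0) abort("`flags` must be non-empty")
  if (anyNA(flags)) abort("`flags` must not contain missing values")
  n <- sum(flags)
  tibble::tibble(n = n, total = length(flags),
                 proportion = n / length(flags),
                 percent = 100 * n / length(flags))
}

shapiro_normal <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(unique(x)) == 1) return(NA)
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  stats::shapiro.test(x)$p.value >= alpha
}

summarise_continuous <- function(x, normal) {
  x <- x[!is.na(x)]
  if (isTRUE(normal)) {
    sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.1f (%.1f)", q[2], q[3] - q[1])
  }
}

#' Normality-gated group comparison
#'
#' Categorical variables are compared with a chi-square test. Continuous
#' variables are gated on per-group Shapiro-Wilk normality (alpha = 0.05):
#' two groups get a t-test if all pass, otherwise a Mann-Whitney U test;
#' more than two groups get one-way ANOVA if all pass, otherwise
#' Kruskal-Wallis. Groups too small for the normality test (< 3
#' observations) fall back to the nonparametric branch with a warning.
#'
#' @param values vector of observations.
#' @param groups grouping vector (>= 2 non-empty groups).
#' @param kind `"continuous"`, `"categorical"`, or `"auto"` (categorical for
#'   non-numeric values).
#' @param yates apply Yates continuity correction on 2x2 tables?
#' @param alpha normality-gate significance level.
#' @param normality `"auto"` applies the Shapiro-Wilk gate; `"normal"` /
#'   `"nonnormal"` force the parametric / nonparametric branch.
#' @return one-row tibble: `test`, `statistic`, `p_value`, `normal`
#'   (normality-gate verdict), `summaries` (list column, one summary string
#'   per group).
#' @export
compare_groups <- function(values, groups,
                           kind = c("auto", "continuous", "categorical"),
                           yates = FALSE, alpha = 0.05,
                           normality = c("auto", "normal", "nonnormal")) {
  kind <- match.arg(kind)
  normality <- match.arg(normality)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  glev <- unique(groups)
  if (length(glev) < 2) abort("need at least 2 non-empty groups")
  if (kind == "auto") kind <- if (is.numeric(values)) "continuous" else "categorical"

  if (kind == "categorical") {
    tab <- table(values, groups)
    if (length(unique(values)) < 2 || all(tab == tab[1])) {
      # degenerate/uniform table: no association by construction
      res <- list(statistic = 0, p.value = 1)
    } else {
      res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    }
    summaries <- lapply(glev, function(g) {
      ct <- table(values[groups == g])
      paste(sprintf("%s: %d (%.1f%%)", names(ct), as.integer(ct),
                    100 * as.integer(ct) / sum(ct)), collapse = "; ")
    })
    names(summaries) <- glev
    return(tibble::tibble(test = "chi_square",
                          statistic = unname(res$statistic),
                          p_value = unname(res$p.value),
                          normal = NA, summaries = list(summaries)))
  }

  by_group <- split(values, groups)[glev]
  small <- vapply(by_group, function(x) sum(!is.na(x)) < 3, logical(1))
  if (normality != "auto") {
    normal <- normality == "normal"
  } else if (any(small)) {
    warn("group(s) with < 3 observations: falling back to the nonparametric branch")
    normal <- FALSE
  } else {
    normal <- all(vapply(by_group, shapiro_normal, logical(1), alpha = alpha))
    normal <- isTRUE(normal)
  }
  if (length(unique(values)) == 1) {
    res <- list(statistic = 0, p.value = 1)
    test <- if (length(glev) == 2) "t_test" else "anova"
  } else if (length(glev) == 2) {
    if (normal) {
      r <- stats::t.test(by_group[[1]], by_group[[2]])
      res <- list(statistic = r$statistic, p.value = r$p.value)
      test <- "t_test"
    } else {
      exact <- max(lengths(by_group)) <= 8 && !any(duplicated(values))
      r <- suppressWarnings(stats::wilcox.test(by_group[[1]], by_group[[2]],
                                               exact = exact, correct = !exact))
      res <- list(statistic = r$statistic, p.value = r$p.value)
      test <- "mann_whitney"
    }
  } else {
    if (normal) {
      fit <- stats::aov(values ~ factor(groups))
      sm <- summary(fit)[[1]]
      res <- list(statistic = sm$`F value`[1], p.value = sm$`Pr(>F)`[1])
      test <- "anova"
    } else {
      r <- stats::kruskal.test(values, factor(groups))
      res <- list(statistic = r$statistic, p.value = r$p.value)
      test <- "kruskal_wallis"
    }
  }
  summaries <- lapply(by_group, summarise_continuous, normal = normal)
  tibble::tibble(test = test, statistic = unname(res$statistic),
                 p_value = unname(res$p.value), normal = normal,
                 summaries = list(summaries))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down Holm correction with monotonicity enforcement and capping at
#' 1; output order matches input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  assert_in_range(p[!is.na(p)], 0, 1, "p")
  stats::p.adjust(p, method = "holm")
}

#' Distribution-gated correlation
#'
#' Pearson when both variables pass Shapiro-Wilk normality (alpha = 0.05),
#' Spearman otherwise; missing pairs are deleted pairwise beforehand.
#'
#' @param x,y numeric vectors.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return tibble with `method`, `estimate`, `p_value`, `n`.
#' @export
cor_assoc <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    if (method == "auto") method <- "pearson"
    est <- if (length(x) == 2) {
      suppressWarnings(stats::cor(x, y, method = method))
    } else NA_real_
    return(tibble::tibble(method = method, estimate = est,
                          p_value = NA_real_, n = length(x)))
  }
  if (method == "auto") {
    method <- if (isTRUE(shapiro_normal(x)) && isTRUE(shapiro_normal(y)))
      "pearson" else "spearman"
  }
  r <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(method = method, estimate = unname(r$estimate),
                 p_value = r$p.value, n = length(x))
}

#' Cohort summary table (per-group descriptives with group tests)
#'
#' One row per variable: per-group summary strings (count/percent for
#' categorical, mean (SD) or median (IQR) for continuous depending on the
#' normality gate), the selected test and its p-value. Group sizes appear
#' as the first row.
#'
#' @param cohort cohort tibble.
#' @param group_col name of the grouping column (>= 2 levels).
#' @param vars variables to summarize; defaults to the IRP covariates plus
#'   the clinical scores.
#' @return tibble with columns `variable`, one column per group, `test`,
#'   `p_value`.
#' @export
summarize_cohort <- function(cohort, group_col = "group",
                             vars = c(irp_columns(), "nds", "nss", "moca_raw")) {
  g <- cohort[[group_col]]
  glev <- if (is.factor(g)) levels(droplevels(g)) else unique(as.character(g))
  if (length(glev) < 2) abort("grouping column must have >= 2 levels")
  g <- as.character(g)
  rows <- list(tibble::tibble(
    variable = "N",
    !!!stats::setNames(as.list(as.character(table(factor(g, glev)))), glev),
    test = NA_character_, p_value = NA_real_
  ))
  for (v in vars) {
    res <- compare_groups(cohort[[v]], g,
                          kind = if (is.numeric(cohort[[v]])) "continuous" else "categorical")
    sums <- unlist(res$summaries[[1]])
    cells <- stats::setNames(as.list(sums[glev]), glev)
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, !!!cells, test = res$test, p_value = res$p_value
    )
  }
  dplyr::bind_rows(rows)
}
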