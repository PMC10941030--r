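#' Standardized mean difference between two groups
#'
#' `|mean_A - mean_B| / sqrt((var_A + var_B) / 2)` with sample variances;
#' for binary (0/1) variables the denominator uses the proportion variance
#' analogue `sqrt((p_A(1-p_A) + p_B(1-p_B)) / 2)`. A zero denominator gives
#' 0 when the means agree and `Inf` otherwise.
#'
#' @param values numeric vector.
#' @param group two-level grouping vector aligned with `values`.
#' @return non-negative scalar.
#' @export
#' @examples
#' smd(c(1, 2, 3, 2, 3, 4), rep(c("A", "B"), each = 3))
smd <- function(values, group) {
  g <- unique(group)
  if (length(g) != 2) abort("`group` must have exactly two levels")
  a <- values[group == g[1]]
  b <- values[group == g[2]]
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  binary <- all(values %in% c(0, 1))
  ma <- mean(a); mb <- mean(b)
  denom <- if (binary) {
    sqrt((ma * (1 - ma) + mb * (1 - mb)) / 2)
  } else {
    va <- if (length(a) > 1) stats::var(a) else 0
    vb <- if (length(b) > 1) stats::var(b) else 0
    sqrt((va + vb) / 2)
  }
  if (denom == 0) return(if (ma == mb) 0 else Inf)
  abs(ma - mb) / denom
}

code_covariates <- function(data, covariates) {
  X <- matrix(NA_real_, nrow(data), length(covariates),
              dimnames = list(NULL, covariates))
  for (j in seq_along(covariates)) {
    x <- data[[covariates[j]]]
    if (!is.numeric(x)) x <- as.numeric(factor(x)) - 1
    if (length(unique(x[!is.na(x)])) == 2) {
      u <- sort(unique(x[!is.na(x)]))
      x <- as.numeric(x == u[2])
    }
    X[, j] <- x
  }
  X
}

smd_matrix <- function(X, sel_a, sel_b) {
  vapply(seq_len(ncol(X)), function(j) {
    smd(c(X[sel_a, j], X[sel_b, j]),
        rep(c("A", "B"), c(length(sel_a), length(sel_b))))
  }, numeric(1))
}

exact_cardinality_search <- function(X, idx_a, idx_b, strata, tolerance) {
  na <- length(idx_a); nb <- length(idx_b)
  feasible <- function(sa, sb) {
    if (!is.null(strata)) {
      ta <- table(factor(strata[sa], levels = unique(strata)))
      tb <- table(factor(strata[sb], levels = unique(strata)))
      if (!all(ta == tb)) return(FALSE)
    }
    all(smd_matrix(X, sa, sb) <= tolerance)
  }
  for (k in seq(min(na, nb), 1)) {
    ca <- utils::combn(idx_a, k, simplify = FALSE)
    cb <- utils::combn(idx_b, k, simplify = FALSE)
    for (sa in ca) for (sb in cb) {
      if (feasible(sa, sb)) {
        return(list(a = sa, b = sb, status = "optimal"))
      }
    }
  }
  list(a = integer(0), b = integer(0), status = "infeasible")
}

greedy_cardinality_search <- function(X, idx_a, idx_b, strata, tolerance) {
  sel_a <- idx_a; sel_b <- idx_b
  dropped <- 0L
  surplus_strata <- function() {
    if (is.null(strata)) return(NULL)
    lev <- unique(strata)
    ta <- table(factor(strata[sel_a], levels = lev))
    tb <- table(factor(strata[sel_b], levels = lev))
    list(a = lev[ta > tb], b = lev[tb > ta])
  }
  best_drop <- function(side_sel, other_sel, candidates) {
    # leave-one-out max SMD for each candidate drop
    scores <- vapply(candidates, function(u) {
      rest <- setdiff(side_sel, u)
      if (length(rest) == 0) return(Inf)
      max(smd_matrix(X, rest, other_sel))
    }, numeric(1))
    list(unit = candidates[which.min(scores)], score = min(scores))
  }
  repeat {
    if (length(sel_a) == 0 || length(sel_b) == 0) {
      return(list(a = integer(0), b = integer(0), status = "infeasible"))
    }
    ss <- surplus_strata()
    sizes_ok <- length(sel_a) == length(sel_b) &&
      (is.null(ss) || (length(ss$a) == 0 && length(ss$b) == 0))
    if (sizes_ok && max(smd_matrix(X, sel_a, sel_b)) <= tolerance) {
      return(list(a = sel_a, b = sel_b,
                  status = if (dropped == 0L) "optimal" else "greedy_fallback"))
    }
    if (length(sel_a) <= 1 && length(sel_b) <= 1) {
      return(list(a = integer(0), b = integer(0), status = "infeasible"))
    }
    # choose the drop side: the larger/surplus side, else the better of both
    cand_a <- if (!is.null(ss) && length(ss$a) > 0) {
      sel_a[strata[sel_a] %in% ss$a]
    } else sel_a
    cand_b <- if (!is.null(ss) && length(ss$b) > 0) {
      sel_b[strata[sel_b] %in% ss$b]
    } else sel_b
    drop_from_a <- if (length(sel_a) != length(sel_b)) {
      length(sel_a) > length(sel_b)
    } else if (!is.null(ss) && (length(ss$a) > 0) != (length(ss$b) > 0)) {
      length(ss$a) > 0
    } else NA
    if (is.na(drop_from_a)) {
      da <- best_drop(sel_a, sel_b, cand_a)
      db <- best_drop(sel_b, sel_a, cand_b)
      drop_from_a <- da$score <= db$score
    }
    if (drop_from_a && length(sel_a) > 1) {
      d <- best_drop(sel_a, sel_b, cand_a)
      sel_a <- setdiff(sel_a, d$unit)
    } else if (length(sel_b) > 1) {
      d <- best_drop(sel_b, sel_a, cand_b)
      sel_b <- setdiff(sel_b, d$unit)
    } else {
      d <- best_drop(sel_a, sel_b, cand_a)
      sel_a <- setdiff(sel_a, d$unit)
    }
    dropped <- dropped + 1L
  }
}

#' Cardinality matching with covariate-balance constraints
#'
#' Selects the largest equal-size subsets of the two outcome groups such
#' that every covariate's post-match standardized mean difference is at or
#' below `tolerance` (optionally with exact per-level count constraints on
#' selected columns). Small instances are solved exactly by subset
#' enumeration (`status = "optimal"`); larger ones by a deterministic
#' greedy search that iteratively drops the participant whose removal most
#' improves the worst imbalance (`status = "greedy_fallback"`).
#'
#' @param data cohort tibble.
#' @param outcome name of a binary column defining the two groups.
#' @param covariates covariate column names to balance; default the six IRP
#'   covariates.
#' @param tolerance maximum post-match SMD (default 0.1).
#' @param exact columns whose per-level counts must match exactly between
#'   retained groups (e.g. `"diabetes_type"`).
#' @param solver `"auto"` (exact up to 16 participants, greedy beyond),
#'   `"exact"`, or `"greedy"`.
#' @param id_col participant-id column.
#' @return object of class `match_result`: retained ids per group, SMDs
#'   before/after, solver status.
#' @export
cardinality_match <- function(data, outcome, covariates = irp_columns(),
                              tolerance = 0.1, exact = NULL,
                              solver = c("auto", "exact", "greedy"),
                              id_col = "id") {
  solver <- match.arg(solver)
  if (tolerance <= 0) abort("`tolerance` must be > 0")
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("`outcome` must be binary")
  X <- code_covariates(data, covariates)
  idx_a <- which(y == 1)
  idx_b <- which(y == 0)
  strata <- if (is.null(exact)) NULL else {
    do.call(paste, c(lapply(exact, function(cn) as.character(data[[cn]])), sep = "|"))
  }
  smd_before <- smd_matrix(X, idx_a, idx_b)
  n <- nrow(data)
  use_exact <- solver == "exact" || (solver == "auto" && n <= 16)
  res <- if (use_exact) {
    exact_cardinality_search(X, idx_a, idx_b, strata, tolerance)
  } else {
    greedy_cardinality_search(X, idx_a, idx_b, strata, tolerance)
  }
  smd_after <- if (length(res$a) > 0) smd_matrix(X, res$a, res$b) else
    rep(NA_real_, length(covariates))
  structure(list(
    retained = list(cases = data[[id_col]][res$a], controls = data[[id_col]][res$b]),
    retained_ids = data[[id_col]][sort(c(res$a, res$b))],
    n_per_group = length(res$a),
    smd = tibble::tibble(covariate = covariates,
                         before = smd_before, after = smd_after),
    status = res$status,
    tolerance = tolerance,
    outcome = outcome,
    diagnostic = if (res$status == "infeasible")
      "no balanced equal-size subsets exist down to size 1" else NULL
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d per group (status: %s, SMD tol %.2f)\n",
              x$n_per_group, x$status, x$tolerance))
  print(x$smd)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.match_result <- function(x, ...) {
  tidyr::pivot_longer(x$smd, c("before", "after"),
                      names_to = "stage", values_to = "smd")
}

#' Covariate balance (love) plot for a matching result
#'
#' @param object a `match_result`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.match_result <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = c("before", "after"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$smd, y = .data$covariate,
                                  colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$tolerance, linetype = "dashed") +
    ggplot2::labs(x = "standardized mean difference", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' Cross-product odds ratio `ad/bc` with the Woolf log-scale standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. Zero cells trigger a 0.5 continuity
#' correction on all cells, flagged in the output.
#'
#' @param a exposed cases. @param b unexposed cases.
#' @param c exposed controls. @param d unexposed controls.
#' @param conf_level confidence level (default 0.95).
#' @return tibble with `or`, `ci_low`, `ci_high`, `log_or`, `se`,
#'   `p_value` (Wald), `corrected`.
#' @export
#' @examples
#' odds_ratio_2x2(61, 28, 92, 80)
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("cell counts must be >= 0")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    log_or = log(or),
    se = se,
    p_value = 2 * stats::pnorm(-abs(log(or) / se)),
    corrected = corrected
  )
}

#' Logistic regression with odds-ratio output
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()]) returning Wald 95% confidence intervals on the odds
#' ratios. Complete separation and non-convergence raise explicit errors.
#'
#' @param data model data.
#' @param outcome binary outcome column name.
#' @param predictors predictor column names; factors use their first level
#'   as reference.
#' @param max_iter IRLS iteration cap.
#' @return object of class `soleplay_logit`.
#' @export
fit_logistic <- function(data, outcome, predictors, max_iter = 50) {
  for (p in predictors) {
    if (length(unique(data[[p]][!is.na(data[[p]])])) < 2) {
      warn(sprintf("predictor `%s` has a single level; dropping it", p))
      predictors <- setdiff(predictors, p)
    }
  }
  if (length(predictors) == 0) abort("no usable predictors")
  f <- stats::as.formula(paste0("`", outcome, "` ~ ",
                                paste0("`", predictors, "`", collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = data, family = stats::binomial(),
               control = stats::glm.control(maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- stats::coef(fit)[-1]
  # a diverging coefficient is the practical signature of separation,
  # with or without the glm.fit boundary warning
  if (any(abs(co) > 15, na.rm = TRUE) || (sep_warn && !fit$converged)) {
    abort(sprintf("complete separation detected (predictor: %s)",
                  gsub("`", "", names(co)[which.max(abs(co))])))
  }
  if (!fit$converged) {
    abort(sprintf("logistic fit did not converge within %d iterations", fit$iter))
  }
  structure(list(fit = fit, outcome = outcome, predictors = predictors),
            class = "soleplay_logit")
}

#' @exportS3Method generics::tidy
tidy.soleplay_logit <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  tibble::tibble(
    term = gsub("`", "", rownames(sm)),
    estimate = unname(est),
    or = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se)),
    p_value = unname(sm[, "Pr(>|z|)"])
  )
}

#' @exportS3Method generics::glance
glance.soleplay_logit <- function(x, ...) {
  tibble::tibble(n = stats::nobs(x$fit),
                 deviance = stats::deviance(x$fit),
                 aic = stats::AIC(x$fit),
                 converged = x$fit$converged,
                 iterations = x$fit$iter)
}

#' @export
print.soleplay_logit <- function(x, ...) {
  cat(sprintf("<soleplay_logit> %s ~ %s\n", x$outcome,
              paste(x$predictors, collapse = " + ")))
  print(tidy(x))
  invisible(x)
}

association_models <- function(cohort, exposure, outcome, adjustment,
                               labels = c("model1", "model2")) {
  ex <- cohort[[exposure]]
  if (length(unique(ex[!is.na(ex)])) < 2) {
    warn(sprintf("exposure `%s` has a single level; returning reference-only row", exposure))
    return(tibble::tibble(model = labels[1], term = paste0(exposure, " (ref)"),
                          estimate = NA_real_, or = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, n = nrow(cohort)))
  }
  uni <- tidy(fit_logistic(cohort, outcome, exposure))
  uni <- dplyr::mutate(uni[-1, ], model = labels[1], n = nrow(cohort), .before = 1)
  out <- uni
  if (length(adjustment) > 0) {
    adj <- tidy(fit_logistic(cohort, outcome, c(exposure, adjustment)))
    keep <- grepl(paste0("^", exposure), adj$term)
    adj <- dplyr::mutate(adj[keep, ], model = labels[2], n = nrow(cohort),
                         .before = 1)
    out <- dplyr::bind_rows(uni, adj)
  } else {
    out <- dplyr::bind_rows(uni, dplyr::mutate(uni, model = labels[2]))
  }
  out
}

#' Pre- and post-matching odds-ratio association analysis (models 1-4)
#'
#' Model 1: univariate logistic regression of the outcome on the exposure
#' in the full cohort. Model 2: adjusted for the six IRP covariates.
#' Models 3 and 4: the same pair in the covariate-matched subcohort.
#' Categorized exposures (factors) use their first level as reference.
#'
#' @param cohort cohort tibble.
#' @param exposure exposure column (binary or factor).
#' @param outcome binary outcome column (default `cd_label`).
#' @param adjustment adjustment covariates for models 2/4 (default the IRP
#'   covariates, excluding the exposure itself).
#' @param matched optional `match_result` from [cardinality_match()]; when
#'   supplied, models 3/4 are fit on its retained participants.
#' @param id_col participant-id column.
#' @return tibble: `model`, `n`, `term`, `estimate`, `or`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
association_analysis <- function(cohort, exposure, outcome = "cd_label",
                                 adjustment = setdiff(irp_columns(), exposure),
                                 matched = NULL, id_col = "id") {
  out <- association_models(cohort, exposure, outcome, adjustment,
                            labels = c("model1", "model2"))
  if (!is.null(matched)) {
    sub <- cohort[cohort[[id_col]] %in% matched$retained_ids, ]
    post <- association_models(sub, exposure, outcome, adjustment,
                               labels = c("model3", "model4"))
    out <- dplyr::bind_rows(out, post)
  }
  out
}

#' Stratified association analysis
#'
#' Runs [association_analysis()] within each level of a stratifier (e.g.
#' gender or diabetes type); strata smaller than `min_n` are flagged
#' unstable.
#'
#' @param cohort cohort tibble.
#' @param stratifier column to stratify by.
#' @param exposure,outcome,adjustment as in [association_analysis()].
#' @param min_n minimum stratum size below which results are flagged.
#' @return tibble with `stratum`, `stratum_n`, `unstable` plus the
#'   association columns.
#' @export
subgroup_analysis <- function(cohort, stratifier, exposure,
                              outcome = "cd_label",
                              adjustment = setdiff(irp_columns(),
                                                   c(exposure, stratifier)),
                              min_n = 20) {
  levels <- unique(cohort[[stratifier]])
  purrr::map_dfr(levels, function(lv) {
    sub <- cohort[cohort[[stratifier]] == lv, ]
    res <- association_analysis(sub, exposure, outcome, adjustment)
    dplyr::mutate(res, stratum = as.character(lv), stratum_n = nrow(sub),
                  unstable = nrow(sub) < min_n, .before = 1)
  })
}
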