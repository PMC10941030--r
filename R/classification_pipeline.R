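#' Greedy correlation pruning of a feature matrix
#'
#' Repeatedly locates the most correlated feature pair with `|r|` above the
#' threshold and drops the member with the larger mean absolute correlation
#' to all remaining features (ties drop the later column). Stops when all
#' pairwise `|r|` are at or below the threshold. IRP columns are exempt and
#' always retained.
#'
#' @param matrix feature tibble (numeric after imputation).
#' @param threshold correlation-coefficient cutoff (default 0.5).
#' @param protect columns exempt from pruning (default `participant_id` and
#'   the IRP covariates).
#' @return character vector of retained column names (game features plus
#'   the protected IRP columns, in original order).
#' @export
prune_correlated <- function(matrix, threshold = 0.5,
                             protect = c("participant_id", irp_columns())) {
  game_cols <- setdiff(names(matrix), protect)
  X <- as.matrix(matrix[, game_cols, drop = FALSE])
  keep <- rep(TRUE, ncol(X))
  if (ncol(X) >= 2) {
    cm <- abs(suppressWarnings(stats::cor(X, use = "pairwise.complete.obs")))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    repeat {
      sub <- cm[keep, keep, drop = FALSE]
      if (all(sub <= threshold)) break
      w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      live <- which(keep)
      i <- live[w[1]]; j <- live[w[2]]
      mi <- mean(cm[i, keep])
      mj <- mean(cm[j, keep])
      drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
      keep[drop] <- FALSE
    }
  }
  retained_game <- game_cols[keep]
  c(intersect(protect, setdiff(names(matrix), "participant_id")), retained_game)
}

model_registry <- function() c("glmnet", "plr", "rf", "gbm")

fit_predict <- function(family, x_train, y_train, x_test, seed, hyper = list()) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  set.seed(seed)
  if (family %in% c("glmnet", "plr")) {
    alpha <- if (family == "glmnet") hyper$alpha %||% 0.5 else 0
    if (ncol(x_train) < 2) {
      df <- data.frame(y = y_train, x_train)
      fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
      return(as.numeric(suppressWarnings(
        stats::predict(fit, data.frame(x_test), type = "response"))))
    }
    nf <- max(3, min(5, min(table(y_train))))
    nf <- min(nf, length(y_train))
    fit <- suppressWarnings(
      glmnet::cv.glmnet(x_train, y_train, family = "binomial",
                        alpha = alpha, nfolds = nf,
                        type.measure = "deviance"))
    as.numeric(stats::predict(fit, x_test, s = "lambda.min", type = "response"))
  } else if (family == "rf") {
    df <- data.frame(y = factor(y_train, levels = c(0, 1)), x_train)
    fit <- ranger::ranger(y ~ ., data = df,
                          num.trees = hyper$num_trees %||% 300,
                          probability = TRUE, seed = seed)
    stats::predict(fit, data.frame(x_test))$predictions[, "1"]
  } else if (family == "gbm") {
    fit <- xgboost::xgboost(
      data = x_train, label = y_train,
      nrounds = hyper$nrounds %||% 60,
      params = list(objective = "binary:logistic", max_depth = 2,
                    eta = 0.1, nthread = 1),
      verbose = 0
    )
    stats::predict(fit, x_test)
  } else {
    abort(sprintf("model family `%s` is not registered (known: %s)",
                  family, paste(model_registry(), collapse = ", ")))
  }
}

#' Rank features by model-estimated importance
#'
#' Family-specific importance averaged over a 5-fold internal split:
#' absolute standardized coefficients for the linear families (elastic-net
#' and ridge logistic), impurity importance for random forests, total split
#' gain for gradient boosting. Deterministic under a fixed seed, descending
#' order, ties broken by name.
#'
#' @param x predictor tibble (numeric).
#' @param y binary labels (0/1 or logical).
#' @param family one of `"glmnet"`, `"plr"`, `"rf"`, `"gbm"`.
#' @param seed integer seed.
#' @return tibble `feature`, `importance`, sorted.
#' @export
rank_importance <- function(x, y, family = "glmnet", seed = 1) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("both classes must be present")
  X <- as.matrix(x)
  n <- nrow(X)
  seeds <- split_seed(seed, 5, salt = 23L)
  set.seed(seeds[1])
  fold <- sample(rep(1:5, length.out = n))
  imp <- matrix(0, 5, ncol(X), dimnames = list(NULL, colnames(X)))
  for (f in 1:5) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    set.seed(seeds[f])
    if (family %in% c("glmnet", "plr")) {
      alpha <- if (family == "glmnet") 0.5 else 0
      nf <- max(3, min(5, min(table(ytr))))
      fit <- suppressWarnings(
        glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = alpha,
                          nfolds = min(nf, length(ytr)),
                          type.measure = "deviance"))
      beta <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
      sds <- apply(Xtr, 2, stats::sd)
      imp[f, ] <- abs(beta) * sds
    } else if (family == "rf") {
      df <- data.frame(y = factor(ytr, levels = c(0, 1)), Xtr)
      fit <- ranger::ranger(y ~ ., data = df, num.trees = 300,
                            importance = "impurity", seed = seeds[f])
      v <- fit$variable.importance
      imp[f, match(names(v), colnames(X))] <- v
    } else if (family == "gbm") {
      fit <- xgboost::xgboost(
        data = Xtr, label = ytr, nrounds = 60,
        params = list(objective = "binary:logistic", max_depth = 2,
                      eta = 0.1, nthread = 1),
        verbose = 0
      )
      itab <- xgboost::xgb.importance(model = fit)
      idx <- match(itab$Feature, colnames(X))
      imp[f, idx[!is.na(idx)]] <- itab$Gain[!is.na(idx)]
    } else {
      abort(sprintf("model family `%s` is not registered (known: %s)",
                    family, paste(model_registry(), collapse = ", ")))
    }
  }
  means <- colMeans(imp)
  ord <- order(-means, colnames(X))
  tibble::tibble(feature = colnames(X)[ord], importance = unname(means[ord]))
}

#' Take the top-k ranked predictors
#'
#' @param ranked ranking tibble from [rank_importance()] (or a character
#'   vector already in rank order).
#' @param k number of predictors (default 10).
#' @return character vector of length `min(k, n)`.
#' @export
select_top_k <- function(ranked, k = 10) {
  nm <- if (is.data.frame(ranked)) ranked$feature else ranked
  if (length(nm) == 0) abort("`ranked` must be non-empty")
  utils::head(nm, k)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `(#concordant pairs + 0.5 #tied pairs) / (n+ * n-)`, computed via
#' midranks.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (logical or 0/1); both classes present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_roc(c(0.9, 0.5, 0.5, 0.1), c(1, 1, 0, 0))
auc_roc <- function(scores, labels) {
  y <- as.logical(labels)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-optimal operating point
#'
#' Scans all candidate thresholds (predict positive at `score >=
#' threshold`) and returns the one maximizing Youden's J = sensitivity +
#' specificity - 1; ties resolve to the lowest threshold.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels, both classes present.
#' @return tibble `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_operating_point <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y)) abort("both classes must be present")
  cand <- sort(unique(scores))
  best <- NULL
  for (th in cand) {
    pred <- scores >= th
    sens <- sum(pred & y) / sum(y)
    spec <- sum(!pred & !y) / sum(!y)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(threshold = th, sensitivity = sens, specificity = spec, j = j)
    }
  }
  tibble::as_tibble(best)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

#' Repeated stratified cross-validated evaluation
#'
#' Stratified k-fold cross-validation repeated `repeats` times: per repeat,
#' out-of-fold scores are pooled into one AUC; the reported AUC is the mean
#' over repeats. Sensitivity and specificity come from the Youden operating
#' point on the out-of-fold scores pooled across all repeats. Fully seeded.
#'
#' @param x predictor tibble/matrix (numeric, no missing values).
#' @param y binary labels.
#' @param family model family (see [rank_importance()]).
#' @param folds,repeats cross-validation geometry (default 10 x 10). If the
#'   rarer class has fewer members than `folds`, folds are reduced with a
#'   warning.
#' @param seed integer seed.
#' @param hyper optional hyperparameter list passed to the model family.
#' @return object of class `game_eval`.
#' @export
repeated_cv_evaluate <- function(x, y, family = "glmnet", folds = 10,
                                 repeats = 10, seed = 1, hyper = list()) {
  y <- as.numeric(as.logical(y))
  if (length(unique(y)) < 2) abort("both classes must be present")
  min_class <- min(table(y))
  if (min_class < folds) {
    warn(sprintf("reducing folds from %d to %d (rarer class size)", folds, min_class))
    folds <- min_class
  }
  X <- as.matrix(x)
  rep_seeds <- split_seed(seed, repeats, salt = 31L)
  auc_per_repeat <- numeric(repeats)
  pooled_scores <- numeric(0)
  pooled_labels <- numeric(0)
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    fold <- stratified_folds(y, folds)
    oof <- numeric(length(y))
    for (f in seq_len(folds)) {
      te <- fold == f
      oof[te] <- fit_predict(family, X[!te, , drop = FALSE], y[!te],
                             X[te, , drop = FALSE],
                             seed = rep_seeds[r] + f, hyper = hyper)
    }
    auc_per_repeat[r] <- auc_roc(oof, y)
    pooled_scores <- c(pooled_scores, oof)
    pooled_labels <- c(pooled_labels, y)
  }
  op <- youden_operating_point(pooled_scores, pooled_labels)
  structure(list(
    family = family,
    auc = mean(auc_per_repeat),
    auc_sd = stats::sd(auc_per_repeat),
    sensitivity = op$sensitivity,
    specificity = op$specificity,
    threshold = op$threshold,
    per_repeat_auc = auc_per_repeat,
    folds = folds, repeats = repeats, seed = seed,
    n = length(y), predictors = colnames(X)
  ), class = "game_eval")
}

#' @export
print.game_eval <- function(x, ...) {
  cat(sprintf("<game_eval> %s: AUC %.3f (SD %.3f), sens %.1f%%, spec %.1f%% [%dx%d CV, n=%d]\n",
              x$family, x$auc, x$auc_sd, 100 * x$sensitivity,
              100 * x$specificity, x$folds, x$repeats, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.game_eval <- function(x, ...) {
  tibble::tibble(repeat_index = seq_along(x$per_repeat_auc),
                 auc = x$per_repeat_auc)
}

#' @exportS3Method generics::glance
glance.game_eval <- function(x, ...) {
  tibble::tibble(family = x$family, auc = x$auc, auc_sd = x$auc_sd,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 folds = x$folds, repeats = x$repeats, n = x$n)
}

#' Per-repeat AUC plot for a cross-validated evaluation
#'
#' @param object a `game_eval`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.game_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$auc)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "per-repeat AUC-ROC",
                  title = sprintf("%s (%dx%d CV)", object$family,
                                  object$folds, object$repeats)) +
    ggplot2::theme_minimal()
}

contrast_groups <- function(contrast) {
  switch(contrast,
    pnp_only = "+PNP-CD",
    cd_only = "-PNP+CD",
    both = "+PNP+CD",
    abort("`contrast` must be one of pnp_only, cd_only, both")
  )
}

#' Run one classification contrast (IRP vs IRP+game)
#'
#' Subsets the feature matrix to the contrast's positive group and the
#' reference group (-PNP-CD), then runs the modeling pipeline per family:
#' correlation pruning of the game features, importance ranking of the
#' pruned features plus the six IRP covariates, top-k selection, and
#' repeated stratified cross-validation. The IRP-only scope uses the six
#' covariates with no selection. By default selection happens once on the
#' full data before cross-validation; `nested = TRUE` moves ranking and
#' selection inside each training fold instead.
#'
#' @param features (preprocessed) feature tibble from
#'   [preprocess_features()].
#' @param cohort cohort tibble with `group` labels.
#' @param contrast `"pnp_only"`, `"cd_only"` or `"both"`.
#' @param families model families to compare.
#' @param folds,repeats cross-validation geometry.
#' @param seed integer seed.
#' @param k number of selected predictors (default 10).
#' @param prune_threshold correlation cutoff (default 0.5).
#' @param nested move feature selection inside each fold?
#' @return object of class `contrast_result`: per-family evaluations for
#'   both scopes, the comparison table, selected predictors, and the best
#'   evaluation per scope.
#' @export
run_contrast <- function(features, cohort, contrast = "both",
                         families = "glmnet", folds = 10, repeats = 10,
                         seed = 1, k = 10, prune_threshold = 0.5,
                         nested = FALSE) {
  positive <- contrast_groups(contrast)
  reference <- "-PNP-CD"
  sub_cohort <- cohort[as.character(cohort$group) %in% c(positive, reference), ]
  dat <- features[features$participant_id %in% sub_cohort$id, ]
  if (nrow(dat) == 0) abort("no participants in the requested contrast")
  y <- as.numeric(as.character(sub_cohort$group[match(dat$participant_id,
                                                      sub_cohort$id)]) == positive)
  if (length(unique(y)) < 2) abort("a contrast group is empty")
  irp <- dat[, irp_columns()]
  retained <- prune_correlated(dat, threshold = prune_threshold)
  candidates <- dat[, retained, drop = FALSE]
  evals_irp <- list()
  evals_game <- list()
  selected <- list()
  rows <- list()
  for (fam in families) {
    salt <- match(fam, model_registry())
    fam_seed <- split_seed(seed, 1, salt = if (is.na(salt)) 99L else salt)
    e_irp <- repeated_cv_evaluate(irp, y, family = fam, folds = folds,
                                  repeats = repeats, seed = fam_seed)
    if (nested) {
      e_game <- nested_cv_evaluate(candidates, y, fam, folds, repeats,
                                   fam_seed, k)
      sel <- e_game$predictors
    } else {
      ranking <- rank_importance(candidates, y, family = fam, seed = fam_seed)
      sel <- select_top_k(ranking, k)
      e_game <- repeated_cv_evaluate(candidates[, sel, drop = FALSE], y,
                                     family = fam, folds = folds,
                                     repeats = repeats, seed = fam_seed)
    }
    evals_irp[[fam]] <- e_irp
    evals_game[[fam]] <- e_game
    selected[[fam]] <- sel
    rows[[fam]] <- dplyr::bind_rows(
      dplyr::mutate(glance(e_irp), scope = "IRP_only", .before = 1),
      dplyr::mutate(glance(e_game), scope = "IRP_plus_game", .before = 1)
    )
  }
  comparison <- dplyr::bind_rows(rows)
  best_game <- evals_game[[which.max(vapply(evals_game, `[[`, 0, "auc"))]]
  best_irp <- evals_irp[[which.max(vapply(evals_irp, `[[`, 0, "auc"))]]
  structure(list(contrast = contrast, positive = positive,
                 reference = reference, comparison = comparison,
                 evals_irp = evals_irp, evals_game = evals_game,
                 selected = selected, best_irp = best_irp,
                 best_game = best_game, n = length(y),
                 n_positive = sum(y)),
            class = "contrast_result")
}

# Nested variant: ranking + top-k selection re-done inside every training
# fold, quantifying the optimism of selecting before CV.
nested_cv_evaluate <- function(x, y, family, folds, repeats, seed, k) {
  y <- as.numeric(as.logical(y))
  min_class <- min(table(y))
  if (min_class < folds) {
    warn(sprintf("reducing folds from %d to %d (rarer class size)", folds, min_class))
    folds <- min_class
  }
  X <- as.matrix(x)
  rep_seeds <- split_seed(seed, repeats, salt = 43L)
  auc_per_repeat <- numeric(repeats)
  pooled_scores <- numeric(0)
  pooled_labels <- numeric(0)
  sel_all <- character(0)
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    fold <- stratified_folds(y, folds)
    oof <- numeric(length(y))
    for (f in seq_len(folds)) {
      te <- fold == f
      rk <- rank_importance(tibble::as_tibble(X[!te, , drop = FALSE]), y[!te],
                            family = family, seed = rep_seeds[r] + f)
      sel <- select_top_k(rk, k)
      sel_all <- c(sel_all, sel)
      oof[te] <- fit_predict(family, X[!te, sel, drop = FALSE], y[!te],
                             X[te, sel, drop = FALSE],
                             seed = rep_seeds[r] + f)
    }
    auc_per_repeat[r] <- auc_roc(oof, y)
    pooled_scores <- c(pooled_scores, oof)
    pooled_labels <- c(pooled_labels, y)
  }
  op <- youden_operating_point(pooled_scores, pooled_labels)
  structure(list(
    family = family, auc = mean(auc_per_repeat),
    auc_sd = stats::sd(auc_per_repeat),
    sensitivity = op$sensitivity, specificity = op$specificity,
    threshold = op$threshold, per_repeat_auc = auc_per_repeat,
    folds = folds, repeats = repeats, seed = seed, n = length(y),
    predictors = names(sort(table(sel_all), decreasing = TRUE))[
      seq_len(min(k, length(unique(sel_all))))]
  ), class = "game_eval")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s vs %s (n=%d, %d positive)\n",
              x$positive, x$reference, x$n, x$n_positive))
  print(x$comparison[, c("scope", "family", "auc", "sensitivity", "specificity")])
  invisible(x)
}

#' @exportS3Method generics::glance
glance.contrast_result <- function(x, ...) {
  dplyr::mutate(x$comparison, contrast = x$contrast, .before = 1)
}

#' AUC comparison plot for a classification contrast
#'
#' @param object a `contrast_result`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.contrast_result <- function(object, ...) {
  d <- object$comparison
  ggplot2::ggplot(d, ggplot2::aes(x = .data$family, y = .data$auc,
                                  fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::labs(x = NULL, y = "mean AUC-ROC over CV repeats",
                  title = sprintf("%s vs %s", object$positive, object$reference)) +
    ggplot2::theme_minimal()
}
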