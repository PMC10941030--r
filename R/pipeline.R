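#' Screen game features for group differences within matched subcohorts
#'
#' For each contrast (+PNP-CD, -PNP+CD, +PNP+CD, each against the -PNP-CD
#' reference), builds a covariate-matched subcohort via
#' [cardinality_match()], compares every non-constant game feature between
#' the groups with the normality-gated test, applies Holm-Bonferroni
#' correction within the subcohort, and returns the significant-feature
#' lists.
#'
#' @param features (preprocessed) feature tibble.
#' @param cohort cohort tibble.
#' @param contrasts subset of `c("pnp_only", "cd_only", "both")`.
#' @param alpha significance level on the adjusted p-values.
#' @param tolerance SMD tolerance for the matching step.
#' @return named list, one tibble per contrast (`feature`, `test`,
#'   `p_value`, `p_adjusted`), containing the significant features; the
#'   full test tables are attached as attribute `"all_tests"`.
#' @export
feature_group_screen <- function(features, cohort,
                                 contrasts = c("pnp_only", "cd_only", "both"),
                                 alpha = 0.05, tolerance = 0.1) {
  out <- list()
  all_tests <- list()
  game_cols <- setdiff(names(features), c("participant_id", irp_columns()))
  for (ct in contrasts) {
    positive <- contrast_groups(ct)
    sub <- cohort[as.character(cohort$group) %in% c(positive, "-PNP-CD") &
                    cohort$id %in% features$participant_id, ]
    sub$is_positive <- as.character(sub$group) == positive
    m <- cardinality_match(sub, "is_positive", solver = "greedy",
                           tolerance = tolerance)
    keep <- sub[sub$id %in% m$retained_ids, ]
    dat <- features[match(keep$id, features$participant_id), game_cols]
    grp <- ifelse(keep$is_positive, "positive", "reference")
    usable <- vapply(dat, function(x) length(unique(x[!is.na(x)])) > 1,
                     logical(1))
    tests <- purrr::map_dfr(game_cols[usable], function(fc) {
      r <- compare_groups(dat[[fc]], grp, kind = "continuous")
      tibble::tibble(feature = fc, test = r$test, p_value = r$p_value)
    })
    tests$p_adjusted <- holm_adjust(tests$p_value)
    all_tests[[ct]] <- tests
    out[[ct]] <- tests[tests$p_adjusted < alpha, ]
  }
  attr(out, "all_tests") <- all_tests
  out
}

#' Run the full assessment pipeline end to end
#'
#' Cohort simulation, session simulation, feature extraction and
#' pre-processing, cohort summary, cardinality matching, odds-ratio
#' association models 1-4, and the three classification contrasts.
#' Idempotent under a fixed seed (one master seed is fanned out
#' deterministically to each stage).
#'
#' @param group_counts four-group quotas (default the published cohort
#'   structure 80/92/28/61).
#' @param seed master seed.
#' @param config a [game_config()]; defaults to the standard session
#'   simulated at 50 Hz (features are sampling-rate-invariant by
#'   construction, so the lighter rate is used for routine runs).
#' @param cohort_cfg a [cohort_config()]; `group_counts` overrides its
#'   quotas.
#' @param families model families for the contrasts.
#' @param folds,repeats cross-validation geometry.
#' @param contrasts which contrasts to run.
#' @param screen also run [feature_group_screen()]?
#' @return object of class `study_run`: list with `cohort`, `features`,
#'   `table1`, `match`, `association`, `contrasts`, optional `screen`, and
#'   a `log` of stage counts.
#' @export
run_study <- function(group_counts = c(80, 92, 28, 61), seed = 1,
                      config = game_config(sampling_rate = 50),
                      cohort_cfg = cohort_config(group_counts),
                      families = "glmnet", folds = 10, repeats = 10,
                      contrasts = c("pnp_only", "cd_only", "both"),
                      screen = FALSE) {
  seeds <- split_seed(seed, 6, salt = 7L)
  cohort_cfg$group_counts <- as.integer(group_counts)
  cohort <- simulate_cohort(cohort_cfg, seed = seeds[1])
  sessions <- simulate_sessions(cohort, config, seed = seeds[2])
  features_raw <- build_feature_matrix(sessions, cohort, config)
  features <- preprocess_features(features_raw)
  table1 <- summarize_cohort(cohort)
  match <- cardinality_match(cohort, "cd_label", exact = "diabetes_type")
  association <- association_analysis(cohort, "pnp_label", matched = match)
  contrast_results <- lapply(contrasts, function(ct) {
    run_contrast(features, cohort, contrast = ct, families = families,
                 folds = folds, repeats = repeats, seed = seeds[4])
  })
  names(contrast_results) <- contrasts
  scr <- if (screen) feature_group_screen(features, cohort) else NULL
  log <- list(
    participants = nrow(cohort),
    valid_sessions = nrow(features),
    features_raw = ncol(features_raw) - 1 - length(irp_columns()),
    features_retained = ncol(features) - 1 - length(irp_columns()),
    matched_per_group = match$n_per_group
  )
  structure(list(cohort = cohort, features = features, table1 = table1,
                 match = match, association = association,
                 contrasts = contrast_results, screen = scr,
                 seed = seed, log = log),
            class = "study_run")
}

#' @export
print.study_run <- function(x, ...) {
  cat("<study_run>\n")
  cat(sprintf("  participants: %d; valid sessions: %d\n",
              x$log$participants, x$log$valid_sessions))
  cat(sprintf("  game features: %d extracted, %d retained after pre-processing\n",
              x$log$features_raw, x$log$features_retained))
  cat(sprintf("  matching: %d per group (%s)\n",
              x$log$matched_per_group, x$match$status))
  for (ct in names(x$contrasts)) {
    cr <- x$contrasts[[ct]]
    cat(sprintf("  %s: IRP AUC %.3f -> IRP+game AUC %.3f\n",
                ct, cr$best_irp$auc, cr$best_game$auc))
  }
  invisible(x)
}
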