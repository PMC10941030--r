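irp_stub <- function(n) {
  tibble::tibble(participant_id = sprintf("P%03d", seq_len(n)),
                 gender = rep(c(0, 1), length.out = n), age = 55 + seq_len(n) %% 20,
                 weight = 80 + seq_len(n) %% 15, bmi = 25 + seq_len(n) %% 8,
                 diabetes_type = rep(c(1, 2), length.out = n),
                 diabetes_duration = 5 + seq_len(n) %% 25)
}

test_that("correlation pruning removes duplicates and respects the threshold", {
  set.seed(1)
  base <- rnorm(50)
  m <- dplyr::bind_cols(irp_stub(50), tibble::tibble(
    f1 = base, f2 = base, f3 = rnorm(50), f4 = rnorm(50)
  ))
  kept <- prune_correlated(m, threshold = 0.5)
  expect_equal(sum(c("f1", "f2") %in% kept), 1)
  expect_true(all(c("f3", "f4") %in% kept))
  expect_true(all(irp_columns() %in% kept))
  # orthogonal columns all retained
  m2 <- dplyr::bind_cols(irp_stub(60), tibble::tibble(
    g1 = rep(c(1, 0, 0), 20), g2 = rep(c(0, 1, 0), 20), g3 = rep(c(0, 0, 1), 20)
  ))
  kept2 <- prune_correlated(m2, threshold = 0.5)
  expect_true(all(c("g1", "g2", "g3") %in% kept2))
})

test_that("pruning agrees with a brute-force application of the rule", {
  set.seed(5)
  for (i in 1:10) {
    n <- 60
    z <- rnorm(n)
    X <- cbind(a = z + rnorm(n, 0, 0.3), b = z + rnorm(n, 0, 0.3),
               c = rnorm(n), d = -z + rnorm(n, 0, 0.5))
    m <- dplyr::bind_cols(irp_stub(n), tibble::as_tibble(X))
    kept <- setdiff(prune_correlated(m, threshold = 0.5), irp_columns())
    oracle <- colnames(X)[brute_prune(X, 0.5)]
    expect_identical(sort(kept), sort(oracle))
    cm <- abs(stats::cor(as.matrix(m[, kept, drop = FALSE])))
    diag(cm) <- 0
    expect_lte(max(cm), 0.5)
  }
})

test_that("AUC matches explicit pair counting", {
  expect_equal(auc_roc(c(0.9, 0.5, 0.5, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_equal(auc_roc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  set.seed(9)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_roc(s, y), brute_auc(s, y))
  }
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(10)
  for (i in 1:30) {
    s <- rnorm(40)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- auc_roc(s, y)
    expect_equal(auc_roc(exp(s), y), a)
    expect_equal(auc_roc(qlogis(plogis(s)), y), a, tolerance = 1e-12)
    expect_equal(auc_roc(-s, y), 1 - a) # tie-free scores
  }
})

test_that("the Youden scan finds the documented operating points", {
  perfect <- youden_operating_point(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_gt(perfect$threshold, 0.3)
  expect_lte(perfect$threshold, 0.8)
  # single positive below all negatives: no threshold beats J = 0
  worst <- youden_operating_point(c(0.1, 0.5, 0.6), c(1, 0, 0))
  expect_equal(worst$j, 0, tolerance = 1e-12)
})

test_that("top-k selection truncates and guards degenerate input", {
  ranked <- tibble::tibble(feature = letters[1:25], importance = 25:1)
  expect_length(select_top_k(ranked), 10)
  expect_identical(select_top_k(ranked, 10), letters[1:10])
  expect_length(select_top_k(tibble::tibble(feature = letters[1:4],
                                            importance = 4:1)), 4)
  expect_length(select_top_k(ranked, 0), 0)
})

test_that("a planted perfect predictor ranks first for every family", {
  set.seed(12)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  x <- tibble::tibble(signal = y + rnorm(n, 0, 0.05))
  for (j in 1:12) x[[paste0("noise", j)]] <- rnorm(n)
  for (fam in c("glmnet", "rf", "gbm")) {
    rk <- rank_importance(x, y, family = fam, seed = 4)
    expect_identical(rk$feature[1], "signal")
  }
  expect_error(rank_importance(x, rep(1, n), family = "glmnet"), "classes")
  expect_error(rank_importance(x, y, family = "made_up"), "not registered")
})

test_that("repeated CV scores a perfectly predictive feature at AUC 1", {
  set.seed(13)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- tibble::tibble(signal = y * 2 - 1 + rnorm(n, 0, 0.01),
                      other = rnorm(n))
  ev <- repeated_cv_evaluate(x, y, family = "glmnet", folds = 5, repeats = 3,
                             seed = 2)
  expect_true(all(ev$per_repeat_auc == 1))
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_length(ev$per_repeat_auc, 3)
  expect_s3_class(autoplot(ev), "ggplot")
})

test_that("label permutation yields chance-level AUC", {
  set.seed(14)
  n <- 200
  x <- tibble::as_tibble(matrix(rnorm(n * 8), n,
                                dimnames = list(NULL, paste0("v", 1:8))))
  y <- sample(rep(c(0, 1), each = n / 2))
  ev <- repeated_cv_evaluate(x, y, family = "glmnet", folds = 10,
                             repeats = 10, seed = 3)
  expect_gte(ev$auc, 0.4)
  expect_lte(ev$auc, 0.6)
})

test_that("folds reduce with a warning when the rarer class is small", {
  set.seed(15)
  y <- rep(c(1, 0), c(9, 40))
  x <- tibble::tibble(a = rnorm(49), b = rnorm(49))
  expect_warning(
    ev <- repeated_cv_evaluate(x, y, family = "glmnet", folds = 10,
                               repeats = 2, seed = 1),
    "reducing folds"
  )
  expect_equal(ev$folds, 9)
  expect_error(repeated_cv_evaluate(x, rep(1, 49)), "classes")
})

test_that("CV evaluation is deterministic under a fixed seed", {
  set.seed(16)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- tibble::as_tibble(matrix(rnorm(n * 5), n,
                                dimnames = list(NULL, paste0("v", 1:5))))
  x$v1 <- x$v1 + y
  a <- repeated_cv_evaluate(x, y, folds = 5, repeats = 2, seed = 8)
  b <- repeated_cv_evaluate(x, y, folds = 5, repeats = 2, seed = 8)
  expect_identical(a$per_repeat_auc, b$per_repeat_auc)
})
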