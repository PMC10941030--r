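test_that("standardized mean difference follows its definition", {
  expect_equal(smd(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3)), 0)
  set.seed(1)
  a <- rnorm(2000, 0, 1); b <- rnorm(2000, 1, 1)
  expect_equal(smd(c(a, b), rep(c("A", "B"), each = 2000)), 1, tolerance = 0.1)
  expect_equal(smd(c(1, 2, 3, 2, 3, 4), rep(c("A", "B"), each = 3)), 1)
  # binary variant
  v <- c(rep(1, 3), rep(0, 7), rep(1, 5), rep(0, 5))
  p1 <- 0.3; p2 <- 0.5
  expect_equal(smd(v, rep(c("A", "B"), each = 10)),
               abs(p1 - p2) / sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2))
})

test_that("already balanced equal groups are fully retained", {
  set.seed(2)
  d <- tibble::tibble(id = sprintf("x%02d", 1:20),
                      grp = rep(c(1, 0), each = 10),
                      age = rep(60:69, 2))
  m <- cardinality_match(d, "grp", covariates = "age", id_col = "id")
  expect_equal(m$n_per_group, 10)
  expect_identical(m$status, "optimal")
  expect_true(all(m$smd$after <= 0.1))
})

test_that("unequal balanced groups are trimmed to equal size", {
  d <- tibble::tibble(id = sprintf("x%02d", 1:20),
                      grp = rep(c(1, 0), c(12, 8)),
                      age = c(rep(60:65, 2), 60:67))
  m <- cardinality_match(d, "grp", covariates = "age", solver = "greedy",
                         id_col = "id")
  expect_equal(length(m$retained$cases), length(m$retained$controls))
  expect_equal(m$n_per_group, 8)
})

test_that("the exact solver matches exhaustive subset search on toy cohorts", {
  # one extreme-age participant must be sacrificed for balance
  set.seed(3)
  for (rep_i in 1:5) {
    ages_a <- c(round(rnorm(5, 65, 3)), 95)
    ages_b <- round(rnorm(6, 65, 3))
    d <- toy_match_cohort(ages_a, ages_b)
    m <- cardinality_match(d, "grp", covariates = "age", tolerance = 0.25,
                           solver = "exact", id_col = "id")
    X <- matrix(d$age, ncol = 1)
    oracle_k <- brute_cardinality(X, d$grp, tolerance = 0.25)
    expect_equal(m$n_per_group, oracle_k)
    if (m$n_per_group > 0) expect_true(all(m$smd$after <= 0.25))
  }
})

test_that("greedy matching achieves the tolerance on a skewed cohort", {
  cohort <- simulate_cohort(cohort_config(c(30, 35, 10, 25)), seed = 8)
  m <- cardinality_match(cohort, "cd_label", exact = "diabetes_type")
  expect_identical(m$status, "greedy_fallback")
  expect_true(all(m$smd$after <= 0.1))
  expect_equal(length(m$retained$cases), length(m$retained$controls))
  # exact constraint: identical diabetes-type counts in both retained arms
  sub <- cohort[cohort$id %in% m$retained$cases, ]
  ref <- cohort[cohort$id %in% m$retained$controls, ]
  expect_identical(table(sub$diabetes_type), table(ref$diabetes_type))
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("odds ratios reproduce the published 2x2 worked examples", {
  pre <- odds_ratio_2x2(61, 28, 92, 80)
  expect_equal(round(pre$or, 2), 1.89)
  post <- odds_ratio_2x2(61, 28, 49, 40)
  expect_equal(round(post$or, 2), 1.78)
  unit <- odds_ratio_2x2(1, 1, 1, 1)
  expect_equal(unit$or, 1)
  zero <- odds_ratio_2x2(0, 5, 5, 5)
  expect_true(zero$corrected)
  expect_gt(zero$ci_low, 0)
})

test_that("univariate logistic coefficients equal the cross-product OR", {
  make_data <- function(a, b, c, d) {
    tibble::tibble(
      y = rep(c(1, 1, 0, 0), c(a, b, c, d)),
      x = rep(c(1, 0, 1, 0), c(a, b, c, d))
    )
  }
  d <- make_data(61, 28, 49, 40)
  fit <- fit_logistic(d, "y", "x")
  expect_equal(exp(tidy(fit)$estimate[2]), odds_ratio_2x2(61, 28, 49, 40)$or,
               tolerance = 1e-6)
  set.seed(21)
  for (i in 1:200) {
    cells <- sample(3:40, 4, replace = TRUE)
    f <- fit_logistic(make_data(cells[1], cells[2], cells[3], cells[4]),
                      "y", "x")
    expect_equal(exp(tidy(f)$estimate[2]),
                 odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])$or,
                 tolerance = 1e-6)
  }
})

test_that("independence and separation are detected", {
  balanced <- tibble::tibble(y = rep(c(1, 0), each = 20),
                             x = rep(c(1, 0, 1, 0), each = 10))
  fit <- fit_logistic(balanced, "y", "x")
  expect_lt(abs(tidy(fit)$estimate[2]), 1e-8)
  sep <- tibble::tibble(y = rep(c(1, 0), each = 20),
                        x = rep(c(1, 0), each = 20))
  expect_error(fit_logistic(sep, "y", "x"), "separation")
})

test_that("Woolf 95% CIs cover a true OR of 2 at the nominal rate", {
  set.seed(31)
  p0 <- 0.3
  p1 <- 2 * (p0 / (1 - p0)) / (1 + 2 * (p0 / (1 - p0)))
  covered <- logical(500)
  for (i in 1:500) {
    a <- rbinom(1, 120, p1); b <- 120 - a
    c <- rbinom(1, 120, p0); d <- 120 - c
    ci <- odds_ratio_2x2(a, b, c, d)
    covered[i] <- ci$ci_low <= 2 && 2 <= ci$ci_high
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("association models recover a planted conditional OR", {
  set.seed(41)
  n <- 2000
  x <- rbinom(n, 1, 0.4)
  logit_p <- -0.5 + log(2) * x
  y <- rbinom(n, 1, plogis(logit_p))
  cohort <- tibble::tibble(id = as.character(1:n), exposure = x == 1,
                           outcome = y == 1)
  res <- association_analysis(cohort, "exposure", outcome = "outcome",
                              adjustment = character(0))
  or1 <- res$or[res$model == "model1"]
  expect_gte(or1, 1.7)
  expect_lte(or1, 2.3)
  # empty adjustment set: model 2 equals model 1
  expect_equal(res$or[res$model == "model2"], or1)
})

test_that("degenerate exposures return a reference-only row with a warning", {
  d <- tibble::tibble(id = as.character(1:30), e = rep(TRUE, 30),
                      y = rbinom(30, 1, 0.5) == 1)
  expect_warning(res <- association_analysis(d, "e", outcome = "y",
                                             adjustment = character(0)),
                 "single level")
  expect_true(grepl("ref", res$term[1]))
})

test_that("subgroup analysis recovers a planted female-only effect", {
  set.seed(51)
  n <- 3000
  female <- rbinom(n, 1, 0.5) == 1
  x <- rbinom(n, 1, 0.5)
  logit_p <- -1 + ifelse(female, log(5), 0) * x
  y <- rbinom(n, 1, plogis(logit_p)) == 1
  d <- tibble::tibble(id = as.character(1:n),
                      gender = ifelse(female, "female", "male"),
                      exposure = x == 1, outcome = y)
  res <- subgroup_analysis(d, "gender", "exposure", outcome = "outcome",
                           adjustment = character(0))
  or_f <- res$or[res$stratum == "female" & res$model == "model1"]
  or_m <- res$or[res$stratum == "male" & res$model == "model1"]
  expect_gt(or_f, or_m)
  expect_false(any(res$unstable))
  # tiny stratum gets flagged
  d2 <- d[c(1:5, which(d$gender == "male")[1:50]), ]
  res2 <- suppressWarnings(subgroup_analysis(d2, "gender", "exposure",
                                             outcome = "outcome",
                                             adjustment = character(0)))
  expect_true(any(res2$unstable))
})
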