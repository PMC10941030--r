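cfg50 <- game_config(sampling_rate = 50)

test_that("reaction time is the first threshold crossing after stimulus onset", {
  # constructed trace crossing 0.2 exactly at t = 0.8 with stimulus at t = 0.3
  cfg <- game_config(sampling_rate = 10)
  cfg$tasks$stimulus_onset[cfg$tasks$game == "AC" & cfg$tasks$task_index == 1] <- 0.3
  t <- seq(0, 2, by = 0.1)
  value <- ifelse(t < 0.8, 0.05, 0.5)
  tr <- manual_trace("AC", 1, t, value,
                     aux = list(catch_success = 1, positional_error = 0,
                                overshoot_count = 0))
  fv <- extract_primary(tr, config = cfg)
  expect_equal(unname(fv["reaction_time"]), 0.5)
})

test_that("timeouts leave time-based features missing and set the flag", {
  t <- seq(0, 25, by = 0.5)
  tr <- manual_trace("CP", 1, t, rep(0.05, length(t)), outcome = "timeout",
                     aux = list(time_to_valid_hold = NA_real_,
                                hold_stability_sd = NA_real_,
                                timeout_flag = 1,
                                band_exceedance_fraction = NA_real_))
  fv <- extract_primary(tr, config = cfg50)
  expect_true(is.na(fv["reaction_time"]))
  expect_true(is.na(fv["time_to_valid_hold"]))
  expect_equal(unname(fv["timeout_flag"]), 1)
})

test_that("a constant in-band hold has zero stability SD", {
  traits <- zero_impairment_traits()
  task <- cfg50$tasks[cfg50$tasks$game == "CP", ][1, ]
  set.seed(1)
  tr <- simulate_task(task, traits, config = cfg50)
  expect_identical(tr$outcome, "success")
  # pressure still converging within the hold window: SD tiny but defined
  expect_lt(tr$aux$hold_stability_sd, 0.02)
  # fully constant synthetic hold
  tr2 <- manual_trace("CP", 1, seq(0, 5, 0.1), rep(0.3, 51),
                      aux = list(time_to_valid_hold = 1,
                                 hold_stability_sd = 0, timeout_flag = 0,
                                 band_exceedance_fraction = 0))
  expect_equal(unname(extract_primary(tr2, config = cfg50)["hold_stability_sd"]), 0)
})

test_that("unknown base features are rejected", {
  tr <- manual_trace("AC", 1, 0:5, rep(0.5, 6))
  expect_error(extract_primary(tr, base_features = "not_a_feature",
                               config = cfg50), "unknown base feature")
})

test_that("secondary aggregation follows sum/mean/sample-SD with missing rules", {
  expect_equal(aggregate_secondary(c(2, 2, 2)),
               tibble::tibble(sum = 6, mean = 2, sd = 0))
  expect_equal(aggregate_secondary(c(1, 2, 3)),
               tibble::tibble(sum = 6, mean = 2, sd = 1))
  one <- aggregate_secondary(3.5)
  expect_equal(one$sum, 3.5)
  expect_equal(one$mean, 3.5)
  expect_true(is.na(one$sd))
  none <- aggregate_secondary(c(NA_real_, NA_real_))
  expect_true(all(is.na(none)))
})

test_that("aggregation agrees with brute-force recomputation on random members", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:8, 1)
    x <- rnorm(n)
    x[runif(n) < 0.2] <- NA
    got <- aggregate_secondary(x)
    xx <- x[!is.na(x)]
    if (length(xx) == 0) {
      expect_true(all(is.na(got)))
    } else {
      expect_equal(got$sum, sum(xx))
      expect_equal(got$mean, sum(xx) / length(xx))
      if (length(xx) >= 2) {
        expect_equal(got$sd, sqrt(sum((xx - mean(xx))^2) / (length(xx) - 1)))
      } else {
        expect_true(is.na(got$sd))
      }
    }
  }
})

test_that("feature matrix keeps only valid sessions and matches the catalogue", {
  cohort <- simulate_cohort(cohort_config(c(2, 1, 0, 1)), seed = 31)
  recs <- simulate_sessions(cohort, cfg50, seed = 32)
  # invalidate one session by truncating it
  recs[[2]]$traces <- recs[[2]]$traces[1:5]
  recs[[2]]$complete <- FALSE
  fm <- build_feature_matrix(recs, cohort, cfg50)
  expect_equal(nrow(fm), 3)
  expect_false(cohort$id[2] %in% fm$participant_id)
  expect_equal(ncol(fm), 1 + 6 + nrow(feature_catalogue(cfg50)))
  expect_true(all(irp_cols <- c("gender", "age", "weight", "bmi",
                                "diabetes_type", "diabetes_duration") %in% names(fm)))
  # unknown participant triggers a join error
  recs[[1]]$participant_id <- "ghost"
  expect_error(build_feature_matrix(recs, cohort, cfg50), "absent")
})

test_that("extraction is a pure function of the trace", {
  cohort <- simulate_cohort(cohort_config(c(1, 0, 0, 1)), seed = 33)
  set.seed(5)
  rec <- simulate_session(cfg50, cohort[2, ])
  a <- lapply(rec$traces, extract_primary, config = cfg50)
  b <- lapply(rec$traces, extract_primary, config = cfg50)
  expect_identical(a, b)
})

test_that("time-based features are stable across sampling rates", {
  cohort <- simulate_cohort(cohort_config(c(1, 0, 0, 0)), seed = 35)
  for (nm in names(cohort)) if (startsWith(nm, "latent_")) cohort[[nm]] <- 0
  cohort$latent_reaction_latency_mean <- 0.5
  cfg200 <- game_config(sampling_rate = 200)
  set.seed(1); rec50 <- simulate_session(cfg50, cohort[1, ])
  set.seed(1); rec200 <- simulate_session(cfg200, cohort[1, ])
  f50 <- extract_primary(rec50$traces[[1]], config = cfg50)
  f200 <- extract_primary(rec200$traces[[1]], config = cfg200)
  expect_lt(abs(f50["reaction_time"] - f200["reaction_time"]), 1 / 50 + 1e-9)
})

test_that("mirroring a session maps TCL features onto TCR exactly", {
  cfg <- game_config(sampling_rate = 50)
  mirrored <- cfg
  mirrored$tasks$controlling_foot <- c(left = "right", right = "left",
                                       both = "both")[cfg$tasks$controlling_foot]
  cohort <- simulate_cohort(cohort_config(c(0, 1, 0, 0)), seed = 36)
  set.seed(11); rec <- simulate_session(cfg, cohort[1, ])
  set.seed(11); rec_m <- simulate_session(mirrored, cohort[1, ])
  fm <- build_feature_matrix(list(rec), cohort, cfg)
  fm_m <- build_feature_matrix(list(rec_m), cohort, mirrored)
  tcl <- grep("^AC_TCL1_reaction_time", names(fm), value = TRUE)
  tcr <- sub("TCL1", "TCR1", tcl)
  expect_equal(unlist(fm[1, tcl]), unlist(fm_m[1, tcr]),
               ignore_attr = TRUE)
})

test_that("pre-processing drops, imputes, and records a manifest", {
  m <- tibble::tibble(
    participant_id = sprintf("P%d", 1:10),
    gender = rep(c(0, 1), 5), age = 51:60, weight = rnorm(10, 80),
    bmi = rnorm(10, 28), diabetes_type = rep(2, 10),
    diabetes_duration = rexp(10, 0.1),
    const_feat = rep(7, 10),
    holey_feat = c(rep(NA, 3), 4:10),
    ok_feat = c(1, NA, 3, 4:10)
  )
  out <- preprocess_features(m, max_missing = 0.2)
  d <- attr(out, "dropped")
  expect_true("const_feat" %in% d$name[d$reason == "constant"])
  expect_true("holey_feat" %in% d$name[d$reason == "missingness"])
  expect_false("holey_feat" %in% names(out))
  expect_equal(out$ok_feat[2], stats::median(c(1, 3, 4:10)))
  expect_false(anyNA(out$ok_feat))
})
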