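#' Diagnose peripheral neuropathy from NDS and NSS
#'
#' PNP is diagnosed by the clinical-practice rule: NDS >= 6, or NDS >= 3
#' combined with NSS >= 5.
#'
#' @param nds Neuropathy Disability Score, integer 0-10 (vectorized).
#' @param nss Neuropathy Symptom Score, integer 0-10 (vectorized).
#' @return logical vector.
#' @export
#' @examples
#' diagnose_pnp(6, 0)
#' diagnose_pnp(3, 5)
#' diagnose_pnp(5, 4)
diagnose_pnp <- function(nds, nss) {
  assert_in_range(nds, 0, 10, "nds")
  assert_in_range(nss, 0, 10, "nss")
  nds >= 6 | (nds >= 3 & nss >= 5)
}

#' Diagnose cognitive dysfunction from MoCA and education
#'
#' One point is added to the raw MoCA score for persons with 12 or fewer
#' years of education (capped at 30); an adjusted score below 26 is
#' classified as cognitive dysfunction.
#'
#' @param moca_raw raw MoCA score, integer 0-30 (vectorized).
#' @param education_years years of education (vectorized).
#' @return logical vector.
#' @export
#' @examples
#' diagnose_cd(25, 13) # TRUE
#' diagnose_cd(25, 12) # FALSE: education point lifts it to 26
diagnose_cd <- function(moca_raw, education_years) {
  assert_in_range(moca_raw, 0, 30, "moca_raw")
  if (any(education_years < 0)) abort("`education_years` must be >= 0")
  adjusted <- pmin(30, moca_raw + as.integer(education_years <= 12))
  adjusted < 26
}

#' Band an NDS or NSS score into severity classes
#'
#' NDS: 3-5 mild, 6-8 moderate, 9-10 severe. NSS: 3-4 mild, 5-6 moderate,
#' 7-10 severe. Scores of 0-2 are normal on both scales.
#'
#' @param score integer 0-10 (vectorized).
#' @param scale `"NDS"` or `"NSS"`.
#' @return factor with levels normal, mild, moderate, severe.
#' @export
classify_severity <- function(score, scale = c("NDS", "NSS")) {
  scale <- match.arg(scale)
  assert_in_range(score, 0, 10, "score")
  breaks <- if (scale == "NDS") c(-1, 2, 5, 8, 10) else c(-1, 2, 4, 6, 10)
  cut(score, breaks = breaks,
      labels = c("normal", "mild", "moderate", "severe"))
}

cohort_group_levels <- function() c("-PNP-CD", "+PNP-CD", "-PNP+CD", "+PNP+CD")

# Per-group covariate parameters moment-matched to published medians/IQRs
# (age, weight, BMI normal; diabetes duration log-normal; gender and
# diabetes type Bernoulli). Order: -PNP-CD, +PNP-CD, -PNP+CD, +PNP+CD.
default_covariate_params <- function() {
  list(
    age = list(median = c(65, 69, 68.5, 71), iqr = c(11, 9, 13.5, 9)),
    weight = list(median = c(85.5, 88, 84.5, 87), iqr = c(20.2, 20, 18.2, 24)),
    bmi = list(median = c(28.2, 29.5, 26.9, 29.6), iqr = c(7.3, 7.1, 5, 7.3)),
    duration = list(median = c(10, 18, 10, 16), iqr = c(11.2, 21, 18.2, 12)),
    p_female = c(0.462, 0.348, 0.214, 0.311),
    p_type1 = c(0.212, 0.261, 0.071, 0.131),
    p_low_education = 0.6
  )
}

#' Moment-match a log-normal to a printed median and IQR
#'
#' Solves for `sdlog` such that the log-normal with `meanlog = log(median)`
#' has the requested interquartile range. Used to turn published
#' median (IQR) table cells into sampling distributions.
#'
#' @param median,iqr target median and interquartile range (> 0).
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormal_from_median_iqr <- function(median, iqr) {
  stopifnot(median > 0, iqr > 0)
  z <- stats::qnorm(0.75)
  f <- function(s) median * (exp(z * s) - exp(-z * s)) - iqr
  s <- stats::uniroot(f, c(1e-6, 10), tol = 1e-10)$root
  list(meanlog = log(median), sdlog = s)
}

#' Cohort generator configuration
#'
#' Defines the four-group cohort structure (group quotas over
#' -PNP-CD / +PNP-CD / -PNP+CD / +PNP+CD), per-group covariate
#' distributions, and the latent-trait effect sizes through which cognitive
#' dysfunction (longer reaction latency, more decision errors) and
#' peripheral neuropathy (noisier pressure control, higher sensation
#' thresholds) express themselves in play.
#'
#' @param group_counts integer vector of length 4, quotas for the groups in
#'   the order above. Defaults to the published cohort structure
#'   (80, 92, 28, 61; n = 261).
#' @param beta_cd_latency added mean reaction latency (s) per unit of
#'   cognitive deficit.
#' @param beta_cd_error logit-scale increase in decision-error probability
#'   per unit of cognitive deficit.
#' @param beta_pnp_noise log-scale increase in pressure-control noise per
#'   unit of neuropathy burden.
#' @param beta_pnp_threshold added sensation threshold (normalized pressure
#'   units) per unit of neuropathy burden.
#' @param covariates per-group covariate parameters
#'   (see `default_covariate_params`).
#' @param max_tries retry cap for rejection-sampling clinical scores
#'   consistent with the group label.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_counts = c(80, 92, 28, 61),
                          beta_cd_latency = 0.45,
                          beta_cd_error = 1.2,
                          beta_pnp_noise = 0.5,
                          beta_pnp_threshold = 0.10,
                          covariates = default_covariate_params(),
                          max_tries = 1000) {
  if (length(group_counts) != 4 || any(group_counts < 0) ||
      any(group_counts != round(group_counts))) {
    abort("`group_counts` must be 4 non-negative integers")
  }
  for (b in c(beta_cd_latency, beta_cd_error, beta_pnp_noise, beta_pnp_threshold)) {
    if (b < 0) abort("effect sizes must be >= 0")
  }
  structure(list(
    group_counts = as.integer(group_counts),
    beta_cd_latency = beta_cd_latency,
    beta_cd_error = beta_cd_error,
    beta_pnp_noise = beta_pnp_noise,
    beta_pnp_threshold = beta_pnp_threshold,
    covariates = covariates,
    max_tries = max_tries
  ), class = "cohort_config")
}

# Rejection-sample integer clinical scores consistent with the target
# labels. Score means are tied to the latent burdens so that, e.g., a more
# neuropathic participant also reports a higher NDS within the +PNP stratum.
draw_clinical_scores <- function(pnp, cd, neuropathy, cognition,
                                 education_years, max_tries = 1000) {
  n <- length(pnp)
  nds <- nss <- moca <- integer(n)
  for (i in seq_len(n)) {
    mu_nds <- if (pnp[i]) 6 + 1.2 * max(0, neuropathy[i]) else 1.5 + 0.8 * neuropathy[i]
    mu_nss <- if (pnp[i]) 6.5 + 1.0 * max(0, neuropathy[i]) else 2.5 + 0.8 * neuropathy[i]
    mu_moca <- if (cd[i]) 23.5 + 1.0 * cognition[i] else 27.5 + 1.0 * max(0, cognition[i])
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      d <- pmin(10L, pmax(0L, as.integer(round(rnorm(1, mu_nds, 1.4)))))
      s <- pmin(10L, pmax(0L, as.integer(round(rnorm(1, mu_nss, 1.6)))))
      m <- pmin(30L, pmax(0L, as.integer(round(rnorm(1, mu_moca, 1.3)))))
      if (diagnose_pnp(d, s) == pnp[i] &&
          diagnose_cd(m, education_years[i]) == cd[i]) {
        nds[i] <- d; nss[i] <- s; moca[i] <- m
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("clinical score generation exhausted its retry cap")
  }
  tibble::tibble(nds = nds, nss = nss, moca_raw = moca)
}

#' Simulate a synthetic diabetes cohort
#'
#' Draws participants group by group: covariates from the per-group
#' moment-matched distributions, latent impairment traits from the
#' configured effect sizes, and integer clinical scores rejection-sampled so
#' that [diagnose_pnp()] and [diagnose_cd()] reproduce the group label
#' exactly. Ages are truncated above 50 years (the study's entry criterion).
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the cohort is byte-identical across runs with
#'   the same seed.
#' @return tibble with one row per participant: identifiers, group labels,
#'   the six individual-risk-profile covariates, education, clinical scores,
#'   and `latent_*` trait columns used by the session simulator.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(c(5, 5, 5, 5)), seed = 1)
#' table(cohort$group)
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  cp <- config$covariates
  groups <- cohort_group_levels()
  pnp_flag <- c(FALSE, TRUE, FALSE, TRUE)
  cd_flag <- c(FALSE, FALSE, TRUE, TRUE)
  out <- vector("list", 4)
  for (g in 1:4) {
    n <- config$group_counts[g]
    if (n == 0) next
    # covariates ---------------------------------------------------------
    rnorm_trunc <- function(n, mean, sd, lower) {
      x <- rnorm(n, mean, sd)
      while (any(bad <- x <= lower)) x[bad] <- rnorm(sum(bad), mean, sd)
      x
    }
    age <- round(rnorm_trunc(n, cp$age$median[g], cp$age$iqr[g] / 1.349, 50))
    weight <- round(rnorm_trunc(n, cp$weight$median[g], cp$weight$iqr[g] / 1.349, 40), 1)
    bmi <- round(rnorm_trunc(n, cp$bmi$median[g], cp$bmi$iqr[g] / 1.349, 15), 1)
    ln <- lognormal_from_median_iqr(cp$duration$median[g], cp$duration$iqr[g])
    duration <- round(rlnorm(n, ln$meanlog, ln$sdlog), 1)
    gender <- ifelse(runif(n) < cp$p_female[g], "female", "male")
    dtype <- ifelse(runif(n) < cp$p_type1[g], 1L, 2L)
    low_edu <- runif(n) < cp$p_low_education
    education <- ifelse(low_edu, sample(8:12, n, replace = TRUE),
                        sample(13:17, n, replace = TRUE))
    # latent traits ------------------------------------------------------
    cognition <- rnorm(n, mean = if (cd_flag[g]) -1 else 0, sd = 0.5)
    neuropathy <- rnorm(n, mean = if (pnp_flag[g]) 1 else 0, sd = 0.5)
    latency_mean <- pmax(0.15, 0.55 - config$beta_cd_latency * cognition)
    error_prob <- plogis(-2.2 - config$beta_cd_error * cognition)
    noise_sd <- 0.025 * exp(config$beta_pnp_noise * pmax(0, neuropathy) +
                              rnorm(n, 0, 0.1))
    threshold <- pmax(0, 0.04 + config$beta_pnp_threshold * neuropathy)
    scores <- draw_clinical_scores(rep(pnp_flag[g], n), rep(cd_flag[g], n),
                                   neuropathy, cognition, education,
                                   config$max_tries)
    out[[g]] <- tibble::tibble(
      group = groups[g],
      pnp_label = pnp_flag[g], cd_label = cd_flag[g],
      gender = gender, age = age, weight = weight, bmi = bmi,
      diabetes_type = dtype, diabetes_duration = duration,
      education_years = as.integer(education),
      nds = scores$nds, nss = scores$nss, moca_raw = scores$moca_raw,
      latent_cognition = cognition,
      latent_neuropathy = neuropathy,
      latent_reaction_latency_mean = latency_mean,
      latent_reaction_latency_sd = 0.08,
      latent_pressure_noise_sd = noise_sd,
      latent_sensation_threshold = threshold,
      latent_decision_error_prob = error_prob,
      latent_fatigue_slope = pmax(0, rnorm(n, 0.010, 0.005))
    )
  }
  cohort <- dplyr::bind_rows(out)
  if (nrow(cohort) == 0) {
    return(tibble::tibble(id = character()))
  }
  cohort <- dplyr::mutate(cohort,
    id = sprintf("P%03d", dplyr::row_number()),
    group = factor(.data$group, levels = groups),
    .before = 1
  )
  stopifnot(all(diagnose_pnp(cohort$nds, cohort$nss) == cohort$pnp_label),
            all(diagnose_cd(cohort$moca_raw, cohort$education_years) == cohort$cd_label))
  cohort
}

irp_columns <- function() {
  c("gender", "age", "weight", "bmi", "diabetes_type", "diabetes_duration")
}
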