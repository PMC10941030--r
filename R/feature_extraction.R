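# Primary-feature formulas. Each is a pure function of (trace, config);
# trace-derived where the signal suffices, otherwise from the simulator's
# task-outcome scalars (aux), exactly as a game engine would log them.
primary_feature_value <- function(trace, base_feature, config) {
  s <- trace$samples
  main <- s[s$sensor_id == s$sensor_id[1], , drop = FALSE]
  switch(base_feature,
    reaction_time = {
      if (identical(trace$outcome, "timeout")) return(NA_real_)
      onset <- config$tasks$stimulus_onset[config$tasks$game == trace$game &
                                             config$tasks$task_index == trace$task_index]
      after <- main$t >= onset
      cross <- which(after & main$value >= config$reaction_threshold)[1]
      if (is.na(cross)) NA_real_ else main$t[cross] - onset
    },
    hold_stability_sd = {
      trace$aux$hold_stability_sd %||% NA_real_
    },
    timeout_flag = as.numeric(identical(trace$outcome, "timeout")),
    catch_success = trace$aux$catch_success %||% NA_real_,
    positional_error = trace$aux$positional_error %||% NA_real_,
    overshoot_count = trace$aux$overshoot_count %||% NA_real_,
    collision_count = trace$aux$collision_count %||% NA_real_,
    points_collected = trace$aux$points_collected %||% NA_real_,
    altitude_tracking_rmse = trace$aux$altitude_tracking_rmse %||% NA_real_,
    correction_latency = trace$aux$correction_latency %||% NA_real_,
    time_to_valid_hold = trace$aux$time_to_valid_hold %||% NA_real_,
    band_exceedance_fraction = trace$aux$band_exceedance_fraction %||% NA_real_,
    attempts_to_success = trace$aux$attempts_to_success %||% NA_real_,
    peak_pressure_error = trace$aux$peak_pressure_error %||% NA_real_,
    jump_success = trace$aux$jump_success %||% NA_real_,
    pressure_rise_time = trace$aux$pressure_rise_time %||% NA_real_,
    abort(sprintf("unknown base feature: %s", base_feature))
  )
}

#' Extract primary features from one task trace
#'
#' Computes each requested base feature by its documented formula (e.g.
#' reaction time is the first crossing of the configured normalized-pressure
#' threshold after stimulus onset; the hold-stability SD is the SD of the
#' pressure during the valid hold window). Features undefined for the trace
#' (e.g. reaction time on a timeout) are `NA`.
#'
#' @param trace a task trace from [simulate_task()].
#' @param base_features character vector of base-feature labels; defaults to
#'   the configured list for the trace's game.
#' @param config a [game_config()].
#' @return named numeric vector.
#' @export
extract_primary <- function(trace, base_features = NULL, config = game_config()) {
  base_features <- base_features %||% config$base_features[[trace$game]]
  vals <- vapply(base_features, primary_feature_value, numeric(1),
                 trace = trace, config = config)
  names(vals) <- base_features
  vals
}

#' Aggregate a primary feature over a task combination
#'
#' Returns the sum, mean and sample (n-1) SD of the non-missing member
#' values. All three are missing when no member value is present; the SD is
#' additionally missing below two values.
#'
#' @param values numeric vector of the primary feature across the TC's
#'   member tasks (may contain `NA`).
#' @return tibble with columns `sum`, `mean`, `sd`.
#' @export
#' @examples
#' aggregate_secondary(c(1, 2, 3))
#' aggregate_secondary(c(3.5, NA))
aggregate_secondary <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) == 0) {
    return(tibble::tibble(sum = NA_real_, mean = NA_real_, sd = NA_real_))
  }
  tibble::tibble(sum = sum(x), mean = mean(x), sd = sd_or_na(x))
}

session_feature_vector <- function(record, config, catalogue, tcs) {
  prim <- numeric(0)
  for (tr in record$traces) {
    v <- extract_primary(tr, config$base_features[[tr$game]], config)
    names(v) <- sprintf("%s_TS%d_%s", tr$game, tr$task_index, names(v))
    prim <- c(prim, v)
  }
  sec <- numeric(0)
  for (i in seq_len(nrow(tcs))) {
    g <- tcs$game[i]
    members <- tcs$member_tasks[[i]]
    for (bf in config$base_features[[g]]) {
      member_names <- sprintf("%s_TS%d_%s", g, members, bf)
      agg <- aggregate_secondary(unname(prim[member_names]))
      nm <- sprintf("%s_%s_%s_%s", g, tcs$tc_id[i], bf, c("sum", "mean", "sd"))
      sec <- c(sec, stats::setNames(c(agg$sum, agg$mean, agg$sd), nm))
    }
  }
  all <- c(prim, sec)
  out <- all[catalogue$name]
  names(out) <- catalogue$name
  out
}

#' Assemble the participants-by-features matrix
#'
#' One row per valid, complete session; columns are the six
#' individual-risk-profile (IRP) covariates followed by the full game
#' feature catalogue in deterministic order. Gender is coded 0/1
#' (male = 1), diabetes type as 1/2.
#'
#' @param sessions list of `game_session` records (from
#'   [simulate_sessions()]).
#' @param cohort cohort tibble; every session's participant must be present.
#' @param config the [game_config()] the sessions were simulated under.
#' @return tibble: `participant_id`, IRP columns, then feature columns.
#' @export
build_feature_matrix <- function(sessions, cohort, config = game_config()) {
  catalogue <- feature_catalogue(config)
  tcs <- enumerate_task_combinations(config)
  keep <- vapply(sessions, function(s) length(validate_session(s, config)) == 0,
                 logical(1))
  kept <- sessions[keep]
  ids <- vapply(kept, function(s) s$participant_id, "")
  if (!all(ids %in% cohort$id)) {
    abort("session participant(s) absent from the cohort table")
  }
  rows <- lapply(kept, session_feature_vector, config = config,
                 catalogue = catalogue, tcs = tcs)
  feat <- if (length(rows) == 0) {
    tibble::as_tibble(matrix(numeric(0), nrow = 0, ncol = nrow(catalogue),
                             dimnames = list(NULL, catalogue$name)))
  } else {
    tibble::as_tibble(do.call(rbind, rows))
  }
  irp <- cohort[match(ids, cohort$id), irp_columns()]
  irp$gender <- as.numeric(irp$gender == "male")
  irp$diabetes_type <- as.numeric(irp$diabetes_type)
  dplyr::bind_cols(tibble::tibble(participant_id = ids), irp, feat)
}

#' Pre-process a feature matrix
#'
#' Drops constant columns and columns missing in more than `max_missing` of
#' rows, then imputes remaining missing values by the column median. The
#' dropped-column manifest is attached as attribute `"dropped"`. IRP columns
#' and `participant_id` are never dropped.
#'
#' @param matrix feature tibble from [build_feature_matrix()].
#' @param max_missing maximum tolerated missing fraction per column.
#' @param drop_constant drop zero-variance columns?
#' @return the processed tibble, with attribute `dropped` (tibble of
#'   `name`, `reason`).
#' @export
preprocess_features <- function(matrix, max_missing = 0.2, drop_constant = TRUE) {
  protected <- c("participant_id", irp_columns())
  dropped <- tibble::tibble(name = character(), reason = character())
  out <- matrix
  for (nm in setdiff(names(matrix), protected)) {
    x <- matrix[[nm]]
    frac_na <- mean(is.na(x))
    if (frac_na > max_missing) {
      dropped <- dplyr::add_row(dropped, name = nm, reason = "missingness")
      out[[nm]] <- NULL
    } else if (drop_constant && length(unique(x[!is.na(x)])) <= 1) {
      dropped <- dplyr::add_row(dropped, name = nm, reason = "constant")
      out[[nm]] <- NULL
    }
  }
  for (nm in setdiff(names(out), "participant_id")) {
    x <- out[[nm]]
    if (anyNA(x)) out[[nm]] <- ifelse(is.na(x), stats::median(x, na.rm = TRUE), x)
  }
  attr(out, "dropped") <- dropped
  out
}
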