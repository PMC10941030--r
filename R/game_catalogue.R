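#' Default insole sensor layout
#'
#' Eight force-sensing resistors per insole, covering the heel, lateral arch,
#' metatarsal heads 1, 3 and 5, hallux and toes. The eighth sensor has no
#' canonical anatomical region and is labelled `aux`; its region label is
#' configurable because insole revisions differ in where they place it.
#'
#' @param aux_region region label for the eighth sensor (default `"aux"`).
#' @return A tibble with columns `foot`, `sensor_id`, `region`.
#' @export
#' @examples
#' default_sensor_layout()
default_sensor_layout <- function(aux_region = "aux") {
  regions <- c("heel", "lateral_arch", "met1", "met3", "met5",
               "hallux", "toes", aux_region)
  tibble::tibble(
    foot = rep(c("left", "right"), each = 8),
    sensor_id = c(paste0("L", 1:8), paste0("R", 1:8)),
    region = rep(regions, times = 2)
  )
}

#' Default per-sensor calibration profile
#'
#' Calibration reduces to a (baseline, maximum) pressure pair per sensor,
#' acquired in practice from rest and maximal-press recordings; game control
#' happens in the normalized 0-1 space between the two.
#'
#' @param layout sensor layout tibble (see [default_sensor_layout()]).
#' @param baseline,maximum rest and voluntary-maximum pressures in mbar.
#' @return A tibble with columns `sensor_id`, `baseline`, `maximum`.
#' @export
default_calibration <- function(layout = default_sensor_layout(),
                                baseline = 300, maximum = 2300) {
  if (!(250 <= baseline && baseline < maximum && maximum <= 7000)) {
    abort("calibration must satisfy 250 <= baseline < maximum <= 7000")
  }
  tibble::tibble(sensor_id = layout$sensor_id,
                 baseline = baseline, maximum = maximum)
}

#' Derive a calibration profile from rest and press recordings
#'
#' @param rest,press data frames with columns `sensor_id`, `value` (mbar);
#'   `rest` recorded with feet relaxed, `press` under maximal voluntary press.
#' @return calibration tibble as in [default_calibration()].
#' @export
derive_calibration <- function(rest, press) {
  b <- dplyr::summarise(dplyr::group_by(rest, .data$sensor_id),
                        baseline = stats::median(.data$value), .groups = "drop")
  m <- dplyr::summarise(dplyr::group_by(press, .data$sensor_id),
                        maximum = stats::quantile(.data$value, 0.95, names = FALSE),
                        .groups = "drop")
  out <- dplyr::inner_join(b, m, by = "sensor_id")
  out$baseline <- pmax(250, out$baseline)
  out$maximum <- pmin(7000, out$maximum)
  if (any(out$baseline >= out$maximum)) {
    abort("derived calibration violates baseline < maximum for some sensor")
  }
  out
}

default_base_features <- function() {
  list(
    AC = c("reaction_time", "catch_success", "positional_error", "overshoot_count"),
    BF = c("collision_count", "points_collected", "altitude_tracking_rmse",
           "correction_latency"),
    CP = c("time_to_valid_hold", "hold_stability_sd", "timeout_flag",
           "band_exceedance_fraction"),
    IJ = c("attempts_to_success", "peak_pressure_error", "jump_success",
           "pressure_rise_time")
  )
}

# Task schedules. Feet alternate left/right for AC, CP and IJ (balloon flying
# is inherently bilateral: altitude is the forefoot pressure differential).
build_task_table <- function(ac_tasks, bf_tasks, cp_tasks, ij_tasks,
                             cp_timeout, cp_hold, layout) {
  met3 <- function(foot) layout$sensor_id[layout$foot == foot & layout$region == "met3"]
  alt_feet <- function(n) rep(c("left", "right"), length.out = n)
  ac <- tibble::tibble(
    game = "AC", task_index = seq_len(ac_tasks),
    controlling_foot = alt_feet(ac_tasks),
    band_low = 0.4, band_high = 0.6, hold_duration = NA_real_,
    timeout = 10, stimulus_onset = 1
  )
  bf <- tibble::tibble(
    game = "BF", task_index = seq_len(bf_tasks),
    controlling_foot = "both",
    band_low = 0.35, band_high = 0.65, hold_duration = NA_real_,
    timeout = 10, stimulus_onset = 1
  )
  # CP alternates green (low) and yellow (high) pressure bands.
  cp <- tibble::tibble(
    game = "CP", task_index = seq_len(cp_tasks),
    controlling_foot = alt_feet(cp_tasks),
    band_low = rep(c(0.2, 0.6), length.out = cp_tasks),
    band_high = rep(c(0.4, 0.8), length.out = cp_tasks),
    hold_duration = cp_hold, timeout = cp_timeout, stimulus_onset = 1
  )
  ij <- tibble::tibble(
    game = "IJ", task_index = seq_len(ij_tasks),
    controlling_foot = alt_feet(ij_tasks),
    band_low = 0.5, band_high = 0.7, hold_duration = NA_real_,
    timeout = 12, stimulus_onset = 1
  )
  tasks <- dplyr::bind_rows(ac, bf, cp, ij)
  tasks$target_sensors <- lapply(seq_len(nrow(tasks)), function(i) {
    foot <- tasks$controlling_foot[i]
    if (foot == "both") c(met3("left"), met3("right")) else met3(foot)
  })
  tasks
}

#' Build a game-session configuration
#'
#' Assembles the full, internally consistent definition of one four-game
#' assessment session: task schedules, target pressure bands, timeouts,
#' sensor layout, calibration, sampling rate and the sensor quantization
#' grid. Defaults follow the deployed assessment: games in the order
#' Apple-Catch (AC), Balloon-Flying (BF), Cross-Pressure (CP), Island-Jump
#' (IJ); 14 AC tasks; 25 s CP task timeout; 200 Hz sampling; 3.4 mbar
#' sensor resolution over 250-7000 mbar; 15 min session budget.
#'
#' @param game_order permutation of `c("AC","BF","CP","IJ")`.
#' @param ac_tasks,bf_tasks,cp_tasks,ij_tasks task counts per game.
#' @param sampling_rate sensor sampling rate in Hz.
#' @param session_time_budget total session budget in seconds.
#' @param quantization_step sensor resolution in mbar.
#' @param pressure_range sensor range `c(min, max)` in mbar.
#' @param cp_timeout CP per-task timeout in seconds.
#' @param cp_hold required in-band hold duration for CP tasks, seconds.
#' @param reaction_threshold normalized pressure level whose first crossing
#'   after stimulus onset defines the reaction time.
#' @param control_tau time constant (s) of the first-order lag with which
#'   simulated players drive pressure toward a target.
#' @param bf_collision_tol normalized altitude-tracking error beyond which a
#'   BF obstacle collision is scored.
#' @param ij_max_attempts retry cap per IJ island before the task is scored
#'   a failure.
#' @param task_gap inter-task transition time in seconds.
#' @param layout sensor layout tibble.
#' @param calibration calibration tibble.
#' @param base_features named list of primary-feature labels per game.
#' @return An object of class `game_config`.
#' @export
#' @examples
#' cfg <- game_config()
#' sum(cfg$tasks$game == "AC")
game_config <- function(game_order = c("AC", "BF", "CP", "IJ"),
                        ac_tasks = 14, bf_tasks = 6, cp_tasks = 8, ij_tasks = 6,
                        sampling_rate = 200,
                        session_time_budget = 900,
                        quantization_step = 3.4,
                        pressure_range = c(250, 7000),
                        cp_timeout = 25,
                        cp_hold = 3,
                        reaction_threshold = 0.2,
                        control_tau = 0.3,
                        bf_collision_tol = 0.15,
                        ij_max_attempts = 5,
                        task_gap = 2,
                        layout = default_sensor_layout(),
                        calibration = default_calibration(layout),
                        base_features = default_base_features()) {
  if (!setequal(game_order, c("AC", "BF", "CP", "IJ")) || length(game_order) != 4) {
    abort("`game_order` must be a permutation of AC, BF, CP, IJ")
  }
  for (fld in c("ac_tasks", "bf_tasks", "cp_tasks", "ij_tasks")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v)) {
      abort(sprintf("invalid configuration: `%s` must be a positive integer", fld))
    }
  }
  if (sampling_rate <= 0) abort("invalid configuration: `sampling_rate` must be > 0")
  if (cp_timeout <= 0) abort("invalid configuration: `cp_timeout` must be > 0")
  if (cp_hold <= 0) abort("invalid configuration: `cp_hold` must be > 0")
  if (session_time_budget < 0) abort("invalid configuration: `session_time_budget` must be >= 0")
  if (!is.numeric(pressure_range) || length(pressure_range) != 2 ||
      pressure_range[1] >= pressure_range[2]) {
    abort("invalid configuration: `pressure_range` must be c(min, max) with min < max")
  }
  for (g in names(base_features)) {
    if (anyDuplicated(base_features[[g]])) {
      abort(sprintf("invalid configuration: duplicate base feature in game %s", g))
    }
    if (length(base_features[[g]]) < 1) {
      abort(sprintf("invalid configuration: game %s has no base features", g))
    }
  }
  n_per_foot <- table(layout$foot)
  if (!all(n_per_foot == 8)) abort("layout must define exactly 8 sensors per foot")
  tasks <- build_task_table(ac_tasks, bf_tasks, cp_tasks, ij_tasks,
                            cp_timeout, cp_hold, layout)
  structure(list(
    game_order = game_order,
    tasks = tasks,
    sampling_rate = sampling_rate,
    session_time_budget = session_time_budget,
    quantization_step = quantization_step,
    pressure_range = pressure_range,
    reaction_threshold = reaction_threshold,
    control_tau = control_tau,
    bf_collision_tol = bf_collision_tol,
    ij_max_attempts = ij_max_attempts,
    task_gap = task_gap,
    layout = layout,
    calibration = calibration,
    base_features = base_features
  ), class = "game_config")
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config>\n")
  cat("  games:", paste(x$game_order, collapse = " -> "), "\n")
  tc <- table(x$tasks$game)[x$game_order]
  cat("  tasks:", paste(sprintf("%s=%d", names(tc), tc), collapse = ", "), "\n")
  cat(sprintf("  sampling %g Hz, budget %g s, grid %g mbar in [%g, %g]\n",
              x$sampling_rate, x$session_time_budget, x$quantization_step,
              x$pressure_range[1], x$pressure_range[2]))
  invisible(x)
}

#' Normalize raw pressure into the calibrated 0-1 control range
#'
#' Affine map `(raw - baseline) / (maximum - baseline)` per sensor, clipped
#' to \[0, 1\]. Monotone non-decreasing in `raw`.
#'
#' @param raw raw pressure values in mbar (vectorized).
#' @param sensor_id sensor identifier(s), recycled against `raw`.
#' @param calibration calibration tibble with `sensor_id`, `baseline`, `maximum`.
#' @return normalized pressures in \[0, 1\].
#' @export
#' @examples
#' cal <- tibble::tibble(sensor_id = "L3", baseline = 300, maximum = 1300)
#' normalize_pressure(800, "L3", cal)
normalize_pressure <- function(raw, sensor_id, calibration) {
  idx <- match(sensor_id, calibration$sensor_id)
  if (anyNA(idx)) {
    abort(sprintf("unknown sensor_id: %s",
                  paste(unique(sensor_id[is.na(idx)]), collapse = ", ")))
  }
  b <- calibration$baseline[idx]
  m <- calibration$maximum[idx]
  pmin(1, pmax(0, (raw - b) / (m - b)))
}

#' Snap raw pressure onto the sensor quantization grid
#'
#' The force-sensing resistors resolve 3.4 mbar steps between 250 mbar and
#' 7 bar; values outside the range clip to it before snapping to the nearest
#' grid point (round-half-to-even). Idempotent.
#'
#' @param raw raw pressure in mbar (vectorized).
#' @param step grid step in mbar.
#' @param range sensor range `c(min, max)` in mbar.
#' @return pressures on the grid `range[1] + step * k`.
#' @export
#' @examples
#' quantize_pressure(c(250, 255, 8000))
quantize_pressure <- function(raw, step = 3.4, range = c(250, 7000)) {
  clipped <- pmin(range[2], pmax(range[1], raw))
  range[1] + step * round((clipped - range[1]) / step)
}

#' Enumerate task combinations (TCs) for a session configuration
#'
#' Tasks with analogous specifications are amalgamated into task
#' combinations: per game, all left-foot-controlled tasks form TCL1, all
#' right-foot tasks TCR1, and all bilateral tasks TCB1. Every task belongs
#' to at least one TC and the output order is deterministic.
#'
#' @param config a [game_config()].
#' @return tibble with columns `game`, `tc_id`, `foot_scope`,
#'   `member_tasks` (list column of task indices).
#' @export
#' @examples
#' enumerate_task_combinations(game_config())
enumerate_task_combinations <- function(config) {
  scopes <- tibble::tibble(
    foot_scope = c("left", "right", "both"),
    tc_id = c("TCL1", "TCR1", "TCB1")
  )
  out <- config$tasks |>
    dplyr::group_by(.data$game, foot_scope = .data$controlling_foot) |>
    dplyr::summarise(member_tasks = list(sort(.data$task_index)), .groups = "drop") |>
    dplyr::inner_join(scopes, by = "foot_scope")
  out <- out[order(match(out$game, config$game_order),
                   match(out$foot_scope, scopes$foot_scope)), ]
  tibble::as_tibble(out[, c("game", "tc_id", "foot_scope", "member_tasks")])
}

#' Enumerate the full feature catalogue
#'
#' One primary descriptor per (task, base feature), plus three secondary
#' descriptors (sum, mean, sd of the primary across the TC's member tasks)
#' per (task combination, base feature). Names are unique and stable:
#' `GAME_TS<k>_<base>` for primaries and `GAME_<TC>_<base>_<agg>` for
#' secondaries.
#'
#' @param config a [game_config()].
#' @return tibble with columns `name`, `kind`, `game`, `source`,
#'   `base_feature`, `aggregation`.
#' @export
#' @examples
#' nrow(feature_catalogue(game_config()))
feature_catalogue <- function(config) {
  bf <- config$base_features
  prim <- config$tasks |>
    dplyr::select("game", "task_index") |>
    dplyr::mutate(base_feature = lapply(.data$game, function(g) bf[[g]])) |>
    tidyr::unnest("base_feature") |>
    dplyr::mutate(
      name = sprintf("%s_TS%d_%s", .data$game, .data$task_index, .data$base_feature),
      kind = "primary",
      source = sprintf("TS%d", .data$task_index),
      aggregation = "none"
    )
  tcs <- enumerate_task_combinations(config)
  sec <- tcs |>
    dplyr::select("game", "tc_id") |>
    dplyr::mutate(base_feature = lapply(.data$game, function(g) bf[[g]])) |>
    tidyr::unnest("base_feature") |>
    tidyr::crossing(aggregation = c("sum", "mean", "sd")) |>
    dplyr::mutate(
      name = sprintf("%s_%s_%s_%s", .data$game, .data$tc_id,
                     .data$base_feature, .data$aggregation),
      kind = "secondary",
      source = .data$tc_id
    )
  out <- dplyr::bind_rows(
    prim[, c("name", "kind", "game", "source", "base_feature", "aggregation")],
    sec[, c("name", "kind", "game", "source", "base_feature", "aggregation")]
  )
  out <- out[order(match(out$game, config$game_order),
                   out$kind == "secondary", out$source, out$base_feature,
                   out$aggregation), ]
  if (anyDuplicated(out$name)) abort("feature catalogue names are not unique")
  tibble::as_tibble(out)
}
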