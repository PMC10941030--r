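# Ornstein-Uhlenbeck-style control noise: slow excursions (correlation time
# tau_n seconds) rather than white noise, so holding a pressure band is
# plausible for an intact controller and hazardous for a noisy one.
ou_noise <- function(n, sd, rate, tau_n = 0.5) {
  if (n <= 0) return(numeric(0))
  if (sd == 0) return(numeric(n))
  if (!is.finite(sd)) return(runif(n)) # degenerate: uncontrolled pressure
  phi <- exp(-1 / (rate * tau_n))
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# First-order lag from `from` toward `to` starting at t0 (times before t0
# stay at `from`).
lag_path <- function(t, t0, from, to, tau) {
  ifelse(t < t0, from, to - (to - from) * exp(-(pmax(0, t - t0)) / tau))
}

task_times <- function(duration, rate) (0:floor(duration * rate + 1e-9)) / rate

# Snap a normalized trace through the physical sensor grid: normalized ->
# mbar via the sensor's calibration -> 3.4 mbar grid -> back to normalized.
quantize_normalized <- function(value, sensor_id, config) {
  cal <- config$calibration
  idx <- match(sensor_id, cal$sensor_id)
  b <- cal$baseline[idx]
  m <- cal$maximum[idx]
  raw <- b + pmin(1, pmax(0, value)) * (m - b)
  q <- quantize_pressure(raw, config$quantization_step, config$pressure_range)
  pmin(1, pmax(0, (q - b) / (m - b)))
}

new_trace <- function(task, outcome, response_time, restarts, t, value, aux) {
  sensor <- task$target_sensors[1]
  samples <- data.frame(t = t, sensor_id = rep(sensor, length(t)), value = value)
  list(game = task$game, task_index = task$task_index,
       controlling_foot = task$controlling_foot,
       outcome = outcome, response_time = response_time,
       restarts = restarts, samples = samples, aux = aux)
}

#' Simulate one game task for one (latent) player
#'
#' Draws a reaction latency from the player's latency distribution (shifted
#' by the fatigue slope times the task position), then drives the target
#' sensor's normalized pressure toward the task's target band through a
#' first-order lag with correlated control noise. Game-specific mechanics:
#' AC scores a catch if the carriage (pressure) sits within half a band
#' width of the target at catch time; BF scores collisions when the
#' bilateral altitude-tracking error exceeds the collision tolerance at
#' obstacle times; CP requires an uninterrupted in-band hold and times out
#' after the configured limit (bands narrower than the player's sensation
#' threshold inflate the drift-out hazard); IJ repeats failed jumps up to
#' the retry cap. Decision errors (wrong initial action) occur with the
#' player's decision-error probability and delay or void the attempt.
#'
#' @param task one row of `config$tasks` (as a list or 1-row tibble).
#' @param traits named list of latent traits (`reaction_latency_mean`,
#'   `reaction_latency_sd`, `pressure_noise_sd`, `sensation_threshold`,
#'   `decision_error_prob`, `fatigue_slope`).
#' @param task_position 1-based position of the task within the session
#'   (drives fatigue drift).
#' @param config a [game_config()].
#' @return a task trace: list with `game`, `task_index`, `outcome`
#'   (`success`/`failure`/`timeout`), `response_time` (NA on timeout),
#'   `restarts`, `samples` (data frame `t`, `sensor_id`, `value`) and
#'   game-specific `aux` scalars.
#' @export
simulate_task <- function(task, traits, task_position = 1, config = game_config()) {
  task <- as.list(task)
  if (is.list(task$target_sensors)) task$target_sensors <- task$target_sensors[[1]]
  rate <- config$sampling_rate
  tau <- config$control_tau
  target <- (task$band_low + task$band_high) / 2
  width <- task$band_high - task$band_low
  latency <- max(0, rnorm(1, traits$reaction_latency_mean +
                            traits$fatigue_slope * (task_position - 1),
                          traits$reaction_latency_sd))
  decision_error <- runif(1) < traits$decision_error_prob
  penalty <- if (decision_error) 1.5 else 0
  response_time <- latency + penalty
  t0 <- task$stimulus_onset + response_time

  switch(task$game,
    AC = simulate_ac(task, traits, config, target, width, t0, response_time,
                     decision_error, rate, tau),
    BF = simulate_bf(task, traits, config, target, width, t0, response_time,
                     decision_error, rate, tau),
    CP = simulate_cp(task, traits, config, target, width, t0, response_time,
                     decision_error, rate, tau),
    IJ = simulate_ij(task, traits, config, target, width, response_time,
                     decision_error, rate, tau),
    abort(sprintf("unknown game: %s", task$game))
  )
}

simulate_ac <- function(task, traits, config, target, width, t0, response_time,
                        decision_error, rate, tau) {
  t_catch <- min(task$timeout, task$stimulus_onset + 4)
  t <- task_times(t_catch, rate)
  value <- lag_path(t, t0, 0, target, tau) +
    ifelse(t >= t0, ou_noise(length(t), traits$pressure_noise_sd, rate), 0)
  value <- pmin(1, pmax(0, value))
  win <- t >= t_catch - 0.25
  positional_error <- abs(mean(value[win]) - target)
  success <- positional_error < width / 2
  up <- value > task$band_high
  overshoots <- sum(diff(up) == 1)
  new_trace(task, if (success) "success" else "failure", response_time, 0L,
            t, value,
            aux = list(catch_success = as.numeric(success),
                       positional_error = positional_error,
                       overshoot_count = overshoots))
}

simulate_bf <- function(task, traits, config, target, width, t0, response_time,
                        decision_error, rate, tau) {
  t <- task_times(task$timeout, rate)
  n <- length(t)
  active <- t >= t0
  # Two forefoot sensors; balloon altitude follows their differential.
  pl <- lag_path(t, t0, 0, target, tau) +
    ifelse(active, ou_noise(n, traits$pressure_noise_sd, rate), 0)
  pr <- lag_path(t, t0, 0, target, tau) +
    ifelse(active, ou_noise(n, traits$pressure_noise_sd, rate), 0)
  err <- pl - pr
  # A decision error sends the balloon the wrong way at the first obstacle.
  obstacles <- task$stimulus_onset + c(2.5, 5, 7.5)
  if (decision_error) {
    bump <- t >= obstacles[1] - 0.5 & t <= obstacles[1] + 0.5
    err[bump] <- err[bump] + 0.25
  }
  obs_idx <- vapply(obstacles, function(ot) which.min(abs(t - ot)), integer(1))
  collisions <- sum(abs(err[obs_idx]) > config$bf_collision_tol |
                      obstacles < t0)
  settled <- t >= t0 + 3 * tau
  rmse <- if (any(settled)) sqrt(mean(err[settled]^2)) else NA_real_
  value <- pmin(1, pmax(0, pl))
  sensors <- task$target_sensors
  samples <- data.frame(
    t = rep(t, 2),
    sensor_id = rep(sensors[1:2], each = n),
    value = c(value, pmin(1, pmax(0, pr)))
  )
  trace <- new_trace(task, if (collisions == 0) "success" else "failure",
                     response_time, 0L, t, value,
                     aux = list(collision_count = collisions,
                                points_collected = length(obstacles) - collisions,
                                altitude_tracking_rmse = rmse,
                                correction_latency = response_time))
  trace$samples <- samples[order(samples$t, samples$sensor_id), ]
  trace
}

simulate_cp <- function(task, traits, config, target, width, t0, response_time,
                        decision_error, rate, tau) {
  hold_n <- round(task$hold_duration * rate)
  # A band narrower than the perceivable pressure difference cannot be held:
  # the unperceived part of the band inflates the drift hazard.
  noise_eff <- traits$pressure_noise_sd +
    0.25 * max(0, traits$sensation_threshold - width / 2)
  t <- task_times(task$timeout, rate)
  value <- lag_path(t, t0, 0, target, tau) +
    ifelse(t >= t0, ou_noise(length(t), noise_eff, rate), 0)
  value <- pmin(1, pmax(0, value))
  in_band <- value >= task$band_low & value <= task$band_high
  r <- rle(in_band)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  valid <- which(r$values & r$lengths >= hold_n + 1)
  if (length(valid) > 0) {
    s <- starts[valid[1]]
    e <- s + hold_n
    t_end <- t[e]
    hold_values <- value[s:e]
    first_entry <- which(in_band)[1]
    exceed <- if (e > first_entry) {
      mean(!in_band[first_entry:e])
    } else 0
    keep <- t <= t_end
    new_trace(task, "success", response_time, 0L, t[keep], value[keep],
              aux = list(time_to_valid_hold = t[s],
                         hold_stability_sd = stats::sd(hold_values),
                         timeout_flag = 0,
                         band_exceedance_fraction = exceed))
  } else {
    new_trace(task, "timeout", NA_real_, 0L, t, value,
              aux = list(time_to_valid_hold = NA_real_,
                         hold_stability_sd = NA_real_,
                         timeout_flag = 1,
                         band_exceedance_fraction = NA_real_))
  }
}

simulate_ij <- function(task, traits, config, target, width, response_time,
                        decision_error, rate, tau) {
  attempt_dur <- 2.2
  peak_sd <- 2 * traits$pressure_noise_sd +
    0.3 * max(0, traits$sensation_threshold - width / 2)
  max_attempts <- config$ij_max_attempts
  t_all <- numeric(0)
  v_all <- numeric(0)
  t_base <- task$stimulus_onset
  attempts <- 0L
  success <- FALSE
  rise_time <- NA_real_
  peak_err <- NA_real_
  while (attempts < max_attempts &&
         t_base + attempt_dur <= task$timeout + 1e-9 && !success) {
    attempts <- attempts + 1L
    wrong_way <- attempts == 1L && decision_error
    peak_err <- if (wrong_way) -target else rnorm(1, 0, peak_sd)
    peak <- max(0.05, target + peak_err)
    ta <- task_times(attempt_dur, rate)[-1]
    onset <- if (attempts == 1L) response_time else 0.2
    va <- lag_path(ta, onset, 0, peak, tau)
    v_all <- c(v_all, pmin(1, pmax(0, va)))
    t_all <- c(t_all, t_base + ta)
    success <- abs(peak - target) <= width / 2
    if (success) {
      cross <- which(va >= task$band_low)[1]
      rise_time <- if (is.na(cross)) NA_real_ else ta[cross] - onset
      peak_err <- abs(peak - target)
    }
    t_base <- t_base + attempt_dur
  }
  peak_err <- abs(peak_err)
  new_trace(task, if (success) "success" else "failure",
            response_time, attempts - 1L, t_all, v_all,
            aux = list(attempts_to_success = if (success) attempts else NA_real_,
                       peak_pressure_error = peak_err,
                       jump_success = as.numeric(success),
                       pressure_rise_time = rise_time))
}

#' Simulate a participant's full four-game session
#'
#' Runs every configured task in game order, passing all samples through the
#' sensor quantization grid, and stops (marking the session incomplete) if
#' the session time budget is exhausted. Reproducible: the result is a pure
#' function of the RNG state, so `set.seed()` before the call (or use
#' [simulate_sessions()], which seeds per participant).
#'
#' @param config a [game_config()].
#' @param participant one cohort row (list or 1-row tibble) with the
#'   `latent_*` trait columns.
#' @return object of class `game_session`: list with `participant_id`,
#'   `traces`, `total_duration`, `complete`.
#' @export
simulate_session <- function(config, participant) {
  participant <- as.list(participant)
  lt <- grepl("^latent_", names(participant))
  if (!any(lt)) abort("participant has no latent trait columns")
  traits <- participant[lt]
  names(traits) <- sub("^latent_", "", names(traits))
  task_order <- config$tasks[order(match(config$tasks$game, config$game_order),
                                   config$tasks$task_index), ]
  traces <- list()
  total <- 0
  complete <- TRUE
  for (i in seq_len(nrow(task_order))) {
    task <- lapply(task_order, `[[`, i)
    task_len <- if (task$game == "AC") min(task$timeout, task$stimulus_onset + 4) else task$timeout
    if (total + config$task_gap >= config$session_time_budget) {
      complete <- FALSE
      break
    }
    tr <- simulate_task(task, traits, task_position = i, config = config)
    tr$samples$value <- quantize_normalized(tr$samples$value,
                                            tr$samples$sensor_id, config)
    traces[[length(traces) + 1]] <- tr
    dur <- if (nrow(tr$samples) > 0) max(tr$samples$t) else 0
    total <- total + dur + config$task_gap
  }
  structure(list(participant_id = participant$id %||% NA_character_,
                 traces = traces, total_duration = total,
                 complete = complete),
            class = "game_session")
}

#' @export
print.game_session <- function(x, ...) {
  cat(sprintf("<game_session> %s: %d task traces, %.1f s, complete=%s\n",
              x$participant_id, length(x$traces), x$total_duration, x$complete))
  invisible(x)
}

#' Simulate sessions for a whole cohort
#'
#' @param cohort cohort tibble from [simulate_cohort()].
#' @param config a [game_config()].
#' @param seed master seed; fanned out deterministically per participant.
#' @return named list of `game_session` objects (names = participant ids).
#' @export
simulate_sessions <- function(cohort, config = game_config(), seed = 1) {
  seeds <- split_seed(seed, nrow(cohort), salt = 17L)
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    set.seed(seeds[i])
    out[[i]] <- simulate_session(config, cohort[i, ])
  }
  names(out) <- cohort$id
  out
}

#' Validate a session record
#'
#' Pure check returning the list of exclusion reasons: incomplete sessions
#' (per missing game), non-monotone sample timestamps, out-of-range
#' normalized pressures, sample times past the task timeout.
#'
#' @param record a `game_session`.
#' @param config the [game_config()] it was simulated under.
#' @return character vector of reasons; `character(0)` means valid.
#' @export
validate_session <- function(record, config = game_config()) {
  reasons <- character(0)
  have <- vapply(record$traces, function(tr) paste(tr$game, tr$task_index), "")
  want <- paste(config$tasks$game, config$tasks$task_index)
  missing_games <- unique(config$tasks$game[!(want %in% have)])
  if (!isTRUE(record$complete) || length(missing_games) > 0) {
    for (g in missing_games) reasons <- c(reasons, paste0("incomplete: ", g))
    if (length(missing_games) == 0) reasons <- c(reasons, "incomplete: session flagged")
  }
  for (tr in record$traces) {
    s <- tr$samples
    for (sid in unique(s$sensor_id)) {
      ts <- s$t[s$sensor_id == sid]
      if (length(ts) > 1 && any(diff(ts) <= 0)) {
        reasons <- c(reasons, sprintf("non-monotone timestamps: %s task %d",
                                      tr$game, tr$task_index))
        break
      }
    }
    if (nrow(s) > 0 && (min(s$value) < 0 || max(s$value) > 1)) {
      reasons <- c(reasons, "pressure out of range")
    }
    tmax <- config$tasks$timeout[config$tasks$game == tr$game &
                                   config$tasks$task_index == tr$task_index]
    if (length(tmax) == 1 && nrow(s) > 0 && max(s$t) > tmax + 1e-9) {
      reasons <- c(reasons, sprintf("trace exceeds timeout: %s task %d",
                                    tr$game, tr$task_index))
    }
  }
  unique(reasons)
}
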