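#' Task configuration for the escape-avoidance experiment
#'
#' Defines the temporal structure of the operant escape/avoidance task at a
#' fixed timestep resolution. Defaults reproduce the standard protocol:
#' 12 sessions of 25 trials, each trial consisting of a danger period
#' (tone, max 72 s) during which a lever press avoids the shock, a shock
#' period (max 20 shocks at 1 per 3.5 s, terminated by an escape press),
#' and a fixed 180-s inter-trial interval (safety signal). Each session
#' begins with 60 s of habituation to the chamber and ends with a block of
#' homecage ("overnight") timesteps with no stimuli and no lever.
#'
#' All durations are expressed in timesteps of `timestep_s` seconds; the
#' constructor enforces consistency between step counts and the task's
#' wall-clock durations (60-s habituation, 72-s danger period, 180-s ITI,
#' and a shock period long enough for `max_shocks` shocks at one per
#' `shock_interval_s` seconds).
#'
#' @param timestep_s Timestep duration in seconds (default 12).
#' @param n_sessions Number of acquisition sessions (default 12).
#' @param trials_per_session Trials per session (default 25).
#' @param habituation_steps Habituation steps at session start (default 5,
#'   i.e. 60 s).
#' @param danger_max_steps Maximum danger-period steps (default 6, i.e. 72 s).
#' @param shock_max_steps Maximum shock-period steps (default 6).
#' @param max_shocks Maximum shocks delivered per trial (default 20).
#' @param iti_steps Inter-trial-interval steps (default 15, i.e. 180 s).
#' @param homecage_steps Homecage ("overnight") steps appended after each
#'   session (default 500).
#' @param shock_interval_s Seconds between successive shocks within the
#'   shock period (default 3.5).
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$danger_max_steps * cfg$timestep_s  # 72 seconds
#' @export
task_config <- function(timestep_s = 12, n_sessions = 12,
                        trials_per_session = 25, habituation_steps = 5,
                        danger_max_steps = 6, shock_max_steps = 6,
                        max_shocks = 20, iti_steps = 15,
                        homecage_steps = 500, shock_interval_s = 3.5) {
  cfg <- list(
    timestep_s = as.numeric(timestep_s),
    n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session),
    habituation_steps = as.integer(habituation_steps),
    danger_max_steps = as.integer(danger_max_steps),
    shock_max_steps = as.integer(shock_max_steps),
    max_shocks = as.integer(max_shocks),
    iti_steps = as.integer(iti_steps),
    homecage_steps = as.integer(homecage_steps),
    shock_interval_s = as.numeric(shock_interval_s)
  )
  if (cfg$timestep_s <= 0) stop("timestep_s must be > 0")
  counts <- c("n_sessions", "trials_per_session", "habituation_steps",
              "danger_max_steps", "shock_max_steps", "max_shocks",
              "iti_steps", "homecage_steps")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop(sprintf("%s must be a count >= 1", nm))
  }
  if (cfg$habituation_steps * cfg$timestep_s != 60)
    stop("habituation_steps x timestep_s must equal 60 s")
  if (cfg$danger_max_steps * cfg$timestep_s != 72)
    stop("danger_max_steps x timestep_s must equal 72 s")
  if (cfg$iti_steps * cfg$timestep_s != 180)
    stop("iti_steps x timestep_s must equal 180 s")
  if (cfg$shock_max_steps !=
      ceiling(cfg$max_shocks * cfg$shock_interval_s / cfg$timestep_s))
    stop("shock_max_steps must equal ceiling(max_shocks * shock_interval_s / timestep_s)")
  structure(cfg, class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Escape-avoidance task configuration\n")
  cat(sprintf("  %d sessions x %d trials, %g-s timesteps\n",
              x$n_sessions, x$trials_per_session, x$timestep_s))
  cat(sprintf("  habituation %d steps | danger <= %d | shock <= %d (max %d shocks) | ITI %d\n",
              x$habituation_steps, x$danger_max_steps, x$shock_max_steps,
              x$max_shocks, x$iti_steps))
  cat(sprintf("  homecage block %d steps/session\n", x$homecage_steps))
  invisible(x)
}

#' Number of shocks falling in a given shock-period timestep
#'
#' Shocks are delivered on a fixed schedule, one every `shock_interval_s`
#' seconds starting at shock-period onset, up to `max_shocks`. This returns
#' how many of those shocks fall within the `step`-th timestep of the shock
#' period (1-based).
#'
#' @param step 1-based timestep index within the shock period.
#' @param config A [task_config()].
#' @return Integer count of shocks delivered during that timestep.
#' @export
shocks_in_step <- function(step, config = task_config()) {
  stopifnot(step >= 1)
  times <- (seq_len(config$max_shocks) - 1) * config$shock_interval_s
  lo <- (step - 1) * config$timestep_s
  hi <- step * config$timestep_s
  sum(times >= lo & times < hi)
}

TRIAL_PHASES <- c("HABITUATION", "DANGER", "SHOCK", "ITI", "HOMECAGE",
                  "SESSION_END")

#' Construct a trial-phase state
#'
#' Tracks where the task currently is within a session: the phase, how many
#' timesteps of that phase have already been emitted, how many shocks have
#' been delivered in the current trial, and the current trial number.
#'
#' @param phase One of `"HABITUATION"`, `"DANGER"`, `"SHOCK"`, `"ITI"`,
#'   `"HOMECAGE"`.
#' @param steps_elapsed_in_phase Timesteps of this phase already emitted.
#' @param shocks_delivered_in_trial Shocks delivered so far in this trial.
#' @param trial Current trial number (1-based; the upcoming trial during
#'   habituation).
#' @return A list of class `trial_phase`.
#' @export
trial_phase <- function(phase = "HABITUATION", steps_elapsed_in_phase = 0L,
                        shocks_delivered_in_trial = 0L, trial = 1L) {
  phase <- match.arg(phase, TRIAL_PHASES[1:5])
  structure(list(phase = phase,
                 steps_elapsed_in_phase = as.integer(steps_elapsed_in_phase),
                 shocks_delivered_in_trial = as.integer(shocks_delivered_in_trial),
                 trial = as.integer(trial)),
            class = "trial_phase")
}

validate_phase_state <- function(state, config) {
  if (!inherits(state, "trial_phase")) stop("phase_state must be a trial_phase")
  if (state$steps_elapsed_in_phase < 0L)
    stop("steps_elapsed_in_phase must be >= 0")
  if (state$shocks_delivered_in_trial > config$max_shocks)
    stop("shocks_delivered_in_trial exceeds max_shocks: inconsistent state")
  max_steps <- switch(state$phase,
    HABITUATION = config$habituation_steps,
    DANGER = config$danger_max_steps,
    SHOCK = config$shock_max_steps,
    ITI = config$iti_steps,
    HOMECAGE = config$homecage_steps)
  if (state$steps_elapsed_in_phase >= max_steps)
    stop(sprintf("steps_elapsed_in_phase (%d) not below the %s cap (%d)",
                 state$steps_elapsed_in_phase, state$phase, max_steps))
  if (state$trial < 1L || state$trial > config$trials_per_session)
    stop("trial out of range for config")
  invisible(TRUE)
}

make_frame <- function(phase, trial, pressed) {
  list(
    danger = as.integer(phase == "DANGER"),
    safety = as.integer(phase == "ITI"),
    shock = as.integer(phase == "SHOCK"),
    chamber = as.integer(phase != "HOMECAGE"),
    homecage = as.integer(phase == "HOMECAGE"),
    press = if (phase == "HOMECAGE") 0L else as.integer(pressed),
    trial = if (phase %in% c("HABITUATION", "HOMECAGE")) 0L else trial
  )
}

#' Advance the task by one timestep
#'
#' Emits the stimulus frame for the current timestep (with the agent's press
#' decision recorded) and returns the next phase state. Phase transitions:
#' a press during the danger period (an avoidance) skips the shock period
#' and starts the ITI; an unanswered danger period runs to its cap and then
#' becomes the shock period; a press during the shock period (an escape)
#' ends the shocks, with the press's own timestep still carrying the shock
#' bit; the shock period otherwise ends when its step cap or the shock
#' count cap is reached; the ITI runs a fixed number of steps and then the
#' next trial's danger period begins (or the homecage block after the last
#' trial). Presses during habituation, the ITI, or the homecage block are
#' recorded (homecage presses are impossible: no lever) but do not alter
#' phase progression.
#'
#' @param phase_state A [trial_phase()] state.
#' @param pressed Logical (or 0/1): did a lever press occur this timestep?
#' @param config A [task_config()].
#' @return A list with elements `state` (the next `trial_phase`; phase
#'   `"SESSION_END"` once the homecage block completes) and `frame` (the
#'   emitted stimulus frame as a named list).
#' @export
advance <- function(phase_state, pressed, config = task_config()) {
  validate_phase_state(phase_state, config)
  pressed <- isTRUE(pressed) || identical(pressed, 1L) || identical(pressed, 1)
  ph <- phase_state$phase
  k <- phase_state$steps_elapsed_in_phase  # steps already emitted
  trial <- phase_state$trial
  shocks <- phase_state$shocks_delivered_in_trial

  frame <- make_frame(ph, trial, pressed)

  nxt <- switch(ph,
    HABITUATION = {
      if (k + 1L >= config$habituation_steps)
        trial_phase("DANGER", 0L, 0L, trial)
      else
        trial_phase("HABITUATION", k + 1L, shocks, trial)
    },
    DANGER = {
      if (pressed)                      # avoidance: skip shock
        trial_phase("ITI", 0L, shocks, trial)
      else if (k + 1L >= config$danger_max_steps)
        trial_phase("SHOCK", 0L, shocks, trial)
      else
        trial_phase("DANGER", k + 1L, shocks, trial)
    },
    SHOCK = {
      shocks <- min(shocks + shocks_in_step(k + 1L, config), config$max_shocks)
      if (pressed ||                    # escape ends the shock period
          k + 1L >= config$shock_max_steps ||
          shocks >= config$max_shocks)
        trial_phase("ITI", 0L, shocks, trial)
      else
        trial_phase("SHOCK", k + 1L, shocks, trial)
    },
    ITI = {
      if (k + 1L >= config$iti_steps) {
        if (trial < config$trials_per_session)
          trial_phase("DANGER", 0L, 0L, trial + 1L)
        else
          trial_phase("HOMECAGE", 0L, shocks, trial)
      } else
        trial_phase("ITI", k + 1L, shocks, trial)
    },
    HOMECAGE = {
      if (k + 1L >= config$homecage_steps) {
        s <- trial_phase("HABITUATION", 0L, 0L, 1L)
        s$phase <- "SESSION_END"
        s
      } else
        trial_phase("HOMECAGE", k + 1L, shocks, trial)
    }
  )
  # record shocks delivered during an emitted SHOCK frame in the next state
  if (ph == "SHOCK") nxt$shocks_delivered_in_trial <- shocks
  list(state = nxt, frame = frame)
}

#' Generate one session's frame sequence under a press policy
#'
#' Drives [advance()] from habituation through all trials and the terminal
#' homecage block, consulting `policy` for a press/no-press decision at
#' every timestep. The emitted frame sequence is fully determined by the
#' policy's decisions.
#'
#' @param config A [task_config()].
#' @param policy A function of the current [trial_phase()] state returning
#'   `TRUE` (press) or `FALSE`.
#' @param session Session label for the emitted frames (default 1).
#' @return A data frame of stimulus frames (columns `timestep`, `session`,
#'   `trial`, `danger`, `safety`, `shock`, `chamber`, `homecage`, `press`),
#'   with an attribute `shock_counts` giving shocks delivered per trial.
#' @examples
#' sk <- session_skeleton(task_config(), function(state) FALSE)
#' nrow(sk)  # 5 + 25 * (6 + 6 + 15) + 500
#' @export
session_skeleton <- function(config = task_config(), policy, session = 1L) {
  stopifnot(is.function(policy))
  n_guess <- config$habituation_steps + config$homecage_steps +
    config$trials_per_session *
      (config$danger_max_steps + config$shock_max_steps + config$iti_steps)
  cols <- c("danger", "safety", "shock", "chamber", "homecage", "press",
            "trial")
  buf <- lapply(setNames(cols, cols), function(.) integer(n_guess))
  shock_counts <- integer(config$trials_per_session)

  state <- trial_phase("HABITUATION", 0L, 0L, 1L)
  n <- 0L
  repeat {
    pressed <- isTRUE(policy(state))
    res <- advance(state, pressed, config)
    n <- n + 1L
    if (n > n_guess) {  # cannot happen: n_guess is the never-press maximum
      for (nm in cols) buf[[nm]] <- c(buf[[nm]], integer(n_guess))
      n_guess <- 2L * n_guess
    }
    f <- res$frame
    for (nm in cols) buf[[nm]][n] <- f[[nm]]
    if (f$shock == 1L)
      shock_counts[f$trial] <- res$state$shocks_delivered_in_trial
    if (res$state$phase == "SESSION_END") break
    state <- res$state
  }
  out <- data.frame(timestep = seq_len(n), session = as.integer(session),
                    trial = buf$trial[seq_len(n)])
  for (nm in c("danger", "safety", "shock", "chamber", "homecage", "press"))
    out[[nm]] <- buf[[nm]][seq_len(n)]
  attr(out, "shock_counts") <- shock_counts
  out
}

#' Generate a full multi-session experiment under a press policy
#'
#' Concatenates [session_skeleton()] over all sessions of `config`, with
#' global timestep numbering and 1-based session labels.
#'
#' @inheritParams session_skeleton
#' @return A data frame of frames spanning all sessions.
#' @export
experiment_skeleton <- function(config = task_config(), policy) {
  sessions <- lapply(seq_len(config$n_sessions), function(s)
    session_skeleton(config, policy, session = s))
  out <- do.call(rbind, sessions)
  out$timestep <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "shock_counts") <- do.call(rbind, lapply(sessions, attr,
                                                     "shock_counts"))
  out
}
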