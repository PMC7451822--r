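#' Score one trial's frames as avoidance, escape, or no press
#'
#' `"A"` if a press occurred during a danger frame (the shock period was
#' skipped), `"E"` if no danger press occurred but a press occurred during
#' a shock frame, `"."` otherwise. A trial containing both a danger press
#' and shock frames violates the task contract (an avoidance skips the
#' shock period) and is an error, not a silent `"A"`.
#'
#' @param trial_frames Data frame of the frames of a single trial (danger,
#'   shock, and ITI frames sharing one session/trial label).
#' @return `"A"`, `"E"`, or `"."`.
#' @export
score_trial <- function(trial_frames) {
  tf <- as.data.frame(trial_frames)
  key <- unique(paste(tf$session, tf$trial))
  if (length(key) != 1L)
    stop("frames from mixed trials passed to score_trial")
  danger_press <- any(tf$danger == 1L & tf$press == 1L)
  has_shock <- any(tf$shock == 1L)
  if (danger_press && has_shock)
    stop("trial has both a danger press and shock frames: scorer contract violated")
  if (danger_press) return("A")
  if (any(tf$shock == 1L & tf$press == 1L)) return("E")
  "."
}

# ITR counts of one trial by ITI minute bin (steps 1-5, 6-10, 11-15).
trial_itr_bins <- function(trial_frames, config) {
  iti <- trial_frames$safety == 1L
  press <- trial_frames$press[iti]
  pos <- seq_along(press)
  steps_per_min <- ceiling(60 / config$timestep_s)
  bin <- pmin(ceiling(pos / steps_per_min), 3L)
  out <- integer(3)
  for (b in 1:3) out[b] <- sum(press[bin == b])
  out
}

#' Score a frame sequence into behavioral summaries
#'
#' The single scoring code path applied to both empirical-format datasets
#' and simulated frames: per-trial outcome codes (`A`/`E`/`.` via
#' [score_trial()]), per-session anticipatory responses (ARs, presses during
#' the habituation period), per-trial inter-trial responses (ITRs, presses
#' during the ITI) broken into three one-minute bins, and per-session
#' avoidance percentages.
#'
#' @param frames A [rat_dataset()] or frame data frame covering whole
#'   sessions.
#' @param config A [task_config()].
#' @return An object of class `behavior_summary`: `outcomes` (sessions x
#'   trials character matrix), `ars` (per-session integer vector), `itrs`
#'   (sessions x trials x 3 integer array), `avoidance_pct` (per-session
#'   numeric vector).
#' @export
score_frames <- function(frames, config = task_config()) {
  fr <- as.data.frame(frames)
  n_ses <- config$n_sessions
  n_tri <- config$trials_per_session
  sessions_present <- sort(unique(fr$session))
  if (!identical(as.integer(sessions_present), seq_len(n_ses)))
    stop("frames must cover sessions 1..n_sessions")
  outcomes <- matrix(".", n_ses, n_tri,
                     dimnames = list(session = NULL, trial = NULL))
  itrs <- array(0L, c(n_ses, n_tri, 3L))
  ars <- integer(n_ses)

  in_trial <- fr$trial > 0L
  grp <- split(which(in_trial),
               list(session = fr$session[in_trial],
                    trial = fr$trial[in_trial]), drop = TRUE)
  for (g in grp) {
    tf <- fr[g, ]
    s <- tf$session[1]
    tr <- tf$trial[1]
    if (tr > n_tri) stop("trial label exceeds trials_per_session")
    outcomes[s, tr] <- score_trial(tf)
    itrs[s, tr, ] <- trial_itr_bins(tf, config)
  }
  hab <- fr$trial == 0L & fr$chamber == 1L
  if (any(hab)) {
    ar_by <- tapply(fr$press[hab], fr$session[hab], sum)
    ars[as.integer(names(ar_by))] <- as.integer(ar_by)
  }
  structure(list(outcomes = outcomes, ars = ars, itrs = itrs,
                 avoidance_pct = 100 * rowSums(outcomes == "A") / n_tri),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("Behavior summary:", nrow(x$outcomes), "sessions x",
      ncol(x$outcomes), "trials\n")
  cat("Avoidance % by session:\n")
  print(round(x$avoidance_pct, 1))
  invisible(x)
}

#' Simulate one generative run through the full experiment
#'
#' A fresh (or supplied) agent is run through all sessions: at every
#' chamber timestep an action is sampled from the softmax policy, the
#' sampled action drives the task's phase transitions (a danger press
#' avoids, a shock press escapes), and the agent is updated by the TD rule;
#' homecage timesteps force the `OTHER` action. Fully reproducible given
#' `seed`.
#'
#' @param params A [model_parameters()] object.
#' @param config A [task_config()].
#' @param seed Integer seed fixing all stochastic choices.
#' @param init_state Optional starting [init_agent()] state (default: fresh
#'   zero-weight agent).
#' @return A list with `frames` (a [rat_dataset()]), `summary` (a
#'   [score_frames()] result), and `final_state`.
#' @export
simulate_run <- function(params, config = task_config(), seed = 1L,
                         init_state = init_agent()) {
  stopifnot(inherits(params, "model_parameters"))
  set.seed(seed)
  sched <- vapply(seq_len(config$shock_max_steps),
                  function(k) as.integer(shocks_in_step(k, config)),
                  integer(1))
  cfg <- c(config$n_sessions, config$trials_per_session,
           config$habituation_steps, config$danger_max_steps,
           config$shock_max_steps, config$max_shocks, config$iti_steps,
           config$homecage_steps)
  res <- simulate_frames_cpp(param_vector(params), as.integer(cfg),
                             as.integer(sched),
                             as.numeric(init_state$v_weights),
                             init_state$m_weights,
                             match(init_state$prev_action, ACTIONS) - 1L)
  frames <- rat_dataset(data.frame(
    timestep = res$timestep, session = res$session, trial = res$trial,
    danger = res$danger, safety = res$safety, shock = res$shock,
    chamber = res$chamber, homecage = res$homecage, press = res$press),
    rat_id = "SIM")
  list(frames = frames,
       summary = score_frames(frames, config),
       final_state = as_agent_state(res))
}

#' Repeated behavioral-recovery simulations of one rat
#'
#' Runs `n_runs` independent simulations (each re-initialized from a fresh
#' agent) under the same parameters, with per-run seeds derived from the
#' master seed by a fixed scheme, and aggregates the mean avoidance
#' percentage per session — the quantity conventionally compared across
#' (simulated) animals.
#'
#' @inheritParams simulate_run
#' @param n_runs Number of independent runs (conventionally 100).
#' @return An object of class `behavior_summary_collection`: `runs` (list
#'   of per-run `behavior_summary`), `mean_avoidance_pct` (per-session),
#'   `se_avoidance_pct`, `n_runs`, `params`.
#' @export
simulate_rat <- function(params, config = task_config(), n_runs = 100L,
                         seed = 1L) {
  stopifnot(n_runs >= 1)
  set.seed(seed)
  run_seeds <- sample.int(2147483646L, n_runs)
  runs <- lapply(seq_len(n_runs), function(i)
    simulate_run(params, config, seed = run_seeds[i])$summary)
  av <- do.call(rbind, lapply(runs, `[[`, "avoidance_pct"))
  structure(list(runs = runs,
                 mean_avoidance_pct = colMeans(av),
                 se_avoidance_pct = apply(av, 2, stats::sd) / sqrt(n_runs),
                 n_runs = n_runs,
                 params = params),
            class = "behavior_summary_collection")
}

#' @export
print.behavior_summary_collection <- function(x, ...) {
  cat("Behavioral-recovery simulation:", x$n_runs, "runs\n")
  cat("Mean avoidance % by session:\n")
  print(round(x$mean_avoidance_pct, 1))
  invisible(x)
}
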