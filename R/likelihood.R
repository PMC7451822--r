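#' Construct a rat dataset from a frame table
#'
#' A rat dataset is an ordered sequence of 12-s stimulus frames spanning all
#' sessions, with interleaved homecage blocks, plus a rat identifier.
#' Validation enforces the per-frame stimulus invariants (exactly one of
#' chamber/homecage active; at most one of danger/safety/shock; homecage
#' frames carry no stimuli and no press; shock implies chamber) and
#' nondecreasing session labels.
#'
#' @param frames Data frame with columns `session`, `trial`, `danger`,
#'   `safety`, `shock`, `chamber`, `homecage`, `press` (and optionally
#'   `timestep`, regenerated if absent).
#' @param rat_id Rat identifier, e.g. `"S09"`.
#' @return A data frame of class `rat_dataset` with a `rat_id` attribute.
#' @export
rat_dataset <- function(frames, rat_id = "RAT") {
  frames <- as.data.frame(frames)
  need <- c("session", "trial", "danger", "safety", "shock", "chamber",
            "homecage", "press")
  missing_cols <- setdiff(need, names(frames))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"timestep" %in% names(frames)) frames$timestep <- seq_len(nrow(frames))
  frames <- frames[, c("timestep", need)]
  validate_frames(frames)
  rownames(frames) <- NULL
  structure(frames, class = c("rat_dataset", "data.frame"), rat_id = rat_id)
}

#' @rdname rat_dataset
#' @param x A `rat_dataset`.
#' @export
rat_id <- function(x) attr(x, "rat_id")

validate_frames <- function(frames) {
  bits <- c("danger", "safety", "shock", "chamber", "homecage", "press")
  for (nm in bits) {
    bad <- which(!(frames[[nm]] %in% c(0L, 1L)))
    if (length(bad))
      stop(sprintf("non-binary '%s' value at row %d", nm, bad[1]))
  }
  ctx <- frames$chamber + frames$homecage
  bad <- which(ctx != 1L)
  if (length(bad))
    stop(sprintf("row %d: exactly one of chamber/homecage must be 1", bad[1]))
  bad <- which(frames$danger + frames$safety + frames$shock > 1L)
  if (length(bad))
    stop(sprintf("row %d: danger, safety and shock are mutually exclusive",
                 bad[1]))
  hm <- frames$homecage == 1L
  bad <- which(hm & (frames$danger | frames$safety | frames$shock |
                       frames$press))
  if (length(bad))
    stop(sprintf("row %d: homecage frames must carry no stimuli and no press",
                 bad[1]))
  bad <- which(frames$shock == 1L & frames$chamber != 1L)
  if (length(bad))
    stop(sprintf("row %d: shock requires chamber", bad[1]))
  if (is.unsorted(frames$session))
    stop("session labels must be nondecreasing")
  invisible(TRUE)
}

frames_to_matrices <- function(data) {
  frames <- as.data.frame(data)
  stim <- cbind(danger = as.integer(frames$danger),
                safety = as.integer(frames$safety),
                shock = as.integer(frames$shock),
                chamber = as.integer(frames$chamber),
                homecage = as.integer(frames$homecage))
  list(stim = stim, press = as.integer(frames$press))
}

#' Negative log-likelihood of observed behavior under the model
#'
#' Replays the dataset once through the actor-critic learner. At every
#' chamber frame the probability of the observed action (press or other)
#' under the current softmax policy contributes `-log p` to the total; the
#' agent is then updated with the observed action and the frame's
#' reinforcement. Homecage frames drive updates too (forced action `OTHER`,
#' zero reinforcement — the overnight extinction block) but contribute
#' nothing to the likelihood unless `include_homecage_ll = TRUE`, since no
#' behavior is recorded in the homecage. The value of the state following
#' the final frame is taken as 0.
#'
#' @param data A [rat_dataset()] (or plain frame data frame).
#' @param params A [model_parameters()] object.
#' @param config A [task_config()] (unused by the likelihood itself; kept
#'   for interface symmetry).
#' @param include_homecage_ll Include homecage frames in the likelihood sum
#'   (default `FALSE`).
#' @param engine `"cpp"` (fast, default) or `"R"` (reference implementation
#'   built from the exported agent primitives).
#' @return A list with `neg_lle` (total, `>= 0`), `final_state` (the
#'   [init_agent()]-shaped end-of-data state), and `n_obs` (frames counted
#'   in the likelihood).
#' @examples
#' cfg <- task_config(n_sessions = 1, trials_per_session = 2,
#'                    homecage_steps = 10)
#' d <- rat_dataset(experiment_skeleton(cfg, function(s) FALSE))
#' p <- model_parameters(0.1, 0.1, 0, -1, persev = 0, gamma = 0.9)
#' res <- neg_log_likelihood(d, p, cfg)
#' all.equal(res$neg_lle, res$n_obs * log(2))  # uniform policy
#' @export
neg_log_likelihood <- function(data, params, config = task_config(),
                               include_homecage_ll = FALSE,
                               engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "model_parameters"))
  if (NROW(data) == 0)
    return(list(neg_lle = 0, final_state = init_agent(), n_obs = 0L))
  mats <- frames_to_matrices(data)
  if (engine == "cpp") {
    res <- nll_replay_cpp(mats$stim, mats$press, param_vector(params),
                          include_homecage_ll)
    return(list(neg_lle = res$neg_lle,
                final_state = as_agent_state(res),
                n_obs = as.integer(res$n_obs)))
  }
  nll_replay_r(mats$stim, mats$press, params, include_homecage_ll)
}

as_agent_state <- function(res) {
  a <- init_agent()
  a$v_weights[] <- res$v_weights
  a$m_weights[] <- res$m_weights
  a$prev_action <- ACTIONS[res$prev_action + 1L]
  a
}

# Pure-R reference replay, built from the exported agent primitives.
nll_replay_r <- function(stim, press, params, include_homecage_ll) {
  agent <- init_agent()
  nll <- 0
  n_obs <- 0L
  T_ <- nrow(stim)
  frame_at <- function(t) list(danger = stim[t, 1], safety = stim[t, 2],
                               shock = stim[t, 3], chamber = stim[t, 4],
                               homecage = stim[t, 5])
  for (t in seq_len(T_)) {
    frame <- frame_at(t)
    home <- frame$homecage == 1L
    if (home) {
      action <- "OTHER"
      if (include_homecage_ll) {
        p <- action_probabilities(agent, frame, params)
        nll <- nll - log(p[["OTHER"]])
        n_obs <- n_obs + 1L
      }
    } else {
      p <- action_probabilities(agent, frame, params)
      action <- if (press[t] == 1L) "PRESS" else "OTHER"
      nll <- nll - log(p[[action]])
      n_obs <- n_obs + 1L
    }
    pressed <- action == "PRESS"
    r <- reinforcement(frame, pressed, params)
    v_now <- state_value(agent, frame)
    v_next <- if (t < T_) state_value(agent, frame_at(t + 1)) else 0
    delta <- td_error(r, v_now, v_next, params)
    agent <- update_agent(agent, frame, action, delta, params)
  }
  list(neg_lle = nll, final_state = agent, n_obs = n_obs)
}

#' Grid specification for exhaustive maximum-likelihood search
#'
#' Each free parameter gets a `c(min, max, step)` range; the grid is the
#' Cartesian product of the per-parameter value sets `min, min + step, ...`
#' up to `max` (inclusive, subject to step arithmetic; values are generated
#' by index as `min + k * step` to avoid accumulation error). `r_press` is
#' held constant, as in the winning model variant where the press cost is
#' not fitted.
#'
#' The default ranges give a coarse, tractable grid of 15000 points:
#' `alpha`, `eps_actor` over 0.05–0.25 (step 0.05), `beta_exploit` 1–9
#' (step 2), `r_shock` -3 to -0.5 (step 0.5), `persev` 0–1 (step 0.25),
#' `gamma` 0.5–0.95 (step 0.15).
#'
#' @param alpha,eps_actor,beta_exploit,r_shock,persev,gamma Numeric
#'   `c(min, max, step)` vectors.
#' @param r_press Constant press cost (not searched).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(alpha = c(0.05, 0.25, 0.05),
                      eps_actor = c(0.05, 0.25, 0.05),
                      beta_exploit = c(1, 9, 2),
                      r_shock = c(-3, -0.5, 0.5),
                      persev = c(0, 1, 0.25),
                      gamma = c(0.5, 0.95, 0.15),
                      r_press = -0.05) {
  ranges <- list(alpha = alpha, eps_actor = eps_actor,
                 beta_exploit = beta_exploit, r_shock = r_shock,
                 persev = persev, gamma = gamma)
  for (nm in names(ranges)) {
    r <- as.numeric(ranges[[nm]])
    if (length(r) != 3 || any(!is.finite(r)))
      stop(sprintf("%s must be a finite c(min, max, step)", nm))
    if (r[1] > r[2]) stop(sprintf("%s: min must be <= max", nm))
    if (r[3] <= 0) stop(sprintf("%s: step must be > 0", nm))
    ranges[[nm]] <- r
  }
  structure(c(ranges, list(r_press = as.numeric(r_press))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("Parameter search grid (", grid_size(x), " points):\n", sep = "")
  for (nm in FREE_PARAMS) {
    r <- x[[nm]]
    cat(sprintf("  %-12s [%g, %g] step %g (%d values)\n", nm, r[1], r[2],
                r[3], length(grid_values(r))))
  }
  cat(sprintf("  %-12s %g (fixed)\n", "r_press", x$r_press))
  invisible(x)
}

# Values of one parameter range, generated by index to avoid accumulation
# error, rounded to 12 decimals so that written values round-trip through
# plain decimal CSV.
grid_values <- function(range) {
  n <- floor((range[2] - range[1]) / range[3] + 1e-9) + 1
  round(range[1] + (seq_len(n) - 1) * range[3], 12)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
grid_size <- function(grid) {
  prod(vapply(FREE_PARAMS, function(nm) length(grid_values(grid[[nm]])),
              numeric(1)))
}

#' Enumerate all parameter combinations of a grid
#'
#' Lexicographic enumeration in the fixed parameter order `alpha`,
#' `eps_actor`, `beta_exploit`, `r_shock`, `persev`, `gamma` (`alpha`
#' varies slowest). The constant `r_press` is carried along in every row.
#'
#' @param grid A [grid_spec()].
#' @return A data frame with one row per grid point and the seven parameter
#'   columns in canonical order.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  vals <- lapply(setNames(FREE_PARAMS, FREE_PARAMS),
                 function(nm) grid_values(grid[[nm]]))
  g <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]  # alpha slowest, gamma fastest
  g$r_press <- grid$r_press
  g <- g[, PARAM_ORDER]
  rownames(g) <- NULL
  g
}

#' Fit model parameters to a rat dataset by exhaustive grid search
#'
#' Evaluates [neg_log_likelihood()] at every point of the grid and returns
#' the minimizing parameter combination (ties broken by enumeration order,
#' first minimum wins), its negLLE, and the agent's final V- and M-weights
#' from replaying the data at the optimum.
#'
#' @inheritParams neg_log_likelihood
#' @param grid A [grid_spec()].
#' @return An object of class `fit_result`: `rat_id`, `best_params`,
#'   `neg_lle`, `final_state`, `grid`, `homecage_steps`, `n_grid`.
#' @export
fit_grid <- function(data, grid = grid_spec(), config = task_config(),
                     include_homecage_ll = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  pts <- enumerate_grid(grid)
  mats <- frames_to_matrices(data)
  nlls <- grid_nll_cpp(mats$stim, mats$press, as.matrix(pts),
                       include_homecage_ll)
  best <- which.min(nlls)  # first minimum in enumeration order
  bp <- do.call(model_parameters, as.list(pts[best, ]))
  replay <- neg_log_likelihood(data, bp, config,
                               include_homecage_ll = include_homecage_ll)
  structure(list(rat_id = if (is.null(rat_id(data))) "RAT" else rat_id(data),
                 best_params = bp,
                 neg_lle = nlls[best],
                 final_state = replay$final_state,
                 grid = grid,
                 homecage_steps = config$homecage_steps,
                 n_grid = nrow(pts)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Grid-search fit for %s (%d grid points)\n", x$rat_id,
              x$n_grid))
  cat(sprintf("  negLLE = %.4f\n", x$neg_lle))
  print(unlist(x$best_params))
  invisible(x)
}

#' Fit a collection of rat datasets
#'
#' Applies [fit_grid()] to each dataset with a shared grid and
#' configuration.
#'
#' @param datasets A list of [rat_dataset()] objects (named or carrying
#'   `rat_id` attributes).
#' @inheritParams fit_grid
#' @param verbose Print a line per rat.
#' @return A list of `fit_result` objects.
#' @export
fit_rats <- function(datasets, grid = grid_spec(), config = task_config(),
                     include_homecage_ll = FALSE, verbose = FALSE) {
  lapply(datasets, function(d) {
    fr <- fit_grid(d, grid, config, include_homecage_ll)
    if (verbose)
      message(sprintf("fitted %s: negLLE = %.3f", fr$rat_id, fr$neg_lle))
    fr
  })
}
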