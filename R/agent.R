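#' Model parameters for the actor-critic avoidance learner
#'
#' The seven parameters of the actor-critic model: the critic learning rate
#' `alpha`, the actor learning rate `eps_actor`, the exploitation/exploration
#' parameter `beta_exploit` (higher values exploit learned propensities more
#' deterministically), the subjective reinforcement values of shock
#' (`r_shock`, non-positive; more negative = more aversive) and of a lever
#' press (`r_press`, non-positive effort cost, held constant during fitting),
#' the perseveration bonus `persev` (tendency to repeat the previous response
#' regardless of outcome), and the discount factor `gamma` (how strongly
#' future states weigh in present evaluations).
#'
#' @param alpha Critic learning rate in `[0, 1]`.
#' @param eps_actor Actor learning rate in `[0, 1]`.
#' @param beta_exploit Exploitation/exploration parameter, `>= 0`.
#' @param r_shock Reinforcement value of a shock timestep, `<= 0`.
#' @param r_press Reinforcement (effort cost) of a lever press, `<= 0`.
#'   Held constant (not fitted).
#' @param persev Perseveration bonus added to the previous action's
#'   propensity; any real number.
#' @param gamma Discount factor in `[0, 1]`.
#' @return An object of class `model_parameters` (a named list).
#' @examples
#' model_parameters(alpha = 0.15, eps_actor = 0.15, beta_exploit = 5,
#'                  r_shock = -1.5, persev = 0.25, gamma = 0.8)
#' @export
model_parameters <- function(alpha, eps_actor, beta_exploit, r_shock,
                             r_press = -0.05, persev = 0, gamma = 0.9) {
  p <- list(alpha = as.numeric(alpha), eps_actor = as.numeric(eps_actor),
            beta_exploit = as.numeric(beta_exploit),
            r_shock = as.numeric(r_shock), r_press = as.numeric(r_press),
            persev = as.numeric(persev), gamma = as.numeric(gamma))
  if (any(!vapply(p, is.finite, logical(1)))) stop("parameters must be finite")
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must be in [0, 1]")
  if (p$eps_actor < 0 || p$eps_actor > 1) stop("eps_actor must be in [0, 1]")
  if (p$beta_exploit < 0) stop("beta_exploit must be >= 0")
  if (p$r_shock > 0) stop("r_shock must be <= 0")
  if (p$r_press > 0) stop("r_press must be <= 0")
  if (p$gamma < 0 || p$gamma > 1) stop("gamma must be in [0, 1]")
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Actor-critic model parameters:\n")
  print(unlist(x))
  invisible(x)
}

# Parameters as a numeric vector in the canonical order.
param_vector <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  unlist(params)[PARAM_ORDER]
}

#' Initialize an agent state
#'
#' All five state-value weights (V-values) and all ten action-propensity
#' weights (M-values, one per action x stimulus) start at zero; the
#' remembered previous action starts as `OTHER`. The previous action is not
#' reset at session boundaries (the homecage block intervenes).
#'
#' @return An object of class `agent_state` with elements `v_weights`
#'   (length-5 named numeric), `m_weights` (2 x 5 named matrix, rows
#'   `OTHER`/`PRESS`), and `prev_action`.
#' @export
init_agent <- function() {
  structure(list(
    v_weights = setNames(numeric(5), STIMULI),
    m_weights = matrix(0, nrow = 2, ncol = 5,
                       dimnames = list(ACTIONS, STIMULI)),
    prev_action = "OTHER"
  ), class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat("Agent state (prev action:", x$prev_action, ")\n")
  cat("V-values:\n"); print(x$v_weights)
  cat("M-values:\n"); print(x$m_weights)
  invisible(x)
}

# Extract the 5-element binary stimulus vector from a frame (a list or a
# one-row data frame with danger/safety/shock/chamber/homecage columns).
# The press bit is not part of the stimulus representation.
frame_stimulus <- function(frame) {
  x <- c(frame$danger, frame$safety, frame$shock, frame$chamber,
         frame$homecage)
  x <- as.numeric(x)
  if (length(x) != 5 || any(is.na(x)) || any(!x %in% c(0, 1)))
    stop("frame must carry five binary stimulus bits")
  if (x[4] + x[5] != 1) stop("exactly one of chamber/homecage must be active")
  setNames(x, STIMULI)
}

#' State value of a stimulus frame
#'
#' The critic's evaluation: the sum of the V-weights of the active stimuli,
#' linear in the binary stimulus vector (overlapping stimuli, e.g.
#' danger + chamber, add).
#'
#' @param agent An [init_agent()] state.
#' @param frame A stimulus frame (named list or one-row data frame).
#' @return The scalar state value.
#' @export
state_value <- function(agent, frame) {
  sum(agent$v_weights * frame_stimulus(frame))
}

#' Action probabilities under the softmax policy
#'
#' Each action's propensity is the sum of its M-weights over the active
#' stimuli, plus the perseveration bonus `persev` if the action equals the
#' previously taken action. Probabilities are a softmax of the propensities
#' scaled by `beta_exploit`, computed with overflow-safe normalization.
#' With `beta_exploit = 0` the policy is uniform regardless of weights.
#'
#' @inheritParams state_value
#' @param params A [model_parameters()] object.
#' @return Named numeric vector `c(OTHER = p_other, PRESS = p_press)`,
#'   summing to 1.
#' @export
action_probabilities <- function(agent, frame, params) {
  x <- frame_stimulus(frame)
  prop <- as.numeric(agent$m_weights %*% x)
  prop[match(agent$prev_action, ACTIONS)] <-
    prop[match(agent$prev_action, ACTIONS)] + params$persev
  if (any(!is.finite(prop))) stop("non-finite action propensities")
  z <- params$beta_exploit * prop
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  setNames(p, ACTIONS)
}

#' Reinforcement received on a timestep
#'
#' `r_shock` is delivered once per timestep whose shock bit is set (the
#' data are binary per timestep, not per individual shock pulse), and the
#' press cost `r_press` once if a press occurred.
#'
#' @param frame A stimulus frame.
#' @param pressed Logical/0-1: did a press occur this timestep?
#' @param params A [model_parameters()] object.
#' @return The scalar reinforcement.
#' @export
reinforcement <- function(frame, pressed, params) {
  pressed <- isTRUE(pressed) || identical(pressed, 1L) || identical(pressed, 1)
  params$r_shock * as.numeric(frame$shock) + params$r_press * as.numeric(pressed)
}

#' Temporal-difference error
#'
#' `delta = r + gamma * v_next - v_now`: the reinforcement plus the
#' discounted value of the next state, minus the value of the current one.
#' Drives both critic and actor updates.
#'
#' @param r Reinforcement on the current timestep.
#' @param v_now Value of the current state.
#' @param v_next Value of the next state (0 at the end of the experiment).
#' @param params A [model_parameters()] object.
#' @return The scalar TD error.
#' @export
td_error <- function(r, v_now, v_next, params) {
  r + params$gamma * v_next - v_now
}

#' Apply one TD update to the agent
#'
#' The critic's V-weights of all active stimuli move by `alpha * delta`;
#' the actor's M-weights of the *chosen* action's active stimuli move by
#' `eps_actor * delta`; weights of inactive stimuli and of the unchosen
#' action are untouched. The chosen action becomes the remembered previous
#' action.
#'
#' @inheritParams state_value
#' @param action `"OTHER"` or `"PRESS"`.
#' @param delta The TD error.
#' @param params A [model_parameters()] object.
#' @return The updated `agent_state`.
#' @export
update_agent <- function(agent, frame, action, delta, params) {
  action <- match.arg(action, ACTIONS)
  x <- frame_stimulus(frame)
  agent$v_weights <- agent$v_weights + params$alpha * delta * x
  agent$m_weights[action, ] <- agent$m_weights[action, ] +
    params$eps_actor * delta * x
  agent$prev_action <- action
  agent
}
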