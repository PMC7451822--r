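# Shared fixtures: a down-scaled task configuration (fewer sessions/trials
# and a short homecage block; the within-session timing structure is fixed
# by the task) and simple press policies.

small_config <- function(n_sessions = 2, trials_per_session = 3,
                         homecage_steps = 20) {
  task_config(n_sessions = n_sessions,
              trials_per_session = trials_per_session,
              homecage_steps = homecage_steps)
}

never_press <- function(state) FALSE
always_press <- function(state) TRUE

random_policy <- function(p = 0.3) function(state) stats::runif(1) < p

# A policy that replays a prerecorded press sequence one decision at a time.
scripted_policy <- function(presses) {
  i <- 0L
  function(state) {
    i <<- i + 1L
    presses[i] == 1L
  }
}

# Mid-range parameters used across tests.
mid_params <- function() {
  model_parameters(alpha = 0.15, eps_actor = 0.15, beta_exploit = 4,
                   r_shock = -1.5, r_press = -0.05, persev = 0.25,
                   gamma = 0.8)
}

# A one-row frame helper.
frame1 <- function(danger = 0, safety = 0, shock = 0, chamber = 1,
                   homecage = 0, press = 0) {
  list(danger = danger, safety = safety, shock = shock, chamber = chamber,
       homecage = homecage, press = press)
}

# Tiny grid: each free parameter restricted to n values around a center.
tiny_grid <- function(n = 1) {
  if (n == 1)
    grid_spec(alpha = c(0.1, 0.1, 0.05), eps_actor = c(0.1, 0.1, 0.05),
              beta_exploit = c(3, 3, 1), r_shock = c(-1.5, -1.5, 0.5),
              persev = c(0.25, 0.25, 0.25), gamma = c(0.8, 0.8, 0.15))
  else
    grid_spec(alpha = c(0.05, 0.05 * n, 0.05),
              eps_actor = c(0.05, 0.05 * n, 0.05),
              beta_exploit = c(1, 2 * n - 1, 2),
              r_shock = c(-0.5 * n, -0.5, 0.5),
              persev = c(0, 0.25 * (n - 1), 0.25),
              gamma = c(0.5, 0.5 + 0.15 * (n - 1), 0.15))
}
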