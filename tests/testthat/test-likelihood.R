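test_that("a uniform policy gives negLLE = T * ln 2 exactly", {
  cfg <- small_config()
  d <- rat_dataset(experiment_skeleton(cfg, random_policy(0.4)))
  p <- model_parameters(0.2, 0.2, 0, -2, persev = 0.7, gamma = 0.9)
  for (eng in c("cpp", "R")) {
    res <- neg_log_likelihood(d, p, cfg, engine = eng)
    T_chamber <- sum(d$chamber)
    expect_equal(res$n_obs, T_chamber)
    expect_equal(res$neg_lle, T_chamber * log(2))
  }
})

test_that("an empty dataset has zero negLLE and a fresh final state", {
  d <- data.frame(session = integer(), trial = integer(), danger = integer(),
                  safety = integer(), shock = integer(), chamber = integer(),
                  homecage = integer(), press = integer())
  res <- neg_log_likelihood(d, mid_params())
  expect_equal(res$neg_lle, 0)
  expect_equal(res$final_state, init_agent())
})

test_that("a frozen learner's negLLE equals the hand-computed softmax sum", {
  # Three chamber frames; alpha = eps_actor = 0 keeps all weights at zero,
  # so only the perseveration term moves the propensities.
  frames <- data.frame(session = 1L, trial = c(1L, 1L, 1L),
                       danger = c(1L, 0L, 0L), safety = c(0L, 1L, 1L),
                       shock = 0L, chamber = 1L, homecage = 0L,
                       press = c(1L, 0L, 1L))
  beta <- 2; pers <- 0.5
  p <- model_parameters(0, 0, beta, -1, persev = pers, gamma = 0.9)
  # step 1: prev OTHER, press observed: p(PRESS) = 1/(1+exp(beta*pers))
  # step 2: prev PRESS, other observed: p(OTHER) = 1/(1+exp(beta*pers))
  # step 3: prev OTHER, press observed: p(PRESS) = 1/(1+exp(beta*pers))
  expected <- 3 * log(1 + exp(beta * pers))
  for (eng in c("cpp", "R"))
    expect_equal(neg_log_likelihood(rat_dataset(frames), p,
                                    engine = eng)$neg_lle,
                 expected, tolerance = 1e-12)
})

test_that("the C++ engine agrees with the R reference implementation", {
  cfg <- small_config()
  set.seed(31)
  for (i in 1:4) {
    p_gen <- model_parameters(runif(1, 0.05, 0.3), runif(1, 0.05, 0.3),
                              runif(1, 0, 8), -runif(1, 0.2, 3),
                              persev = runif(1, -0.5, 1),
                              gamma = runif(1, 0.3, 1))
    d <- generate_synthetic_rat(p_gen, cfg, seed = 100 + i)
    p_eval <- model_parameters(runif(1, 0.05, 0.3), runif(1, 0.05, 0.3),
                               runif(1, 0, 8), -runif(1, 0.2, 3),
                               persev = runif(1, -0.5, 1),
                               gamma = runif(1, 0.3, 1))
    for (ihl in c(FALSE, TRUE)) {
      a <- neg_log_likelihood(d, p_eval, cfg, include_homecage_ll = ihl,
                              engine = "cpp")
      b <- neg_log_likelihood(d, p_eval, cfg, include_homecage_ll = ihl,
                              engine = "R")
      expect_equal(a$neg_lle, b$neg_lle, tolerance = 1e-10)
      expect_equal(a$n_obs, b$n_obs)
      expect_equal(a$final_state$v_weights, b$final_state$v_weights,
                   tolerance = 1e-10)
      expect_equal(a$final_state$m_weights, b$final_state$m_weights,
                   tolerance = 1e-10)
      expect_equal(a$final_state$prev_action, b$final_state$prev_action)
    }
  }
})

test_that("negLLE is nonnegative, monotone in length, and deterministic", {
  cfg <- small_config()
  d <- generate_synthetic_rat(mid_params(), cfg, seed = 9)
  p <- model_parameters(0.1, 0.2, 3, -1, persev = 0.5, gamma = 0.7)
  full <- neg_log_likelihood(d, p, cfg)
  expect_gte(full$neg_lle, 0)
  for (cut in c(10L, nrow(d) %/% 2L, nrow(d) - 1L)) {
    pre <- neg_log_likelihood(rat_dataset(as.data.frame(d)[seq_len(cut), ]),
                              p, cfg)
    expect_lte(pre$neg_lle, full$neg_lle)
  }
  again <- neg_log_likelihood(d, p, cfg)
  expect_identical(full$neg_lle, again$neg_lle)
})

test_that("homecage frames update the agent but not the likelihood", {
  cfg <- small_config()
  d <- generate_synthetic_rat(mid_params(), cfg, seed = 12)
  p <- mid_params()
  excl <- neg_log_likelihood(d, p, cfg)
  incl <- neg_log_likelihood(d, p, cfg, include_homecage_ll = TRUE)
  expect_equal(excl$n_obs, sum(d$chamber))
  expect_equal(incl$n_obs, nrow(d))
  expect_gte(incl$neg_lle, excl$neg_lle)
  # the final weights do not depend on the likelihood bookkeeping
  expect_equal(excl$final_state, incl$final_state)
})

test_that("grid enumeration counts and ordering follow the spec of the grid", {
  g1 <- tiny_grid(1)
  expect_equal(grid_size(g1), 1)
  expect_equal(nrow(enumerate_grid(g1)), 1)

  g2 <- grid_spec(alpha = c(0.1, 0.2, 0.1), eps_actor = c(0.1, 0.1, 1),
                  beta_exploit = c(3, 3, 1), r_shock = c(-1, -1, 1),
                  persev = c(0, 0, 1), gamma = c(0.5, 0.5, 0.15))
  e2 <- enumerate_grid(g2)
  expect_equal(nrow(e2), 2)
  expect_equal(e2$alpha, c(0.1, 0.2))

  g3 <- tiny_grid(3)
  expect_equal(grid_size(g3), 3^6)
  e3 <- enumerate_grid(g3)
  expect_equal(nrow(e3), 729)
  expect_equal(nrow(unique(e3)), 729)
  # lexicographic: alpha varies slowest, gamma fastest
  expect_equal(e3$gamma[1:3], grid_values(c(0.5, 0.8, 0.15))[1:3])
  expect_equal(e3$alpha, rep(c(0.05, 0.1, 0.15), each = 243))
  # index-generated values carry no accumulation error
  expect_identical(sort(unique(e3$eps_actor)), c(0.05, 0.1, 0.15))
  expect_identical(sort(unique(enumerate_grid(grid_spec())$alpha)),
                   c(0.05, 0.1, 0.15, 0.2, 0.25))
})

test_that("fit_grid equals a stored-scan argmin and bounds any grid point", {
  cfg <- small_config()
  d <- generate_synthetic_rat(mid_params(), cfg, seed = 77)
  grid <- tiny_grid(3)  # 729 points
  pts <- enumerate_grid(grid)
  # independent oracle: evaluate every point singly, store, take argmin
  scan <- vapply(seq_len(nrow(pts)), function(i) {
    neg_log_likelihood(d, do.call(model_parameters, as.list(pts[i, ])),
                       cfg)$neg_lle
  }, numeric(1))
  oracle_best <- which.min(scan)
  fit <- fit_grid(d, grid, cfg)
  expect_equal(fit$neg_lle, scan[oracle_best])
  expect_equal(unlist(fit$best_params)[names(pts)],
               unlist(pts[oracle_best, ]))
  expect_true(all(fit$neg_lle <= scan + 1e-12))
  # singleton grid returns that point
  f1 <- fit_grid(d, tiny_grid(1), cfg)
  expect_equal(f1$best_params$alpha, 0.1)
  expect_equal(f1$neg_lle,
               neg_log_likelihood(d, f1$best_params, cfg)$neg_lle)
  # final state comes from replay at the optimum
  expect_equal(fit$final_state,
               neg_log_likelihood(d, fit$best_params, cfg)$final_state)
})
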