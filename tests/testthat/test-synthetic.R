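test_that("synthetic rats are format-identical to empirical files", {
  cfg <- small_config()
  d <- generate_synthetic_rat(mid_params(), cfg, seed = 61, rat_id = "S01")
  expect_s3_class(d, "rat_dataset")
  expect_silent(rat_dataset(as.data.frame(d), "S01"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rat_csv(d, path)
  expect_silent(d2 <- read_rat_csv(path, rat_id = "S01"))
  expect_identical(as.data.frame(d2), as.data.frame(d))
  # homecage placeholders never carry presses
  expect_true(all(d$press[d$homecage == 1L] == 0L))
})

test_that("a press-averse synthetic rat shows the never-press structure", {
  cfg <- small_config(n_sessions = 1, trials_per_session = 3)
  frozen <- model_parameters(0, 0, 50, -1, persev = 0, gamma = 0.9)
  averse <- init_agent(); averse$m_weights["OTHER", "chamb"] <- 10
  d <- generate_synthetic_rat(frozen, cfg, seed = 1, init_state = averse)
  expect_true(all(d$press == 0L))
  for (tr in 1:3) {
    f <- d[d$trial == tr, ]
    expect_equal(sum(f$danger), 6)
    expect_equal(sum(f$shock), 6)
    expect_equal(sum(f$safety), 15)
  }
})

test_that("the generating parameters beat far-off parameters in likelihood", {
  cfg <- small_config(n_sessions = 2, trials_per_session = 10)
  truth <- mid_params()
  off <- truth; off$beta_exploit <- 0.1   # near-random policy
  off <- do.call(model_parameters, unclass(off))
  d_truth <- d_off <- numeric(10)
  for (i in 1:10) {
    d <- generate_synthetic_rat(truth, cfg, seed = 500 + i)
    d_truth[i] <- neg_log_likelihood(d, truth, cfg)$neg_lle
    d_off[i] <- neg_log_likelihood(d, off, cfg)$neg_lle
  }
  expect_lt(mean(d_truth), mean(d_off))
})

test_that("cohorts are deterministic, uniquely labelled, and truth is on-grid", {
  cfg <- small_config()
  coh <- make_cohort(n_per_strain = 3, config = cfg, seed = 17)
  expect_equal(names(coh$datasets),
               c("S01", "S02", "S03", "W01", "W02", "W03"))
  expect_false(anyDuplicated(names(coh$datasets)) > 0)
  coh2 <- make_cohort(n_per_strain = 3, config = cfg, seed = 17)
  expect_identical(coh$truth, coh2$truth)
  expect_identical(as.data.frame(coh$datasets$W02),
                   as.data.frame(coh2$datasets$W02))
  # distinct seeds give distinct press sequences
  expect_false(identical(coh$datasets$S01$press, coh$datasets$S02$press))
  # every true value lies on the generating grid
  for (nm in c("alpha", "epsilon", "beta", "R_shock", "P", "gamma")) {
    gnm <- switch(nm, epsilon = "eps_actor", beta = "beta_exploit",
                  R_shock = "r_shock", P = "persev", nm)
    expect_true(all(coh$truth[[nm]] %in% grid_values(coh$grid[[gnm]])))
  }
})

test_that("written cohorts reload through the standard readers", {
  cfg <- small_config()
  coh <- make_cohort(n_per_strain = 2, config = cfg, seed = 23)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  ids <- read_listfile(file.path(dir, "listfile.txt"))
  expect_equal(ids, names(coh$datasets))
  truth <- read_parm_listfile(file.path(dir, "parm_listfile.csv"))
  expect_identical(truth, coh$truth)
  d <- read_rat_csv(file.path(dir, "S02.csv"))
  expect_identical(as.data.frame(d), as.data.frame(coh$datasets$S02))
  # deleting IDs from the listfile restricts which rats get fitted
  keep <- ids[c(1, 3)]
  write_listfile(keep, file.path(dir, "listfile.txt"))
  datasets <- lapply(read_listfile(file.path(dir, "listfile.txt")),
                     function(id) read_rat_csv(file.path(dir,
                                                         paste0(id, ".csv"))))
  expect_equal(length(datasets), 2)
})

test_that("recovery fractions score fitted against generating parameters", {
  cfg <- small_config()
  coh <- make_cohort(n_per_strain = 2, config = cfg, seed = 31)
  # perfect "fits" constructed from the truth itself score 1 everywhere
  fits <- lapply(names(coh$datasets), function(id) {
    structure(list(rat_id = id, best_params = coh$params[[id]],
                   neg_lle = 0, grid = coh$grid), class = "fit_result")
  })
  expect_equal(unname(recovery_fractions(fits, coh)), rep(1, 6))
  # shifting beta_exploit by two grid steps drops only that fraction to 0
  fits2 <- lapply(fits, function(f) {
    p <- f$best_params
    p$beta_exploit <- p$beta_exploit + 2 * coh$grid$beta_exploit[3]
    f$best_params <- p
    f
  })
  fr <- recovery_fractions(fits2, coh)
  expect_equal(unname(fr["beta_exploit"]), 0)
  expect_equal(unname(fr["alpha"]), 1)
})
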