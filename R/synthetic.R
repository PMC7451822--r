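#' Generate a synthetic rat dataset from known parameters
#'
#' Runs one generative simulation ([simulate_run()]) and returns the frame
#' sequence as a [rat_dataset()] — sessions, trials, homecage blocks and
#' press bits, format-identical to empirical per-rat files — so that
#' fitting and I/O are testable without any downloaded data and truth is
#' known for parameter-recovery studies.
#'
#' @inheritParams simulate_run
#' @param rat_id Identifier for the synthetic rat.
#' @return A [rat_dataset()].
#' @export
generate_synthetic_rat <- function(params, config = task_config(),
                                   seed = 1L, rat_id = "SYN01",
                                   init_state = init_agent()) {
  run <- simulate_run(params, config, seed = seed, init_state = init_state)
  attr(run$frames, "rat_id") <- rat_id
  run$frames
}

#' Default strain parameter centers for synthetic cohorts
#'
#' Two behaviorally plausible parameter centers on the default search grid,
#' emulating a faster-acquiring strain (`S`: higher learning rates and
#' exploitation, milder shock value, weaker perseveration) and a
#' slower-acquiring strain (`W`: lower learning rates, stronger shock
#' aversion and perseveration, shorter horizon).
#'
#' @return A named list of two [model_parameters()] objects (`S` and `W`).
#' @export
default_strain_centers <- function() {
  list(
    S = model_parameters(alpha = 0.15, eps_actor = 0.15, beta_exploit = 5,
                         r_shock = -1.5, r_press = -0.05, persev = 0.25,
                         gamma = 0.8),
    W = model_parameters(alpha = 0.10, eps_actor = 0.10, beta_exploit = 3,
                         r_shock = -2.0, r_press = -0.05, persev = 0.5,
                         gamma = 0.65)
  )
}

# Index of the grid value nearest to a requested center value.
grid_index_of <- function(value, values) {
  which.min(abs(values - value))
}

#' Generate a synthetic two-strain cohort with known parameters
#'
#' For each rat, each free parameter's true value is drawn from the grid
#' values within `jitter_steps` grid steps of its strain center (uniformly,
#' clipped to the grid), giving between-rat variability while keeping truth
#' exactly on the search grid. Datasets are generated by
#' [generate_synthetic_rat()] with per-rat seeds derived from `seed`; the
#' truth table mirrors the parameter-listfile layout so recovery scoring
#' doubles as an I/O integration test.
#'
#' @param n_per_strain Rats per strain (default 10).
#' @param config A [task_config()].
#' @param grid A [grid_spec()]; truth values are drawn from this grid and
#'   fitting on the same grid makes recovery well-defined.
#' @param centers Named list of two [model_parameters()] centers (defaults
#'   to [default_strain_centers()]); names become rat-ID prefixes.
#' @param jitter_steps Maximum grid-step deviation of each true parameter
#'   from its strain center (default 1).
#' @param seed Master seed.
#' @return An object of class `synthetic_cohort`: `datasets` (named list
#'   of [rat_dataset()]), `truth` (data frame in parameter-listfile
#'   layout), `params` (named list of `model_parameters`), `grid`,
#'   `config`.
#' @export
make_cohort <- function(n_per_strain = 10L, config = task_config(),
                        grid = grid_spec(),
                        centers = default_strain_centers(),
                        jitter_steps = 1L, seed = 1L) {
  stopifnot(n_per_strain >= 1, length(centers) >= 1,
            !is.null(names(centers)))
  set.seed(seed)
  vals <- lapply(setNames(FREE_PARAMS, FREE_PARAMS),
                 function(nm) grid_values(grid[[nm]]))
  rats <- list()
  for (strain in names(centers)) {
    center <- centers[[strain]]
    for (i in seq_len(n_per_strain)) {
      id <- sprintf("%s%02d", strain, i)
      truth <- lapply(setNames(FREE_PARAMS, FREE_PARAMS), function(nm) {
        v <- vals[[nm]]
        ci <- grid_index_of(center[[nm]], v)
        j <- ci + sample(seq(-jitter_steps, jitter_steps), 1L)
        v[min(max(j, 1L), length(v))]
      })
      rats[[id]] <- do.call(model_parameters,
                            c(truth, list(r_press = grid$r_press)))
    }
  }
  rat_seeds <- sample.int(2147483646L, length(rats))
  datasets <- lapply(seq_along(rats), function(k)
    generate_synthetic_rat(rats[[k]], config, seed = rat_seeds[k],
                           rat_id = names(rats)[k]))
  names(datasets) <- names(rats)
  truth_df <- data.frame(
    rat = names(rats),
    alpha = vapply(rats, `[[`, numeric(1), "alpha"),
    epsilon = vapply(rats, `[[`, numeric(1), "eps_actor"),
    beta = vapply(rats, `[[`, numeric(1), "beta_exploit"),
    R_shock = vapply(rats, `[[`, numeric(1), "r_shock"),
    P = vapply(rats, `[[`, numeric(1), "persev"),
    gamma = vapply(rats, `[[`, numeric(1), "gamma"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(datasets = datasets, truth = truth_df, params = rats,
                 grid = grid, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$datasets), "rats (",
      paste(unique(substr(names(x$datasets), 1, 1)), collapse = "/"),
      ")\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Produces one per-rat data CSV, a `listfile.txt` of rat IDs, and a truth
#' `parm_listfile.csv` in the layout of [write_parm_listfile()].
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(cohort$datasets))
    write_rat_csv(cohort$datasets[[id]], file.path(dir, paste0(id, ".csv")))
  write_listfile(names(cohort$datasets), file.path(dir, "listfile.txt"))
  write_parm_listfile(cohort$truth, file.path(dir, "parm_listfile.csv"))
  invisible(dir)
}

#' Score parameter recovery of a fitted cohort
#'
#' For each free parameter, the fraction of rats whose fitted value lies
#' within `steps` grid steps of the generating truth.
#'
#' @param fits List of [fit_grid()] results for the cohort's datasets.
#' @param cohort The generating [make_cohort()] object.
#' @param steps Tolerance in grid steps (default 1).
#' @return Named numeric vector of per-parameter recovery fractions.
#' @export
recovery_fractions <- function(fits, cohort, steps = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- vapply(fits, `[[`, character(1), "rat_id")
  out <- setNames(numeric(length(FREE_PARAMS)), FREE_PARAMS)
  for (nm in FREE_PARAMS) {
    step <- cohort$grid[[nm]][3]
    truth <- vapply(cohort$params[ids], `[[`, numeric(1), nm)
    fitted <- vapply(fits, function(f) f$best_params[[nm]], numeric(1))
    out[nm] <- mean(abs(fitted - truth) <= steps * step + 1e-9)
  }
  out
}
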