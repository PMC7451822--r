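#' Read a per-rat behavioral data CSV
#'
#' One row per 12-s timestep with session and trial labels, the five binary
#' stimulus columns (danger signal, safety signal, shock, chamber,
#' homecage) and the binary press column. Header matching is
#' case-insensitive and accepts the documented synonyms (`ds` for danger,
#' `ss` for safety, `sh` for shock, `chamb` for chamber, `home` for
#' homecage, `lever`/`lever_press` for press). A `timestep` column, if
#' present, is ignored and regenerated. Rows violating the stimulus-frame
#' invariants are rejected with row-numbered errors.
#'
#' @param path Path to the CSV file.
#' @param rat_id Rat identifier; defaults to the file name without
#'   extension.
#' @return A [rat_dataset()].
#' @export
read_rat_csv <- function(path, rat_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(rat_id)) rat_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  syn <- list(session = c("session", "sess"),
              trial = c("trial"),
              danger = c("danger", "ds", "danger_signal"),
              safety = c("safety", "ss", "safety_signal"),
              shock = c("shock", "sh"),
              chamber = c("chamber", "chamb"),
              homecage = c("homecage", "home"),
              press = c("press", "lever", "lever_press"))
  nm <- tolower(names(raw))
  cols <- list()
  for (canon in names(syn)) {
    hit <- which(nm %in% syn[[canon]])
    if (length(hit) == 0)
      stop(sprintf("%s: missing column '%s'", basename(path), canon))
    cols[[canon]] <- raw[[hit[1]]]
  }
  fr <- as.data.frame(cols)
  for (nm2 in c("session", "trial")) {
    if (any(is.na(suppressWarnings(as.integer(fr[[nm2]])))))
      stop(sprintf("%s: non-integer '%s' values", basename(path), nm2))
    fr[[nm2]] <- as.integer(fr[[nm2]])
  }
  for (nm2 in c("danger", "safety", "shock", "chamber", "homecage",
                "press")) {
    v <- suppressWarnings(as.integer(fr[[nm2]]))
    bad <- which(is.na(v) | !(v %in% c(0L, 1L)))
    if (length(bad))
      stop(sprintf("%s: non-binary '%s' value at row %d", basename(path),
                   nm2, bad[1]))
    fr[[nm2]] <- v
  }
  rat_dataset(fr, rat_id = rat_id)
}

#' Write a rat dataset to CSV
#'
#' Inverse of [read_rat_csv()]; timestep labels are written as integer
#' indices.
#'
#' @param data A [rat_dataset()].
#' @param path Output path.
#' @export
write_rat_csv <- function(data, path) {
  fr <- as.data.frame(data)
  write.csv(fr[, c("timestep", "session", "trial", "danger", "safety",
                   "shock", "chamber", "homecage", "press")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a listfile of rat IDs
#'
#' One rat ID per line; blank lines are skipped; order is preserved.
#' Duplicate IDs raise a warning but are kept.
#'
#' @param path Path to the text file.
#' @return Character vector of rat IDs.
#' @export
read_listfile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids))
    warning("duplicate rat IDs in listfile: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ids
}

#' @rdname read_listfile
#' @param ids Character vector of rat IDs.
#' @export
write_listfile <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

GRID_COL_PREFIX <- c(alpha = "A", eps_actor = "E", beta_exploit = "B",
                     r_shock = "RS", r_press = "RP", persev = "P",
                     gamma = "G")
ESTPARM_PARAM_COLS <- c("alpha", "epsilon", "beta", "R_shock", "R_press",
                        "P", "gamma")

estparm_columns <- function() {
  c("rat", ESTPARM_PARAM_COLS, "negLLE",
    paste0("m_OTHER_", STIMULI), paste0("m_PRESS_", STIMULI),
    paste0("V_", STIMULI),
    as.vector(vapply(GRID_COL_PREFIX,
                     function(p) paste0(p, c("min", "max", "step")),
                     character(3))),
    "overnight_steps")
}

#' Write fitted parameters to an estimated-parameters CSV
#'
#' One row per rat with 46 columns: the rat ID; the 7 parameters; the
#' negLLE; the 10 end-of-training M-values (`m_OTHER_DS` ... `m_PRESS_home`)
#' and 5 V-values (`V_DS` ... `V_home`); 21 columns recording the searched
#' min/max/step of each parameter (`Amin`/`Amax`/`Astep` for `alpha`, and
#' analogously `E*`, `B*`, `RS*`, `RP*`, `P*`, `G*`; the fixed press cost
#' is recorded with min = max and step 0); and the number of homecage
#' ("overnight") timesteps per session.
#'
#' @param results A list of [fit_grid()] results sharing one grid/config.
#' @param path Output path.
#' @export
write_estimated_parms <- function(results, path) {
  stopifnot(length(results) >= 1)
  rows <- lapply(results, function(fr) {
    stopifnot(inherits(fr, "fit_result"))
    p <- fr$best_params
    g <- fr$grid
    grid_cells <- unlist(lapply(PARAM_ORDER, function(nm) {
      if (nm == "r_press") c(g$r_press, g$r_press, 0) else g[[nm]]
    }))
    st <- fr$final_state
    c(list(fr$rat_id),
      as.list(c(p$alpha, p$eps_actor, p$beta_exploit, p$r_shock, p$r_press,
                p$persev, p$gamma, fr$neg_lle,
                st$m_weights["OTHER", ], st$m_weights["PRESS", ],
                st$v_weights, grid_cells, fr$homecage_steps)))
  })
  df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(df) <- estparm_columns()
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an estimated-parameters CSV
#'
#' Inverse of [write_estimated_parms()].
#'
#' @param path Path to the CSV.
#' @return A data frame with the 46 documented columns.
#' @export
read_estimated_parms <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(estparm_columns(), names(df))
  if (length(miss))
    stop("estimated-parameters file missing columns: ",
         paste(miss, collapse = ", "))
  df <- df[, estparm_columns()]
  num <- setdiff(names(df), "rat")
  df[num] <- lapply(df[num], as.numeric)
  df
}

#' Read / write a parameter listfile (simulation input)
#'
#' Per-rat parameter values driving the behavioral simulations: the rat ID
#' plus the six free parameters (`alpha`, `epsilon`, `beta`, `R_shock`,
#' `P`, `gamma`); the constant press cost is not a column.
#'
#' @param path Path to the CSV.
#' @return A data frame with columns `rat`, `alpha`, `epsilon`, `beta`,
#'   `R_shock`, `P`, `gamma`.
#' @export
read_parm_listfile <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("rat", "alpha", "epsilon", "beta", "R_shock", "P", "gamma")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parameter listfile missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  df[need[-1]] <- lapply(df[need[-1]], as.numeric)
  df
}

#' @rdname read_parm_listfile
#' @param parms Data frame in the same layout (as from [make_cohort()]'s
#'   truth table or [read_estimated_parms()] subset).
#' @export
write_parm_listfile <- function(parms, path) {
  need <- c("rat", "alpha", "epsilon", "beta", "R_shock", "P", "gamma")
  write.csv(parms[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# One model_parameters per row of a parameter listfile.
parm_row_to_parameters <- function(row, r_press = -0.05) {
  model_parameters(alpha = row$alpha, eps_actor = row$epsilon,
                   beta_exploit = row$beta, r_shock = row$R_shock,
                   r_press = r_press, persev = row$P, gamma = row$gamma)
}

#' Write a per-rat behavioral summary file
#'
#' One row per session: 25 per-trial outcome codes (`A`/`E`/`.`), the
#' session's total anticipatory responses (ARs, habituation presses), and
#' 25 per-trial ITR totals (presses during the ITI following each trial).
#'
#' @param x A [rat_dataset()] / frame data frame, or a [score_frames()]
#'   result.
#' @param path Output path.
#' @param config A [task_config()].
#' @export
write_summary_file <- function(x, path, config = task_config()) {
  sm <- if (inherits(x, "behavior_summary")) x else score_frames(x, config)
  n_tri <- ncol(sm$outcomes)
  df <- data.frame(session = seq_len(nrow(sm$outcomes)))
  for (tr in seq_len(n_tri)) df[[paste0("trial_", tr)]] <- sm$outcomes[, tr]
  df$ARs <- sm$ars
  itr_tot <- apply(sm$itrs, c(1, 2), sum)
  for (tr in seq_len(n_tri)) df[[paste0("ITR_", tr)]] <- itr_tot[, tr]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_file
#' @export
read_summary_file <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"session" %in% names(df) || !"ARs" %in% names(df))
    stop("not a summary file: ", path)
  df
}

#' Write a behavioral-simulation output file
#'
#' One row per simulated run. Column blocks: per-trial outcome codes under
#' `session_trial` headers (e.g. `5_17` = 17th trial of the 5th session);
#' per-session AR counts (`AR_1` ... `AR_12`); per-trial-per-minute ITR
#' counts under `session_trial_minute_ITRs` headers (e.g. `2_3_1_ITRs` =
#' session 2, trial 3, first ITI minute).
#'
#' @param sim A [simulate_rat()] result (or list of [score_frames()]
#'   results).
#' @param path Output path.
#' @export
write_simulation_output <- function(sim, path) {
  runs <- if (inherits(sim, "behavior_summary_collection")) sim$runs else sim
  stopifnot(length(runs) >= 1)
  n_ses <- nrow(runs[[1]]$outcomes)
  n_tri <- ncol(runs[[1]]$outcomes)
  out_cols <- as.vector(t(outer(seq_len(n_ses), seq_len(n_tri), paste,
                                sep = "_")))
  itr_cols <- character(0)
  for (s in seq_len(n_ses))
    for (tr in seq_len(n_tri))
      itr_cols <- c(itr_cols, paste0(s, "_", tr, "_", 1:3, "_ITRs"))
  out_mat <- do.call(rbind, lapply(runs, function(r) as.vector(t(r$outcomes))))
  ar_mat <- do.call(rbind, lapply(runs, `[[`, "ars"))
  itr_mat <- do.call(rbind, lapply(runs, function(r)
    as.vector(aperm(r$itrs, c(3, 2, 1)))))
  colnames(out_mat) <- out_cols
  colnames(ar_mat) <- paste0("AR_", seq_len(n_ses))
  colnames(itr_mat) <- itr_cols
  df <- data.frame(run = seq_along(runs), out_mat, ar_mat, itr_mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_simulation_output
#' @export
read_simulation_output <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"run" %in% names(df))
    stop("not a simulation output file: ", path)
  df
}

#' Read a YAML task/grid configuration file
#'
#' Optional `task:` and `grid:` sections; `task` keys are [task_config()]
#' arguments, `grid` keys are [grid_spec()] arguments (each free parameter
#' as a `[min, max, step]` list, `r_press` a scalar). Missing sections fall
#' back to defaults.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `config` (a `task_config`) and `grid` (a
#'   `grid_spec`).
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(task_config, as.list(y$task))
  grid_args <- lapply(as.list(y$grid), function(v) unlist(v))
  grid <- do.call(grid_spec, grid_args)
  list(config = cfg, grid = grid)
}
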