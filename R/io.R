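# Shared I/O: validated trial-table CSVs, JSON run configurations and the
# end-to-end pipeline (simulate -> analyze -> GLM demo) with a reproducible
# run log.

.trial_schema <- c("participant", "session", "task", "run", "trial",
                   "condition", "level", "choice1", "correct1", "conf1",
                   "u1", "rt1", "choice2", "correct2", "conf2", "u2",
                   "rt2", "delta_u")

#' Write a trial table to CSV
#'
#' @param tab A trial table.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_trial_table <- function(tab, path) {
  missing <- setdiff(.trial_schema, names(tab))
  if (length(missing)) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "redecide_validation_error")
  }
  readr::write_csv(dplyr::select(tab, dplyr::all_of(.trial_schema)), path)
  invisible(tab)
}

#' Read and validate a trial table
#'
#' Enforces the TrialRecord schema: confidence ratings in 1..4 with
#' uncertainty `u = 5 - conf`, response times within the (0, 2] s window,
#' levels in 0..10 (0 = control). Rows violating row-level invariants are
#' dropped with a warning that reports their count and line numbers.
#'
#' @param path CSV path.
#' @return A validated tibble in row order.
#' @export
read_trial_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(.trial_schema, names(tab))
  if (length(missing)) {
    abort(paste0("Trial table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "redecide_validation_error")
  }
  int_cols <- c("conf1", "conf2", "u1", "u2", "level", "choice1", "choice2",
                "correct1", "correct2")
  for (cl in int_cols) {
    if (!is.numeric(tab[[cl]]) || any(tab[[cl]] != round(tab[[cl]]), na.rm = TRUE)) {
      abort(sprintf("Column '%s' must be integer-valued.", cl),
            class = "redecide_validation_error")
    }
  }
  ok <- tab$conf1 %in% 1:4 & tab$conf2 %in% 1:4 &
    tab$u1 == 5L - tab$conf1 & tab$u2 == 5L - tab$conf2 &
    tab$level %in% 0:10 &
    tab$rt1 > 0 & tab$rt1 <= 2 & tab$rt2 > 0 & tab$rt2 <= 2 &
    tab$correct1 %in% 0:1 & tab$correct2 %in% 0:1 &
    tab$delta_u == tab$u1 - tab$u2
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    warn(sprintf("Dropping %d invalid trial row(s) (lines %s).",
                 sum(!ok),
                 paste(utils::head(which(!ok) + 1L, 10), collapse = ", ")))
  }
  tab[ok, ]
}

.config_defaults <- function() {
  list(
    task = "sudoku",
    n_participants = 4L,
    sessions = 1L,
    runs = 4L,
    trials_per_run = 30L,
    controls_per_run = 10L,
    staircase = TRUE,
    fixed_level = 5L,
    agent = list(),
    timing = list(),
    glm = list(tr = 2, orth_order = c("u1", "rt", "delta_u"),
               true_betas = c(decision = 1, postdecision = 1, iti = 0,
                              mod_u1 = 0.5, mod_rt = 0, mod_delta_u = 0.3),
               noise_sd = 1, noise_rho = 0.3),
    seed = 1L
  )
}

#' Read and validate a JSON run configuration
#'
#' Unknown keys are rejected; known keys override the documented defaults.
#'
#' @param path JSON file path, or a list to validate directly.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    path
  }
  defaults <- .config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "redecide_config_error")
  }
  merged <- utils::modifyList(defaults, cfg)
  if (is.null(merged$seed)) {
    abort("Config must carry a seed.", class = "redecide_config_error")
  }
  stopifnot(merged$n_participants >= 1, merged$sessions >= 1,
            merged$runs >= 1, merged$trials_per_run >= 1)
  agent_ok <- setdiff(names(merged$agent), names(formals(agent_params)))
  if (length(agent_ok)) {
    abort(paste0("Unknown agent parameter(s): ", paste(agent_ok, collapse = ", ")),
          class = "redecide_config_error")
  }
  timing_ok <- setdiff(names(merged$timing), names(formals(timing_config)))
  if (length(timing_ok)) {
    abort(paste0("Unknown timing parameter(s): ",
                 paste(timing_ok, collapse = ", ")),
          class = "redecide_config_error")
  }
  structure(merged, class = "run_config")
}

config_hash <- function(cfg) {
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic pipeline
#'
#' Simulates a cohort, analyzes it and runs the GLM demonstration
#' (schedule, design, VIF, simulated BOLD, fit, PPI, connectivity) on the
#' first participant's first run. All artifacts are written into `out_dir`
#' as CSV/JSON, together with a run log carrying the seed, the config hash
#' and the package version; reruns with the same config are bit-identical.
#'
#' @param config A `run_config`, or a path to a JSON config.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the cohort table, the summary and the GLM
#'   report.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  say("stage=init seed=%d config_hash=%s version=%s", cfg$seed,
      config_hash(cfg), as.character(utils::packageVersion("redecide")))

  # stage 1: simulate
  agents <- do.call(sample_cohort_params,
                    c(list(n_participants = cfg$n_participants,
                           seed = child_seed(cfg$seed, 1L),
                           tasks = cfg$task), cfg$agent))
  cohort <- simulate_cohort(
    agents, sessions_per_participant = cfg$sessions,
    seed = child_seed(cfg$seed, 2L), tasks = cfg$task,
    config = list(n_runs = cfg$runs, trials_per_run = cfg$trials_per_run,
                  controls_per_run = cfg$controls_per_run,
                  staircase = cfg$staircase, fixed_level = cfg$fixed_level)
  )
  write_trial_table(cohort, file.path(out_dir, "trials.csv"))
  say("stage=simulate rows=%d", nrow(cohort))

  # stage 2: analyze
  summ <- summarize_cohort(cohort)
  readr::write_csv(summ$metrics, file.path(out_dir, "metrics.csv"))
  readr::write_csv(summ$reliability, file.path(out_dir, "reliability.csv"))
  jsonlite::write_json(summ$tables, file.path(out_dir, "tables.json"),
                       auto_unbox = TRUE, digits = NA)
  say("stage=analyze sessions=%d", nrow(summ$metrics))

  # stage 3: GLM demo on the first participant/run
  run1 <- dplyr::filter(cohort, .data$participant == 1,
                        .data$session == 1, .data$run == 1)
  timing <- do.call(timing_config, cfg$timing)
  sched <- build_schedule(run1, timing)
  design <- build_design(sched, tr = cfg$glm$tr,
                         orth_order = cfg$glm$orth_order)
  tb <- cfg$glm$true_betas[colnames(design$X)]
  tb[is.na(tb)] <- 0
  bold <- simulate_bold(design, tb, sigma = cfg$glm$noise_sd,
                        rho = cfg$glm$noise_rho,
                        seed = child_seed(cfg$seed, 3L))
  fit <- fit_glm(bold, design)
  ppi <- ppi_design(bold, sched, tr = cfg$glm$tr, target = bold)
  roi2 <- simulate_bold(design, tb * 0.8, sigma = cfg$glm$noise_sd,
                        rho = cfg$glm$noise_rho,
                        seed = child_seed(cfg$seed, 4L))
  conn <- trialwise_connectivity(cbind(roi_a = bold, roi_b = roi2), sched,
                                 tr = cfg$glm$tr)
  report <- list(
    vif = as.list(vif(design, c("decision", "postdecision"))),
    betas = as.list(fit$beta),
    r_squared = fit$r_squared,
    ppi_coupling = ppi$coupling,
    connectivity = lapply(conn$matrices, function(m) as.data.frame(m))
  )
  jsonlite::write_json(report, file.path(out_dir, "glm_report.json"),
                       auto_unbox = TRUE, digits = NA)
  say("stage=glm volumes=%d", length(bold))

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(cohort = cohort, summary = summ, glm_report = report))
}
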