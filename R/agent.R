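# Generative observer for decision-redecision trials.
#
# Decision stage: a 4-alternative race. The true option's evidence is
# N(a*delta_L, 1) and each distractor's is N(0, 1); the choice is the
# maximum. delta_L is calibrated per difficulty level so that the marginal
# accuracy follows the logistic psychometric function
#   acc(L) = 0.25 + 0.75 / (1 + exp((L - m)/s)),
# where a is a lognormal per-trial attention/efficiency multiplier (mean 1).
#
# Metacognitive stage (second-order readout): the monitor holds its own
# noisy sample of the evidence (precision kappa relative to the decision
# sample) and reads out the Bayesian posterior probability that the chosen
# option is correct; confidence 1-4 is the readout binned at three criteria
# on the log-odds scale, after adding readout noise with sd sigma_meta.
# sigma_meta = 0 gives a near-ideal error monitor; large sigma_meta gives an
# uninformative one.
#
# Redecision stage: extra evidence is accumulated with a gain that grows
# with the initial uncertainty report (metacognitive control allocates
# effort where it is needed); the redecision gain g is the evidence
# multiplier at maximal uncertainty, and g = 1 adds no information, so the
# redecision then reproduces the initial accuracy.

#' Generative parameters of a simulated observer
#'
#' @param m Psychometric midpoint level (defaults to 5, the level that
#'   trained participants reach).
#' @param s Psychometric slope (levels per log-odds unit).
#' @param sigma_meta Metacognitive readout noise (sd on the log-odds scale);
#'   0 = near-ideal uncertainty monitor.
#' @param criteria Strictly increasing confidence criteria (length 3) on the
#'   log-odds-correct scale.
#' @param crit_shift Additive shift applied to all three criteria; a
#'   negative shift makes the observer overconfident (lower reported
#'   uncertainty), a positive one underconfident. This is the planted
#'   "uncertainty bias" knob.
#' @param rt_base,rt_slope,rt_sd Linear response-time model
#'   `rt = rt_base + rt_slope * uncertainty + noise(rt_sd)`, clipped to the
#'   (0.2, 2] s response window. Units: seconds.
#' @param g Redecision evidence gain at maximal uncertainty (>= 1). May be a
#'   named vector with one entry per task (e.g.
#'   `c(sudoku = 2, rdm = 1.6)`) to plant task-specific decision-adjustment
#'   propensities.
#' @param lapse Probability that the initial choice is a uniform random
#'   lapse, in [0, 0.1].
#' @param s_att Lognormal sd of the per-trial attention multiplier.
#' @param kappa Precision of the monitor's private evidence sample relative
#'   to the decision sample.
#' @param boost Deliberation confidence gain: constant added to the phase-2
#'   log-odds readout on trials that engaged redecision (initial
#'   uncertainty > 1).
#' @param control_accuracy Target accuracy on control trials (level 0).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(m = 5, s = 1.5, sigma_meta = 1.5,
                         criteria = c(-0.6, 0.3, 1.2), crit_shift = 0,
                         rt_base = 0.5, rt_slope = 0.25, rt_sd = 0.15,
                         g = 2, lapse = 0.02, s_att = 1.4, kappa = 16,
                         boost = 1.5, control_accuracy = 0.95) {
  stopifnot(length(criteria) == 3L, !is.unsorted(criteria, strictly = TRUE),
            sigma_meta >= 0, all(g >= 1), lapse >= 0, lapse <= 0.1,
            rt_sd >= 0, s_att >= 0, kappa > 0, s > 0,
            control_accuracy > 0.25, control_accuracy < 1)
  structure(
    list(m = m, s = s, sigma_meta = sigma_meta, criteria = criteria,
         crit_shift = crit_shift, rt_base = rt_base, rt_slope = rt_slope,
         rt_sd = rt_sd, g = g, lapse = lapse, s_att = s_att, kappa = kappa,
         boost = boost, control_accuracy = control_accuracy),
    class = "agent_params"
  )
}

#' Psychometric function of the simulated observer
#'
#' @param agent An [agent_params()] object.
#' @param level Difficulty level(s) 1..10, or 0 for control.
#' @return Expected initial-decision accuracy.
#' @export
psychometric_accuracy <- function(agent, level) {
  stopifnot(inherits(agent, "agent_params"), all(level %in% 0:10))
  out <- 0.25 + 0.75 / (1 + exp((level - agent$m) / agent$s))
  out[level == 0] <- agent$control_accuracy
  out
}

# P(argmax is the true option) in the 4-alternative race at signal strength
# delta: E_z[pnorm(z + delta)^3] with z the true option's own noise.
.p4_grid <- qnorm((seq_len(801) - 0.5) / 801)
four_afc_accuracy <- function(delta) {
  vapply(delta, function(d) mean(pnorm(.p4_grid + d)^3), numeric(1))
}

# Marginal accuracy at signal delta under the lognormal attention mixture.
.att_grid <- qnorm((seq_len(21) - 0.5) / 21)
acc_given_delta <- function(delta, s_att) {
  a <- exp(-s_att^2 / 2 + s_att * .att_grid)
  mean(four_afc_accuracy(delta * a))
}

# Signal strength per level such that the marginal accuracy matches the
# psychometric function. Memoized: calibration only depends on (m, s,
# s_att, lapse, control_accuracy).
.delta_cache <- new.env(parent = emptyenv())
delta_for_level <- function(agent) {
  key <- paste(agent$m, agent$s, agent$s_att, agent$lapse,
               agent$control_accuracy, sep = "|")
  hit <- .delta_cache[[key]]
  if (!is.null(hit)) return(hit)
  # solve acc_raw such that (1 - lapse) * acc_raw + lapse * 0.25 = target
  target <- psychometric_accuracy(agent, 0:10)
  acc_raw <- pmin((target - agent$lapse * 0.25) / (1 - agent$lapse), 1 - 1e-6)
  delta <- vapply(acc_raw, function(ac) {
    if (ac <= 0.25 + 1e-6) return(0)
    hi <- 1
    while (acc_given_delta(hi, agent$s_att) < ac && hi < 4096) hi <- hi * 2
    uniroot(function(d) acc_given_delta(d, agent$s_att) - ac,
            c(0, hi), tol = 1e-6)$root
  }, numeric(1))
  names(delta) <- as.character(0:10)
  .delta_cache[[key]] <- delta
  delta
}

clamp01 <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

# One decision-redecision trial given the trial's signal strength. Not
# seeded: callers manage the RNG. Returns a one-row list.
sim_trial_core <- function(agent, delta) {
  a <- exp(rnorm(1, -agent$s_att^2 / 2, agent$s_att))
  d <- delta * a
  crit <- agent$criteria + agent$crit_shift
  truth <- sample.int(4L, 1L)
  signal <- as.numeric(seq_len(4L) == truth)

  v1 <- rnorm(4) + d * signal
  ch1 <- which.max(v1)
  if (runif(1) < agent$lapse) ch1 <- sample.int(4L, 1L)
  vm <- rnorm(4, 0, 1 / sqrt(agent$kappa)) + d * signal
  sc1 <- d * (v1 + agent$kappa * vm)
  post1 <- exp(sc1 - max(sc1)); post1 <- post1 / sum(post1)
  x1 <- qlogis(clamp01(post1[ch1])) + rnorm(1, 0, agent$sigma_meta)
  conf1 <- 1L + sum(x1 > crit)
  u1 <- 5L - conf1

  gt <- 1 + (agent$g_task - 1) * (u1 - 1) / 3
  if (gt > 1) {
    v2 <- rnorm(4, 0, 1 / sqrt(gt - 1)) + d * signal
    w <- v1 + (gt - 1) * v2
  } else {
    w <- v1
  }
  ch2 <- which.max(w)
  sc2 <- d * (w + agent$kappa * vm)
  post2 <- exp(sc2 - max(sc2)); post2 <- post2 / sum(post2)
  x2 <- qlogis(clamp01(post2[ch2])) + agent$boost * (u1 > 1L) +
    rnorm(1, 0, agent$sigma_meta)
  conf2 <- 1L + sum(x2 > crit)
  u2 <- 5L - conf2

  rt1 <- min(max(agent$rt_base + agent$rt_slope * u1 + rnorm(1, 0, agent$rt_sd),
                 0.2), 2)
  rt2 <- min(max(agent$rt_base + agent$rt_slope * u2 + rnorm(1, 0, agent$rt_sd),
                 0.2), 2)
  list(choice1 = ch1, correct1 = as.integer(ch1 == truth),
       conf1 = conf1, u1 = u1, rt1 = rt1,
       choice2 = ch2, correct2 = as.integer(ch2 == truth),
       conf2 = conf2, u2 = u2, rt2 = rt2,
       delta_u = u1 - u2)
}

# Resolve the task-specific redecision gain.
gain_for_task <- function(agent, task) {
  g <- agent$g
  if (!is.null(names(g)) && task %in% names(g)) unname(g[[task]]) else unname(g[[1]])
}

#' Simulate independent decision-redecision trials at a fixed level
#'
#' @param agent An [agent_params()] object.
#' @param level Difficulty level 1..10, or 0 for a control trial.
#' @param task Task label (`"sudoku"` or `"rdm"`); selects the task's
#'   redecision gain when `agent$g` is named.
#' @param seed Integer seed.
#' @param n Number of independent trials.
#' @return A tibble with one row per trial (TrialRecord columns).
#' @export
simulate_trial <- function(agent, level, task = "sudoku", seed = 1L, n = 1L) {
  stopifnot(inherits(agent, "agent_params"), level %in% 0:10, n >= 1)
  delta <- delta_for_level(agent)[[as.character(level)]]
  agent$g_task <- gain_for_task(agent, task)
  with_seed_(seed, {
    rows <- purrr::map(seq_len(n), function(i) sim_trial_core(agent, delta))
    out <- dplyr::bind_rows(rows)
    dplyr::mutate(out,
                  task = task, trial = dplyr::row_number(),
                  condition = if (level == 0) "control" else "task",
                  level = as.integer(level),
                  .before = 1)
  })
}

#' Simulate a full session driven by the adaptive staircase
#'
#' Each run interleaves task trials with control trials at random positions.
#' The staircase advances on the correctness of the initial decision of task
#' trials only; control trials (level 0) do not move it.
#'
#' @param agent An [agent_params()] object.
#' @param config A list: `task` ("sudoku"/"rdm"), `n_runs` (4),
#'   `trials_per_run` (30 task trials), `controls_per_run` (10),
#'   `staircase` (TRUE), `fixed_level` (level used when the staircase is
#'   off), `start_level` (initial staircase level).
#' @param seed Integer seed.
#' @return A tibble of TrialRecords, columns `task`, `session`, `run`,
#'   `trial`, `condition`, `level`, `choice1`, `correct1`, `conf1`, `u1`,
#'   `rt1`, `choice2`, `correct2`, `conf2`, `u2`, `rt2`, `delta_u`.
#' @export
simulate_session <- function(agent, config = list(), seed = 1L) {
  stopifnot(inherits(agent, "agent_params"))
  defaults <- list(task = "sudoku", n_runs = 4L, trials_per_run = 30L,
                   controls_per_run = 10L, staircase = TRUE,
                   fixed_level = 5L, start_level = 5L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown session config field(s): ",
                 paste(unknown, collapse = ", ")),
          class = "redecide_config_error")
  }
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$task %in% c("sudoku", "rdm")) {
    abort("config$task must be 'sudoku' or 'rdm'.",
          class = "redecide_config_error")
  }
  stopifnot(cfg$n_runs >= 1, cfg$trials_per_run >= 1, cfg$controls_per_run >= 0,
            cfg$fixed_level %in% 1:10, cfg$start_level %in% 1:10)

  deltas <- delta_for_level(agent)
  agent$g_task <- gain_for_task(agent, cfg$task)
  with_seed_(seed, {
    state <- staircase_state(level = cfg$start_level)
    rows <- vector("list", cfg$n_runs * (cfg$trials_per_run + cfg$controls_per_run))
    k <- 0L
    for (run in seq_len(cfg$n_runs)) {
      n_tot <- cfg$trials_per_run + cfg$controls_per_run
      is_control <- logical(n_tot)
      if (cfg$controls_per_run > 0L) {
        is_control[sample.int(n_tot, cfg$controls_per_run)] <- TRUE
      }
      for (t in seq_len(n_tot)) {
        if (is_control[t]) {
          lev <- 0L
        } else if (cfg$staircase) {
          lev <- state$level
        } else {
          lev <- as.integer(cfg$fixed_level)
        }
        rec <- sim_trial_core(agent, deltas[[as.character(lev)]])
        k <- k + 1L
        rows[[k]] <- c(list(task = cfg$task, run = run, trial = t,
                            condition = if (lev == 0L) "control" else "task",
                            level = lev), rec)
        if (!is_control[t] && cfg$staircase) {
          state <- staircase_update(state, rec$correct1 == 1L)
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Draw a cohort of observer parameter sets with planted structure
#'
#' Per participant, the metacognitive readout noise `sigma_meta` and the
#' confidence criterion shift are drawn once and shared by all sessions and
#' tasks (stable traits, so uncertainty sensitivity and uncertainty bias are
#' reliable). The redecision gain is drawn independently for each task
#' (task-specific decision-adjustment propensity, so accuracy change is
#' consistent within a task but dissociates across tasks).
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @param tasks Task labels to draw gains for.
#' @param sigma_meta_mean Median of the lognormal sigma_meta distribution.
#' @param sigma_meta_sdlog Lognormal sd of sigma_meta across participants.
#' @param gain_mean Median redecision gain (g - 1 is lognormal).
#' @param gain_sdlog Lognormal sd of (g - 1) across participant x task.
#' @param crit_shift_sd SD of the criterion shift across participants.
#' @param ... Fixed fields passed to every [agent_params()] call.
#' @return A list of `agent_params`, length `n_participants`.
#' @export
sample_cohort_params <- function(n_participants, seed = 1L,
                                 tasks = c("sudoku", "rdm"),
                                 sigma_meta_mean = 1.5, sigma_meta_sdlog = 0.4,
                                 gain_mean = 2, gain_sdlog = 0.35,
                                 crit_shift_sd = 0.5, ...) {
  stopifnot(n_participants >= 1)
  with_seed_(seed, {
    lapply(seq_len(n_participants), function(i) {
      g <- 1 + exp(rnorm(length(tasks), log(gain_mean - 1), gain_sdlog))
      names(g) <- tasks
      agent_params(
        sigma_meta = exp(rnorm(1, log(sigma_meta_mean), sigma_meta_sdlog)),
        crit_shift = rnorm(1, 0, crit_shift_sd),
        g = g, ...
      )
    })
  })
}

#' Simulate a cohort of participants over repeated sessions
#'
#' @param params_list List of [agent_params()], one per participant (e.g.
#'   from [sample_cohort_params()]).
#' @param sessions_per_participant Number of sessions per participant and
#'   task.
#' @param seed Integer seed.
#' @param tasks Tasks each participant performs in every session.
#' @param config Session configuration, as in [simulate_session()] (the
#'   `task` field is set per task internally).
#' @return A tidy long-format tibble of TrialRecords with `participant` and
#'   `session` columns.
#' @export
simulate_cohort <- function(params_list, sessions_per_participant = 1L,
                            seed = 1L, tasks = c("sudoku", "rdm"),
                            config = list()) {
  stopifnot(length(params_list) >= 1,
            all(vapply(params_list, inherits, logical(1), "agent_params")))
  counter <- 0L
  out <- purrr::map_dfr(seq_along(params_list), function(p) {
    purrr::map_dfr(seq_len(sessions_per_participant), function(sess) {
      purrr::map_dfr(tasks, function(tk) {
        counter <<- counter + 1L
        tab <- simulate_session(params_list[[p]],
                                config = utils::modifyList(config, list(task = tk)),
                                seed = child_seed(seed, counter))
        dplyr::mutate(tab, participant = p, session = sess, .before = 1)
      })
    })
  })
  out
}
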