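# Behavioral metacognition statistics: type-2 ROC uncertainty sensitivity,
# RT-uncertainty correlation, uncertainty bias, accuracy change,
# Goodman-Kruskal gamma, Cronbach alpha and Fisher-z comparisons.

#' Type-2 ROC for uncertainty-based error detection
#'
#' The ROC treats each uncertainty level k as a threshold for flagging a
#' trial as an error: the hit rate is P(u >= k | error) and the false-alarm
#' rate is P(u >= k | correct). The curve is anchored at (0,0) and (1,1) and
#' the area (`a_roc`) is the trapezoidal area under the resulting points:
#' 0.5 means uncertainty carries no information about accuracy, 1 means
#' perfect error detection. The complementary confidence framing (flagging
#' corrects with confidence >= k) yields the same area and is exposed as an
#' option.
#'
#' @param u Ordinal uncertainty ratings (1..4 in the standard trial schema;
#'   any ordinal coding works since the area only depends on the ordering).
#' @param correct Logical or 0/1 correctness, one per trial.
#' @param framing `"uncertainty"` (default; hit = error flagged at high
#'   uncertainty) or `"confidence"`.
#' @return An object of class `redecide_roc`: list with `points` (tibble of
#'   false-alarm and hit rates) and `a_roc`.
#' @export
type2_roc <- function(u, correct, framing = c("uncertainty", "confidence")) {
  framing <- match.arg(framing)
  correct <- as.logical(correct)
  stopifnot(length(u) == length(correct), !anyNA(u), !anyNA(correct))
  if (all(correct) || !any(correct)) {
    abort("Type-2 ROC is undefined without both correct and error trials.",
          class = "redecide_undefined_roc_error")
  }
  if (framing == "confidence") {
    # flag correct trials at high confidence instead; same area
    u <- -as.numeric(u)
    correct <- !correct
  }
  flag <- u[!correct] # "signal" trials are errors in the uncertainty framing
  noise <- u[correct]
  ks <- sort(unique(u), decreasing = TRUE)
  hit <- vapply(ks, function(k) mean(flag >= k), numeric(1))
  fa <- vapply(ks, function(k) mean(noise >= k), numeric(1))
  pts <- tibble::tibble(
    threshold = c(Inf, ks, -Inf),
    fa = c(0, fa, 1),
    hit = c(0, hit, 1)
  )
  a <- sum(diff(pts$fa) * (head(pts$hit, -1) + pts$hit[-1]) / 2)
  structure(list(points = pts, a_roc = a, framing = framing,
                 n_error = length(flag), n_correct = length(noise)),
            class = "redecide_roc")
}

#' @export
print.redecide_roc <- function(x, ...) {
  cat(sprintf("Type-2 ROC (%s framing): A_ROC = %.3f (%d errors, %d corrects)\n",
              x$framing, x$a_roc, x$n_error, x$n_correct))
  invisible(x)
}

#' Correlation between response time and uncertainty
#'
#' Pearson correlation with its t statistic, `t = r * sqrt(n - 2) /
#' sqrt(1 - r^2)`; the default alternative is one-tailed positive (slower
#' responses on more uncertain trials).
#'
#' @param rt Response times.
#' @param u Uncertainty ratings.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return A list with `r`, `t`, `df`, `p`, `n`.
#' @export
rt_uncertainty_correlation <- function(rt, u, alternative = "greater") {
  stopifnot(length(rt) == length(u))
  ok <- !is.na(rt) & !is.na(u)
  rt <- rt[ok]; u <- u[ok]
  if (length(rt) < 3 || sd(rt) == 0 || sd(u) == 0) {
    abort("RT-uncertainty correlation needs >= 3 trials with variance in both.",
          class = "redecide_undefined_correlation_error")
  }
  ct <- cor.test(rt, u, alternative = alternative, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, n = length(rt))
}

#' Uncertainty bias: mean uncertainty with sensitivity regressed out
#'
#' Ordinary least squares of mean uncertainty on A_ROC across participants;
#' the bias is the residual plus the grand mean of the mean uncertainty, so
#' biases average to the grand mean and are orthogonal to A_ROC. If A_ROC is
#' constant (no regressor variance) the demeaned-plus-grand-mean fallback is
#' used and flagged with a warning.
#'
#' @param mean_u Mean uncertainty per participant.
#' @param a_roc A_ROC per participant.
#' @return Numeric vector of biases (one per participant) with attribute
#'   `fallback` (TRUE if the regressor was constant).
#' @export
uncertainty_bias <- function(mean_u, a_roc) {
  stopifnot(length(mean_u) == length(a_roc), !anyNA(mean_u), !anyNA(a_roc))
  if (length(mean_u) < 3) {
    abort("Uncertainty bias needs >= 3 participants.",
          class = "redecide_validation_error")
  }
  fallback <- var(a_roc) == 0
  if (fallback) {
    warn("A_ROC is constant across participants; bias falls back to mean uncertainty.")
    res <- mean_u - mean(mean_u)
  } else {
    res <- residuals(lm(mean_u ~ a_roc))
  }
  structure(as.numeric(res) + mean(mean_u), fallback = fallback)
}

#' Accuracy change from the initial to the final decision
#'
#' `mean(correct2) - mean(correct1)` over task trials (control trials are
#' excluded when a `condition` column is present).
#'
#' @param session A trial table with `correct1` and `correct2` columns.
#' @return A single numeric value.
#' @export
accuracy_change <- function(session) {
  stopifnot(all(c("correct1", "correct2") %in% names(session)))
  if ("condition" %in% names(session)) {
    session <- dplyr::filter(session, .data$condition == "task")
  }
  if (!nrow(session)) {
    abort("No task trials to compute accuracy change from.",
          class = "redecide_validation_error")
  }
  mean(session$correct2) - mean(session$correct1)
}

#' Goodman-Kruskal gamma for two ordinal variables
#'
#' `gamma = (C - D) / (C + D)` with C and D the numbers of concordant and
#' discordant pairs; pairs tied on either variable are excluded.
#'
#' @param x,y Ordinal vectors of equal length.
#' @return Gamma in [-1, 1].
#' @export
goodman_kruskal_gamma <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  tab <- table(x[ok], y[ok])
  nr <- nrow(tab); nc <- ncol(tab)
  conc <- 0; disc <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      nij <- tab[i, j]
      if (nij == 0) next
      if (i < nr && j < nc) {
        conc <- conc + nij * sum(tab[(i + 1):nr, (j + 1):nc])
      }
      if (i < nr && j > 1) {
        disc <- disc + nij * sum(tab[(i + 1):nr, 1:(j - 1)])
      }
    }
  }
  if (conc + disc == 0) {
    abort("All pairs are tied; gamma is undefined.",
          class = "redecide_undefined_gamma_error")
  }
  (conc - disc) / (conc + disc)
}

#' Cronbach's alpha across repeated sessions
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` where the item variances
#' `var_i` are the per-session variances across participants and `var_total`
#' is the variance of the per-participant session sums.
#'
#' @param mat Numeric matrix, participants x sessions; no missing cells.
#' @return Alpha (at most 1; can be negative).
#' @export
cronbach_alpha <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    abort("Cronbach's alpha requires complete data (no imputation is done).",
          class = "redecide_validation_error")
  }
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    abort("Cronbach's alpha needs >= 2 participants and >= 2 sessions.",
          class = "redecide_validation_error")
  }
  k <- ncol(mat)
  k / (k - 1) * (1 - sum(apply(mat, 2, var)) / var(rowSums(mat)))
}

#' Fisher-z test on one correlation or the difference of two
#'
#' Single sample: `z = atanh(r) * sqrt(n - 3)`. Two samples:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r,n First correlation and its sample size.
#' @param r2,n2 Optional second correlation and sample size.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A list with `z` and `p`.
#' @export
fisher_z_compare <- function(r, n, r2 = NULL, n2 = NULL,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (abs(r) >= 1 || (!is.null(r2) && abs(r2) >= 1)) {
    abort("|r| = 1 has an infinite Fisher transform.",
          class = "redecide_infinite_transform_error")
  }
  stopifnot(n >= 4, is.null(n2) || n2 >= 4)
  if (is.null(r2)) {
    z <- atanh(r) * sqrt(n - 3)
  } else {
    z <- (atanh(r) - atanh(r2)) / sqrt(1 / (n - 3) + 1 / (n2 - 3))
  }
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(z)),
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z))
  list(z = z, p = p)
}

# Metrics for one session's task trials. NA where undefined.
session_metrics <- function(tab) {
  task <- dplyr::filter(tab, .data$condition == "task")
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  tibble::tibble(
    n_trials = nrow(task),
    accuracy1 = mean(task$correct1),
    accuracy2 = mean(task$correct2),
    accuracy_change = accuracy2 - accuracy1,
    a_roc1 = safe(type2_roc(task$u1, task$correct1)$a_roc),
    a_roc2 = safe(type2_roc(task$u2, task$correct2)$a_roc),
    r_rt_uncertainty = safe(rt_uncertainty_correlation(task$rt1, task$u1)$r),
    mean_uncertainty = mean(task$u1),
    gamma_u1_reduction = safe(goodman_kruskal_gamma(task$u1, task$delta_u))
  )
}

reliability_alpha <- function(metrics, metric, tasks) {
  per_task <- purrr::map_dfr(tasks, function(tk) {
    wide <- metrics |>
      dplyr::filter(.data$task == tk) |>
      dplyr::select("participant", "session", dplyr::all_of(metric)) |>
      tidyr::pivot_wider(names_from = "session", values_from = dplyr::all_of(metric)) |>
      dplyr::select(-"participant") |>
      as.matrix()
    a <- tryCatch(cronbach_alpha(wide), error = function(e) NA_real_)
    tibble::tibble(metric = metric, scope = tk, alpha = a,
                   n_participants = nrow(wide), k = ncol(wide))
  })
  # across tasks: session-averaged metric per participant x task
  wide <- metrics |>
    dplyr::summarise(value = mean(.data[[metric]], na.rm = TRUE),
                     .by = c("participant", "task")) |>
    tidyr::pivot_wider(names_from = "task", values_from = "value") |>
    dplyr::select(-"participant") |>
    as.matrix()
  across <- tibble::tibble(
    metric = metric, scope = "across_tasks",
    alpha = tryCatch(cronbach_alpha(wide), error = function(e) NA_real_),
    n_participants = nrow(wide), k = ncol(wide)
  )
  dplyr::bind_rows(per_task, across)
}

#' Summarize a cohort trial table
#'
#' Computes the per-session, per-task metacognition metrics (uncertainty
#' sensitivity A_ROC for both decisions, RT-uncertainty correlation, mean
#' uncertainty, uncertainty bias, accuracy change, Goodman-Kruskal gamma
#' between initial uncertainty and uncertainty reduction), the reliability
#' report (Cronbach's alpha across sessions within task and across tasks)
#' and trial-level descriptive tables (error rate per uncertainty level for
#' both decisions; uncertainty reduction and final uncertainty per initial
#' uncertainty level). Control trials are excluded from all metacognition
#' metrics. The uncertainty bias is regressed across participants within
#' each session and task, then averaged per participant.
#'
#' @param cohort A tidy trial table (from [simulate_cohort()] or
#'   [read_trial_table()]) with `participant`, `session`, `task`,
#'   `condition` and the TrialRecord columns.
#' @return A list of class `redecide_cohort_summary` with elements
#'   `metrics` (per participant x session x task), `participant_metrics`
#'   (session-averaged), `reliability` and `tables`.
#' @export
summarize_cohort <- function(cohort) {
  required <- c("participant", "session", "task", "condition", "level",
                "correct1", "conf1", "u1", "rt1", "correct2", "conf2",
                "u2", "rt2", "delta_u")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "redecide_validation_error")
  }
  metrics <- cohort |>
    dplyr::group_by(.data$participant, .data$session, .data$task) |>
    dplyr::group_modify(~ session_metrics(.x)) |>
    dplyr::ungroup()

  # uncertainty bias: across participants within session x task
  metrics <- metrics |>
    dplyr::group_by(.data$session, .data$task) |>
    dplyr::mutate(uncertainty_bias = if (dplyr::n() >= 3 && !anyNA(.data$a_roc1)) {
      as.numeric(uncertainty_bias(.data$mean_uncertainty, .data$a_roc1))
    } else {
      NA_real_
    }) |>
    dplyr::ungroup()

  participant_metrics <- metrics |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) & !dplyr::matches("^n_trials$"),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_sessions = dplyr::n(),
                     .by = c("participant", "task"))

  # Figure-style tables are within-participant curves averaged across
  # participants (with the between-participant SEM), not pooled trials:
  # pooling heterogeneous observers can distort the per-level shape.
  tasktab <- dplyr::filter(cohort, .data$condition == "task")
  err_p <- dplyr::bind_rows(
    tasktab |>
      dplyr::summarise(value = mean(1 - .data$correct1),
                       .by = c("participant", "task", "u1")) |>
      dplyr::rename(u = "u1") |> dplyr::mutate(decision = "initial"),
    tasktab |>
      dplyr::summarise(value = mean(1 - .data$correct2),
                       .by = c("participant", "task", "u2")) |>
      dplyr::rename(u = "u2") |> dplyr::mutate(decision = "final")
  )
  tables <- list(
    error_rate_by_u = err_p |>
      dplyr::summarise(
        error_rate = mean(.data$value),
        sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
        n_participants = dplyr::n(), .by = c("task", "decision", "u")
      ) |>
      dplyr::arrange(.data$task, .data$decision, .data$u),
    reduction_by_u1 = tasktab |>
      dplyr::summarise(delta_u = mean(.data$delta_u), u2 = mean(.data$u2),
                       .by = c("participant", "task", "u1")) |>
      dplyr::rename(u = "u1") |>
      tidyr::pivot_longer(c("delta_u", "u2"), names_to = "quantity",
                          values_to = "value") |>
      dplyr::summarise(
        mean = mean(.data$value),
        sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else 0,
        n_participants = dplyr::n(), .by = c("task", "quantity", "u")
      ) |>
      dplyr::arrange(.data$task, .data$quantity, .data$u),
    accuracy_change_by_reduction = tasktab |>
      dplyr::summarise(accuracy_change = mean(.data$correct2 - .data$correct1),
                       n = dplyr::n(), .by = c("task", "delta_u")) |>
      dplyr::arrange(.data$task, .data$delta_u)
  )

  reliability <- if (dplyr::n_distinct(metrics$session) >= 2) {
    purrr::map_dfr(c("a_roc1", "accuracy_change", "mean_uncertainty",
                     "uncertainty_bias"),
                   reliability_alpha, metrics = metrics,
                   tasks = unique(metrics$task))
  } else {
    tibble::tibble(metric = character(), scope = character(),
                   alpha = numeric(), n_participants = integer(),
                   k = integer())
  }

  structure(list(metrics = metrics, participant_metrics = participant_metrics,
                 reliability = reliability, tables = tables),
            class = "redecide_cohort_summary")
}

#' @export
print.redecide_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d participants, %d sessions, tasks: %s\n",
              dplyr::n_distinct(x$metrics$participant),
              dplyr::n_distinct(x$metrics$session),
              paste(unique(x$metrics$task), collapse = ", ")))
  cat(sprintf("Mean A_ROC (initial) %.3f; mean accuracy change %+.3f\n",
              mean(x$metrics$a_roc1, na.rm = TRUE),
              mean(x$metrics$accuracy_change, na.rm = TRUE)))
  invisible(x)
}
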