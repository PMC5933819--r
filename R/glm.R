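# First-level fMRI design machinery for the decision-redecision paradigm:
# event schedules from trial tables, canonical double-gamma HRF, boxcar
# convolution at 0.1-s microtime, demeaned serially orthogonalized
# parametric modulators, VIF diagnostics, OLS fitting, PPI designs,
# trial-wise beta-series connectivity and oversampled ROI epoching.

#' Trial timing configuration
#'
#' Defaults reproduce the 15-s trial of the main experiment: 1-s cue, 2-s
#' stimulus, 2-s choice, 2-s confidence rating, 4-s re-presentation
#' (redecision), 2-s second choice, 2-s second confidence. Setting
#' `redecision = 2` reproduces the 13-s variant. All durations in seconds.
#'
#' @param cue,stim,choice,confidence,redecision,choice2,confidence2 Phase
#'   durations in seconds.
#' @param iti Inter-trial interval in seconds (not printed in the source
#'   protocol; fixed 2 s by default).
#' @return A list of class `timing_config` with a `trial_span` field.
#' @export
timing_config <- function(cue = 1, stim = 2, choice = 2, confidence = 2,
                          redecision = 4, choice2 = 2, confidence2 = 2,
                          iti = 2) {
  vals <- c(cue = cue, stim = stim, choice = choice, confidence = confidence,
            redecision = redecision, choice2 = choice2,
            confidence2 = confidence2, iti = iti)
  if (any(vals <= 0)) {
    abort("All timing durations must be positive.",
          class = "redecide_config_error")
  }
  out <- as.list(vals)
  out$trial_span <- cue + stim + choice + confidence + redecision +
    choice2 + confidence2
  structure(out, class = "timing_config")
}

#' Build the three-regressor event schedule for one run
#'
#' Regressor 1 (decision) is time-locked to the onset of the first stimulus
#' presentation with duration = presentation time + differential RT from the
#' mean control-trial RT. Regressor 2 (post-decision: metacognition and
#' redecision) is time-locked to the onset of the first confidence judgment
#' with duration = confidence report + re-presentation time + differential
#' redecision RT. Regressor 3 is the inter-trial interval. Per-trial
#' modulator values (initial uncertainty, RT, uncertainty reduction) ride
#' along for use by [build_design()].
#'
#' @param session A trial table for one run (rows in presentation order)
#'   with `condition`, `rt1`, `rt2`, `u1`, `delta_u` columns.
#' @param timing A [timing_config()].
#' @param zero_delta_rt If TRUE the differential-RT terms are forced to zero
#'   (nominal-duration schedule); otherwise they are computed against the
#'   mean RT of the run's control trials (0 when there are none).
#' @return A tibble of class `redecide_schedule`, one row per trial, with
#'   onsets/durations for the three regressors, the redecision-phase window
#'   and the modulator values; the timing config is attached as an
#'   attribute.
#' @export
build_schedule <- function(session, timing = timing_config(),
                           zero_delta_rt = FALSE) {
  stopifnot(inherits(timing, "timing_config"))
  required <- c("condition", "rt1", "rt2", "u1", "delta_u")
  missing <- setdiff(required, names(session))
  if (length(missing)) {
    abort(paste0("Schedule input is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "redecide_validation_error")
  }
  n <- nrow(session)
  is_ctl <- session$condition == "control"
  if (zero_delta_rt) {
    drt1 <- drt2 <- rep(0, n)
  } else {
    ctl_rt1 <- if (any(is_ctl)) mean(session$rt1[is_ctl]) else 0
    ctl_rt2 <- if (any(is_ctl)) mean(session$rt2[is_ctl]) else 0
    drt1 <- if (any(is_ctl)) session$rt1 - ctl_rt1 else rep(0, n)
    drt2 <- if (any(is_ctl)) session$rt2 - ctl_rt2 else rep(0, n)
  }
  tm <- timing
  t0 <- (seq_len(n) - 1) * (tm$trial_span + tm$iti)
  out <- tibble::tibble(
    trial = seq_len(n),
    condition = session$condition,
    onset_decision = t0 + tm$cue,
    dur_decision = tm$stim + drt1,
    onset_postdecision = t0 + tm$cue + tm$stim + tm$choice,
    dur_postdecision = tm$confidence + tm$redecision + drt2,
    onset_redecision = t0 + tm$cue + tm$stim + tm$choice + tm$confidence,
    dur_redecision = tm$redecision,
    onset_iti = t0 + tm$trial_span,
    dur_iti = tm$iti,
    u1 = session$u1,
    rt = session$rt1,
    delta_u = session$delta_u
  )
  if (any(out$dur_decision <= 0) || any(out$dur_postdecision <= 0)) {
    abort("Computed a non-positive event duration; check the RTs.",
          class = "redecide_schedule_error")
  }
  attr(out, "timing") <- timing
  attr(out, "run_duration") <- n * (tm$trial_span + tm$iti)
  class(out) <- c("redecide_schedule", class(out))
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' Response gamma density peaking at 6 s minus an undershoot gamma peaking
#' at 16 s with a 6:1 peak ratio, on 32 s of support, normalized to unit
#' peak.
#'
#' @param dt Sampling interval in seconds, in (0, 1].
#' @param peak,undershoot Gamma shape parameters (rate 1) of the response
#'   and undershoot components.
#' @param ratio Peak:undershoot amplitude ratio.
#' @param duration Kernel support in seconds.
#' @return Numeric vector sampled at `seq(0, duration, by = dt)`.
#' @export
canonical_hrf <- function(dt, peak = 6, undershoot = 16, ratio = 6,
                          duration = 32) {
  stopifnot(dt > 0, dt <= 1)
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = peak, rate = 1) -
    dgamma(t, shape = undershoot, rate = 1) / ratio
  h / max(h)
}

# Boxcar on the microtime grid; weights recycle per event.
microtime_boxcar <- function(grid, onset, duration, weight = 1) {
  weight <- rep_len(weight, length(onset))
  b <- numeric(length(grid))
  for (i in seq_along(onset)) {
    sel <- grid >= onset[i] & grid < onset[i] + duration[i]
    b[sel] <- b[sel] + weight[i]
  }
  b
}

convolve_downsample <- function(box, kernel, grid, vol_times) {
  x <- convolve(box, rev(kernel), type = "open")[seq_along(grid)]
  approx(grid, x, xout = vol_times, rule = 2)$y
}

# Demean a modulator over task trials; control trials get weight 0 so they
# do not enter the modulated regressor.
demean_modulator <- function(values, condition) {
  task <- condition == "task"
  out <- numeric(length(values))
  if (any(task)) out[task] <- values[task] - mean(values[task])
  out
}

#' Build an HRF-convolved design matrix with orthogonalized modulators
#'
#' Boxcars are laid down at microtime resolution, multiplied by the demeaned
#' modulator values (modulated columns), convolved with the canonical HRF
#' and sampled at the volume acquisition times. Modulator columns are then
#' serially orthogonalized: each is replaced by its residual against all
#' earlier design columns (plus an intercept), in `orth_order`. This is
#' equivalent to a stepwise regression in that order: the estimate for the
#' last-entered covariate equals its estimate in the joint un-orthogonalized
#' model.
#'
#' @param schedule A [build_schedule()] result.
#' @param modulators Character vector of schedule columns to use as
#'   parametric modulators of the post-decision regressor (default
#'   `c("u1", "rt", "delta_u")`).
#' @param tr Volume repetition time in seconds.
#' @param n_volumes Number of volumes (default: run duration / TR, rounded
#'   up).
#' @param orth_order Order of serial orthogonalization, or `NULL` to skip
#'   orthogonalization.
#' @param microtime Microtime resolution in seconds.
#' @param hrf_fun Function of `dt` returning the convolution kernel.
#' @return A list of class `redecide_design` with the design matrix `X`
#'   (columns `decision`, `postdecision`, `iti`, then `mod_<name>`), `tr`,
#'   `vol_times`, `orth_order` and `microtime`.
#' @export
build_design <- function(schedule, modulators = c("u1", "rt", "delta_u"),
                         tr = 2, n_volumes = NULL,
                         orth_order = modulators, microtime = 0.1,
                         hrf_fun = canonical_hrf) {
  stopifnot(inherits(schedule, "redecide_schedule"))
  bad <- setdiff(modulators, names(schedule))
  if (length(bad)) {
    abort(paste0("Unknown modulator column(s): ", paste(bad, collapse = ", ")),
          class = "redecide_schema_error")
  }
  if (!is.null(orth_order) && !setequal(orth_order, modulators)) {
    abort("orth_order must be a permutation of the modulators.",
          class = "redecide_schema_error")
  }
  run_dur <- attr(schedule, "run_duration")
  if (is.null(n_volumes)) n_volumes <- ceiling(run_dur / tr)
  grid <- seq(0, max(run_dur, n_volumes * tr), by = microtime)
  vol_times <- (seq_len(n_volumes) - 1) * tr
  kernel <- hrf_fun(microtime)

  base <- list(
    decision = microtime_boxcar(grid, schedule$onset_decision,
                                schedule$dur_decision),
    postdecision = microtime_boxcar(grid, schedule$onset_postdecision,
                                    schedule$dur_postdecision),
    iti = microtime_boxcar(grid, schedule$onset_iti, schedule$dur_iti)
  )
  mods <- list()
  for (mn in modulators) {
    w <- demean_modulator(schedule[[mn]], schedule$condition)
    mods[[paste0("mod_", mn)]] <-
      microtime_boxcar(grid, schedule$onset_postdecision,
                       schedule$dur_postdecision, weight = w)
  }
  X <- vapply(c(base, mods), convolve_downsample, numeric(n_volumes),
              kernel = kernel, grid = grid, vol_times = vol_times)

  if (!is.null(orth_order)) {
    for (mn in paste0("mod_", orth_order)) {
      j <- match(mn, colnames(X))
      earlier <- X[, seq_len(j - 1), drop = FALSE]
      X[, j] <- residuals(lm.fit(cbind(1, earlier), X[, j]))
    }
  }
  structure(list(X = X, tr = tr, vol_times = vol_times,
                 orth_order = orth_order, microtime = microtime,
                 schedule = schedule),
            class = "redecide_design")
}

#' @export
print.redecide_design <- function(x, ...) {
  cat(sprintf("fMRI design: %d volumes x %d regressors (TR %.1f s)\n",
              nrow(x$X), ncol(x$X), x$tr))
  cat(" columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Variance inflation factors of design columns
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column j on
#' the other selected columns plus an intercept. Perfectly collinear columns
#' are flagged with `Inf` rather than an error.
#'
#' @param design A `redecide_design` or a numeric matrix.
#' @param columns Columns (names or indices) to diagnose; default all.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design, columns = NULL) {
  X <- if (inherits(design, "redecide_design")) design$X else as.matrix(design)
  if (is.null(columns)) columns <- colnames(X) %||% seq_len(ncol(X))
  X <- X[, columns, drop = FALSE]
  if (ncol(X) < 2) {
    abort("VIF needs at least two columns.", class = "redecide_validation_error")
  }
  if (any(apply(X, 2, var) == 0)) {
    abort("VIF is undefined for constant columns.",
          class = "redecide_validation_error")
  }
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X) %||% as.character(seq_len(ncol(X)))
  out
}

#' Simulate ROI BOLD from a design
#'
#' `Y = X beta + AR(1) noise`; deterministic under the seed.
#'
#' @param design A `redecide_design`.
#' @param true_betas Numeric vector, one per design column.
#' @param sigma Innovation SD of the AR(1) noise.
#' @param rho AR(1) coefficient.
#' @param seed Integer seed.
#' @return Numeric BOLD vector, one value per volume.
#' @export
simulate_bold <- function(design, true_betas, sigma = 1, rho = 0.3, seed = 1L) {
  stopifnot(inherits(design, "redecide_design"),
            length(true_betas) == ncol(design$X), sigma >= 0, abs(rho) < 1)
  n <- nrow(design$X)
  with_seed_(seed, {
    innov <- rnorm(n, 0, sigma)
    noise <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    as.numeric(design$X %*% true_betas) + noise
  })
}

#' Fit an OLS GLM to a BOLD series
#'
#' @param y Numeric BOLD vector (one value per volume).
#' @param design A `redecide_design` or numeric matrix. An intercept is
#'   added automatically.
#' @return An object of class `redecide_glm_fit` with coefficients, standard
#'   errors, t statistics, residuals, R^2 and the VIFs of the design
#'   columns.
#' @export
fit_glm <- function(y, design) {
  X <- if (inherits(design, "redecide_design")) design$X else as.matrix(design)
  stopifnot(length(y) == nrow(X))
  Xi <- cbind(`(intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    abort("Design matrix is rank deficient.",
          class = "redecide_singular_design_error")
  }
  beta <- qr.coef(qrx, y)
  fitted <- as.numeric(Xi %*% beta)
  res <- y - fitted
  df <- length(y) - ncol(Xi)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- setNames(sqrt(diag(XtXinv) * sigma2), names(beta))
  tstat <- beta / se
  tss <- sum((y - mean(y))^2)
  structure(
    list(beta = beta, se = se, t = tstat, df = df,
         p = 2 * pt(-abs(tstat), df),
         residuals = res, fitted = fitted,
         r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
         sigma = sqrt(sigma2),
         vif = tryCatch(vif(X), error = function(e) NULL)),
    class = "redecide_glm_fit"
  )
}

#' @export
print.redecide_glm_fit <- function(x, ...) {
  cat(sprintf("OLS GLM fit: %d regressors, R^2 = %.3f\n",
              length(x$beta) - 1L, x$r_squared))
  print(round(rbind(beta = x$beta, t = x$t), 3))
  invisible(x)
}

#' Psycho-physiological interaction design and coupling fit
#'
#' The psychological factor is the initial-decision uncertainty level
#' (demeaned over task trials) as a modulated boxcar over the
#' redecision-phase window, convolved with the canonical HRF. The
#' physiological factor is the seed ROI series with its mean and its
#' uncertainty-related component removed (the residual of a regression on
#' the psychological factor plus intercept). The interaction is their
#' elementwise product. When a target series is supplied the full GLM
#' (physiological + psychological as confounds, plus interaction) is fitted
#' and the interaction coefficient is returned as the coupling strength.
#'
#' @param physio Seed ROI BOLD series (one value per volume).
#' @param schedule A [build_schedule()] result carrying per-trial `u1`.
#' @param tr Repetition time in seconds.
#' @param target Optional target ROI series to fit the PPI GLM on.
#' @param microtime Microtime resolution.
#' @param hrf_fun HRF kernel generator.
#' @return A list of class `redecide_ppi`: design matrix `X` (columns
#'   `physio`, `psych`, `interaction`), plus `fit` and `coupling` when a
#'   target was given.
#' @export
ppi_design <- function(physio, schedule, tr = 2, target = NULL,
                       microtime = 0.1, hrf_fun = canonical_hrf) {
  stopifnot(inherits(schedule, "redecide_schedule"))
  n_volumes <- length(physio)
  run_dur <- attr(schedule, "run_duration")
  grid <- seq(0, max(run_dur, n_volumes * tr), by = microtime)
  vol_times <- (seq_len(n_volumes) - 1) * tr
  w <- demean_modulator(schedule$u1, schedule$condition)
  psych <- convolve_downsample(
    microtime_boxcar(grid, schedule$onset_redecision, schedule$dur_redecision,
                     weight = w),
    hrf_fun(microtime), grid, vol_times
  )
  physio_resid <- residuals(lm(physio ~ psych))
  interaction <- physio_resid * psych
  X <- cbind(physio = physio_resid, psych = psych, interaction = interaction)
  out <- list(X = X, tr = tr)
  if (!is.null(target)) {
    out$fit <- fit_glm(target, X)
    out$coupling <- unname(out$fit$beta["interaction"])
  }
  structure(out, class = "redecide_ppi")
}

# Full nuisance design for connectivity: mean activity, the three modulated
# regressors and their pairwise interactions, following the functional
# connectivity recipe.
connectivity_nuisance <- function(schedule, tr, n_volumes, microtime,
                                  hrf_fun) {
  sched <- schedule
  prods <- list(
    u1_rt = sched$u1 * sched$rt,
    u1_delta_u = sched$u1 * sched$delta_u,
    rt_delta_u = sched$rt * sched$delta_u
  )
  for (nm in names(prods)) sched[[nm]] <- prods[[nm]]
  attr(sched, "timing") <- attr(schedule, "timing")
  attr(sched, "run_duration") <- attr(schedule, "run_duration")
  class(sched) <- class(schedule)
  build_design(sched,
               modulators = c("u1", "rt", "delta_u", names(prods)),
               tr = tr, n_volumes = n_volumes, orth_order = NULL,
               microtime = microtime, hrf_fun = hrf_fun)
}

#' Trial-wise beta-series functional connectivity
#'
#' Per ROI, the mean activity and the uncertainty/RT/uncertainty-reduction
#' modulated regressors and their interactions are regressed out; the
#' residual series is segmented into trials; each trial's segment is fitted
#' with a single HRF-convolved redecision-phase regressor, yielding one
#' regression value per trial; those values are correlated across trials
#' between every ROI pair, separately per condition.
#'
#' @param roi_mat Numeric matrix, volumes x ROIs (named columns).
#' @param schedule A [build_schedule()] result.
#' @param tr Repetition time in seconds.
#' @param conditions Character vector of conditions to report (default: the
#'   distinct conditions in the schedule).
#' @param microtime Microtime resolution.
#' @param hrf_fun HRF kernel generator.
#' @return An object of class `redecide_connectivity`: a named list of
#'   symmetric correlation matrices (one per condition) with unit diagonal,
#'   plus the per-trial beta series.
#' @export
trialwise_connectivity <- function(roi_mat, schedule, tr = 2,
                                   conditions = NULL, microtime = 0.1,
                                   hrf_fun = canonical_hrf) {
  roi_mat <- as.matrix(roi_mat)
  if (ncol(roi_mat) < 2) {
    abort("Connectivity needs at least two ROIs.",
          class = "redecide_validation_error")
  }
  if (is.null(colnames(roi_mat))) {
    colnames(roi_mat) <- paste0("roi", seq_len(ncol(roi_mat)))
  }
  n_volumes <- nrow(roi_mat)
  if (is.null(conditions)) conditions <- unique(schedule$condition)
  nuis <- connectivity_nuisance(schedule, tr, n_volumes, microtime, hrf_fun)
  resid_mat <- apply(roi_mat, 2, function(yy) residuals(lm(yy ~ nuis$X)))

  run_dur <- attr(schedule, "run_duration")
  grid <- seq(0, max(run_dur, n_volumes * tr), by = microtime)
  vol_times <- (seq_len(n_volumes) - 1) * tr
  kernel <- hrf_fun(microtime)
  tm <- attr(schedule, "timing")
  trial_len <- tm$trial_span + tm$iti

  n_trials <- nrow(schedule)
  betas <- matrix(NA_real_, n_trials, ncol(roi_mat),
                  dimnames = list(NULL, colnames(roi_mat)))
  for (i in seq_len(n_trials)) {
    t0 <- (i - 1) * trial_len
    seg <- which(vol_times >= t0 & vol_times < t0 + trial_len)
    if (length(seg) < 3) next
    reg <- convolve_downsample(
      microtime_boxcar(grid, schedule$onset_redecision[i],
                       schedule$dur_redecision[i]),
      kernel, grid, vol_times
    )[seg]
    if (var(reg) == 0) next
    for (r in seq_len(ncol(roi_mat))) {
      betas[i, r] <- coef(lm(resid_mat[seg, r] ~ reg))[2]
    }
  }
  mats <- lapply(conditions, function(cd) {
    rows <- which(schedule$condition == cd & !is.na(betas[, 1]))
    if (length(rows) < 3) {
      abort(sprintf("Fewer than 3 usable trials in condition '%s'.", cd),
            class = "redecide_insufficient_trials_error")
    }
    m <- cor(betas[rows, , drop = FALSE])
    diag(m) <- 1
    m
  })
  names(mats) <- conditions
  structure(list(matrices = mats, betas = betas,
                 condition = schedule$condition),
            class = "redecide_connectivity")
}

#' @export
print.redecide_connectivity <- function(x, ...) {
  for (cd in names(x$matrices)) {
    cat(sprintf("Condition '%s' (trial-wise beta-series correlations):\n", cd))
    print(round(x$matrices[[cd]], 3))
  }
  invisible(x)
}

#' Oversampled event-locked epochs of ROI time courses
#'
#' The time course is oversampled by linear interpolation (factor
#' `upsample`), epochs are extracted from each onset onward, averaged across
#' trials within participant, and then averaged across participants with
#' the between-participant SEM.
#'
#' @param series A numeric vector (one participant) or a list of numeric
#'   vectors (participants), one value per volume.
#' @param onsets Event onsets in seconds.
#' @param window Epoch length in seconds.
#' @param tr Repetition time in seconds.
#' @param upsample Oversampling factor (10 reproduces the source protocol;
#'   1 returns the raw volume samples).
#' @return A tibble with `time` (s from onset), `mean`, `sem` and `n`
#'   (participants). Epochs extending past the series end are truncated
#'   with a warning.
#' @export
epoch_timecourses <- function(series, onsets, window, tr = 2, upsample = 10) {
  if (!is.list(series)) series <- list(series)
  stopifnot(upsample >= 1, window > 0, length(onsets) >= 1)
  dt <- tr / upsample
  rel_t <- seq(0, window, by = dt)
  per_participant <- lapply(series, function(yy) {
    vol_times <- (seq_along(yy) - 1) * tr
    if (max(onsets) + window > max(vol_times)) {
      warn("Epoch window extends past the series end; epochs are truncated.")
    }
    ep <- vapply(onsets, function(on) {
      approx(vol_times, yy, xout = on + rel_t, rule = 1)$y
    }, numeric(length(rel_t)))
    rowMeans(ep, na.rm = TRUE)
  })
  m <- do.call(cbind, per_participant)
  n <- rowSums(!is.na(m))
  avg <- rowMeans(m, na.rm = TRUE)
  sem <- apply(m, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  })
  tibble::tibble(time = rel_t, mean = avg, sem = sem, n = n)
}
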