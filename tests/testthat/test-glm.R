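session_fixture <- function(n = 20, seed = 1, controls = 4) {
  ag <- agent_params()
  simulate_session(ag, list(n_runs = 1, trials_per_run = n - controls,
                            controls_per_run = controls), seed = seed)
}

test_that("the reconstructed schedule reproduces the printed trial timing", {
  sess <- session_fixture()
  sched <- build_schedule(sess, timing_config(), zero_delta_rt = TRUE)
  # with zero differential RT the decision regressor lasts the 2-s stimulus
  expect_true(all(sched$dur_decision == 2))
  expect_true(all(sched$dur_postdecision == 6)) # 2-s confidence + 4-s redecision
  # last event end minus cue onset = 15 s, every trial
  t0 <- sched$onset_decision - 1 # cue precedes the stimulus by 1 s
  expect_true(all(sched$onset_iti - t0 == 15))
  expect_true(all(diff(sched$onset_decision) > 0))
  expect_true(all(sched$onset_decision + sched$dur_decision <=
                    sched$onset_postdecision))

  # 2-s redecision variant: post-decision regressor shortens by 2 s
  sched4 <- build_schedule(sess, timing_config(redecision = 2),
                           zero_delta_rt = TRUE)
  expect_true(all(sched4$dur_postdecision == 4))
  expect_true(all(sched4$onset_iti - (sched4$onset_decision - 1) == 13))

  # differential RT against the control mean
  sched_rt <- build_schedule(sess, timing_config())
  ctl <- sess$condition == "control"
  expect_equal(sched_rt$dur_decision,
               2 + sess$rt1 - mean(sess$rt1[ctl]))
})

test_that("the canonical HRF has double-gamma shape", {
  h <- canonical_hrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1) # unit peak normalization
  expect_lt(abs(t[which.max(h)] - 5), 0.1 + 1e-9) # gamma(6,1) mode at 5 s
  expect_gt(sum(h) * 0.1, 0) # positive net response
  expect_lt(min(h), 0) # undershoot present
})

test_that("design construction demeans, convolves and orthogonalizes", {
  sess <- session_fixture()
  sched <- build_schedule(sess, timing_config())
  des <- build_design(sched)
  X <- des$X
  expect_equal(colnames(X), c("decision", "postdecision", "iti",
                              "mod_u1", "mod_rt", "mod_delta_u"))
  # serial orthogonalization: each modulator column orthogonal to all
  # earlier columns (and the constant)
  for (j in 4:6) {
    for (k in 1:(j - 1)) {
      expect_lt(abs(sum(X[, j] * X[, k])),
                1e-8 * sqrt(sum(X[, j]^2) * sum(X[, k]^2)))
    }
    expect_lt(abs(mean(X[, j])), 1e-10)
  }
  # a constant modulator demeans to an all-zero column
  sess2 <- sess
  sess2$u1 <- 3L
  des2 <- build_design(build_schedule(sess2, timing_config()),
                       orth_order = NULL)
  expect_true(all(des2$X[, "mod_u1"] == 0))
})

test_that("serial orthogonalization is equivalent to stepwise regression", {
  sess <- session_fixture(seed = 3)
  sched <- build_schedule(sess, timing_config())
  des_orth <- build_design(sched)
  des_raw <- build_design(sched, orth_order = NULL)
  y <- simulate_bold(des_raw, c(1, 0.8, 0.2, 0.5, -0.3, 0.4),
                     sigma = 0.7, rho = 0.2, seed = 9)
  fit_orth <- fit_glm(y, des_orth)
  fit_raw <- fit_glm(y, des_raw)
  # the last-entered covariate keeps its joint-model estimate exactly
  expect_equal(fit_orth$beta[["mod_delta_u"]], fit_raw$beta[["mod_delta_u"]],
               tolerance = 1e-10)
  # earlier columns' estimates are unaffected by later orthogonalized columns
  expect_equal(fit_orth$beta[["decision"]],
               fit_glm(y, build_design(sched, modulators = c("u1", "rt"),
                                       orth_order = c("u1", "rt")))$beta[["decision"]],
               tolerance = 1e-10)
  # orthogonalized modulators have VIF exactly 1 against each other
  v <- vif(des_orth, c("mod_u1", "mod_rt", "mod_delta_u"))
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-9)
})

test_that("VIF identifies orthogonal and collinear designs", {
  set.seed(4)
  # columns mutually orthogonal and orthogonal to the intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100, 3))))[, 2:4]
  colnames(Q) <- c("a", "b", "c")
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)
  dup <- cbind(x = Q[, 1], y = Q[, 1], z = Q[, 2])
  expect_true(is.infinite(vif(dup)[["x"]]))
  expect_error(vif(Q[, 1, drop = FALSE]), class = "redecide_validation_error")
})

test_that("noiseless BOLD is recovered exactly; pseudoinverse agrees", {
  sess <- session_fixture(seed = 5)
  des <- build_design(build_schedule(sess, timing_config()))
  betas <- c(1.2, 0.9, 0.1, 0.6, -0.2, 0.35)
  y0 <- simulate_bold(des, betas, sigma = 0, seed = 1)
  fit0 <- fit_glm(y0, des)
  expect_equal(unname(fit0$beta[-1]), betas, tolerance = 1e-10)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-10)

  y <- simulate_bold(des, betas, sigma = 1, rho = 0.4, seed = 2)
  fit <- fit_glm(y, des)
  expect_equal(unname(fit$beta), oracle_pinv_beta(y, des$X), tolerance = 1e-10)
  # residuals orthogonal to the design (OLS normal equations)
  expect_lt(max(abs(crossprod(cbind(1, des$X), fit$residuals))), 1e-8)

  # rho = 0 noise leaves residuals roughly uncorrelated at lag 1
  yw <- simulate_bold(des, betas, sigma = 1, rho = 0, seed = 3)
  rw <- fit_glm(yw, des)$residuals
  expect_lt(abs(cor(rw[-1], rw[-length(rw)])), 0.15)

  expect_error(fit_glm(y, cbind(des$X, dup = des$X[, 1])),
               class = "redecide_singular_design_error")
})

test_that("PPI design builds the textbook factors and recovers planted coupling", {
  sess <- session_fixture(n = 40, seed = 6, controls = 8)
  sched <- build_schedule(sess, timing_config())
  des <- build_design(sched)
  n_vol <- nrow(des$X)

  physio <- simulate_bold(des, c(1, 0.5, 0, 0.4, 0, 0), sigma = 0.5,
                          rho = 0.2, seed = 7)
  ppi <- ppi_design(physio, sched)
  # interaction invariant to a constant shift of the physiological series
  ppi_shift <- ppi_design(physio + 100, sched)
  expect_equal(ppi$X[, "interaction"], ppi_shift$X[, "interaction"],
               tolerance = 1e-8)
  # constant uncertainty: psychological factor and interaction vanish
  sess_const <- sess
  sess_const$u1 <- 2L
  ppi0 <- ppi_design(physio, build_schedule(sess_const, timing_config()))
  expect_true(all(abs(ppi0$X[, "psych"]) < 1e-12))
  expect_true(all(abs(ppi0$X[, "interaction"]) < 1e-12))

  # injection-recovery of a planted interaction coefficient
  b_true <- 0.8
  withr::with_seed(8, {
    target <- 0.3 * ppi$X[, "physio"] + 0.5 * ppi$X[, "psych"] +
      b_true * ppi$X[, "interaction"] + rnorm(n_vol, 0, 0.5)
  })
  fit <- ppi_design(physio, sched, target = target)
  se <- fit$fit$se[["interaction"]]
  expect_lt(abs(fit$coupling - b_true), 2 * se)
})

test_that("trial-wise beta-series connectivity recovers planted structure", {
  sess <- session_fixture(n = 130, seed = 10, controls = 10)
  sched <- build_schedule(sess, timing_config())
  des <- build_design(sched, orth_order = NULL)
  n_vol <- nrow(des$X)
  grid_reg <- des$X[, "postdecision"]

  # two ROIs sharing a planted trial-wise gain on the redecision response
  tm <- attr(sched, "timing")
  n_trials <- nrow(sched)
  withr::with_seed(11, {
    gain <- rnorm(n_trials, 1, 0.8)
    base <- vapply(seq_len(n_trials), function(i) {
      s <- sess[i, ]
      one <- sched[i, , drop = FALSE]
      attr(one, "timing") <- tm
      attr(one, "run_duration") <- attr(sched, "run_duration")
      class(one) <- class(sched)
      d1 <- build_design(one, modulators = character(0), orth_order = NULL,
                         n_volumes = n_vol)
      d1$X[, "postdecision"]
    }, numeric(n_vol))
    shared <- as.numeric(base %*% gain)
    roi_a <- shared + rnorm(n_vol, 0, 0.3)
    roi_b <- shared + rnorm(n_vol, 0, 0.3)
    roi_c <- rnorm(n_vol) # independent
  })
  conn <- trialwise_connectivity(cbind(a = roi_a, b = roi_b, c = roi_c),
                                 sched, conditions = "task")
  m <- conn$matrices$task
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_true(all(m >= -1 & m <= 1))
  expect_gt(m["a", "b"], 0.8)
  expect_lt(abs(m["a", "c"]), 0.35)
  expect_error(
    trialwise_connectivity(cbind(a = roi_a, b = roi_b), sched[1:2, ],
                           conditions = "task"),
    class = "redecide_insufficient_trials_error"
  )
})

test_that("epoching oversamples, truncates and averages as specified", {
  # constant series: flat epochs, zero SEM
  ep <- epoch_timecourses(rep(3, 50), onsets = c(10, 30), window = 12, tr = 2)
  expect_true(all(ep$mean == 3))
  expect_true(all(ep$sem == 0))
  expect_equal(nrow(ep), 12 / (2 / 10) + 1)

  # upsample = 1 returns the raw volume samples
  y <- sin(seq(0, 6, length.out = 40))
  ep1 <- epoch_timecourses(y, onsets = 10, window = 10, tr = 2, upsample = 1)
  vol_idx <- (10 / 2 + 1):(10 / 2 + 6)
  expect_equal(ep1$mean, y[vol_idx])

  # a planted HRF-shaped response peaks where the kernel peaks
  h <- canonical_hrf(0.1)
  tr_grid <- seq(0, 32, by = 0.1)
  y2 <- approx(tr_grid, h, xout = seq(0, 38, by = 2), rule = 2)$y
  ep2 <- epoch_timecourses(y2, onsets = 0, window = 20, tr = 2, upsample = 10)
  # interpolation cannot beat the TR; peak within one volume of 5 s
  expect_lte(abs(ep2$time[which.max(ep2$mean)] - 5), 2)

  # window past the end of the series triggers the truncation warning
  expect_warning(epoch_timecourses(rep(1, 10), onsets = 16, window = 10, tr = 2),
                 "truncated")

  # multiple participants: SEM between participants
  ep3 <- epoch_timecourses(list(rep(1, 30), rep(2, 30)), onsets = 10,
                           window = 8, tr = 2)
  expect_true(all(ep3$mean == 1.5))
  expect_true(all(abs(ep3$sem - 0.5) < 1e-12))
  expect_true(all(ep3$n == 2))
})
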