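test_that("degenerate ROC shapes give the textbook areas", {
  # identical ratings on every trial: one interior point on the diagonal
  expect_equal(type2_roc(rep(2L, 10), c(rep(1, 6), rep(0, 4)))$a_roc, 0.5)
  # perfect separation
  u <- c(rep(4L, 5), rep(1L, 5))
  correct <- c(rep(0, 5), rep(1, 5))
  expect_equal(type2_roc(u, correct)$a_roc, 1.0)
  # undefined without both outcome classes
  expect_error(type2_roc(1:4, rep(1, 4)), class = "redecide_undefined_roc_error")
  expect_error(type2_roc(1:4, rep(0, 4)), class = "redecide_undefined_roc_error")
})

test_that("A_ROC equals the independent threshold-sweep and rank oracles", {
  # corrects at levels (1,2,3,4) = (10,5,3,2) trials, errors (1,2,3,4) each
  u <- c(rep(1L, 10), rep(2L, 5), rep(3L, 3), rep(4L, 2),
         rep(1L, 1), rep(2L, 2), rep(3L, 3), rep(4L, 4))
  correct <- c(rep(1, 20), rep(0, 10))
  got <- type2_roc(u, correct)$a_roc
  expect_equal(got, oracle_sweep_auc(u, correct), tolerance = 1e-12)
  expect_equal(got, oracle_rank_auc(u, correct), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    u <- sample(1:4, n, replace = TRUE)
    correct <- sample(0:1, n, replace = TRUE, prob = c(0.4, 0.6))
    if (all(correct == correct[1])) next
    a <- type2_roc(u, correct)$a_roc
    expect_equal(a, oracle_rank_auc(u, correct), tolerance = 1e-12)
    expect_equal(a, oracle_sweep_auc(u, correct), tolerance = 1e-12)
    # both framings agree
    expect_equal(type2_roc(u, correct, framing = "confidence")$a_roc, a,
                 tolerance = 1e-12)
  }
})

test_that("A_ROC is invariant to strictly monotone relabeling of the ratings", {
  set.seed(3)
  u <- sample(1:4, 80, replace = TRUE)
  correct <- sample(0:1, 80, replace = TRUE)
  relabeled <- c(2, 10, 11, 40)[u]
  expect_equal(type2_roc(relabeled, correct)$a_roc,
               type2_roc(u, correct)$a_roc, tolerance = 1e-12)
})

test_that("ROC points are monotone and anchored", {
  set.seed(11)
  u <- sample(1:4, 100, replace = TRUE)
  correct <- sample(0:1, 100, replace = TRUE)
  pts <- tidy(type2_roc(u, correct))
  expect_equal(pts$fa[1], 0); expect_equal(pts$hit[1], 0)
  expect_equal(pts$fa[nrow(pts)], 1); expect_equal(pts$hit[nrow(pts)], 1)
  expect_true(all(diff(pts$fa) >= 0))
  expect_true(all(diff(pts$hit) >= 0))
})

test_that("RT-uncertainty correlation matches the closed form and rejects degenerate input", {
  u <- rep(1:4, each = 5)
  rt <- 0.3 + 0.2 * u
  res <- rt_uncertainty_correlation(rt, u)
  expect_equal(res$r, 1)
  expect_error(rt_uncertainty_correlation(rep(1, 10), rep(2, 10)),
               class = "redecide_undefined_correlation_error")
  set.seed(5)
  rt2 <- rnorm(50, 1, 0.2)
  u2 <- sample(1:4, 50, replace = TRUE)
  res2 <- rt_uncertainty_correlation(rt2, u2, alternative = "two.sided")
  expect_equal(res2$t, res2$r * sqrt(48) / sqrt(1 - res2$r^2))
})

test_that("uncertainty bias is the A_ROC-orthogonal residual plus the grand mean", {
  # constant regressor: fall back to the mean uncertainty itself
  expect_warning(b <- uncertainty_bias(c(1.5, 2.5, 3.5), rep(0.8, 3)))
  expect_equal(as.numeric(b), c(1.5, 2.5, 3.5))
  expect_true(attr(b, "fallback"))

  # perfectly linear relation: every bias equals the grand mean
  a_roc <- c(0.6, 0.7, 0.8, 0.9)
  mean_u <- 5 - 3 * a_roc
  b2 <- uncertainty_bias(mean_u, a_roc)
  expect_equal(as.numeric(b2), rep(mean(mean_u), 4))

  # planted offsets (independent of sensitivity): rank order recovered exactly
  set.seed(2)
  a3 <- runif(15, 0.55, 0.95)
  planted <- residuals(lm(seq(-0.7, 0.7, length.out = 15) ~ a3))
  b3 <- uncertainty_bias(2 + 1.2 * a3 + planted, a3)
  expect_equal(cor(rank(b3), rank(planted)), 1) # Spearman rho = 1
  expect_equal(sum(b3), 15 * mean(2 + 1.2 * a3 + planted))
})

test_that("accuracy change is the plain difference over task trials and antisymmetric", {
  tab <- make_trial_tab(n = 20, correct1 = rep(c(1, 0), 10),
                        correct2 = c(rep(1, 12), rep(0, 8)))
  expect_equal(accuracy_change(tab), 12 / 20 - 10 / 20)
  swapped <- dplyr::rename(tab, correct1 = "correct2", correct2 = "correct1")
  expect_equal(accuracy_change(swapped), -accuracy_change(tab))
  same <- make_trial_tab(n = 10)
  expect_equal(accuracy_change(same), 0)
  # control trials are excluded
  tab$condition[1:10] <- "control"
  expect_equal(accuracy_change(tab),
               mean(tab$correct2[11:20]) - mean(tab$correct1[11:20]))
})

test_that("redecision gain increases the accuracy change", {
  acc_chg <- vapply(c(1, 2), function(g) {
    ag <- agent_params(g = g)
    accuracy_change(simulate_trial(ag, level = 5, seed = 40, n = 3000))
  }, numeric(1))
  expect_gt(acc_chg[2], acc_chg[1] + 0.02)
})

test_that("gamma matches the brute-force pair count and handles ties by exclusion", {
  expect_equal(goodman_kruskal_gamma(1:6, c(2, 4, 5, 7, 8, 9)), 1)
  expect_equal(goodman_kruskal_gamma(1:6, 6:1), -1)
  # 4x4 contingency-style fixture
  x <- rep(1:4, times = c(3, 5, 4, 2))
  y <- c(1, 1, 2, 1, 2, 2, 3, 4, 2, 3, 3, 3, 4, 4)
  expect_equal(goodman_kruskal_gamma(x, y), oracle_gamma(x, y),
               tolerance = 1e-12)
  set.seed(13)
  for (i in 1:15) {
    xx <- sample(1:4, 40, replace = TRUE)
    yy <- sample(1:5, 40, replace = TRUE)
    expect_equal(goodman_kruskal_gamma(xx, yy), oracle_gamma(xx, yy),
                 tolerance = 1e-12)
  }
  expect_error(goodman_kruskal_gamma(rep(1, 5), 1:5),
               class = "redecide_undefined_gamma_error")
})

test_that("Cronbach alpha matches its closed form and limit cases", {
  set.seed(21)
  base <- rnorm(30)
  identical_cols <- cbind(base, base, base)
  expect_equal(cronbach_alpha(identical_cols), 1)
  noise <- matrix(rnorm(30 * 8), 30, 8)
  expect_lt(abs(cronbach_alpha(noise)), 0.35)
  # 3 participants x 5 sessions fixture against the hand-evaluated formula
  fix <- matrix(c(1, 2, 3, 2, 3, 4, 2, 2, 5, 3, 4, 4, 1, 3, 3), nrow = 3)
  expect_equal(cronbach_alpha(fix), oracle_alpha(fix), tolerance = 1e-12)
  expect_error(cronbach_alpha(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "redecide_validation_error")
})

test_that("Fisher-z statistics match the transform algebra", {
  expect_equal(fisher_z_compare(0, 30)$z, 0)
  expect_equal(fisher_z_compare(0.5, 25, 0.5, 40)$z, 0)
  res <- fisher_z_compare(0.61, 21, alternative = "greater")
  expect_equal(res$z, atanh(0.61) * sqrt(18))
  expect_equal(res$p, pnorm(atanh(0.61) * sqrt(18), lower.tail = FALSE))
  expect_error(fisher_z_compare(1, 10),
               class = "redecide_infinite_transform_error")
})

test_that("summarize_cohort aggregates sessions and validates its input", {
  # near-homogeneous cohort at the default observer parameters
  prm <- sample_cohort_params(6, seed = 9, sigma_meta_sdlog = 0.2,
                              crit_shift_sd = 0)
  cohort <- simulate_cohort(prm, sessions_per_participant = 1, seed = 10,
                            tasks = "sudoku",
                            config = list(n_runs = 2, trials_per_run = 500,
                                          controls_per_run = 10))
  summ <- summarize_cohort(cohort)
  expect_equal(nrow(summ$metrics), 6)
  expect_equal(nrow(summ$reliability), 0) # single session: no reliability
  expect_true(all(summ$metrics$n_trials == 1000)) # controls excluded
  # error rate grows with reported uncertainty, in both decision phases
  err <- summ$tables$error_rate_by_u
  for (dec in c("initial", "final")) {
    curve <- err[err$decision == dec, ]
    expect_true(all(diff(curve$error_rate[order(curve$u)]) > 0))
  }

  expect_error(summarize_cohort(dplyr::select(cohort, -"conf1")),
               class = "redecide_validation_error")
  expect_error(summarize_cohort(dplyr::select(cohort, -"delta_u")),
               "delta_u", class = "redecide_validation_error")
})
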