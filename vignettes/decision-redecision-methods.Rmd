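---
title: "Decision–redecision metacognition: models, metrics and design machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision–redecision metacognition: models, metrics and design machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redecide)
```

## The paradigm

In a decision–redecision trial a participant makes a fast four-alternative
decision (a 4×4 Sudoku target digit, or the net direction of a random-dot
kinematogram), rates confidence on a 1–4 scale, then immediately sees the
identical stimulus again, decides again and rates confidence again. Decision
*uncertainty* is the inverse of the confidence rating, `u = 5 − conf`.
Because there is no feedback, any improvement between the two decisions must
come from the participant's own monitoring of decision uncertainty
(metacognitive monitoring) and the consequent reallocation of effort
(metacognitive control). Trial difficulty is driven by an adaptive
staircase — one level harder after two consecutive correct initial
decisions, one level easier after two consecutive errors — which pins
initial accuracy near 50% (chance is 25%).

The package implements that world end to end: the task engines, a
generative observer that produces realistic trial tables, the behavioral
metacognition statistics, and the first-level fMRI design machinery the
paradigm requires. Everything is exercised on synthetic data; no real data
ship with the package.

## Task engines

### Sudoku difficulty

A 4×4 Sudoku grid must contain each digit 1–4 exactly once per row, column
and 2×2 corner box. `solve_sudoku()` enumerates completions by exhaustive
backtracking and is the uniqueness oracle: a well-posed puzzle has exactly
one completion (the empty grid has 288).

Difficulty grading uses the smallest standard rule set that solves every
uniquely-completable 4×4 puzzle: *naked singles* (a cell with one remaining
candidate) and *hidden singles* (a digit with one remaining place in a
unit). One logic step fills one cell. `score_sudoku_difficulty()` reports
two statistics:

* `difficulty_steps` — the minimum number of logic inferences needed to
  arrive at the complete solution. Each inference fills exactly one cell,
  so once rule-solvability is verified by propagation this equals the
  number of empty cells. It spans 1–12 and feeds the 10-level ladder
  (steps 1–9 → levels 1–9, ≥10 → level 10).
* `target_steps` — the minimum number of inferences after which the target
  cell itself can be filled, minimized over inference orderings by
  breadth-first search over reachable partial grids.

Why two numbers? We initially graded difficulty by `target_steps` alone,
but exhaustive enumeration over *all* uniquely-solvable 4×4 puzzles (all
twelve digit-relabeling classes of the 288 complete grids, every subset of
givens) shows that the target chain never exceeds 4 under this rule set —
the board is simply too small for long forced chains — so it cannot span a
10-level ladder. The number of cells that must be inferred does span the
ladder, grows monotonically with the length of the solving procedure, and
is what a solver experiences as workload; it is therefore the graded
statistic, with the target chain kept as a secondary diagnostic. The same
enumeration shows every uniquely-solvable 4×4 puzzle *is* solvable by naked
and hidden singles, so the "beyond-ladder" error can only fire on puzzles
without a unique completion.

`generate_sudoku()` rejection-samples: complete a random grid, remove cells
in random order while uniqueness is preserved (the first removed cell is
the target, so it is empty in every prefix), and accept the removal prefix
whose re-grade matches the requested level. Generator and grader are a
fixed point by construction, and the acceptance suite re-checks 50 puzzles
per level.

### Random-dot motion

`coherence_for_level()` maps levels 1–10 onto coherences 51.2%…1.6%.
The ladder is log-spaced — the convention for coherence ladders in
psychophysics; only the endpoints are printed in the source protocol — and
level 0 is the 100%-coherence control. `generate_rdm_frames()` implements
~300 dots in a 3° aperture at 8°/s with a 3-frame lifetime, staggered
re-spawns, and wrap-around re-entry. The protocol's printed dot "density:
2.0%" is dimensionally ambiguous (300 dots of radius 0.08° in a 3° aperture
cover ~21% of its area), so the dot count is primitive and a derived
`density` field is recorded as metadata only.

### Staircase

`staircase_update()` is the two-consecutive rule with clamping at levels 1
and 10 and a streak reset after every level change. For any psychometric
function that decreases across levels and crosses 50%, the chain's
stationary accuracy is ~50%: transitions up and down balance where
p(correct)² = p(error)². This is verified both directly on the Markov chain
and through the full observer.

## The generative observer

The analyses need trial tables with the behavioral structure the paradigm
produces. No generative model is given in the source material, so the
package's observer is a deliberately minimal signal-detection account with
a separate second-order readout — the "separate metacognitive monitor"
architecture — with these components:

* **Decision** — a four-alternative race: the true option's evidence is
  `N(a·δ_L, 1)`, distractors are `N(0, 1)`, the choice is the maximum.
  `δ_L` is calibrated numerically per level so marginal accuracy follows
  the logistic psychometric `acc(L) = 0.25 + 0.75/(1 + exp((L − m)/s))`,
  with midpoint `m = 5` (the level trained participants reach) and slope
  `s = 1.5` (accuracy ≈ 95% at level 1, ≈ 28% at level 10).
* **Attention variability** — `a` is a lognormal per-trial efficiency
  multiplier (mean 1, log-sd `s_att = 1.4`). Without it, an
  accuracy-matched ideal observer caps near A_ROC ≈ 0.67 under the
  staircase — far below what humans show — because the evidence that
  misleads the decision also misleads confidence. Trial-to-trial efficiency
  fluctuation is the standard resolution: blank moments produce guesses the
  monitor can flag.
* **Second-order readout** — the monitor holds a private evidence sample of
  precision `kappa = 16` relative to the decision sample and reads out the
  Bayesian posterior that the chosen option is correct; confidence is this
  log-odds readout plus `N(0, sigma_meta)` noise, binned at criteria
  (−0.6, 0.3, 1.2) (posterior ≈ 0.35/0.57/0.77). `sigma_meta` is *the*
  metacognitive-ability dial: 0 gives a near-ideal error monitor
  (A_ROC ≥ 0.9 across the difficulty range), large values drive A_ROC to
  0.5. The default 1.5 puts a single session in the empirically typical
  0.8–0.9 band under the staircase.
* **Redecision** — extra evidence is accumulated with precision
  `(g_t − 1)` where the engaged gain grows with the reported initial
  uncertainty, `g_t = 1 + (g − 1)(u1 − 1)/3`: metacognitive control
  allocates effort where uncertainty was detected. `g = 2` means the
  second look doubles the evidence on maximally uncertain trials; `g = 1`
  adds nothing, so the redecision reproduces the initial choice and
  accuracy exactly. The phase-2 confidence readout adds a deliberation
  gain (`boost = 1.5` on the log-odds scale) on engaged trials: having
  re-examined the stimulus raises reported confidence even when the
  posterior barely moves, which is what keeps mean uncertainty reduction
  non-negative at every initial uncertainty level, as observed empirically.
  A plain Bayesian re-read without it *increases* reported uncertainty on
  initially mid-confidence trials (posterior polarization), which the
  empirical pattern rules out.
* **Response times** — linear in reported uncertainty,
  `rt = 0.5 + 0.25·u + N(0, 0.15)` s, clipped to the (0.2, 2] s window.
* **Lapses** — with probability 0.02 the initial choice is uniform.
  Control trials (level 0) are calibrated to 95% accuracy.

`sample_cohort_params()` plants the population structure the reliability
analyses assume: `sigma_meta` and the confidence-criterion shift are drawn
once per participant (stable traits → uncertainty sensitivity and
uncertainty bias are reliable across sessions and tasks), while the
redecision gain is drawn independently per task (task-bound control
propensity → accuracy change is consistent within a task but dissociates
across tasks).

What the generator does *not* emulate: sequential dependencies beyond the
staircase, learning or fatigue within a session, response omissions,
post-decisional evidence accumulation as a process in time, and any
neural dynamics. A green test therefore establishes that the analysis
stack recovers planted behavioral structure — not that this observer is
the true model of human redecision.

## Behavioral metrics

* `type2_roc()` — the uncertainty ratings act as thresholds for flagging
  errors: hit rate `P(u ≥ k | error)` against false-alarm rate
  `P(u ≥ k | correct)`, anchored at (0,0) and (1,1); `a_roc` is the
  trapezoidal area. This equals the rank statistic P(a random error trial
  carries higher uncertainty than a random correct trial, ties ½), which
  the tests assert to 1e-12, and it is invariant to monotone relabeling of
  the ratings. The complementary confidence framing is exposed and yields
  the same area. All-correct or all-error input is an error, never a
  silent 0.5. No parametric ROC model is fitted — the construction is
  deliberately nonparametric.
* `rt_uncertainty_correlation()` — Pearson r with its t statistic,
  one-tailed positive by default (the empirically expected direction);
  tail-edness is an argument because the source analyses mix one- and
  two-tailed tests without a stated rule.
* `uncertainty_bias()` — mean uncertainty with the A_ROC component
  regressed out (OLS across participants), plus the grand mean. The
  regression runs across participants within a session–task cell and the
  per-participant results are then averaged across sessions; the source
  text does not say whether the regression runs across participants or
  sessions, and the across-participant reading matches "individual bias"
  semantics.
* `accuracy_change()` — mean final minus mean initial accuracy over task
  trials.
* `goodman_kruskal_gamma()` — (C − D)/(C + D) over concordant/discordant
  pairs, ties dropped (the standard definition), computed from the
  contingency table and asserted against an O(n²) pair-count oracle.
* `cronbach_alpha()` — the classical k/(k−1)(1 − Σvar_i/var_total) form;
  missing cells are an error, never imputed.
* `fisher_z_compare()` — one- and two-sample Fisher-z tests.
* `summarize_cohort()` — per-session metrics, per-participant averages,
  the reliability report (alpha across sessions within task and across
  tasks), and figure-style descriptive tables. Control trials are excluded
  from every metacognition metric. The descriptive tables average
  *within-participant* curves across participants (with between-participant
  SEM) rather than pooling trials: pooling heterogeneous observers can
  make a per-level error-rate curve non-monotone even when every
  individual curve is monotone. No multiple-testing correction is applied
  anywhere in this module.

## First-level fMRI machinery

`build_schedule()` reconstructs the three-regressor trial model from the
printed timing (1-s cue, 2-s stimulus, 2-s choice, 2-s confidence, 4-s
re-presentation, 2-s choice, 2-s confidence; 15 s per trial): regressor 1
at stimulus onset with duration 2 s + ΔRT, regressor 2 at the first
confidence judgment with duration 2 s + 4 s + ΔRT, regressor 3 over the
ITI. ΔRT is the trial's RT minus the mean control-trial RT. The ITI is not
printed; the default is a fixed 2 s and it is configurable. Setting
`redecision = 2` reproduces the 13-s protocol variant. Confidence-report
durations are not simulated, so the nominal 2-s slot stands in — the
recorded-report option documented for real data ingestion reduces to this
default when the field is absent.

`build_design()` lays boxcars on a 0.1-s microtime grid (matching the 10×
oversampling used for ROI epoching), multiplies modulated copies of
regressor 2 by *demeaned* per-trial modulators (initial uncertainty, RT,
uncertainty reduction; control trials carry weight 0), convolves with the
canonical double-gamma HRF (peaks at 6 s and 16 s, 6:1 ratio, 32-s support,
unit peak — "canonical" is all the source states, so the standard
parameters are exposed as arguments), samples at the volume times, and
serially orthogonalizes the modulator columns (default order u1 → RT → Δu,
reversible). Each orthogonalized column is the residual against *all*
earlier columns plus an intercept, which makes the construction exactly
equivalent to stepwise regression: the last-entered covariate keeps its
joint-model estimate (asserted to 1e-10), and whether modulators are
convolved after multiplication with the boxcar (our choice) or separately
is immaterial for the demeaned boxcar-weighting used here but is stated
for reproducibility.

`vif()` is 1/(1 − R²) of one column on the others plus intercept, with
perfect collinearity flagged as `Inf` rather than thrown. `fit_glm()` is
plain OLS by QR with an automatic intercept — deliberately no prewhitening,
since the source describes none. `simulate_bold()` adds AR(1) noise for
testing. A consequence the tests document honestly: OLS nominal 95%
intervals are exactly calibrated under white noise (coverage ≈ 0.95) and
degrade as the AR(1) coefficient grows (≈ 0.91 at ρ = 0.15, ≈ 0.87 at
ρ = 0.3 for the uncertainty-modulator column of the standard design). The
whole-stack calibration check therefore plants ρ = 0.15, a mild
autocorrelation representative of residuals after standard preprocessing;
inference from heavily autocorrelated series would need prewhitening,
which is out of scope.

`ppi_design()` builds the psycho-physiological interaction: psychological
factor = demeaned initial uncertainty as a modulated boxcar over the
redecision window, HRF-convolved; physiological factor = the seed series
with its mean and uncertainty-related component regressed out; interaction
= their product; both factors enter the GLM as confounds alongside the
interaction. `trialwise_connectivity()` implements beta-series
connectivity: per ROI, regress out the mean and the three modulated
regressors and their pairwise interactions, segment the residual per
trial, fit one HRF-convolved redecision regressor per trial segment, and
correlate the per-trial values across ROI pairs within condition.
`epoch_timecourses()` oversamples by linear interpolation (factor 10),
extracts event-locked epochs, and averages across trials then participants
with the between-participant SEM.

## Numerical choices and degenerate inputs

* Signal-strength calibration inverts the 4AFC accuracy integral
  `E_z[Φ(z + δ)³]` by bisection on a fixed quadrature grid (801 + 21
  points); the calibration is memoized per psychometric parameter set.
* The posterior readout is clamped to [1e-6, 1 − 1e-6] before the log-odds
  transform, bounding the readout at ±13.8; "infinite meta-noise" in tests
  therefore means noise large against that bound.
* Orthogonality assertions use the relative inner-product criterion
  |x·y| < 1e-8 · |x||y|.
* Degenerate inputs fail loudly with classed conditions: all-correct ROCs,
  zero-variance correlations, all-tied gamma, missing reliability cells,
  rank-deficient designs, non-unique puzzles, out-of-range levels.
* All randomness flows through explicit `seed` arguments (`withr`-scoped,
  so the caller's RNG state is never touched); the pipeline fans a single
  seed out to per-stage child seeds so stages can be rerun independently.

## Known limitations

* The difficulty grader's rule set (naked + hidden singles) is one
  defensible reading of "logic operation steps"; other rule sets would
  re-bin the ladder, though any reasonable set orders puzzles similarly on
  a 4×4 board.
* The observer's uncertainty-proportional gain and deliberation boost are
  one plausible instantiation of metacognitive control; the magnitude of
  the uncertainty-reduction/accuracy-change coupling is a free parameter,
  not an estimate.
* The reconstructed design's decision/post-decision collinearity (VIF
  ≈ 1.48 under the nominal timing with 2-s ITIs) depends on unprinted
  protocol details — the actual RT-dependent durations and the ITI
  distribution; plausible settings of those span roughly 1.2–2.5.
* OLS interval coverage under strong autocorrelation is knowingly below
  nominal (no prewhitening by design).
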