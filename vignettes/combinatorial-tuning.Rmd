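---
title: "Analysing combinatorial stimulus tuning and supra-linear summation"
author: "combtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing combinatorial stimulus tuning and supra-linear summation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combtune)
```

## The scientific problem

When a sensory cortex is probed with combinations of discrete stimulus
elements — five whiskers touching five pistons, or five patches of drifting
gratings — each of the $2^5 - 1 = 31$ possible element subsets is a distinct
stimulus. Two questions arise. First, how does a single neuron *summate*
across elements: does its response to a combination equal the sum of its
responses to the components (linear), fall short (sub-linear, the classical
surround-suppression picture), or exceed it (supra-linear facilitation)?
Second, do the preferred stimuli of the population *cover* the combinatorial
space, so that every combination is encoded by its own small ensemble — a
sparse, comprehensive (overcomplete) population code?

`combtune` implements the full analysis chain needed to answer both
questions from two-photon calcium-imaging sessions, together with a
synthetic-session generator with known ground truth so that every stage can
be validated end to end without any recorded data.

## Pipeline overview

1. **Preprocessing** (`neuropil_correct`, `dff_catch_baseline`,
   `dff_percentile_baseline`, `deconvolve`): raw ROI fluorescence
   $R_i(t)$ is corrected by the scaled neuropil channel,
   $F_i(t) = R_i(t) - k_i N_i(t)$ with
   $k_i = \min_t R_i(t)/N_i(t)$ clamped to $[0, 1]$ — the largest
   coefficient for which the corrected trace can never go negative.
   $\Delta F/F$ uses a baseline $f_0$ from the last second of the
   inter-trial interval after catch (no-stimulus) trials, or a sliding
   20th-percentile filter (3,000 frames) for sessions with short
   inter-stimulus intervals, where nonnegative sparse deconvolution
   (an exponential-kernel $\ell_1$-penalized least-squares problem solved
   by FISTA) recovers event rates.
2. **Trial responses** (`trial_responses`, `filter_responses`,
   `responsiveness`): a trial's response is the mean signal over the 1-s
   stimulus window. Trials are filtered by behavioural state (running:
   mean speed > 10 cm/s; stationary: max |speed| < 1 cm/s), and outliers
   are removed by the median rule (beyond 2.3 IQR from the median, type-7
   quantiles), per neuron and condition, before any analysis. A condition
   is a *significant response* if its mean is positive **and** a Welch
   two-sample t-test against the catch responses survives
   Benjamini–Hochberg correction across the neuron's 31 conditions.
   Neurons are classed `single` / `multi` / `combination` / `none` from
   their significant single- and multi-element conditions.
3. **Tuning and summation** (`tuning_curve`, `linear_difference`,
   `population_matrices`, `sorted_linear_difference`,
   `supralinearity_test`): catch-subtracted tuning curves with percentile
   bootstrap CIs; the **linear difference**
   $\mathrm{ld}(s) = r(s) - \sum_{j \in s} r(\{j\})$ for every
   multi-element condition; cross-validated population matrices
   (reliability gate $r > 0.5$ between partition tuning curves, rows
   sorted by the train-partition preferred stimulus, held-out partition
   displayed); and a per-neuron two-one-sided bootstrap test of whether
   the top-ranked stimulus is more supra-linear than the other
   multi-element stimuli.
4. **LN model vs oracle** (`fit_ln`, `oracle_predict`, `compare_models`):
   the seven-parameter linear–nonlinear tuning model
   $r_s = a\, f(\textstyle\sum_j w_j x_{sj} + h)$ with
   $f(x) = x\,\Phi(x) + \phi(x)$ — a rectified linear function convolved
   with a unit Gaussian — fit by squared error with L-BFGS-B, compared on
   held-out $R^2$ against a 31-parameter oracle that copies the training
   tuning curve verbatim.
5. **Surrogate controls** (`build_surrogate`, `surrogate_battery`,
   `diagonal_enrichment`): linear-null and signal-plus-noise surrogates
   establishing that detected supra-linearity requires genuine
   stimulus-dependent nonlinearity rather than selection noise.
6. **Kinematics** (`curvature`, `bend_force_proxy`): signed planar
   whisker-bend curvature
   $\kappa = (x'y'' - x''y')/(x'^2 + y'^2)^{3/2}$ and the
   free-whisking-subtracted bend as a contact-force proxy.

`run_pipeline()` ties stages 1–5 into a seeded, reproducible run writing
TSV/JSON artifacts, and `report()` renders the standard figures.

## The synthetic-data generator

`simulate_session()` emulates the statistical structure the analysis
assumes: 32 conditions (31 combinations plus catch) presented 20 times each
in seeded pseudo-random order, 1-s stimuli with 2-s inter-trial intervals at
15.45 Hz, GCaMP6s-like calcium kinetics (single-exponential kernel,
$\tau = 1.5$ s, instantaneous rise — a reasonable idealization at these
frame rates), neuropil contamination (shared slow background plus white
noise, mixed in with a per-neuron coefficient), homoscedastic Gaussian
trial-to-trial noise matching the LN model's noise assumption, and
lognormal running speeds (median 30 cm/s) with 10% slow trials so the
running filter is exercised. Ground-truth neurons come in three kinds:

- **labeled-line** — one positive weight, baseline drive $h \approx 0$;
- **combination-selective** — two or three positive weights drawn from
  $U(2.5, 3.5)$ with $h = -( \sum_j w_j - u)$, $u \sim U(0.5, 1)$: dropping
  any one target element leaves the drive at least ~1.5 units below
  threshold, so only the full combination (and its supersets) responds, and
  the response to the combination exceeds the sum of the component
  responses by the convexity of $f$;
- **tabulated** — an arbitrary supplied tuning vector, used for
  misspecification checks (e.g. XOR-like tuning that no LN model fits).

The default mixture (52% / 35% / 13%) mirrors the reported composition of
responsive barrel-cortex populations. Per-neuron trial noise defaults to
0.2 × the neuron's maximum mean response.

Two generator choices deserve emphasis. *Catch trials* carry each LN
neuron's spontaneous rate $a f(h)$ rather than exactly zero, so that the
analysis-side catch subtraction recovers $a(f(\cdot) - f(h))$, consistent
with the model. And because the LN neurons have nonnegative weights and $f$
is strictly convex, their catch-subtracted tuning can never be sub-linear
($\mathrm{ld} \ge 0$ always — increments of a convex function above a common
baseline are superadditive). Genuinely suppressive surround interactions,
prominent in real cortex, are therefore *not* represented by the LN kinds;
tests of sub-linearity rely on tabulated neurons or on real data. Passing
tests on synthetic sessions show the pipeline's statistics are correct and
calibrated, not that cortical data will look like the generator's output.

## Numerical and statistical choices

- **Quantiles** are type-7 (linear interpolation) throughout; the median
  rule and percentile baselines depend on this convention.
- **Neuropil guard**: frames with $N \le 10^{-9}$ are excluded from the
  min-ratio; an all-degenerate neuron is flagged and passed through with
  $k = 0$ rather than dropped. A negative min ratio clamps to 0. The
  literal minimum over valid frames is used; with high somatic baselines
  the estimator is conservative (it tends toward the upper clamp), and the
  catch-baseline $\Delta F/F$ absorbs the residual offset — the end-to-end
  recovery tests quantify the combined effect.
- **Percentile baseline** windows are centered and truncated at the edges;
  a window longer than the trace falls back to a global percentile with a
  warning.
- **Deconvolution** solves
  $\min_{e \ge 0} \|y - K e\|_2^2 + \lambda \|e\|_1$ (FISTA, O(T)
  recursive-filter convolutions, $\lambda = 0.02$ by default) and scales
  rates so a train whose reconvolution has time-averaged $\Delta F/F = 1$
  has time-averaged rate 1. The reconvolution residual is floored by the
  negative-going noise energy in the trace — a nonnegative event train
  cannot (and should not) reproduce it — so the residual contract is
  meaningful only for signal-dominated traces.
- **Window rounding**: stimulus windows are `round(window_s * rate)` frames
  (half away from zero), minimum one frame; at 15.45 Hz a 1-s window is 15
  frames.
- **Bootstrap**: percentile method, resampling trials with replacement
  within condition, catch re-drawn per replicate; 1,000 replicates for CIs
  and (by default) 10,000 for the supra-linearity test, whose statistic
  $D = \mathrm{ld}(\mathrm{top}) - \overline{\mathrm{ld}}(\mathrm{non\text{-}top})$
  is a fixed linear functional of the per-condition means, making the
  resampling O(trials × replicates). Two one-sided tests at $\alpha = 0.01$
  per side label neurons supra/sub/ns.
- **Ties**: preferred stimulus ties resolve toward the smaller subset,
  then canonical order (size ascending, then lexicographic masks — the
  package's fixed convention, required for reproducible matrices);
  principal-whisker ties resolve toward the lower element index.
- **Partitioning**: per-condition counts differ by at most one; when pupil
  covariates are present a greedy within-condition swap refinement
  balances their means across partitions (the exact balancing algorithm is
  an implementation choice; the refinement provably never worsens the
  imbalance objective).
- **Surrogates**: the across-partition SD is estimated per neuron ×
  condition from the base partitions and debiased by the Gaussian $c_4$
  constant (with two partitions the raw sample SD underestimates $\sigma$
  by ~20%); the shared stimulus-dependent signal is drawn once per neuron
  with SD equal to the SD across the 31 conditions of the original curve.
  Optional pseudo-trials (recentred so trial means equal the partition
  curves exactly) let the trial-level bootstrap run on surrogates.
  Per-condition SD matching is the default; pooled matching is available
  via `pool_sd = TRUE`.
- **Fitting**: `fit_ln` bounds $a \ge 0$, leaves $w, h$ unbounded, and uses
  multi-start (OLS-initialized weights, $h \in \{-1, 0, -2\}$ plus random
  jitter); `single_start = TRUE` reproduces the minimal single-start
  procedure. Held-out $R^2$ is not clipped below zero — the oracle
  comparison depends on this.
- **Model-comparison gate**: neurons enter the Wilcoxon signed-rank
  comparison only if the oracle's held-out $R^2$ exceeds 0.5; with fewer
  than six passing neurons only descriptive output is returned.
- **`mean > 0` clause** in responsiveness is applied to the raw (not
  catch-subtracted) condition mean.
- **Curvature** uses cubic-spline resampling to uniform arc length and
  central differences; the default segment is the third of the whisker
  nearest the base (configurable). Segment membership carries a $10^{-9}$
  tolerance so boundary grid points are kept regardless of floating
  rounding, which keeps rigid-motion invariance exact.
- The LN model can be fit to either $\Delta F/F$ responses or deconvolved
  event rates; both are first-class `signal_kind`s of the response matrix.
- The supra-linearity statistic's "non-top" average runs over the
  multi-element conditions only (the linear difference is undefined for
  singletons); including singletons would mix a different quantity into
  the average.

## Cross-validation honesty

The halves scheme estimates preference on one half and displays the other;
with two partitions the reliability gate itself touches the displayed half,
which can leak selection noise into the diagonal of the displayed
linear-difference matrix. The thirds scheme removes this: thirds 1–2 drive
the gate and the preference, third 3 is displayed, and no display data
enters selection. The package's honesty checks poison the selection
partitions (displayed values are unchanged) and shuffle the display
partition's condition labels (the diagonal enrichment collapses), and the
surrogate battery runs with three partitions for exactly this reason.

## Problem sizes used in the tests and acceptance script

Simulated checks use 20-trial conditions as in the study design, with
population sizes chosen for stable statistics: 200 neurons for parameter
recovery and for supra-linearity power, 1,000 linear-null neurons for
type-I calibration (bootstrap 2,000 replicates per neuron), 600 neurons
for the surrogate battery, 2,000 repeats of a 100-trial Gaussian toy for
bootstrap-CI coverage, and small rendered sessions (≤ 8 neurons) for the
end-to-end trace checks.

## Known limitations

- The generator contains no sub-linear LN mechanism (see above), no
  spiking or Poisson variability, no whisk-cycle-resolved touch structure,
  and no video; single-class accuracy of the responsiveness classifier is
  intrinsically capped (~0.85) by false-positive singletons under the
  adaptive BH threshold when a neuron genuinely drives half the stimulus
  family.
- The min-ratio contamination coefficient is the literal minimum over
  valid frames; a robust low quantile would be less sensitive to single
  frames but is not what the estimator specifies.
- Motion correction, ROI segmentation, barrel-column mapping, touch
  detection and whisker tracking are upstream of this package's inputs.
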