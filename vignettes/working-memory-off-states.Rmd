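---
title: "Population analyses of persistent activity and off states in spatial working memory"
author: "wmoff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analyses of persistent activity and off states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wmoff)
```

## The scientific question

During oculomotor delayed-response (ODR) tasks, a monkey sees a brief
peripheral cue at one of 8 locations (45 degrees apart), holds fixation
through a 3 s memory delay, and then saccades to the remembered location.
Whether the memory is carried by continuous ("persistent") population
spiking, or by activity-silent mechanisms punctuated by genuine pauses, is a
long-standing debate. This package implements a family of population-level
analyses that address it:

* per-unit selectivity and bias-corrected explained variance (PEV,
  $\omega^2$) over time;
* circular-mean preferred-location estimation;
* a pooled inter-spike-interval (ISI) permutation test for *coordinated*
  silent periods across co-tuned neurons;
* leave-one-out lasso-logistic population decoding (cross-temporal 8-way and
  binary diametric) with softmax posterior confidence;
* on/off state labeling from decoder confidence against shuffled-label
  nulls, with cluster-mass multiple-comparison control;
* shuffle-debiased state-conditioned tuning curves and population rates,
  within and across cortical areas (PFC/PPC);
* simultaneous versus pseudo-population decoding comparisons, beta-mixture
  modeling of confidence, state power spectra, and reaction-time/outcome
  statistics.

Because raw recordings of this kind are rarely redistributable, the package
ships a synthetic ODR-session generator that provides ground truth for every
stage; all tests run against it.

## Data model and conventions

A session (`wm_session`) is three plain tables — units, trials, spikes —
plus epoch boundaries in seconds relative to cue onset: fixation
$[-1, 0)$, cue $[0, 0.5)$, delay $[0.5, 3.5)$, response $[3.5, 4.1)$. The
response window defaults to the 0.6 s saccade deadline and is configurable,
since saccade-aligned analyses may prefer other extents. All intervals,
including rate windows and epochs, are half-open $[a, b)$: a spike exactly
on a boundary belongs to the later window, which makes tie-breaking
deterministic. Spike times round-trip through CSV at $10^{-5}$ s.

`bin_firing_rates()` estimates rates in 100 ms windows stepped by 50 ms
(both configurable). Windows are labeled by center; the first window is the
earliest whose full extent fits the requested span, so no partial windows
bias the edges. Optional z-scoring is per (unit, window) across trials; a
unit with zero variance in a window maps to 0 rather than NaN so that
downstream classifiers stay well defined for silent units.

## The synthetic generator

`simulate_tuned_session()` draws inhomogeneous-Poisson spikes. Each unit has
a baseline rate $b$, a multiplicative delay gain $g$ at its preferred angle
$\theta_0$, and a von-Mises-shaped tuning kernel
$k(\Delta) = \exp\{\kappa(\cos\Delta - 1)\}$, giving an expected rate
$b\,[1 + (g-1)\,k(\theta - \theta_0)]$ from cue onset onward. The kernel
shape is a package choice: it is smooth, circular, and controlled by a
single concentration $\kappa$ ($\kappa = 0$ is untuned).

Off states are modeled as intervals of the delay during which only the
*location-dependent* component is scaled by `off_tuning_gain`
$\in [0, 1]$; the baseline survives. This mirrors the empirical signature of
off states — a flattening of tuning curves rather than a cessation of
firing. Off onsets are Poisson in time (default 0.3 /s) with fixed duration
(default 0.3 s); these two defaults are placeholders chosen to produce a few
brief off states per trial, since no quantitative off-state statistics exist
to calibrate against, and analyses that depend on them set their own values
explicitly. Positive noise correlations are induced by a per-trial,
per-100-ms log-normal common gain (mean 1, SD `shared_gain_sd`) multiplying
all units.

Sampling is exact for these piecewise-constant rates: each constant segment
(boundaries on the millisecond grid) draws a Poisson count with uniform
placement, which is distributionally identical to thinning at fine
resolution but vectorizes. All randomness flows through one integer seed;
identical seeds reproduce sessions bit for bit.

Surrogate populations for the ISI test (`simulate_silence_populations()`)
follow the validation design of the method: 2–20 neurons, 10–20 trials of
3 s, per-neuron rates discrete-uniform 1–20 Hz, and optionally 1–3
coordinated 100 ms silent windows per trial, placed uniformly and shared
across neurons (per-neuron independent silences sit behind a flag; the test
targets population-level silences). The with/without versions share base
spike trains, so imposing silence only removes spikes.

What the generator does *not* emulate: biophysical membrane or network
dynamics, eye movements, drift in excitability across a session,
non-Poisson spike-train irregularity (e.g. bursting or refractoriness), and
any topographic organization across units. Passing tests therefore show the
statistical machinery behaves as designed under its own assumptions, not
that real cortex satisfies those assumptions.

## Selectivity, PEV, preferred locations, layers

A unit is location-selective in an epoch if a one-way ANOVA of per-trial
mean rates across the 8 locations is significant *and* its best location
reaches 2 spikes/s — the rate gate prevents nearly silent units from
passing on a handful of spikes. The ANOVA level defaults to
$\alpha = 0.05$ and is configurable.

The PEV statistic per 100 ms window is the bias-corrected omega squared,

$$\omega^2 = \frac{SS_{between} - df \cdot MSE}{SS_{total} + MSE}\times 100,
\qquad df = 7$$

for 8 stimulus conditions. Groups are first balanced by seeded random
subsampling to the lowest common trial count; the subsample is drawn once
per call so all windows share trials (a per-window flag exists). Negative
values are expected under the null — the correction centers the statistic
at zero. If a window has no variance at all, $\omega^2$ is defined as 0.

The preferred location is the spike-count-weighted circular mean
$T = \sum_j n_j e^{i\theta_j} / \sum_j n_j$ over the cue angles; its
argument is the preferred angle and its modulus (0 to 1) the tuning
strength. A resultant below $10^{-9}$ (or all-zero counts) is flagged
undefined and the unit is excluded downstream. Recording depths classify
units into superficial $[0, 0.8)$ mm, middle $[0.8, 1.2)$ mm, and deep
$\ge 1.2$ mm, measured from the shallowest spiking contact.

## The pooled-ISI silence test

For each (session, cue location) candidate, the delay-selective units whose
snapped preferred location matches the cue form a population (kept when at
least `n_min = 5`; the threshold is an argument). Delay periods are
concatenated back to back — trial $k$ occupies $[kD, (k+1)D)$ — and all
member spikes are pooled and sorted. The two statistics per population are
the maximum successive ISI and the pooled rate (spikes over pooled
duration). ISIs spanning trial boundaries are retained on the contiguous
timeline (a flag excludes them for sensitivity analysis).

The null shuffles trial assignments: per iteration, each unit's trains are
independently permuted across trial slots (a permutation, so each unit's
trial multiset — and hence the pooled count and rate — is conserved
exactly), and the pooled maximum ISI is recomputed. The compiled kernel
finds each iteration's maximum gap in linear time by the pigeonhole method
(with $2(n-1)$ uniform buckets the bucket width is at most half the maximum
gap, which therefore always spans a bucket boundary), and draws from R's
RNG so seeds propagate.

Across populations, $\log_{10}(\text{max ISI})$ regresses on
$\log_{10}(\text{rate})$; per shuffle iteration the same regression over
each population's $i$-th shuffled value yields a null distribution of
slopes and intercepts. Coordinated silences make the maximum ISI
rate-independent and hence *flatten* (raise toward zero) the empirical
slope relative to the null; the default one-sided test counts null slopes
at least as shallow as the empirical one, with the add-one convention
$p = (1 + \#\{\text{extreme}\})/(1 + n_{iter})$ so $p$ is never zero. The
opposite tail ("steeper", indicating super-Poisson regularity and
delay-tiling) is available via an argument. The default is 10,000
iterations; the test suite uses 1,000 with documented seeds.

## Decoding and confidence

The decoder is a linear logistic model with L1 penalty $\lambda = 0.01$,
one-vs-all per class, leave-one-trial-out. For the 8-way cross-temporal
analysis, classifiers trained at one window score the held-out trial at
every window; accuracy per (train, test) pair is the fraction of correct
held-out classifications, with argmax ties broken toward the lowest class
index. For the binary diametric analysis (a location versus its opposite),
the confidence assigned to the true location is the softmax over the two
per-class linear scores, $e^{s_i} / \sum_j e^{s_j}$. For a diametric pair
the two one-vs-all problems are exact sign flips of one another (the
logistic loss and the penalty are both symmetric), so one fit provides both
scores.

Numerical choices: the built-in solver is a compiled FISTA proximal-gradient
method with adaptive restart on the objective
$\frac1n \ell(\beta) + \lambda\|\beta\|_1$ (unpenalized intercept),
tolerance $10^{-6}$ on the parameter change, at most $10^4$ iterations; a
glmnet engine minimizing the identical objective is available and the two
agree to solver tolerance (the built-in engine exists because leave-one-out
pipelines make on the order of $10^5$ small fits, where per-call overhead
dominates). Intercepts are on and classes unweighted. z-scoring statistics
are computed on the training fold only and applied to the held-out trial by
default; passing an already z-scored matrix reproduces whole-set z-scoring.
When training labels are permuted for chance calibration, the labels are
drawn from the full-session label multiset rather than the fold's, so the
held-out class is not systematically under-represented in training (a small
but real leave-one-out chance bias otherwise pushes accuracy below 0.5).

The 120-stimulus task variant is handled upstream by grouping stimuli into
the 8 canonical bins; the decoder always sees 8 (or 2) labels.

## On/off state labeling

The classification is repeated 50 times with shuffled training labels,
giving each trial a per-window null distribution of confidence. The true
confidence is z-scored by the null mean and SD; windows with zero null SD
are flagged, break runs, and stay unlabeled. Contiguous runs with
$z > 1.64$ form candidate clusters with mass defined as the sum of z within
the run (the standard cluster-mass statistic; the threshold and statistic
are arguments). Each shuffled series is itself clustered the same way and
contributes its *maximum* cluster mass, giving family-wise control; a
pooled-across-trials alternative sits behind a flag. Clusters with mass
above the null 95th percentile are on states. Maximal runs of $z < 0.3$
lasting at least 3 consecutive windows (150 ms on the 50 ms grid; both
configurable) outside on-clusters are off states. The thresholds leave a
gap, so windows with $0.3 \le z \le 1.64$ remain "neither" — the partition
is exhaustive and exclusive by construction.

A practical note on temporal sensitivity: with $\lambda = 0.01$ and a few
dozen trials, the label-shuffled classifier overfits and its held-out
posteriors spread far from 0.5, so the null SD is large (about 0.3–0.45)
and single-window confidence is itself noisy. In simulations with complete
tuning loss during imposed off states, the off-labeling rule recovers off
windows with high precision but roughly 30–50% per-window sensitivity, and
window-set overlap (Jaccard) with ground truth plateaus near 0.3 across
window widths, unit counts, firing rates and trial counts. Detected off
states are therefore trustworthy, but their boundaries and completeness at
the single-window level are not — a limitation inherent to the
decoder-plus-threshold construction at these scales, not to any particular
parameter choice.

## State-conditioned tuning and rates

Per unit, 8-element on- and off-state vectors hold the trial-averaged
z-scored rate per cue over the windows labeled with each state. The
preferred location is the argmax of the summed on+off vector, and both
vectors are circularly rotated to put it at the center position. Because
this alignment manufactures a peak even from noise, the identical pipeline
is repeated for 1000 cue-label permutations and the mean shuffled curves
are subtracted, leaving debiased tuning functions with zero expectation
under the null. Tuning depth per state is the debiased center (peak) value
minus the curve minimum; the off/on depth ratio recovers an imposed
off-state tuning gain in simulation. Population rate traces average each
unit's preferred-cue trials within on windows, off windows, and all
windows.

For cross-areal analysis, states labeled from one area's confidence are
evaluated on the simultaneously recorded other area (same trials); a
genuine global off state reduces the evaluated area's off-state tuning
depth even though its activity played no role in the labeling. The
real-data requirement of more than 80 units per area is enforced by default
and relaxable for synthetic work.

## Population statistics

Pseudo-populations permute, per unit and per stimulus condition, the
assignment of whole single-trial responses to trials, preserving every
marginal exactly while destroying within-trial correlations (responses are
shuffled as whole time series, so each unit's within-trial temporal
structure survives). The decoding comparison runs the identical
leave-one-out decoder on the source and on (by default 100) replicates;
per-window significance compares the simultaneous accuracy to the replicate
distribution by rank (add-one, two-sided) with Bonferroni correction across
windows, a Wilcoxon signed-rank test compares the traces, and cue / delay /
response epoch means summarize the direction.

Beta-mixture modeling asks whether delay confidence is one-state or
two-state: a single Beta$(a, b)$ fit (moment-matched start, direct ML)
versus $w\,\mathrm{Beta}(a,b) + (1-w)\,\mathrm{Beta}(a',b')$ by EM with 10
seeded restarts, tolerance $10^{-8}$, at most 500 iterations, values
clipped to $[10^{-6}, 1-10^{-6}]$. $\Delta AIC$ and $\Delta BIC$ use 2 and
5 parameters; negative values favor two states. The EM's observed-data
log-likelihood is checked to be non-decreasing on every fit.

State rhythmicity is assessed on 10 ms binary state series (100 Hz, spectra
to 50 Hz) with Welch's method: 2.0 s Hamming windows, 50% overlap,
1024-point zero-padded FFT, PSDs averaged across trials. The in-package
Welch estimator uses the $1/(f_s \sum w^2)$ scaling under which the PSD
integrates to the series variance (checked to ~1% on white noise); no
installed package provides this estimator directly.

Reaction-time effects fit, per session, RT on an on/off indicator at
fixation offset (the coefficient is simply RT_on − RT_off in ms), then
bootstrap the across-session mean (10,000 draws of sessions with
replacement); the one-sided p is the proportion of bootstrap means at or
above zero, so small p means faster responses from the on state. State
counts in correct versus error trials tally on/off segments intersecting
the last 0.5 s of the delay at the session's most- and least-preferred cue
(by mean delay confidence), and a three-way ANOVA with all interactions
runs on the session-level cell means.

## Problem sizes used by the test suite

The suite validates each stage at sizes chosen to keep the full run on one
CPU within tens of minutes while leaving Monte-Carlo margins interpretable:
surrogate-ISI validation uses 20 replicate ensembles of 50 populations with
1,000 shuffle iterations; chance calibration uses 600 trials at 8 windows;
state-labeling recovery uses a 25-unit, 40-trial session on the full
100/50 ms delay grid with 50-shuffle nulls; tuning-depth recovery uses 240
units with ground-truth state labels and 1,000 debias shuffles; the
pseudo-population comparison uses 100 replicates of a 15-unit session.
Statistical conclusions do not hinge on these sizes; they set the
Monte-Carlo resolution of the checks.

## Known limitations

* The state-labeling thresholds (z > 1.64, z < 0.3 for 3 windows) are taken
  as given; their single-window sensitivity at desk scales is limited (see
  above), and boundary windows straddling a state transition dilute both
  tuning and overlap measures.
* The ISI test conditions on co-tuned populations selected by the same
  delay activity it analyzes; selection effects are not modeled.
* The simulator's off states are step changes; gradual gain drifts, bursting
  and refractoriness are absent, and Poisson variability likely understates
  real spike-count dispersion.
* Oscillatory or traveling-wave structure in states is out of scope beyond
  the Welch spectrum.
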