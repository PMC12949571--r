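# wmoff

Population analyses of persistent activity and "off states" in spatial
working memory.

During an oculomotor delayed-response (ODR) task, a brief cue at one of 8
locations (45° apart) must be remembered across a 3 s delay. Whether that
memory is carried by continuous population spiking or punctuated by genuine
coordinated pauses is contested. `wmoff` implements the population-level
statistical machinery for this question on tabular spike data (one row per
spike: unit, trial, time):

* **Selectivity & explained variance** — per-unit one-way location ANOVA
  (with a 2 spikes/s best-location gate) and the bias-corrected percentage
  of explained variance per 100 ms window,
  `ω² = (SS_between − df·MSE)/(SS_total + MSE) × 100`, df = 7 for 8
  conditions, with trial-count stratification.
* **Preferred locations** — spike-count-weighted circular mean
  `T = Σ nⱼ e^{iθⱼ} / Σ nⱼ`; laminar classification from recording depth.
* **Coordinated-silence ISI test** — delay spikes of co-tuned populations
  pooled over concatenated delays; the maximum inter-spike interval versus
  pooled rate relation on log10 axes, against a trial-shuffle null
  (compiled, linear-time max-gap kernel); one-sided permutation p for slope
  flattening.
* **Decoding** — one-vs-all lasso-logistic (λ = 0.01) with leave-one-trial-
  out: cross-temporal 8-way accuracy matrices and binary diametric decoding
  with softmax posterior confidence.
* **On/off states** — confidence z-scored against 50 shuffled-label nulls;
  `z > 1.64` clusters kept by cluster-mass (family-wise) control are "on",
  runs of `z < 0.3` over ≥ 3 windows are "off"; shuffle-debiased
  state-conditioned tuning curves, population rates, and cross-areal
  (PFC/PPC) evaluation.
* **Population statistics** — simultaneous vs 100-replicate
  pseudo-population decoding comparisons, beta-mixture (ΔAIC/ΔBIC)
  modeling of confidence, Welch spectra of state series, reaction-time and
  correct/error state-count statistics.
* **Synthetic sessions** — an exact inhomogeneous-Poisson ODR generator
  with von-Mises tuning, global off states, and controllable shared-gain
  noise correlations, returning ground truth for every stage.

## Worked example

Simulate a session of tuned units with imposed off states, decode the
remembered location, and label on/off states:

```r
library(wmoff)

sched <- state_schedule(off_rate_per_s = 0.3, off_duration = 0.6,
                        off_tuning_gain = 0)
sim <- simulate_tuned_session(
  n_units = 25, n_trials_per_location = 20, seed = 601,
  unit_specs = tuned_unit_specs(25, baseline_rate = 6, delay_gain = 5,
                                kappa = 2,
                                preferred_angle = rep(c(90, 270),
                                                      length.out = 25)),
  schedule = sched, cue_locations = c(90, 270), p_error = 0)
sim
#> <wm_sim> synthetic session with ground truth
#> <wm_session 'sim'> 25 units, 40 trials, 74436 spikes
#>   epochs: fixation [-1,0) cue [0,0.5) delay [0.5,3.5) response [3.5,4.1)
#>   provenance: synthetic, seed 601
#>   ground truth: 34 off intervals, off_tuning_gain 0.00

rm_ <- bin_firing_rates(sim$session, epoch = "delay")   # 100 ms / 50 ms grid
cs  <- binary_confidence(rm_, pair = c(90, 270))
cs
#> <confidence_series> pair 90/270 deg: 40 trials x 59 windows
#>   mean posterior of true cue 0.900, mean accuracy 0.905

nl <- build_null(rm_, pair = c(90, 270), n_shuffles = 50, seed = 602)
st <- label_states(cs, nl)
st
#> <wm_states> 40 trials x 59 windows: 0.0% on, 6.6% off, 93.4% neither
```

The decoder reads the remembered location from 90% of held-out
trial-windows; during the imposed off intervals (complete tuning loss) its
confidence collapses toward the 0.5 chance line of the shuffled-label null,
and those stretches are picked up as off states.

The coordinated-silence test on surrogate populations:

```r
pops <- simulate_silence_populations(50, seed = 1)   # paper-style surrogates
with_silence <- isi_silence_test(lapply(pops, `[[`, "with_silence"),
                                 n_iter = 1000, seed = 2)
with_silence
#> <isi_slope_test> 50 populations, 1000 shuffle iterations
#>   empirical slope -0.3235 (intercept -0.0733, R^2 0.637)
#>   null slope mean -0.8680 [-0.9209, -0.8159] (2.5th/97.5th pct)
#>   one-sided p (shallower) = 0.000999
```

Imposed 100 ms coordinated silences make the maximum pooled ISI nearly
rate-independent, flattening the slope (−0.32) far outside the
trial-shuffled null (≈ −0.87): the test detects them at p ≈ 0.001. The same
ensembles without silences give a slope inside the null band.

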