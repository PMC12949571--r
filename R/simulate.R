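#' Specify tuned Poisson units
#'
#' Each unit fires as an inhomogeneous Poisson process: `baseline_rate` during
#' fixation, and from cue onset onward an expected rate of
#' `baseline * (1 + (delay_gain - 1) * k(cue - preferred))`, where
#' `k(d) = exp(kappa * (cos(d) - 1))` is a von-Mises-shaped tuning kernel
#' (`kappa = 0` means untuned).
#'
#' @param n number of units.
#' @param baseline_rate baseline rate(s), Hz (recycled).
#' @param delay_gain multiplicative elevation at the preferred cue (recycled).
#' @param preferred_angle preferred angle(s) in degrees (recycled).
#' @param kappa tuning concentration(s), >= 0 (recycled).
#' @param kind `"single"` or `"multi"` (recycled).
#' @return data.frame with one row per unit.
#' @export
tuned_unit_specs <- function(n, baseline_rate = 5, delay_gain = 3,
                             preferred_angle = cue_angles(), kappa = 1.5,
                             kind = "single") {
  spec <- data.frame(baseline_rate = rep_len(baseline_rate, n),
                     delay_gain = rep_len(delay_gain, n),
                     preferred_angle = rep_len(preferred_angle, n) %% 360,
                     kappa = rep_len(kappa, n),
                     kind = rep_len(kind, n))
  if (any(spec$baseline_rate < 0) || any(spec$delay_gain < 0) || any(spec$kappa < 0))
    stop("baseline_rate, delay_gain and kappa must be non-negative")
  spec
}

#' Draw heterogeneous unit specifications
#'
#' Default population statistics chosen to resemble dorsolateral PFC delay
#' activity: baselines gamma-distributed around 5 Hz, delay gains between 1.5
#' and 4, preferred angles uniform on the circle, moderate and variable
#' tuning concentrations.
#'
#' @param n number of units.
#' @param seed integer seed.
#' @param p_multi proportion of multi-units.
#' @return data.frame as in [tuned_unit_specs()].
#' @export
draw_unit_specs <- function(n, seed, p_multi = 0.25) {
  with_seed(seed, {
    data.frame(baseline_rate = stats::rgamma(n, shape = 4, scale = 1.25),
               delay_gain = runif(n, 1.5, 4),
               preferred_angle = runif(n, 0, 360),
               kappa = runif(n, 0.8, 3),
               kind = ifelse(runif(n) < p_multi, "multi", "single"))
  })
}

#' Specify a global on/off state schedule
#'
#' Off states are intervals of the delay period during which the
#' location-dependent (tuned) rate component of every affected unit is
#' multiplied by `off_tuning_gain`; the baseline component is preserved,
#' mirroring a flattening of tuning rather than a cessation of firing.
#'
#' @param off_rate_per_s expected off-state onsets per second of delay.
#' @param off_duration duration of each off state, seconds (clipped to delay).
#' @param off_tuning_gain factor in `[0, 1]` applied to the tuned component.
#' @param shared_across_units logical; one schedule per trial for all units?
#' @return list of class `state_schedule`.
#' @export
state_schedule <- function(off_rate_per_s = 0.3, off_duration = 0.3,
                           off_tuning_gain = 0.25, shared_across_units = TRUE) {
  if (off_tuning_gain < 0 || off_tuning_gain > 1)
    stop("off_tuning_gain must lie in [0, 1]")
  if (off_rate_per_s < 0 || off_duration <= 0)
    stop("off_rate_per_s must be >= 0 and off_duration > 0")
  structure(list(off_rate_per_s = off_rate_per_s, off_duration = off_duration,
                 off_tuning_gain = off_tuning_gain,
                 shared_across_units = shared_across_units),
            class = "state_schedule")
}

## von-Mises-shaped tuning kernel on degrees, in [0, 1]
tuning_kernel <- function(delta_deg, kappa) {
  exp(kappa * (cos(delta_deg * pi / 180) - 1))
}

## expected delay rate of a unit spec at cue angle, tuned component scaled by g
expected_delay_rate <- function(spec, cue_deg, tuned_gain = 1) {
  k <- tuning_kernel(cue_deg - spec$preferred_angle, spec$kappa)
  spec$baseline_rate * (1 + tuned_gain * (spec$delay_gain - 1) * k)
}

## draw off intervals for one trial; merged, clipped to the delay epoch
draw_off_intervals <- function(delay, rate_per_s, duration) {
  d <- delay[2] - delay[1]
  n <- rpois(1, rate_per_s * d)
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  on <- sort(runif(n, delay[1], delay[2]))
  iv <- cbind(on, pmin(on + duration, delay[2]))
  ## merge overlaps
  out <- iv[1, , drop = FALSE]
  if (n > 1) for (i in 2:n) {
    if (iv[i, 1] <= out[nrow(out), 2]) out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    else out <- rbind(out, iv[i, ])
  }
  out
}

#' Simulate a tuned ODR session with ground truth
#'
#' Generates inhomogeneous-Poisson spikes for `n_units` tuned units over
#' trials at the 8 cue locations, with optional global off states (tuned
#' component scaled by `off_tuning_gain` during off intervals of the delay)
#' and optional common multiplicative gain fluctuations that induce positive
#' noise correlations between units. Sampling is exact for the piecewise-
#' constant rate functions used: per-segment Poisson counts with uniform
#' placement, segment boundaries on the millisecond grid.
#'
#' @param n_units number of units (ignored if `unit_specs` given).
#' @param n_trials_per_location trials per cue location (>= 1).
#' @param unit_specs data.frame from [tuned_unit_specs()]/[draw_unit_specs()],
#'   or `NULL` to draw defaults.
#' @param schedule a [state_schedule()] or `NULL` for no off states.
#' @param shared_gain_sd SD of the per-trial, per-100-ms common log-normal
#'   gain applied to all units (0 = independent Poisson).
#' @param seed integer seed; identical seeds reproduce sessions bit-for-bit.
#' @param cue_locations cue angles used (default all 8).
#' @param epochs epoch list, see [default_epochs()].
#' @param area area label for all units.
#' @param p_error proportion of trials marked as errors (behavioral
#'   performance in this task is ~90% correct, so the default is 0.1).
#' @param rt_mean,rt_sd reaction-time distribution (ms), truncated at 100 ms.
#' @param trials optional pre-built trial table (to share trial structure
#'   across simultaneously "recorded" areas).
#' @param off_intervals optional pre-drawn off intervals (data.frame
#'   `trial_id`, `start`, `end`) to impose a shared schedule across areas.
#' @param session_id session identifier.
#' @return list of class `wm_sim` with elements `session` (a `wm_session`)
#'   and `ground_truth` (unit specs with preferred angles, off intervals per
#'   trial, seed).
#' @export
simulate_tuned_session <- function(n_units = 20, n_trials_per_location = 10,
                                   unit_specs = NULL, schedule = NULL,
                                   shared_gain_sd = 0, seed = 1,
                                   cue_locations = cue_angles(),
                                   epochs = default_epochs(), area = "PFC",
                                   p_error = 0.1, rt_mean = 250, rt_sd = 40,
                                   trials = NULL, off_intervals = NULL,
                                   session_id = "sim") {
  stopifnot(n_trials_per_location >= 1)
  epochs <- validate_epochs(epochs)
  if (is.null(unit_specs)) unit_specs <- draw_unit_specs(n_units, seed = seed + 1)
  n_units <- nrow(unit_specs)
  delay <- epochs$delay
  span <- session_span(epochs)
  cue_on <- epochs$cue[1]

  with_seed(seed, {
    if (is.null(trials)) {
      cue_seq <- rep(cue_locations, each = n_trials_per_location)
      cue_seq <- sample(cue_seq)               # interleave locations
      nt <- length(cue_seq)
      rt <- pmax(100, rnorm(nt, rt_mean, rt_sd))
      trials <- data.frame(trial_id = sprintf("t%03d", seq_len(nt)),
                           cue_location_deg = cue_seq,
                           correct = runif(nt) >= p_error,
                           reaction_time_ms = rt)
    }
    nt <- nrow(trials)

    ## off-state schedule (ground truth)
    if (is.null(off_intervals)) {
      off_intervals <- data.frame(trial_id = character(0), start = numeric(0),
                                  end = numeric(0))
      if (!is.null(schedule)) {
        for (i in seq_len(nt)) {
          iv <- draw_off_intervals(delay, schedule$off_rate_per_s,
                                   schedule$off_duration)
          if (nrow(iv))
            off_intervals <- rbind(off_intervals,
                                   data.frame(trial_id = trials$trial_id[i],
                                              start = round(iv[, 1], 3),
                                              end = round(iv[, 2], 3)))
        }
      }
    }
    off_g <- if (is.null(schedule)) 1 else schedule$off_tuning_gain

    ## per-trial piecewise-constant segments
    seg_list <- vector("list", nt)
    for (i in seq_len(nt)) {
      iv <- off_intervals[off_intervals$trial_id == trials$trial_id[i], , drop = FALSE]
      bounds <- c(span[1], cue_on, span[2])
      if (nrow(iv)) bounds <- c(bounds, iv$start, iv$end)
      if (shared_gain_sd > 0)
        bounds <- c(bounds, seq(span[1], span[2], by = 0.1))
      bounds <- sort(unique(round(bounds, 3)))
      s <- bounds[-length(bounds)]; e <- bounds[-1]
      mid <- (s + e) / 2
      tuned <- as.numeric(mid >= cue_on)
      gfac <- rep(1, length(s))
      if (nrow(iv)) {
        for (j in seq_len(nrow(iv)))
          gfac[mid >= iv$start[j] & mid < iv$end[j]] <- off_g
      }
      seg_list[[i]] <- data.frame(trial = i, start = s, end = e,
                                  tuned = tuned, gfac = gfac)
    }
    segs <- do.call(rbind, seg_list)
    nseg <- nrow(segs)

    ## common gain per segment (per trial x 100 ms block), log-normal, mean 1
    if (shared_gain_sd > 0) {
      blk <- paste(segs$trial, floor((segs$start - span[1]) / 0.1 + 1e-9))
      ub <- unique(blk)
      sdl <- sqrt(log(1 + shared_gain_sd^2))
      g <- exp(rnorm(length(ub), -sdl^2 / 2, sdl))
      cgain <- g[match(blk, ub)]
    } else cgain <- rep(1, nseg)

    ## expected rate per (segment, unit)
    K <- outer(trials$cue_location_deg[segs$trial], unit_specs$preferred_angle, "-")
    K <- tuning_kernel(K, rep(unit_specs$kappa, each = nseg))
    tuned_amp <- rep(unit_specs$delay_gain - 1, each = nseg) * K
    eff <- segs$tuned * segs$gfac
    rate <- rep(unit_specs$baseline_rate, each = nseg) * (1 + eff * tuned_amp)
    rate <- rate * cgain
    lambda <- rate * (segs$end - segs$start)

    n_sp <- rpois(nseg * n_units, lambda)
    tot <- sum(n_sp)
    if (tot > 0) {
      seg_idx <- rep(seq_len(nseg * n_units), n_sp)
      seg_row <- (seg_idx - 1L) %% nseg + 1L
      unit_row <- (seg_idx - 1L) %/% nseg + 1L
      tt <- runif(tot) * (segs$end[seg_row] - segs$start[seg_row]) + segs$start[seg_row]
      spikes <- data.frame(unit_id = sprintf("u%03d", unit_row),
                           trial_id = trials$trial_id[segs$trial[seg_row]],
                           time_s = round(tt, 5))
    } else {
      spikes <- data.frame(unit_id = character(0), trial_id = character(0),
                           time_s = numeric(0))
    }

    units <- data.frame(unit_id = sprintf("u%03d", seq_len(n_units)),
                        area = area,
                        depth_mm = round(runif(n_units, 0, 2), 3),
                        kind = unit_specs$kind)
  })

  sess <- wm_session(units, trials, spikes, session_id = session_id,
                     epochs = epochs,
                     provenance = sprintf("synthetic, seed %d", seed))
  gt <- list(unit_specs = cbind(unit_id = units$unit_id, unit_specs),
             off_intervals = off_intervals,
             off_tuning_gain = off_g, seed = seed)
  structure(list(session = sess, ground_truth = gt), class = "wm_sim")
}

#' @export
print.wm_sim <- function(x, ...) {
  cat("<wm_sim> synthetic session with ground truth\n")
  print(x$session)
  cat(sprintf("  ground truth: %d off intervals, off_tuning_gain %.2f\n",
              nrow(x$ground_truth$off_intervals), x$ground_truth$off_tuning_gain))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Surrogate populations for the pooled-ISI silence test
# ---------------------------------------------------------------------------

#' Specify surrogate populations for silence-test validation
#'
#' Parameters follow the validation simulation of the pooled-ISI method:
#' population sizes uniform on 2--20 neurons, 10--20 trials of 3 s, per-neuron
#' rates discrete-uniform 1--20 Hz, and 1--3 coordinated 100 ms silent
#' periods per trial placed uniformly.
#'
#' @param n_neurons_range,n_trials_range integer ranges sampled uniformly.
#' @param trial_length trial length, seconds.
#' @param rate_range discrete-uniform per-neuron rate range, Hz.
#' @param silences_range silent periods per trial (integer range).
#' @param silence_length length of each silent period, seconds.
#' @param coordinated logical; share silence windows across neurons within a
#'   trial (the population-level silences the test targets)? Per-neuron
#'   independent silences are available by setting this `FALSE`.
#' @return list of class `silence_spec`.
#' @export
silence_spec <- function(n_neurons_range = c(2, 20), n_trials_range = c(10, 20),
                         trial_length = 3, rate_range = c(1, 20),
                         silences_range = c(1, 3), silence_length = 0.100,
                         coordinated = TRUE) {
  structure(as.list(environment()), class = "silence_spec")
}

## plain container for pooled-ISI analysis: list of per-unit, per-trial
## spike-time vectors (times within [0, trial_length) of each trial)
new_spike_population <- function(trains, trial_length) {
  structure(list(trains = trains, n_trials = length(trains[[1]]),
                 n_units = length(trains), trial_length = trial_length),
            class = "spike_population")
}

#' @export
print.spike_population <- function(x, ...) {
  cat(sprintf("<spike_population> %d units x %d trials of %g s, %d spikes\n",
              x$n_units, x$n_trials, x$trial_length,
              sum(lengths(unlist(x$trains, recursive = FALSE)))))
  invisible(x)
}

#' Simulate surrogate populations with and without coordinated silences
#'
#' Each population is homogeneous-Poisson spiking per neuron; the
#' `with_silence` version removes every spike falling inside the per-trial
#' silence windows (identical across neurons within a trial when
#' `coordinated`). Both versions share the same base spike trains so the two
#' conditions differ only by the imposed silences.
#'
#' @param n_populations number of populations (default 50).
#' @param spec a [silence_spec()].
#' @param seed integer seed.
#' @return list of populations; each has elements `without_silence` and
#'   `with_silence` (class `spike_population`), `silence_windows` (per trial,
#'   a 2-column matrix; for uncoordinated silences a list per neuron),
#'   `rates` (Hz per neuron), `n_trials`.
#' @export
simulate_silence_populations <- function(n_populations = 50,
                                         spec = silence_spec(), seed = 1) {
  stopifnot(inherits(spec, "silence_spec"))
  D <- spec$trial_length
  ## guard against sample()'s scalar expansion when a range collapses
  draw_int <- function(rng, n = 1) {
    v <- rng[1]:rng[2]
    if (length(v) == 1) rep(v, n) else sample(v, n, replace = TRUE)
  }
  with_seed(seed, {
    lapply(seq_len(n_populations), function(p) {
      nn <- draw_int(spec$n_neurons_range)
      nt <- draw_int(spec$n_trials_range)
      rates <- draw_int(spec$rate_range, nn)
      base <- lapply(seq_len(nn), function(u) {
        lapply(seq_len(nt), function(k) sort(runif(rpois(1, rates[u] * D)) * D))
      })
      draw_windows <- function() {
        k <- draw_int(spec$silences_range)
        on <- runif(k, 0, D - spec$silence_length)
        cbind(on, on + spec$silence_length)
      }
      if (spec$coordinated) {
        win <- lapply(seq_len(nt), function(k) draw_windows())
        silenced <- lapply(base, function(u_tr) {
          lapply(seq_len(nt), function(k) {
            t <- u_tr[[k]]
            w <- win[[k]]
            drop <- rep(FALSE, length(t))
            for (j in seq_len(nrow(w)))
              drop <- drop | (t >= w[j, 1] & t < w[j, 2])
            t[!drop]
          })
        })
      } else {
        win <- lapply(seq_len(nn), function(u) lapply(seq_len(nt), function(k) draw_windows()))
        silenced <- lapply(seq_len(nn), function(u) {
          lapply(seq_len(nt), function(k) {
            t <- base[[u]][[k]]
            w <- win[[u]][[k]]
            drop <- rep(FALSE, length(t))
            for (j in seq_len(nrow(w)))
              drop <- drop | (t >= w[j, 1] & t < w[j, 2])
            t[!drop]
          })
        })
      }
      list(without_silence = new_spike_population(base, D),
           with_silence = new_spike_population(silenced, D),
           silence_windows = win, rates = rates, n_trials = nt)
    })
  })
}

#' Split a session into per-area sessions
#'
#' Used for simultaneously recorded areas sharing the same trials: units and
#' spikes are partitioned by `area`, trials are kept identical.
#'
#' @param session a `wm_session`.
#' @return named list of `wm_session`, one per area present.
#' @export
split_session_by_area <- function(session) {
  areas <- unique(session$units$area)
  setNames(lapply(areas, function(a) {
    u <- session$units[session$units$area == a, , drop = FALSE]
    sp <- session$spikes[session$spikes$unit_id %in% u$unit_id, , drop = FALSE]
    wm_session(u, session$trials, sp,
               session_id = paste(session$session_id, a, sep = "_"),
               epochs = session$epochs,
               provenance = paste(session$provenance, "split", a))
  }), areas)
}
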