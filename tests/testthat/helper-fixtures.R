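# Shared fixtures, all generated in code.

units_df <- function(n, area = "PFC", depth = seq(0, 1.9, length.out = n),
                     kind = "single") {
  data.frame(unit_id = sprintf("u%02d", seq_len(n)), area = area,
             depth_mm = depth, kind = kind)
}

trials_df <- function(cues, correct = TRUE, rt = 250) {
  n <- length(cues)
  data.frame(trial_id = sprintf("t%03d", seq_len(n)), cue_location_deg = cues,
             correct = rep_len(correct, n), reaction_time_ms = rep_len(rt, n))
}

## deterministic session: unit u fires `rates[u, cue_index]` evenly spaced
## spikes/s throughout the given epoch, zero elsewhere
regular_session <- function(rates, trials_per_loc = 2, epoch = "delay") {
  cues <- rep(cue_angles(), each = trials_per_loc)
  tr <- trials_df(cues)
  un <- units_df(nrow(rates))
  ep <- default_epochs()[[epoch]]
  rows <- list()
  for (u in seq_len(nrow(rates))) {
    for (t in seq_len(nrow(tr))) {
      r <- rates[u, match(tr$cue_location_deg[t], cue_angles())]
      if (r > 0) {
        k <- round(r * (ep[2] - ep[1]))
        if (k > 0) {
          times <- ep[1] + (seq_len(k) - 0.5) / k * (ep[2] - ep[1])
          rows[[length(rows) + 1]] <-
            data.frame(unit_id = un$unit_id[u], trial_id = tr$trial_id[t],
                       time_s = times)
        }
      }
    }
  }
  sp <- if (length(rows)) do.call(rbind, rows)
        else data.frame(unit_id = character(0), trial_id = character(0),
                        time_s = numeric(0))
  wm_session(un, tr, sp, session_id = "fixture")
}

## hand-built rate_matrix around plain values (trials x units x windows)
make_rate_matrix <- function(values, cues, centers = NULL, width = 0.1,
                             step = 0.05, zscored = FALSE) {
  d <- dim(values)
  centers <- centers %||% (0.55 + step * (seq_len(d[3]) - 1))
  dimnames(values) <- list(sprintf("t%03d", seq_len(d[1])),
                           sprintf("u%02d", seq_len(d[2])),
                           sprintf("%.3f", centers))
  structure(values, window_centers = centers, window_width = width,
            window_step = step, zscored = zscored,
            cue_location_deg = cues, epoch = "delay",
            class = c("rate_matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_vec <- function(seed, expr) withr::with_seed(seed, expr)

## manual confidence_series / null_confidence pair for labeling-logic tests
make_confidence <- function(post, centers = NULL) {
  nt <- nrow(post); nw <- ncol(post)
  centers <- centers %||% (0.55 + 0.05 * (seq_len(nw) - 1))
  tid <- sprintf("t%03d", seq_len(nt))
  dimnames(post) <- list(tid, sprintf("%.3f", centers))
  structure(list(posterior = post, correct = (post > 0.5) * 1,
                 trial_ids = tid, labels = rep(c(0, 180), length.out = nt),
                 pair = c(0, 180), window_centers = centers,
                 trial_index = seq_len(nt)),
            class = "confidence_series")
}

make_null <- function(nt, nw, mean = 0.5, sd = 0.1, cluster_masses = 1,
                      centers = NULL, z_on = 1.64) {
  centers <- centers %||% (0.55 + 0.05 * (seq_len(nw) - 1))
  n_sh <- max(length(cluster_masses), 20)
  structure(list(null = array(mean, c(nt, nw, n_sh)),
                 mean = matrix(mean, nt, nw), sd = matrix(sd, nt, nw),
                 cluster_null = matrix(rep_len(cluster_masses, nt * n_sh),
                                       nt, n_sh),
                 z_on = z_on, n_shuffles = n_sh,
                 trial_ids = sprintf("t%03d", seq_len(nt)),
                 window_centers = centers, pair = c(0, 180)),
            class = "null_confidence")
}

## simple two-location tuned session used across decoding/state tests
diametric_sim <- function(n_units = 12, n_per_loc = 10, seed = 42,
                          schedule = NULL, gain = 4, kappa = 2,
                          baseline = 6, shared_gain_sd = 0) {
  simulate_tuned_session(
    n_units = n_units, n_trials_per_location = n_per_loc, seed = seed,
    unit_specs = tuned_unit_specs(n_units, baseline_rate = baseline,
                                  delay_gain = gain, kappa = kappa,
                                  preferred_angle = rep(c(90, 270),
                                                        length.out = n_units)),
    schedule = schedule, shared_gain_sd = shared_gain_sd,
    cue_locations = c(90, 270))
}
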