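#' Shuffled-label null distribution of decoder confidence
#'
#' Repeats the binary diametric classification `n_shuffles` times (default
#' 50), each time randomly permuting the training labels across trials,
#' giving for each trial a null distribution of confidence values over
#' windows. Also records, per shuffled series, the maximum cluster mass
#' (sum of z-values within a contiguous `z > z_on` run, z-scored against the
#' null mean/SD), which forms the family-wise cluster-mass null.
#'
#' @param rate_matrix a `rate_matrix`.
#' @param pair diametric cue pair.
#' @param n_shuffles number of label shuffles (default 50).
#' @param config a [decoder_config()].
#' @param windows window indices (default all; use the delay windows).
#' @param z_on cluster-forming threshold used for the mass null.
#' @param seed integer seed.
#' @return list of class `null_confidence`: `null` (trial x window x shuffle
#'   posterior array), `mean`, `sd` (trial x window), `cluster_null` (trial x
#'   shuffle max masses), `z_on`, `trial_ids`, `window_centers`, `pair`.
#' @export
build_null <- function(rate_matrix, pair, n_shuffles = 50,
                       config = decoder_config(), windows = NULL,
                       z_on = 1.64, seed = 1) {
  seeds <- derive_seeds(seed, n_shuffles)
  all_lab <- attr(rate_matrix, "cue_location_deg")
  keep <- which(all_lab %in% (sort(pair %% 360)))
  series <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    perm_lab <- all_lab
    perm_lab[keep] <- with_seed(seeds[s], sample(all_lab[keep]))
    cs <- binary_confidence(rate_matrix, pair, config = config,
                            windows = windows, training_labels = perm_lab,
                            seed = seeds[s])
    series[[s]] <- cs$posterior
  }
  arr <- array(unlist(series), dim = c(dim(series[[1]]), n_shuffles))
  mu <- apply(arr, c(1, 2), mean)
  sg <- apply(arr, c(1, 2), sd)
  ## z-score each shuffled series against the null and collect max cluster mass
  nt <- nrow(mu)
  cl_null <- matrix(0, nt, n_shuffles)
  for (s in seq_len(n_shuffles)) {
    z <- (arr[, , s] - mu) / ifelse(sg > 0, sg, NA)
    for (t in seq_len(nt))
      cl_null[t, s] <- max_cluster_mass(z[t, ], z_on)
  }
  structure(list(null = arr, mean = mu, sd = sg, cluster_null = cl_null,
                 z_on = z_on, n_shuffles = n_shuffles,
                 trial_ids = rownames(series[[1]]),
                 window_centers = as.numeric(colnames(series[[1]])),
                 pair = sort(pair %% 360)),
            class = "null_confidence")
}

## maximum sum-of-z mass over contiguous runs with z > threshold (NA breaks)
max_cluster_mass <- function(z, z_on) {
  flag <- !is.na(z) & z > z_on
  if (!any(flag)) return(0)
  runs <- logical_runs(flag)
  max(vapply(seq_len(nrow(runs)), function(r)
    sum(z[runs$start_idx[r]:runs$end_idx[r]]), numeric(1)))
}

#' Label on and off states from decoder confidence
#'
#' Confidence is z-scored per trial and window against the shuffled-label
#' null. Contiguous runs of `z > z_on` (1.64) form candidate clusters whose
#' mass (sum of z within the run) is compared to the 95th percentile of the
#' null distribution of per-series maximum cluster masses: clusters
#' exceeding it are on states. Maximal runs of `z < z_off` (0.3) lasting at
#' least `min_off_windows` (3) consecutive windows are off states. The
#' thresholds leave a gap (`z_off <= z <= z_on`), so remaining windows are
#' labeled neither. Windows with undefined z (null SD of 0) break both runs
#' and clusters and are labeled neither.
#'
#' @param confidence a `confidence_series` (same pair/grid as the null).
#' @param null a `null_confidence`.
#' @param z_on,z_off thresholds (defaults 1.64 and 0.3).
#' @param min_off_windows minimum off-run length in windows (default 3; with
#'   the 50 ms step this is a 150 ms minimum off duration).
#' @param cluster_null `"per_trial"` (each trial's own shuffle maxima) or
#'   `"pooled"` (maxima pooled over trials).
#' @return list of class `wm_states`: `states` (trial x window character
#'   matrix: "on"/"off"/"neither"), `z`, `on_clusters`, `off_runs`,
#'   `trial_ids`, `window_centers`.
#' @export
label_states <- function(confidence, null, z_on = 1.64, z_off = 0.3,
                         min_off_windows = 3, cluster_null = "per_trial") {
  stopifnot(inherits(confidence, "confidence_series"),
            inherits(null, "null_confidence"))
  if (!isTRUE(all.equal(confidence$window_centers, null$window_centers)) ||
      !identical(confidence$trial_ids, null$trial_ids))
    stop("confidence and null are not on the same trial/window grid")
  z <- (confidence$posterior - null$mean) / ifelse(null$sd > 0, null$sd, NA)
  nt <- nrow(z); nw <- ncol(z)
  states <- matrix("neither", nt, nw,
                   dimnames = list(confidence$trial_ids,
                                   colnames(confidence$posterior)))
  on_clusters <- off_runs <- NULL
  for (t in seq_len(nt)) {
    zt <- z[t, ]
    thr <- if (cluster_null == "pooled") quantile(null$cluster_null, 0.95)
           else quantile(null$cluster_null[t, ], 0.95)
    runs <- logical_runs(!is.na(zt) & zt > z_on)
    if (nrow(runs)) for (r in seq_len(nrow(runs))) {
      idx <- runs$start_idx[r]:runs$end_idx[r]
      mass <- sum(zt[idx])
      if (mass > thr) {
        states[t, idx] <- "on"
        on_clusters <- rbind(on_clusters,
                             data.frame(trial_id = confidence$trial_ids[t],
                                        start_idx = runs$start_idx[r],
                                        end_idx = runs$end_idx[r], mass = mass))
      }
    }
    offr <- logical_runs(!is.na(zt) & zt < z_off & states[t, ] != "on")
    if (nrow(offr)) for (r in seq_len(nrow(offr))) {
      if (offr$len[r] >= min_off_windows) {
        idx <- offr$start_idx[r]:offr$end_idx[r]
        states[t, idx] <- "off"
        off_runs <- rbind(off_runs,
                          data.frame(trial_id = confidence$trial_ids[t],
                                     start_idx = offr$start_idx[r],
                                     end_idx = offr$end_idx[r]))
      }
    }
  }
  structure(list(states = states, z = z,
                 on_clusters = on_clusters %||% data.frame(),
                 off_runs = off_runs %||% data.frame(),
                 trial_ids = confidence$trial_ids,
                 window_centers = confidence$window_centers),
            class = "wm_states")
}

#' @export
print.wm_states <- function(x, ...) {
  tab <- table(factor(x$states, levels = c("on", "off", "neither")))
  cat(sprintf("<wm_states> %d trials x %d windows: %.1f%% on, %.1f%% off, %.1f%% neither\n",
              nrow(x$states), ncol(x$states),
              100 * tab["on"] / sum(tab), 100 * tab["off"] / sum(tab),
              100 * tab["neither"] / sum(tab)))
  invisible(x)
}

#' Build state labels from a simulation's ground-truth off intervals
#'
#' Windows of the delay grid whose center falls inside a recorded off
#' interval are labeled off, all others on. Used to validate state-dependent
#' analyses independently of the decoding pipeline.
#'
#' @param sim a `wm_sim` from [simulate_tuned_session()].
#' @param window_width,window_step grid parameters (defaults 0.1 / 0.05).
#' @return A `wm_states` (with no z-scores).
#' @export
ground_truth_states <- function(sim, window_width = 0.100, window_step = 0.050) {
  stopifnot(inherits(sim, "wm_sim"))
  ses <- sim$session
  centers <- window_centers(ses$epochs$delay, window_width, window_step)
  tid <- ses$trials$trial_id
  states <- matrix("on", length(tid), length(centers),
                   dimnames = list(tid, sprintf("%.3f", centers)))
  iv <- sim$ground_truth$off_intervals
  if (nrow(iv)) for (r in seq_len(nrow(iv))) {
    t <- match(iv$trial_id[r], tid)
    states[t, centers >= iv$start[r] & centers < iv$end[r]] <- "off"
  }
  structure(list(states = states, z = NULL, on_clusters = data.frame(),
                 off_runs = data.frame(), trial_ids = tid,
                 window_centers = centers),
            class = "wm_states")
}

## rotate v (length 8) so that index `pref` lands on `center`
rotate_to_center <- function(v, pref, center = 5L) {
  n <- length(v)
  v[((seq_len(n) - 1 + (pref - center)) %% n) + 1]
}

#' State-conditioned, shuffle-debiased tuning functions
#'
#' For every unit, computes 8-element vectors of trial-averaged z-scored
#' firing rate per cue location over the windows labeled on and off. The
#' unit's preferred location is the cue maximizing the summed on+off vector;
#' both vectors are circularly rotated to place it at the center position.
#' Because this alignment itself produces a spurious peak, the identical
#' pipeline (group means, preferred location, rotation) is repeated for
#' `n_shuffles` cue-label permutations and the mean shuffled curves are
#' subtracted, giving debiased tuning functions whose expectation is flat
#' under the null. Tuning depth per state is the debiased curve's center
#' (peak) value minus its minimum.
#'
#' @param session a `wm_session`.
#' @param states a `wm_states` whose trials are (a subset of) the session's.
#' @param n_shuffles label shuffles for debiasing (default 1000).
#' @param seed integer seed.
#' @param rate_matrix optional precomputed z-scored delay `rate_matrix`.
#' @return list of class `state_tuning`: `on`, `off` (8 x units aligned raw
#'   vectors), `on_debiased`, `off_debiased`, `depth_on`, `depth_off` (per
#'   unit), `pref_index`, `positions` (relative cue offsets, deg), `unit_ids`.
#' @export
state_tuning <- function(session, states, n_shuffles = 1000, seed = 1,
                         rate_matrix = NULL) {
  stopifnot(inherits(states, "wm_states"))
  rm_ <- rate_matrix %||% bin_firing_rates(session, epoch = "delay", zscore = TRUE)
  tid <- intersect(dimnames(rm_)[[1]], states$trial_ids)
  if (!length(tid)) stop("no overlapping trials between session and states")
  ti_rm <- match(tid, dimnames(rm_)[[1]])
  ti_st <- match(tid, states$trial_ids)
  cue <- factor(attr(rm_, "cue_location_deg")[ti_rm], levels = cue_angles())
  nu <- dim(rm_)[2]; nt <- length(tid)

  ## per-trial mean z-rate over on / off windows: trials x units
  on_resp <- off_resp <- matrix(NA_real_, nt, nu)
  for (i in seq_len(nt)) {
    M <- rm_[ti_rm[i], , , drop = FALSE]
    dim(M) <- dim(rm_)[2:3]
    on_w <- states$states[ti_st[i], ] == "on"
    off_w <- states$states[ti_st[i], ] == "off"
    if (any(on_w)) on_resp[i, ] <- rowMeans(M[, on_w, drop = FALSE])
    if (any(off_w)) off_resp[i, ] <- rowMeans(M[, off_w, drop = FALSE])
  }

  group_means <- function(resp, labels) {
    ## 8 x units matrix of per-cue means ignoring NA trials
    ok <- !is.na(resp)
    num <- rowsum(ifelse(ok, resp, 0), labels)
    den <- rowsum(ok * 1, labels)
    out <- num / ifelse(den > 0, den, NA)
    out[match(levels(labels), rownames(num)), , drop = FALSE]
  }
  align_pair <- function(onv, offv) {
    ## returns list(on, off, pref) with both 8-vectors rotated per unit
    pref <- integer(ncol(onv))
    on_a <- onv; off_a <- offv
    for (u in seq_len(ncol(onv))) {
      s <- onv[, u] + offv[, u]
      if (all(is.na(s))) { pref[u] <- NA_integer_; next }
      pref[u] <- which.max(replace(s, is.na(s), -Inf))
      on_a[, u] <- rotate_to_center(onv[, u], pref[u])
      off_a[, u] <- rotate_to_center(offv[, u], pref[u])
    }
    list(on = on_a, off = off_a, pref = pref)
  }

  on_vec <- group_means(on_resp, cue)
  off_vec <- group_means(off_resp, cue)
  raw <- align_pair(on_vec, off_vec)

  seeds <- derive_seeds(seed, 1)
  acc_on <- acc_off <- matrix(0, 8, nu)
  cnt_on <- cnt_off <- matrix(0, 8, nu)
  with_seed(seeds[1], {
    for (s in seq_len(n_shuffles)) {
      perm <- sample(nt)
      sh <- align_pair(group_means(on_resp[perm, , drop = FALSE], cue),
                       group_means(off_resp[perm, , drop = FALSE], cue))
      okon <- !is.na(sh$on); okoff <- !is.na(sh$off)
      acc_on[okon] <- acc_on[okon] + sh$on[okon]
      acc_off[okoff] <- acc_off[okoff] + sh$off[okoff]
      cnt_on <- cnt_on + okon
      cnt_off <- cnt_off + okoff
    }
  })
  on_db <- raw$on - acc_on / ifelse(cnt_on > 0, cnt_on, NA)
  off_db <- raw$off - acc_off / ifelse(cnt_off > 0, cnt_off, NA)
  depth <- function(m) apply(m, 2, function(v)
    if (all(is.na(v))) NA_real_ else v[5] - min(v, na.rm = TRUE))
  positions <- ((0:7) - 4) * 45
  structure(list(on = raw$on, off = raw$off, on_debiased = on_db,
                 off_debiased = off_db, depth_on = depth(on_db),
                 depth_off = depth(off_db), pref_index = raw$pref,
                 positions = positions,
                 unit_ids = dimnames(rm_)[[2]], n_shuffles = n_shuffles),
            class = "state_tuning")
}

#' @export
print.state_tuning <- function(x, ...) {
  cat(sprintf("<state_tuning> %d units, %d debias shuffles\n",
              length(x$unit_ids), x$n_shuffles))
  cat(sprintf("  mean tuning depth: on %.3f, off %.3f (reduction %.1f%%)\n",
              mean(x$depth_on, na.rm = TRUE), mean(x$depth_off, na.rm = TRUE),
              100 * (1 - mean(x$depth_off, na.rm = TRUE) /
                       mean(x$depth_on, na.rm = TRUE))))
  invisible(x)
}

#' State-conditioned population firing-rate traces at the preferred cue
#'
#' For every unit, averages its firing rate across trials of its preferred
#' cue location restricted to on windows, off windows, and all windows, then
#' averages across units.
#'
#' @param session a `wm_session`.
#' @param states a `wm_states`.
#' @param preferred named vector mapping unit_id to preferred cue angle
#'   (defaults to the snapped circular-mean preferred locations).
#' @param rate_matrix optional precomputed delay `rate_matrix` (raw rates).
#' @return list of class `state_rate_traces`: `traces` (3 x windows matrix:
#'   on, off, all), `per_unit` (data.frame of scalar means), `window_centers`.
#' @export
population_rate_by_state <- function(session, states, preferred = NULL,
                                     rate_matrix = NULL) {
  rm_ <- rate_matrix %||% bin_firing_rates(session, epoch = "delay", zscore = FALSE)
  if (is.null(preferred)) {
    pl <- session_preferred_locations(session)
    preferred <- setNames(pl$snapped_cue, pl$unit_id)
  }
  tid <- intersect(dimnames(rm_)[[1]], states$trial_ids)
  ti_rm <- match(tid, dimnames(rm_)[[1]])
  ti_st <- match(tid, states$trial_ids)
  cue <- attr(rm_, "cue_location_deg")[ti_rm]
  nu <- dim(rm_)[2]; nw <- dim(rm_)[3]
  uids <- dimnames(rm_)[[2]]
  on_tr <- off_tr <- all_tr <- matrix(NA_real_, nu, nw)
  per_unit <- data.frame(unit_id = uids, on = NA_real_, off = NA_real_,
                         all = NA_real_)
  st <- states$states[ti_st, , drop = FALSE]
  for (u in seq_len(nu)) {
    pc <- preferred[uids[u]]
    if (is.na(pc)) next
    sel <- which(cue == pc)
    if (!length(sel)) next
    R <- rm_[ti_rm[sel], u, , drop = FALSE]
    dim(R) <- c(length(sel), nw)
    m_on <- ifelse(st[sel, , drop = FALSE] == "on", R, NA)
    m_off <- ifelse(st[sel, , drop = FALSE] == "off", R, NA)
    on_tr[u, ] <- colMeans(m_on, na.rm = TRUE)
    off_tr[u, ] <- colMeans(m_off, na.rm = TRUE)
    all_tr[u, ] <- colMeans(R)
    per_unit$on[u] <- mean(m_on, na.rm = TRUE)
    per_unit$off[u] <- mean(m_off, na.rm = TRUE)
    per_unit$all[u] <- mean(R)
  }
  traces <- rbind(on = colMeans(on_tr, na.rm = TRUE),
                  off = colMeans(off_tr, na.rm = TRUE),
                  all = colMeans(all_tr, na.rm = TRUE))
  structure(list(traces = traces, per_unit = per_unit,
                 window_centers = attr(rm_, "window_centers")),
            class = "state_rate_traces")
}

#' @export
print.state_rate_traces <- function(x, ...) {
  cat(sprintf("<state_rate_traces> mean rate at preferred cue: on %.2f, off %.2f, all %.2f sp/s\n",
              mean(x$per_unit$on, na.rm = TRUE),
              mean(x$per_unit$off, na.rm = TRUE),
              mean(x$per_unit$all, na.rm = TRUE)))
  invisible(x)
}

#' Cross-areal state evaluation
#'
#' States identified from one area's decoder confidence are used to evaluate
#' tuning and firing rate in the simultaneously recorded other area: if off
#' states are globally coordinated, the evaluated area's off-state tuning
#' depth is reduced even though its own activity played no part in labeling.
#'
#' @param eval_session `wm_session` of the evaluated area (same trials as
#'   the defining area's session).
#' @param states a `wm_states` labeled from the defining area.
#' @param min_units minimum units required in the evaluated area (default
#'   80, the requirement for cross-areal comparisons; lower it for small
#'   synthetic sessions via `check_min_units = FALSE`).
#' @param check_min_units enforce the unit-count requirement?
#' @param n_shuffles,seed passed to [state_tuning()].
#' @return list of class `cross_areal`: `tuning` (a `state_tuning`),
#'   `rates` (a `state_rate_traces`), `depth_change_pct` (mean percent
#'   reduction of off- vs on-state tuning depth).
#' @export
cross_areal_states <- function(eval_session, states, min_units = 80,
                               check_min_units = TRUE, n_shuffles = 200,
                               seed = 1) {
  if (check_min_units && nrow(eval_session$units) < min_units)
    stop(sprintf("evaluated area has %d units; >= %d required",
                 nrow(eval_session$units), min_units))
  tun <- state_tuning(eval_session, states, n_shuffles = n_shuffles, seed = seed)
  rts <- population_rate_by_state(eval_session, states)
  per_unit <- data.frame(unit_id = tun$unit_ids,
                         depth_change_pct = 100 * (1 - tun$depth_off /
                                                     tun$depth_on))
  dc <- 100 * (1 - mean(tun$depth_off, na.rm = TRUE) /
                 mean(tun$depth_on, na.rm = TRUE))
  structure(list(tuning = tun, rates = rts, depth_change_pct = dc,
                 per_unit = per_unit),
            class = "cross_areal")
}

#' @export
print.cross_areal <- function(x, ...) {
  cat(sprintf("<cross_areal> off-state tuning depth reduced by %.1f%% in the evaluated area\n",
              x$depth_change_pct))
  invisible(x)
}
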