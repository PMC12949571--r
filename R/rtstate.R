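#' Reaction time versus neural state at fixation offset
#'
#' For each session, trials are marked by whether the neural state in the
#' last delay window (fixation offset, the go cue) was on or off; trials
#' labeled neither are excluded as missing. A per-session linear model of RT
#' on the state indicator gives `beta_state = mean RT_on - mean RT_off`
#' (ms). Population-level inference accounts for session clustering by a
#' nonparametric bootstrap over sessions (`B` draws of sessions with
#' replacement, averaging their coefficients); the one-sided p-value is the
#' proportion of bootstrap means >= 0, so small p indicates shorter RTs in
#' the on state.
#'
#' @param session_states list; each element has `session` (a `wm_session`)
#'   and `states` (a `wm_states` covering its trials).
#' @param B bootstrap draws (default 10000).
#' @param seed integer seed.
#' @return list of class `rt_state_effect`: `beta` (per retained session),
#'   `excluded_sessions`, `boot_mean`, `p`, `B`.
#' @export
rt_state_effect <- function(session_states, B = 10000, seed = 1) {
  if (length(session_states) < 2) stop("need at least 2 sessions")
  betas <- c(); excluded <- c()
  for (ss in session_states) {
    ses <- ss$session; st <- ss$states
    last_w <- ncol(st$states)
    state_go <- st$states[, last_w]
    tr <- ses$trials[match(st$trial_ids, ses$trials$trial_id), , drop = FALSE]
    keep <- state_go %in% c("on", "off") & !is.na(tr$reaction_time_ms)
    if (length(unique(state_go[keep])) < 2) {
      excluded <- c(excluded, ses$session_id)
      next
    }
    s01 <- as.integer(state_go[keep] == "on")
    fit <- lm(tr$reaction_time_ms[keep] ~ s01)
    b <- unname(coef(fit)[2])
    if (abs(b) < 1e-10) b <- 0   # guard the p >= 0 rule against QR noise
    betas <- c(betas, setNames(b, ses$session_id))
  }
  if (!length(betas)) stop("no session has both states at fixation offset")
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b)
      mean(betas[sample.int(length(betas), replace = TRUE)]), numeric(1))
  })
  structure(list(beta = betas, excluded_sessions = excluded,
                 boot_mean = mean(boot), p = mean(boot >= 0), B = B),
            class = "rt_state_effect")
}

#' @export
print.rt_state_effect <- function(x, ...) {
  cat(sprintf("<rt_state_effect> %d sessions (%d excluded), B = %d\n",
              length(x$beta), length(x$excluded_sessions), x$B))
  cat(sprintf("  mean beta_state (RT_on - RT_off) = %.2f ms; one-sided p(mean >= 0) = %.4f\n",
              mean(x$beta), x$p))
  invisible(x)
}

## number of distinct state segments of `what` intersecting window indices idx
count_states_in <- function(state_row, idx, what) {
  r <- rle(state_row)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  sum(r$values == what & starts <= max(idx) & ends >= min(idx))
}

#' On/off state counts in correct versus error trials
#'
#' Per session, the overall preferred cue is the location with the greatest
#' mean delay classification confidence (least-preferred the smallest).
#' Counts the on and off state segments occurring in the last 0.5 s of the
#' delay period per trial, averaged per session cell of (outcome x cue
#' preference x state), and runs a three-way ANOVA with all interactions on
#' the session-level cell means.
#'
#' @param session_data list; each element has `states` (a `wm_states` on the
#'   delay grid), `confidence` (a `confidence_series` or list of them, used
#'   to rank cue locations by mean delay confidence), `trials` (data.frame
#'   with `trial_id`, `cue_location_deg`, `correct`), and `session_id`.
#' @param last_s length of the end-of-delay window (default 0.5 s).
#' @return list of class `state_counts`: `cells` (session-level mean counts
#'   per cell), `anova` (the `aov` fit), `anova_table`.
#' @export
state_counts_by_outcome <- function(session_data, last_s = 0.5) {
  cells <- NULL
  for (sd_ in session_data) {
    st <- sd_$states
    tr <- sd_$trials
    conf_list <- if (inherits(sd_$confidence, "confidence_series"))
      list(sd_$confidence) else sd_$confidence
    ## mean delay confidence per cue location
    cue_conf <- c()
    for (cs in conf_list) {
      for (loc in cs$pair) {
        rowsel <- cs$labels == loc
        if (any(rowsel))
          cue_conf[as.character(loc)] <- mean(cs$posterior[rowsel, , drop = FALSE])
      }
    }
    pref <- as.numeric(names(cue_conf)[which.max(cue_conf)])
    nonpref <- as.numeric(names(cue_conf)[which.min(cue_conf)])
    ctr <- st$window_centers
    idx <- which(ctr >= max(ctr) - last_s + 1e-9)
    tr <- tr[match(st$trial_ids, tr$trial_id), , drop = FALSE]
    for (outcome in c("correct", "error")) {
      for (pcls in c("preferred", "nonpreferred")) {
        loc <- if (pcls == "preferred") pref else nonpref
        sel <- which(tr$cue_location_deg == loc &
                     tr$correct == (outcome == "correct"))
        for (state in c("on", "off")) {
          cnt <- if (length(sel))
            mean(vapply(sel, function(i)
              count_states_in(st$states[i, ], idx, state), numeric(1)))
          else NA_real_
          cells <- rbind(cells,
                         data.frame(session_id = sd_$session_id,
                                    outcome = outcome, preference = pcls,
                                    state = state, mean_count = cnt))
        }
      }
    }
  }
  cc <- cells[complete.cases(cells), , drop = FALSE]
  if (any(is.na(cells$mean_count)))
    warning("empty cells dropped; the three-way ANOVA is degraded")
  fit <- aov(mean_count ~ outcome * preference * state, data = cc)
  structure(list(cells = cells, anova = fit,
                 anova_table = summary(fit)[[1]]),
            class = "state_counts")
}

#' @export
print.state_counts <- function(x, ...) {
  cat(sprintf("<state_counts> %d session-level cells\n", nrow(x$cells)))
  print(x$anova_table)
  invisible(x)
}
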