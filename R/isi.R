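#' Enumerate candidate co-tuned populations across sessions
#'
#' One candidate population exists per (session, cue location) pair; a
#' candidate is retained iff at least `n_min` delay-selective units of that
#' session share the location as their preferred cue (circular-mean preferred
#' angle snapped to the nearest of the 8 cues).
#'
#' @param sessions a `wm_session` or list of them.
#' @param n_min minimum number of co-tuned selective units (default 5).
#' @param alpha,min_rate selectivity criteria, see [test_selectivity()].
#' @return data.frame of class `wm_populations`: one row per candidate with
#'   `session_id`, `cue_location_deg`, `n_units`, `retained` and a list
#'   column `member_units`.
#' @export
select_populations <- function(sessions, n_min = 5, alpha = 0.05, min_rate = 2) {
  if (inherits(sessions, "wm_session")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    sel <- test_selectivity(s, epoch = "delay", alpha = alpha, min_rate = min_rate)
    pref <- session_preferred_locations(s, epoch = "delay")
    ok <- sel$is_selective & pref$defined[match(sel$unit_id, pref$unit_id)]
    snapped <- pref$snapped_cue[match(sel$unit_id, pref$unit_id)]
    lapply(cue_angles(), function(loc) {
      members <- sel$unit_id[ok & !is.na(snapped) & snapped == loc]
      data.frame(session_id = s$session_id, cue_location_deg = loc,
                 n_units = length(members),
                 retained = length(members) >= n_min,
                 member_units = I(list(members)))
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  class(out) <- c("wm_populations", "data.frame")
  out
}

#' Extract a population's delay-period spike trains from a session
#'
#' @param session a `wm_session`.
#' @param unit_ids member units.
#' @param trial_ids trials to include (default all; pass the correct-trial
#'   subset to restrict the analysis to correct trials).
#' @return A `spike_population` with delay-relative spike times.
#' @export
population_from_session <- function(session, unit_ids, trial_ids = NULL) {
  delay <- session$epochs$delay
  D <- delay[2] - delay[1]
  trial_ids <- trial_ids %||% session$trials$trial_id
  sp <- epoch_spikes(session, "delay", unit_ids = unit_ids, trial_ids = trial_ids)
  trains <- lapply(unit_ids, function(u) {
    su <- sp[sp$unit_id == u, , drop = FALSE]
    lapply(trial_ids, function(tr) {
      sort(su$time_s[su$trial_id == tr]) - delay[1]
    })
  })
  new_spike_population(trains, D)
}

#' Pooled ISIs of a co-tuned population over concatenated delay periods
#'
#' Trial k's delay period is mapped to the contiguous span
#' `[(k-1) D, k D)`; all member units' spikes are pooled and sorted, and
#' successive differences give the ISI distribution. The maximum pooled ISI
#' and the pooled rate (total spikes over total pooled duration) are the two
#' statistics of the coordinated-silence test. ISIs spanning trial
#' boundaries are retained on the contiguous pooled timeline by default.
#'
#' @param population a `spike_population`.
#' @param exclude_boundary drop ISIs whose endpoints lie in different trial
#'   slots (sensitivity analysis)?
#' @return list of class `pooled_isi`: `max_isi` (s; `NA` with
#'   `excluded = TRUE` if the pooled stream has fewer than 2 spikes),
#'   `freq` (spikes/s), `n_spikes`, `duration` (s), `isis`.
#' @export
pool_population_isis <- function(population, exclude_boundary = FALSE) {
  stopifnot(inherits(population, "spike_population"))
  D <- population$trial_length
  nt <- population$n_trials
  pooled <- unlist(lapply(population$trains, function(u_tr) {
    unlist(lapply(seq_len(nt), function(k) u_tr[[k]] + (k - 1) * D))
  }))
  pooled <- sort(pooled)
  n <- length(pooled)
  dur <- nt * D
  if (n < 2) {
    return(structure(list(max_isi = NA_real_, freq = n / dur, n_spikes = n,
                          duration = dur, isis = numeric(0), excluded = TRUE,
                          reason = "fewer than 2 pooled spikes"),
                     class = "pooled_isi"))
  }
  isis <- diff(pooled)
  if (exclude_boundary) {
    slot <- floor(pooled / D)
    isis <- isis[slot[-n] == slot[-1]]
  }
  structure(list(max_isi = if (length(isis)) max(isis) else NA_real_,
                 freq = n / dur, n_spikes = n, duration = dur, isis = isis,
                 excluded = length(isis) == 0,
                 reason = if (length(isis)) NA_character_ else "no within-trial ISIs"),
            class = "pooled_isi")
}

#' @export
print.pooled_isi <- function(x, ...) {
  cat(sprintf("<pooled_isi> %d spikes over %.1f s: rate %.3f sp/s, max ISI %.4f s\n",
              x$n_spikes, x$duration, x$freq, x$max_isi))
  invisible(x)
}

#' Trial-shuffle null for the pooled maximum ISI
#'
#' Each iteration independently permutes, for every member unit, the
#' assignment of that unit's spike trains to trial slots (a permutation
#' without replacement, preserving each unit's trial multiset and hence the
#' total spike count and rate exactly), rebuilds the pooled stream, and
#' records the maximum ISI. Breaking trial-specific coordination this way
#' removes any population-level silences while leaving single-train
#' statistics intact.
#'
#' @param population a `spike_population` with >= 2 trials.
#' @param n_iter number of shuffle iterations (default 10000).
#' @param seed integer seed.
#' @return list of class `isi_null`: `max_isi` (length `n_iter`), `freq`
#'   (constant, spike count is conserved), `n_iter`, `seed`.
#' @export
shuffle_null <- function(population, n_iter = 10000, seed = 1) {
  stopifnot(inherits(population, "spike_population"))
  if (population$n_trials < 2)
    stop("trial shuffling requires at least 2 trials")
  nt <- population$n_trials
  nu <- length(population$trains)
  D <- population$trial_length
  lens <- unlist(lapply(population$trains, lengths), use.names = FALSE)
  time <- unlist(population$trains, recursive = TRUE, use.names = FALSE) %||%
    numeric(0)
  unit <- rep(rep(seq_len(nu) - 1L, each = nt), lens)
  trial <- rep(rep(seq_len(nt) - 1L, nu), lens)
  mx <- with_seed(seed, cpp_shuffle_max_isi(time, unit, trial, nu, nt, D,
                                            as.integer(n_iter)))
  structure(list(max_isi = mx, freq = rep(length(time) / (nt * D), n_iter),
                 n_iter = n_iter, seed = seed),
            class = "isi_null")
}

## least-squares line on log10 axes; x = rate, y = max ISI
loglog_fit <- function(freq, max_isi) {
  x <- log10(freq); y <- log10(max_isi)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  vx <- sum((x - mean(x))^2)
  if (vx <= 0) stop("zero variance in log10(rate): fit undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / vx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (sum((y - mean(y))^2) > 0)
    slope^2 * vx / sum((y - mean(y))^2) else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2, n = length(x))
}

#' Fit the log-log maxISI-rate relation and test the empirical slope
#'
#' Across populations, fits `log10(max ISI) ~ log10(rate)` for the empirical
#' data and, per shuffle iteration, for the null (each population
#' contributing its i-th shuffled value), giving a null distribution of
#' slopes and intercepts. Coordinated silences lengthen the maximum ISI
#' independently of rate and therefore flatten the empirical slope relative
#' to the null; the default one-sided test (`tail = "shallower"`) counts
#' null slopes >= the empirical slope, with the add-one convention
#' `p = (1 + #extreme) / (1 + n_iter)`. Use `tail = "steeper"` to test the
#' opposite direction (more regular, delay-tiling firing).
#'
#' @param pooled list of [pool_population_isis()] results.
#' @param nulls list of [shuffle_null()] results, same order.
#' @param tail `"shallower"` or `"steeper"`.
#' @return list of class `isi_slope_test`: `empirical` (slope, intercept,
#'   r2, n), `null_slopes`, `null_intercepts`, `p`, `tail`, `n_populations`.
#' @export
fit_and_test <- function(pooled, nulls, tail = c("shallower", "steeper")) {
  tail <- match.arg(tail)
  ok <- vapply(pooled, function(p) is.finite(p$max_isi), logical(1))
  pooled <- pooled[ok]; nulls <- nulls[ok]
  if (length(pooled) < 3)
    stop("need at least 3 populations with a defined maximum ISI")
  freq <- vapply(pooled, `[[`, numeric(1), "freq")
  maxe <- vapply(pooled, `[[`, numeric(1), "max_isi")
  emp <- loglog_fit(freq, maxe)
  n_iter <- nulls[[1]]$n_iter
  null_max <- vapply(nulls, `[[`, numeric(n_iter), "max_isi")   # iter x pop
  null_freq <- vapply(nulls, `[[`, numeric(n_iter), "freq")
  lx <- log10(null_freq)
  ly <- log10(null_max)
  mx <- rowMeans(lx); my <- rowMeans(ly)
  vx <- rowSums((lx - mx)^2)
  slopes <- rowSums((lx - mx) * (ly - my)) / vx
  intercepts <- my - slopes * mx
  n_extreme <- switch(tail,
                      shallower = sum(slopes >= emp$slope),
                      steeper = sum(slopes <= emp$slope))
  p <- (1 + n_extreme) / (1 + n_iter)
  structure(list(empirical = emp, null_slopes = slopes,
                 null_intercepts = intercepts, p = p, tail = tail,
                 n_populations = length(pooled), n_iter = n_iter),
            class = "isi_slope_test")
}

#' @export
print.isi_slope_test <- function(x, ...) {
  cat(sprintf("<isi_slope_test> %d populations, %d shuffle iterations\n",
              x$n_populations, x$n_iter))
  cat(sprintf("  empirical slope %.4f (intercept %.4f, R^2 %.3f)\n",
              x$empirical$slope, x$empirical$intercept, x$empirical$r2))
  cat(sprintf("  null slope mean %.4f [%.4f, %.4f] (2.5th/97.5th pct)\n",
              mean(x$null_slopes), quantile(x$null_slopes, 0.025),
              quantile(x$null_slopes, 0.975)))
  cat(sprintf("  one-sided p (%s) = %.4g\n", x$tail, x$p))
  invisible(x)
}

#' Run the coordinated-silence ISI test on a set of populations
#'
#' Convenience wrapper: pools each population's delay spikes, builds its
#' trial-shuffle null, and fits/tests the log-log slope.
#'
#' @param populations list of `spike_population`.
#' @param n_iter shuffle iterations per population.
#' @param seed integer seed.
#' @param tail see [fit_and_test()].
#' @return An `isi_slope_test`.
#' @export
isi_silence_test <- function(populations, n_iter = 10000, seed = 1,
                             tail = "shallower") {
  seeds <- derive_seeds(seed, length(populations))
  pooled <- lapply(populations, pool_population_isis)
  nulls <- lapply(seq_along(populations), function(i)
    shuffle_null(populations[[i]], n_iter = n_iter, seed = seeds[i]))
  fit_and_test(pooled, nulls, tail = tail)
}
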